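#' Split samples into expression-extreme groups for one miRNA
#'
#' Assigns each clinical sample to the under-expressed group (expression at
#' or below the `fraction` empirical quantile of that miRNA's values), the
#' over-expressed group (at or above the `1 - fraction` quantile), or
#' `excluded`. Quantiles are nearest-rank: the k-th smallest / largest value
#' with k = ceiling(fraction * n); ties at a boundary are all included. If
#' tied values make the two groups overlap the input is degenerate and an
#' error is raised.
#'
#' @param exprRow named numeric vector, one miRNA's expression by sample id.
#' @param clinical clinical data.frame (see [readClinical()]).
#' @param fraction extreme fraction per tail, default 0.10.
#' @return named character vector over clinical samples with values
#'   `"under"`, `"over"`, `"excluded"`.
#' @export
splitExtremes <- function(exprRow, clinical, fraction = 0.10) {
  stopifnot(fraction > 0, fraction < 0.5)
  common <- intersect(names(exprRow), clinical$sample_id)
  if (length(common) < 10L)
    stop("need at least 10 samples with clinical records")
  x <- exprRow[common]
  n <- length(x)
  k <- ceiling(fraction * n)
  s <- sort(x)
  lowThr <- s[k]
  highThr <- s[n - k + 1L]
  under <- x <= lowThr
  over <- x >= highThr
  if (any(under & over))
    stop("degenerate expression values: extreme groups overlap")
  grp <- rep("excluded", n)
  grp[under] <- "under"
  grp[over] <- "over"
  stats::setNames(grp, common)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step function as
#' a table. Censored subjects leave the risk set without contributing a
#' death factor; the curve starts at 1 and is non-increasing.
#'
#' @param time numeric survival times (days).
#' @param event 0/1 event indicator (1 = death).
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` (one row per
#'   observed time point).
#' @export
kaplanMeier <- function(time, event) {
  if (!length(time)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on 1 degree of freedom comparing the
#' survival distributions of two groups, via [survival::survdiff()].
#'
#' @param timeA,eventA times and 0/1 events for group A.
#' @param timeB,eventB times and 0/1 events for group B.
#' @return list with `statistic` (chi-square) and `p`.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  if (!length(timeA) || !length(timeB)) stop("empty group")
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c("A", "B"), c(length(timeA), length(timeB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- unname(sd$chisq)
  list(statistic = stat, p = stats::pchisq(stat, df = 1L,
                                           lower.tail = FALSE))
}

#' Survival analysis for one miRNA
#'
#' Splits clinical samples by expression extremes ([splitExtremes()]),
#' estimates a Kaplan-Meier curve per group and tests the difference with
#' the log-rank test.
#'
#' @param dataset a [PairedDataset-class] with clinical records.
#' @param mirnaId miRNA id in the dataset.
#' @param fraction extreme fraction per tail, default 0.10.
#' @return list with `mirna`, `groups`, `km_under`, `km_over`, `n_under`,
#'   `n_over`, `statistic`, `p`.
#' @export
mirnaSurvival <- function(dataset, mirnaId, fraction = 0.10) {
  cl <- clinicalData(dataset)
  if (!nrow(cl)) stop("dataset has no clinical records")
  mi <- mirnaExprs(dataset)
  if (!mirnaId %in% rownames(mi)) stop("miRNA not in dataset: ", mirnaId)
  grp <- splitExtremes(mi[mirnaId, ], cl, fraction)
  cl <- cl[match(names(grp), cl$sample_id), ]
  u <- grp == "under"
  o <- grp == "over"
  if (!any(u) || !any(o)) stop("empty extreme group")
  lr <- logrankTest(cl$time[u], cl$event[u], cl$time[o], cl$event[o])
  list(mirna = mirnaId, groups = grp,
       km_under = kaplanMeier(cl$time[u], cl$event[u]),
       km_over = kaplanMeier(cl$time[o], cl$event[o]),
       n_under = sum(u), n_over = sum(o),
       statistic = lr$statistic, p = lr$p)
}

#' Survival screen over the top-ranked miRNAs
#'
#' @param result an [IntegrationResult-class], or a character vector of
#'   miRNA ids already in ranked order.
#' @param dataset the corresponding [PairedDataset-class] with clinical
#'   records.
#' @param top number of top-ranked miRNAs to screen, default 100.
#' @param fraction extreme fraction per tail, default 0.10.
#' @return data.frame `mirna`, `n_under`, `n_over`, `logrank_stat`, `p`,
#'   in ranking order.
#' @export
survivalScreen <- function(result, dataset, top = 100L, fraction = 0.10) {
  ids <- if (is.character(result)) result else rankedIds(result)
  ids <- utils::head(ids, top)
  rows <- lapply(ids, function(id) {
    s <- mirnaSurvival(dataset, id, fraction)
    data.frame(mirna = id, n_under = s$n_under, n_over = s$n_over,
               logrank_stat = s$statistic, p = s$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
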