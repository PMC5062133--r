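#' Cumulative annotation-ratio curve
#'
#' For a ranked miRNA list and a disease-annotation set, computes at every
#' cutoff k the fraction of the top k miRNAs that are annotated. A ranking
#' enriched for known disease miRNAs shows a high curve at small k decaying
#' toward the overall annotation rate.
#'
#' @param rankedIds character vector, best candidate first, duplicate-free.
#' @param annotatedIds character vector of annotated miRNA ids (or the list
#'   returned by [readAnnotation()]).
#' @return data.frame with columns `k`, `count`, `ratio`.
#' @export
cumulativeRatio <- function(rankedIds, annotatedIds) {
  if (is.list(annotatedIds)) annotatedIds <- annotatedIds$mirnaIds
  if (anyDuplicated(rankedIds)) stop("duplicates in ranked list")
  hit <- rankedIds %in% annotatedIds
  k <- seq_along(rankedIds)
  data.frame(k = k, count = cumsum(hit), ratio = cumsum(hit) / k)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `x` annotated miRNAs in a top list of
#' size `n` drawn from a universe of `M` miRNAs of which `K` are annotated:
#' p = P(X >= x), X ~ Hypergeometric(M, K, n). Evaluated in log space so
#' p-values far below 1e-40 remain finite and positive.
#'
#' @param M universe size.
#' @param K annotated miRNAs in the universe.
#' @param n top-list size (n <= M).
#' @param x annotated miRNAs observed in the top list (x <= min(K, n)).
#' @return data.frame row with `M`, `K`, `n`, `x`, `p`, `log10_p`.
#' @export
hypergeomOverlap <- function(M, K, n, x) {
  stopifnot(length(M) == 1L, M >= 0, K >= 0, n >= 0, x >= 0)
  if (n > M || K > M) stop("n and K must not exceed M")
  if (x > min(K, n)) stop("x must not exceed min(K, n)")
  logp <- stats::phyper(x - 1, K, M - K, n, lower.tail = FALSE,
                        log.p = TRUE)
  data.frame(M = M, K = K, n = n, x = x, p = exp(logp),
             log10_p = logp / log(10))
}

#' Differential-expression t-test baseline ranking
#'
#' The standard comparison method: per-miRNA two-sample Welch t-test of
#' tumor vs normal expression, with miRNAs ranked by ascending p-value.
#'
#' @param tumor,normal numeric matrices (miRNAs x samples) sharing row ids;
#'   each group needs >= 2 samples.
#' @return data.frame `mirna`, `t`, `p`, `rank`, sorted by rank (smallest p
#'   first; ties broken lexicographically).
#' @export
deTTestRank <- function(tumor, normal) {
  ids <- intersect(rownames(tumor), rownames(normal))
  if (!length(ids)) stop("no shared miRNA ids between groups")
  if (ncol(tumor) < 2L || ncol(normal) < 2L)
    stop("each group needs at least 2 samples")
  x <- tumor[ids, , drop = FALSE]
  y <- normal[ids, , drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 == 0,
                  ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
                  (m1 - m2) / sqrt(se2))
  df <- ifelse(se2 == 0, n1 + n2 - 2,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) +
                        v2^2 / (n2^2 * (n2 - 1))))
  p <- ifelse(se2 == 0 & m1 == m2, 1,
              2 * stats::pt(-abs(tstat), df))
  rk <- integer(length(ids))
  rk[order(p, ids)] <- seq_along(ids)
  out <- data.frame(mirna = ids, t = tstat, p = p, rank = rk,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$rank), ]
}
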