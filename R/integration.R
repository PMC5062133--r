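#' Ranking ratios of a feature vector
#'
#' Ranks the values in the requested direction (rank 1 = best for that
#' direction, i.e. the largest value when `direction = "descending"`), with
#' tied values receiving the average of their ranks, and divides by the
#' number of entries M. Ratios therefore lie in (0, 1]: the top value gets
#' 1/M, the bottom value 1. For tie-free data the descending and ascending
#' ratios of the same entry sum to (M + 1)/M.
#'
#' @param values numeric vector, length M >= 1.
#' @param direction `"descending"` (large is good) or `"ascending"`.
#' @return numeric vector of ranking ratios in (0, 1].
#' @export
rankingRatio <- function(values, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (!length(values)) stop("empty value vector")
  M <- length(values)
  r <- if (direction == "descending") rank(-values, ties.method = "average")
       else rank(values, ties.method = "average")
  r / M
}

#' Joint order-statistics Q statistic
#'
#' Probability that the order statistics of N independent Uniform(0,1)
#' variables satisfy \eqn{U_{(k)} \le r_{(k)}} for all k, where
#' \eqn{r_{(1)} \le \dots \le r_{(N)}} are the supplied ratios sorted
#' ascending. Computed with the recursive solution of Stuart et al. (2003):
#' \deqn{V_0 = 1,\quad
#'   V_k = \sum_{i=1}^{k} (-1)^{i-1}\, V_{k-i}\, \frac{r_{(N-k+1)}^i}{i!},
#'   \quad Q = N!\, V_N.}
#' A miRNA ranking uniformly well on all features (all ratios small) gets a
#' small Q. Closed forms used in validation: N = 1 gives r, N = 2 gives
#' \eqn{2 r_1 r_2 - r_1^2}, and equal ratios give \eqn{r^N}.
#'
#' @param ratios numeric vector of N ranking ratios in [0, 1] (any order).
#' @return Q in [0, 1].
#' @export
qStatistic <- function(ratios) {
  if (!length(ratios)) stop("empty ratio vector")
  if (anyNA(ratios) || any(ratios < 0 | ratios > 1))
    stop("ratios must lie in [0, 1]")
  r <- sort(ratios)
  N <- length(r)
  V <- numeric(N + 1L)
  V[1L] <- 1
  for (k in seq_len(N)) {
    i <- seq_len(k)
    V[k + 1L] <- sum((-1)^(i - 1) * V[k - i + 1L] *
                       r[N - k + 1L]^i / factorial(i))
  }
  min(1, max(0, factorial(N) * V[N + 1L]))
}

# Row-wise Q over a matrix of ratios (one row per miRNA).
qStatisticRows <- function(ratioMat) {
  apply(ratioMat, 1L, qStatistic)
}

#' Bidirectional order-statistics integration of the three features
#'
#' The core prioritization. Each feature (a, c, t) is converted to ranking
#' ratios twice: descending (`RD`, relevance: large feature values get small
#' ratios) and ascending (`RI`, irrelevance). Per miRNA, `Q1` is the
#' [qStatistic()] of its three RD ratios and `Q2` that of its three RI
#' ratios. `Q1` is ranked ascending into `RQ1` (small Q1 = uniformly strong
#' candidate); `Q2` is ranked descending into `RQ2` (large Q2 = little
#' evidence of irrelevance). The final score is `RQ = RQ1 + RQ2`, ranked
#' ascending; using both directions penalizes miRNAs that owe a good Q1 to
#' a single dominant feature. Ties in `RQ1`/`RQ2` receive average ranks;
#' the final permutation breaks `RQ` ties by smaller `RQ1`, then
#' lexicographic miRNA id.
#'
#' @param features a [FeatureTable-class] with M >= 2 miRNAs.
#' @return an [IntegrationResult-class].
#' @export
integrateRanks <- function(features) {
  M <- length(features@mirna)
  if (M < 2L) stop("need at least 2 miRNAs to integrate")
  feats <- cbind(features@a, features@c, features@t)
  rd <- apply(feats, 2L, rankingRatio, direction = "descending")
  ri <- apply(feats, 2L, rankingRatio, direction = "ascending")
  q1 <- qStatisticRows(rd)
  q2 <- qStatisticRows(ri)
  rq1 <- rank(q1, ties.method = "average")
  rq2 <- rank(-q2, ties.method = "average")
  rq <- rq1 + rq2
  finalRank <- integer(M)
  finalRank[order(rq, rq1, features@mirna)] <- seq_len(M)
  methods::new("IntegrationResult", mirna = features@mirna,
               q1 = q1, q2 = q2, rq1 = rq1, rq2 = rq2, rq = rq,
               finalRank = finalRank)
}

#' Baseline integrator: (weighted) average of descending ranking ratios
#'
#' Score = sum(w_k * RD_k) / sum(w_k), ranked ascending (small mean ratio =
#' strong candidate). With the default equal weights this is the plain
#' average-ranking-ratio baseline; degenerate weights such as `c(1, 0, 0)`
#' reduce it to a single-feature ranking.
#'
#' @param features a [FeatureTable-class].
#' @param weights three positive-or-zero weights (not all zero) for
#'   (a, c, t).
#' @return data.frame `mirna`, `score`, `rank`, sorted by rank.
#' @export
integrateAverageRatio <- function(features, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  feats <- cbind(features@a, features@c, features@t)
  rd <- apply(feats, 2L, rankingRatio, direction = "descending")
  score <- as.numeric(rd %*% weights) / sum(weights)
  rk <- integer(length(score))
  rk[order(score, features@mirna)] <- seq_along(score)
  out <- data.frame(mirna = features@mirna, score = score, rank = rk,
                    stringsAsFactors = FALSE)
  out[order(out$rank), ]
}

#' Baseline integrator: inverse-normal (z-score) combination
#'
#' Each feature's descending rank is mapped to the open interval via
#' u = (rank - 0.5)/M and then to a z-score z = qnorm(1 - u), so the top
#' rank gets a large positive z; the three z-scores are averaged and miRNAs
#' are ranked by decreasing mean z.
#'
#' @param features a [FeatureTable-class].
#' @return data.frame `mirna`, `z`, `rank`, sorted by rank.
#' @export
integrateInverseNormal <- function(features) {
  M <- length(features@mirna)
  feats <- cbind(features@a, features@c, features@t)
  z <- apply(feats, 2L, function(v) {
    u <- (rank(-v, ties.method = "average") - 0.5) / M
    stats::qnorm(1 - u)
  })
  mz <- rowMeans(z)
  rk <- integer(M)
  rk[order(-mz, features@mirna)] <- seq_len(M)
  out <- data.frame(mirna = features@mirna, z = mz, rank = rk,
                    stringsAsFactors = FALSE)
  out[order(out$rank), ]
}

#' Serialize an integration result (with its features) as TSV
#'
#' Columns: mirna, a, c, t, q1, q2, rq1, rq2, rq, final_rank.
#'
#' @param result an [IntegrationResult-class].
#' @param features the [FeatureTable-class] it came from.
#' @param path output path.
#' @export
writeIntegrationResult <- function(result, features, path) {
  stopifnot(identical(result@mirna, features@mirna))
  df <- cbind(as.data.frame(features),
              as.data.frame(result)[, -1L, drop = FALSE])
  for (col in c("a", "c", "q1", "q2"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(df[order(df$final_rank), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
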