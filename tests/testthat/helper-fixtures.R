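# Shared fixture builders. Everything is generated in code; tests that need
# files write them into withr-style tempdirs via these helpers.

# Tiny paired dataset with hand-controllable values.
makeToyDataset <- function(mirna, genes, clinical = NULL) {
  alignPaired(mirna, genes, clinical)
}

# Random paired dataset (no planted structure) for property tests.
randomDataset <- function(nMirna = 5L, nGene = 8L, nSample = 7L,
                          seed = 1L) {
  set.seed(seed)
  mi <- matrix(rnorm(nMirna * nSample, 5), nrow = nMirna,
               dimnames = list(sprintf("mir-%02d", seq_len(nMirna)),
                               sprintf("s%02d", seq_len(nSample))))
  ge <- matrix(rnorm(nGene * nSample, 5), nrow = nGene,
               dimnames = list(sprintf("gene-%02d", seq_len(nGene)),
                               sprintf("s%02d", seq_len(nSample))))
  alignPaired(mi, ge)
}

# Write an entities x samples matrix as the TSV dialect the readers expect.
writeMatrixTsv <- function(mat, path) {
  writeExpressionMatrix(mat, path)
  path
}

# Random feature table for rank-integration property tests.
randomFeatureTable <- function(M, seed) {
  set.seed(seed)
  featureTable(sprintf("mir-%03d", seq_len(M)),
               a = rnorm(M, 5), c = runif(M),
               t = rpois(M, 20))
}

# Independent N=3 joint-CDF oracle: P(U(1)<=r1, U(2)<=r2, U(3)<=r3) by the
# nested simplex integral 6 * int_0^{r1} int_{u1}^{r2} (r3 - u2) du2 du1,
# with the inner integral in closed form and the outer one numeric.
jointCdfOracle3 <- function(r) {
  r <- sort(r)
  inner <- function(u1) r[3] * (r[2] - u1) - (r[2]^2 - u1^2) / 2
  6 * stats::integrate(inner, 0, r[1], rel.tol = 1e-10)$value
}

# Monte-Carlo estimate of the same probability for N = 3.
jointCdfMc3 <- function(r, nDraw = 1e6L) {
  u <- matrix(stats::runif(3 * nDraw), ncol = 3L)
  lo <- pmin(u[, 1], u[, 2], u[, 3])
  hi <- pmax(u[, 1], u[, 2], u[, 3])
  mid <- u[, 1] + u[, 2] + u[, 3] - lo - hi
  r <- sort(r)
  mean(lo <= r[1] & mid <= r[2] & hi <= r[3])
}

# Exhaustive hypergeometric upper tail from binomial coefficients (log
# space), independent of phyper.
chooseTailOracle <- function(M, K, n, x) {
  xs <- x:min(K, n)
  xs <- xs[n - xs <= M - K]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(M - K, n - xs) - lchoose(M, n)))
}
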