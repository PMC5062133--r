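test_that("mean expression is the arithmetic mean over tumor samples", {
  mi <- matrix(c(2, 4, 6, 5, 5, 5), nrow = 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  ge <- matrix(rnorm(6), 2, dimnames = list(c("g1", "g2"),
                                            c("s1", "s2", "s3")))
  ds <- makeToyDataset(mi, ge)
  a <- meanExpression(ds)
  expect_equal(unname(a), c(4, 5))

  # naive summation oracle on a random 20 x 7 matrix
  set.seed(9)
  ds <- randomDataset(nMirna = 20, nGene = 3, nSample = 7, seed = 9)
  a <- meanExpression(ds)
  oracle <- apply(mirnaExprs(ds), 1, function(r) {
    s <- 0
    for (v in r) s <- s + v
    s / length(r)
  })
  expect_equal(a, oracle, tolerance = 1e-12)
})

test_that("mean |PCC| handles perfect, orthogonal and random genes", {
  x <- c(1, 3, 2, 5, 4)
  mi <- matrix(x, 1, dimnames = list("m1", sprintf("s%d", 1:5)))
  ge <- rbind(g1 = x, g2 = -x)
  colnames(ge) <- sprintf("s%d", 1:5)
  expect_equal(unname(meanAbsCorrelation(makeToyDataset(mi, ge))), 1)

  # a gene orthogonal to the centered miRNA contributes |PCC| = 0
  xc <- x - mean(x)
  g <- c(1, -1, 0, 0, 0)
  g <- g - xc * sum(g * xc) / sum(xc^2)  # project out the miRNA direction
  ge <- rbind(g1 = g + 5)
  colnames(ge) <- sprintf("s%d", 1:5)
  expect_equal(unname(meanAbsCorrelation(makeToyDataset(mi, ge))), 0,
               tolerance = 1e-12)

  # per-pair covariance/sigma oracle on a random 15-sample, 50-gene matrix
  ds <- randomDataset(nMirna = 6, nGene = 50, nSample = 15, seed = 21)
  got <- meanAbsCorrelation(ds)
  mi <- mirnaExprs(ds); ge <- geneExprs(ds)
  oracle <- sapply(rownames(mi), function(m) {
    mean(sapply(rownames(ge), function(g) {
      xm <- mi[m, ]; xg <- ge[g, ]
      abs(sum((xm - mean(xm)) * (xg - mean(xg))) /
            sqrt(sum((xm - mean(xm))^2) * sum((xg - mean(xg))^2)))
    }))
  })
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("degenerate correlation inputs are rejected or flagged", {
  mi <- matrix(rnorm(4), 2, dimnames = list(c("m1", "m2"),
                                            c("s1", "s2")))
  ge <- matrix(rnorm(4), 2, dimnames = list(c("g1", "g2"),
                                            c("s1", "s2")))
  expect_error(meanAbsCorrelation(makeToyDataset(mi, ge)), "3 samples")

  mi <- matrix(rnorm(6), 2, dimnames = list(c("m1", "m2"),
                                            c("s1", "s2", "s3")))
  geConst <- matrix(5, 2, 3, dimnames = dimnames(mi))
  rownames(geConst) <- c("g1", "g2")
  expect_error(meanAbsCorrelation(makeToyDataset(mi, geConst)),
               "zero variance")

  miZ <- rbind(m1 = rnorm(5), m2 = rep(2, 5))
  colnames(miZ) <- sprintf("s%d", 1:5)
  geR <- matrix(rnorm(10), 2, dimnames = list(c("g1", "g2"),
                                              colnames(miZ)))
  expect_warning(cc <- meanAbsCorrelation(makeToyDataset(miZ, geR)),
                 "zero-variance miRNA")
  expect_equal(unname(cc["m2"]), 0)
})

test_that("zero-variance genes are excluded globally from the F2 average", {
  set.seed(5)
  mi <- matrix(rnorm(10), 2, dimnames = list(c("m1", "m2"),
                                             sprintf("s%d", 1:5)))
  geVar <- matrix(rnorm(15), 3, dimnames = list(c("g1", "g2", "g3"),
                                                colnames(mi)))
  geAll <- rbind(geVar, gconst = rep(7, 5))
  expect_equal(meanAbsCorrelation(makeToyDataset(mi, geAll)),
               meanAbsCorrelation(makeToyDataset(mi, geVar)))
})

test_that("target counts are distinct-gene counts with absent ids at 0", {
  pairs <- data.frame(mirna = c("m1", "m1", "m1", "m3"),
                      gene = c("gA", "gB", "gA", "gC"))
  t <- targetCount(c("m1", "m2", "m3"), pairs)
  expect_equal(unname(t), c(2L, 0L, 1L))

  # brute-force distinct-gene oracle on a random duplicate-laden table
  set.seed(8)
  tab <- data.frame(mirna = sample(sprintf("m%d", 1:5), 60, TRUE),
                    gene = sample(sprintf("g%d", 1:12), 60, TRUE))
  ids <- sprintf("m%d", 1:6)
  got <- targetCount(ids, tab)
  oracle <- vapply(ids, function(m)
    length(unique(tab$gene[tab$mirna == m])), integer(1))
  expect_equal(got, oracle)
})

test_that("feature table composes the three features and is invariant to
           sample and gene permutations", {
  set.seed(13)
  mi <- matrix(rnorm(15, 5), 3, dimnames = list(c("m1", "m2", "m3"),
                                                sprintf("s%d", 1:5)))
  ge <- matrix(rnorm(20, 5), 4, dimnames = list(sprintf("g%d", 1:4),
                                                sprintf("s%d", 1:5)))
  pairs <- data.frame(mirna = c("m1", "m1", "m2"),
                      gene = c("g1", "g2", "g1"))
  ft <- buildFeatureTable(makeToyDataset(mi, ge), pairs)

  # hand-computed composition
  expect_equal(ft@a, unname(rowMeans(mi)))
  expect_equal(ft@t, c(2, 1, 0))
  cHand <- sapply(1:3, function(i)
    mean(abs(apply(ge, 1, function(g) cor(mi[i, ], g)))))
  expect_equal(ft@c, cHand, tolerance = 1e-12)

  perm <- c(4, 2, 5, 1, 3)
  ft2 <- buildFeatureTable(
    makeToyDataset(mi[, perm], ge[, perm]), pairs)
  expect_equal(as.data.frame(ft2), as.data.frame(ft))

  ft3 <- buildFeatureTable(
    makeToyDataset(mi, ge[c(3, 1, 4, 2), ]), pairs)
  expect_equal(ft3@c, ft@c)
})

test_that("F2 is affine-invariant and F1 scale-equivariant", {
  ds <- randomDataset(nMirna = 4, nGene = 10, nSample = 8, seed = 17)
  mi <- mirnaExprs(ds); ge <- geneExprs(ds)
  c0 <- meanAbsCorrelation(ds)
  mi2 <- mi; mi2[2, ] <- 3.7 * mi2[2, ] + 11
  ge2 <- ge; ge2[5, ] <- 0.2 * ge2[5, ] - 4
  expect_equal(meanAbsCorrelation(makeToyDataset(mi2, ge2)), c0,
               tolerance = 1e-12)
  expect_equal(meanExpression(makeToyDataset(mi * 2.5, ge)),
               2.5 * meanExpression(ds))
})

test_that("feature tables round-trip through TSV", {
  ft <- randomFeatureTable(12, seed = 2)
  f <- tempfile(fileext = ".tsv")
  writeFeatureTable(ft, f)
  back <- readFeatureTable(f)
  expect_equal(as.data.frame(back), as.data.frame(ft))
})
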