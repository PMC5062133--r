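test_that("ranking ratios: strict order, average-rank ties, direction identity", {
  expect_equal(rankingRatio(c(10, 5, 1), "descending"), c(1, 2, 3) / 3)
  expect_equal(rankingRatio(c(5, 5, 1), "descending"), c(1.5, 1.5, 3) / 3)
  expect_equal(rankingRatio(c(10, 5, 1), "ascending"), c(3, 2, 1) / 3)
  expect_error(rankingRatio(numeric(0)), "empty")

  # tie-free identity: descending + ascending = (M + 1)/M per entry
  set.seed(4)
  for (M in c(2, 7, 33)) {
    v <- rnorm(M)
    expect_equal(rankingRatio(v, "descending") + rankingRatio(v, "ascending"),
                 rep((M + 1) / M, M))
  }
})

test_that("Q statistic matches closed forms", {
  expect_equal(qStatistic(c(1, 1, 1)), 1)
  expect_equal(qStatistic(c(0.5, 0.5, 0.5)), 0.125)
  expect_equal(qStatistic(c(0, 0.4, 0.9)), 0)
  # N = 1 and N = 2 closed forms
  for (r in c(0.05, 0.3, 0.77, 1)) expect_equal(qStatistic(r), r,
                                                tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    r <- sort(runif(2))
    expect_equal(qStatistic(r), 2 * r[1] * r[2] - r[1]^2,
                 tolerance = 1e-12)
  }
  # equal ratios collapse to r^N for several N
  for (N in 1:5) expect_equal(qStatistic(rep(0.3, N)), 0.3^N,
                              tolerance = 1e-12)
  expect_error(qStatistic(c(0.2, 1.4)), "0, 1")
})

test_that("Q statistic equals the joint order-statistic CDF (N = 3)", {
  # inclusion-exclusion hand value from the worked example
  r <- c(0.1, 0.5, 1.0)
  expect_equal(qStatistic(r), 1 - 0.9^3 - 3 * 0.1 * 0.5^2,
               tolerance = 1e-12)
  expect_equal(qStatistic(r), 0.196, tolerance = 1e-12)
  # independent simplex-integration oracle on random triples
  set.seed(10)
  for (i in 1:25) {
    r <- runif(3)
    expect_equal(qStatistic(r), jointCdfOracle3(r), tolerance = 1e-8)
  }
})

test_that("Q statistic is monotone and bounded", {
  set.seed(12)
  for (i in 1:50) {
    r <- runif(3)
    q <- qStatistic(r)
    expect_gte(q, 0); expect_lte(q, 1)
    j <- sample(3, 1)
    r2 <- r; r2[j] <- min(1, r2[j] + runif(1, 0, 1 - r2[j]))
    expect_gte(qStatistic(r2) + 1e-12, q)
    expect_equal(qStatistic(c(0, r[2:3])), 0)
  }
})

test_that("integration: dominance, total ties, and the two directions", {
  # 2 miRNAs, A strictly better everywhere
  ft <- featureTable(c("A", "B"), a = c(9, 1), c = c(0.9, 0.1),
                     t = c(50, 5))
  res <- integrateRanks(ft)
  expect_equal(res@rq1[1], 1)
  expect_equal(res@rq2[1], 1)
  expect_equal(res@rq[1], 2)
  expect_equal(res@finalRank, c(1L, 2L))
  expect_identical(rankedIds(res)[1], "A")

  # all miRNAs identical: every rank vector is tied, final ranks 1..M by id
  ftTied <- featureTable(c("c", "a", "b"), a = c(2, 2, 2),
                         c = c(0.5, 0.5, 0.5), t = c(7, 7, 7))
  resT <- integrateRanks(ftTied)
  expect_true(all(resT@rq == resT@rq[1]))
  expect_equal(rankedIds(resT), c("a", "b", "c"))

  expect_error(integrateRanks(featureTable("x", 1, 0.5, 3)),
               "at least 2")
})

test_that("a one-feature specialist ranks below a uniform all-rounder", {
  # miRNA 'spike' is 1st on a but last on c and t; 'steady' is middling
  # on all three. The bidirectional Q ranking must prefer 'steady'.
  M <- 10
  set.seed(31)
  a <- sort(runif(M, 1, 9));  cft <- sort(runif(M));  t <- 10 * (1:M)
  # spike: top a, bottom c and t; steady: ranks 5-6 on everything
  ids <- c("spike", "steady", sprintf("bg%02d", 1:(M - 2)))
  ft <- featureTable(ids,
                     a = c(max(a) + 1, a[5], a[-c(5, 10)]),
                     c = c(min(cft) - 0.01, cft[5], cft[-c(1, 5)]),
                     t = c(0, t[5], t[-c(1, 5)]))
  res <- integrateRanks(ft)
  fr <- setNames(res@finalRank, ids)
  expect_lt(fr["steady"], fr["spike"])

  # exhaustively recompute both Q vectors with the independent CDF oracle
  feats <- cbind(ft@a, ft@c, ft@t)
  rd <- apply(feats, 2, rankingRatio, direction = "descending")
  ri <- apply(feats, 2, rankingRatio, direction = "ascending")
  q1o <- apply(rd, 1, jointCdfOracle3)
  q2o <- apply(ri, 1, jointCdfOracle3)
  expect_equal(res@q1, q1o, tolerance = 1e-8)
  expect_equal(res@q2, q2o, tolerance = 1e-8)
})

test_that("integration is equivariant under miRNA input permutation", {
  ft <- randomFeatureTable(25, seed = 44)
  res <- integrateRanks(ft)
  perm <- sample(25)
  ftP <- featureTable(ft@mirna[perm], ft@a[perm], ft@c[perm], ft@t[perm])
  resP <- integrateRanks(ftP)
  expect_equal(resP@q1, res@q1[perm])
  expect_equal(resP@rq, res@rq[perm])
  expect_equal(resP@finalRank, res@finalRank[perm])
})

test_that("weak dominance never yields a worse final rank", {
  set.seed(55)
  for (rep in 1:40) {
    M <- sample(3:50, 1)
    ft <- randomFeatureTable(M, seed = 1000 + rep)
    res <- integrateRanks(ft)
    dom <- outer(ft@a, ft@a, ">=") & outer(ft@c, ft@c, ">=") &
      outer(ft@t, ft@t, ">=")
    strict <- outer(ft@a, ft@a, ">") | outer(ft@c, ft@c, ">") |
      outer(ft@t, ft@t, ">")
    idx <- which(dom & strict, arr.ind = TRUE)
    if (nrow(idx))
      expect_true(all(res@rq[idx[, 1]] <= res@rq[idx[, 2]] + 1e-9))
  }
})

test_that("average-ratio integrator is a weighted mean of RD ratios", {
  ft <- featureTable(c("x", "y", "z"), a = c(3, 2, 1), c = c(0.1, 0.3, 0.2),
                     t = c(5, 5, 9))
  # equal features -> all scores equal
  ftEq <- featureTable(c("x", "y"), a = c(1, 1), c = c(0.5, 0.5),
                       t = c(3, 3))
  eq <- integrateAverageRatio(ftEq)
  expect_equal(diff(eq$score), 0)

  # degenerate weights reduce to the single-feature ranking
  w <- integrateAverageRatio(ft, weights = c(1, 0, 0))
  expect_identical(w$mirna, c("x", "y", "z"))

  # arithmetic oracle
  got <- integrateAverageRatio(ft, weights = c(2, 1, 1))
  rd <- cbind(rankingRatio(ft@a, "descending"),
              rankingRatio(ft@c, "descending"),
              rankingRatio(ft@t, "descending"))
  hand <- as.numeric(rd %*% c(2, 1, 1)) / 4
  expect_equal(got$score[match(ft@mirna, got$mirna)], hand)
})

test_that("inverse-normal integrator maps ranks through the normal quantile", {
  # odd M: the median rank maps to z = 0
  ft <- featureTable(sprintf("m%d", 1:5), a = 1:5, c = (1:5) / 10,
                     t = 1:5)
  got <- integrateInverseNormal(ft)
  z <- got$z[match(ft@mirna, got$mirna)]
  expect_equal(z[3], 0, tolerance = 1e-12)
  # symmetric ranks give symmetric z pairs
  expect_equal(z[1], -z[5], tolerance = 1e-12)
  expect_equal(z[2], -z[4], tolerance = 1e-12)
  # quantile-table oracle: ranks 1..5 -> qnorm(1 - (rank - 0.5)/5)
  expect_equal(z[5], qnorm(1 - 0.5 / 5), tolerance = 1e-12)
  expect_equal(z[4], qnorm(1 - 1.5 / 5), tolerance = 1e-12)
})

test_that("integration result serializes in final-rank order", {
  ft <- randomFeatureTable(8, seed = 3)
  res <- integrateRanks(ft)
  f <- tempfile(fileext = ".tsv")
  writeIntegrationResult(res, ft, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$final_rank, 1:8)
  expect_equal(back$mirna, rankedIds(res))
  expect_equal(sort(back$rq), sort(res@rq))
})
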