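test_that("mirror pooling reflects, preserves size, and is idempotent", {
  pts <- rbind(c(3, 1), c(7, 2), c(5, 5))
  out <- mirrorPool(pts, midline = 5)
  expect_equal(nrow(out), 3)
  expect_equal(out[, 1], c(3, 3, 5))   # 7 reflects to 3 about 5
  expect_equal(out[, 2], pts[, 2])
  expect_equal(mirrorPool(out, 5), out)
  # all points already on the kept side: identity
  low <- rbind(c(1, 0), c(2, 3))
  expect_equal(mirrorPool(low, 5), low)
  ps <- new("PointSet2D", coords = pts, label = "a",
            projection = "z_projection")
  expect_s4_class(mirrorPool(ps, 5), "PointSet2D")
})

test_that("KDE integrates to 1, peaks at a single point, and respects symmetry", {
  g <- kdeGrid(rbind(c(0, 0)), kernel_sd = 5, spacing = 1)
  d1 <- kde2d(rbind(c(0, 0)), g, 5)
  area <- (g$x[2] - g$x[1]) * (g$y[2] - g$y[1])
  expect_equal(sum(d1@z) * area, 1, tolerance = 1e-9)
  pk <- which(d1@z == max(d1@z), arr.ind = TRUE)
  expect_equal(g$x[pk[1]], 0); expect_equal(g$y[pk[2]], 0)
  # two symmetric points: density symmetric about the midpoint
  pts <- rbind(c(-10, 0), c(10, 0))
  g2 <- kdeGrid(pts, kernel_sd = 5, spacing = 1)
  d2 <- kde2d(pts, g2, 5)
  expect_equal(d2@z, d2@z[rev(seq_along(g2$x)), , drop = FALSE],
               tolerance = 1e-12)
  expect_error(kde2d(matrix(0, 0, 2), g, 5), "empty")
})

test_that("matching score anchors: identity, disjoint supports, 2-SD separation", {
  set.seed(4)
  pts <- cbind(runif(6, 0, 30), runif(6, 0, 30))
  g <- kdeGrid(pts, kernel_sd = 10, spacing = 1)
  p <- kde2d(pts, g, 10)
  expect_equal(matchingScore(p, p), 1, tolerance = 1e-6)
  # symmetric in its arguments
  q <- kde2d(pts + 5, g, 10)
  expect_equal(matchingScore(p, q), matchingScore(q, p))
  expect_gte(matchingScore(p, q), 0); expect_lte(matchingScore(p, q), 1)
  # far-separated single points: MS ~ 0
  a <- rbind(c(0, 0)); b <- rbind(c(300, 300))
  gf <- kdeGrid(a, b, kernel_sd = 10, spacing = 2)
  expect_lt(matchingScore(kde2d(a, gf, 10), kde2d(b, gf, 10)), 1e-3)
  # two single points at d = 2 SD: closed form 2 * pnorm(-1)
  b2 <- rbind(c(20, 0))
  g2 <- kdeGrid(a, b2, kernel_sd = 10, spacing = 1, pad_sd = 6)
  ms <- matchingScore(kde2d(a, g2, 10), kde2d(b2, g2, 10))
  expect_equal(ms, 2 * pnorm(-1), tolerance = 0.005)
  # grid mismatch is an error
  expect_error(matchingScore(p, kde2d(a, gf, 10)), "grid")
})

test_that("matching score agrees with the double-loop oracle to 1e-8", {
  P <- cbind(c(0, 3, 5), c(1, 2, 0))
  Q <- cbind(c(8, 10), c(4, 6))
  g <- kdeGrid(P, Q, kernel_sd = 4, spacing = 2)
  expect_equal(matchingScore(kde2d(P, g, 4), kde2d(Q, g, 4)),
               msOracle(P, Q, g, 4), tolerance = 1e-8)
})

test_that("matching index arithmetic and antisymmetry", {
  expect_equal(matchingIndex(matrix(0.4, 2, 2)), 0)
  ms <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  expect_equal(matchingIndex(ms), -matchingIndex(ms[, 2:1]))
  expect_equal(matchingIndex(ms), (0.9 + 0.8) / 2 - (0.1 + 0.2) / 2)
  expect_error(matchingIndex(matrix(c(1, NA, 0, 1), 2, 2)), "missing")
  # identical, far-separated class pairs: MI ~ 1
  A1 <- cbind(rnorm(20, 0, 3), rnorm(20, 0, 3))
  A2 <- cbind(rnorm(20, 150, 3), rnorm(20, 150, 3))
  g <- kdeGrid(A1, A2, kernel_sd = 10, spacing = 2)
  ms2 <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2)
    ms2[i, j] <- matchingScore(
      kde2d(list(A1, A2)[[i]], g, 10), kde2d(list(A1, A2)[[j]], g, 10))
  expect_gt(matchingIndex(ms2), 0.95)
})

test_that("bootstrap null is seeded and centered near zero under exchangeability", {
  set.seed(8)
  A1 <- cbind(rnorm(25, 0, 10), rnorm(25, 0, 10))
  A2 <- cbind(rnorm(25, 0, 10), rnorm(25, 0, 10))
  F1 <- cbind(rnorm(25, 0, 10), rnorm(25, 0, 10))
  F2 <- cbind(rnorm(25, 0, 10), rnorm(25, 0, 10))
  n1 <- bootstrapMiNull(list(A1, A2), list(F1, F2), n = 200, kernel_sd = 10,
                        seed = 5)
  n2 <- bootstrapMiNull(list(A1, A2), list(F1, F2), n = 200, kernel_sd = 10,
                        seed = 5)
  expect_identical(n1, n2)
  expect_lt(abs(mean(n1)), 0.05)
})

test_that("significance threshold is the 99.17th percentile and needs both regions", {
  null <- seq(0, 1, length.out = 1201)
  dec <- decideSignificance(0.999, null, alpha = 0.05, n_comparisons = 6)
  expect_equal(dec$threshold_percentile, 100 - 5 / 6)
  expect_equal(round(dec$threshold_percentile, 2), 99.17)
  expect_equal(dec$threshold,
               unname(quantile(null, (100 - 5 / 6) / 100, type = 7)))
  expect_true(dec$significant)
  # equality is not significant (strict >)
  expect_false(decideSignificance(dec$threshold, null)$significant)
  # both regions required
  r1 <- list(significant = TRUE); r2 <- list(significant = FALSE)
  expect_true(combineRegions(list(r1, r1)))
  expect_false(combineRegions(list(r1, r2)))
})

test_that("skeleton endpoint extraction counts tips correctly", {
  line <- matrix(FALSE, 10, 10); line[3, 2:9] <- TRUE
  expect_equal(nrow(skeletonEndpoints(line)), 2)
  lone <- matrix(FALSE, 5, 5); lone[3, 3] <- TRUE
  expect_equal(nrow(skeletonEndpoints(lone)), 1)
  # Y shape: 3 endpoints
  y <- matrix(FALSE, 12, 12)
  y[6, 2:6] <- TRUE
  for (k in 1:4) { y[6 - k, 6 + k] <- TRUE; y[6 + k, 6 + k] <- TRUE }
  ends <- skeletonEndpoints(y)
  expect_equal(nrow(ends), 3)
  # brute-force neighbor-count oracle on the same mask
  brute <- 0
  for (i in 1:12) for (j in 1:12) if (y[i, j]) {
    nb <- sum(y[max(1, i - 1):min(12, i + 1),
                max(1, j - 1):min(12, j + 1)]) - 1
    if (nb <= 1) brute <- brute + 1
  }
  expect_equal(nrow(ends), brute)
  expect_warning(skeletonEndpoints(matrix(TRUE, 5, 5)), "thin")
})

test_that("axis marginals integrate to 1 and order class modes correctly", {
  set.seed(12)
  fwd <- cbind(rnorm(40, 30, 8), rnorm(40, 0, 5))
  bwd <- cbind(rnorm(40, 70, 8), rnorm(40, 0, 5))
  df <- axisDensity(fwd, axis = 1, kernel_sd = 10)
  db <- axisDensity(bwd, axis = 1, kernel_sd = 10)
  expect_equal(sum(df$y) * diff(df$x[1:2]), 1, tolerance = 1e-3)
  expect_lt(df$x[which.max(df$y)], db$x[which.max(db$y)])
  # two well-separated clusters give a bimodal curve
  both <- rbind(fwd, bwd + 200)
  d2 <- axisDensity(both, axis = 1, kernel_sd = 10)
  peaks <- which(diff(sign(diff(d2$y))) == -2)
  expect_gte(length(peaks), 2)
})

test_that("point sets round-trip through CSV", {
  a <- new("PointSet2D", coords = cbind(1:3, 4:6), label = "unipolar",
           projection = "lateral_projection")
  b <- new("PointSet2D", coords = cbind(7:9, 1:3), label = "multipolar",
           projection = "lateral_projection")
  f <- tempfile(fileext = ".csv")
  writePointSetsCsv(list(a, b), f)
  back <- readPointSetsCsv(f)
  expect_equal(length(back), 2)
  lab <- vapply(back, function(p) p@label, "")
  expect_setequal(lab, c("unipolar", "multipolar"))
  uni <- back[[which(lab == "unipolar")]]
  expect_equal(uni@coords, cbind(1:3, 4:6), ignore_attr = TRUE)
})
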