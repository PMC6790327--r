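test_that("static within-compartment FC matches the Pearson formula", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  ts <- makeTs(cbind(a = x, b = y, c = x, d = -x + 10),
               labels = paste0("GM_0", 1:4))
  fc <- fcValues(staticFCWithin(ts))
  expect_equal(fc[1, 2], 0.9827, tolerance = 5e-5)
  expect_equal(fc[1, 2], pearsonByHand(x, y), tolerance = 1e-12)
  expect_equal(fc[1, 3], 1)          # identical columns
  expect_equal(fc[1, 4], -1)         # negated plus constant
  expect_equal(diag(fc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(fc, t(fc))
})

test_that("zero-variance ROIs yield zeroed edges with a warning", {
  ts <- makeTs(cbind(rnorm(20), rep(1, 20)), labels = c("GM_01", "GM_02"))
  expect_warning(fc <- staticFCWithin(ts), "zero-variance")
  expect_equal(fcValues(fc)[1, 2], 0)
  expect_equal(diag(fcValues(fc)), c(1, 1), ignore_attr = TRUE)
})

test_that("cross-compartment FC agrees with within-FC on identical inputs", {
  set.seed(10)
  d <- matrix(rnorm(50 * 4), 50, 4)
  gm <- makeTs(d)
  wm <- makeTs(d, compartment = "WM")
  expect_equal(fcValues(staticFCCross(wm, gm)),
               fcValues(staticFCWithin(gm)), ignore_attr = TRUE)
  # single WM ROI equal to a GM ROI: exact 1 at that column
  wm1 <- makeTs(d[, 3, drop = FALSE], compartment = "WM", labels = "WM_01")
  row <- fcValues(staticFCCross(wm1, gm))
  expect_equal(unname(row[1, 3]), 1)
  # white-noise null bound ~ 3/sqrt(T)
  set.seed(11)
  nz <- fcValues(staticFCCross(makeTs(matrix(rnorm(500 * 5), 500, 5), "WM"),
                               makeTs(matrix(rnorm(500 * 6), 500, 6))))
  expect_true(all(abs(nz) < 0.15))
  expect_error(staticFCCross(makeTs(matrix(rnorm(30), 30, 1), "WM"), gm),
               "mismatch")
})

test_that("windowed correlations equal a brute-force per-window Pearson", {
  set.seed(12)
  for (rep in 1:50) {
    a <- rnorm(140); b <- rnorm(140)
    ts <- makeTs(cbind(a, b), labels = c("GM_01", "GM_02"))
    d <- dynamicFC(ts, windowLength = 30, step = 1)
    expect_equal(nWindows(d), 111L)
    ks <- c(1L, 37L, 111L)
    for (k in ks) {
      idx <- k:(k + 29L)
      expect_equal(fcValues(d)[1, k], pearsonByHand(a[idx], b[idx]),
                   tolerance = 1e-12)
    }
  }
  # full brute-force check over every window for one instance
  set.seed(13)
  a <- rnorm(60); b <- rnorm(60)
  d <- dynamicFC(makeTs(cbind(a, b), labels = c("GM_01", "GM_02")),
                 windowLength = 10, step = 3)
  expect_equal(nWindows(d), (60 - 10) %/% 3 + 1)
  for (k in seq_len(nWindows(d))) {
    idx <- ((k - 1) * 3 + 1):((k - 1) * 3 + 10)
    expect_equal(fcValues(d)[1, k], pearsonByHand(a[idx], b[idx]),
                 tolerance = 1e-12)
  }
})

test_that("dynamic FC window bookkeeping and degenerate handling", {
  ts <- makeTs(matrix(rnorm(140 * 3), 140, 3))
  expect_equal(nWindows(dynamicFC(ts, windowLength = 30, step = 1)), 111L)
  expect_error(dynamicFC(makeTs(matrix(rnorm(20 * 2), 20, 2)),
                         windowLength = 30), "exceeds")
  # identical ROIs give C^k = 1 everywhere
  d <- matrix(rnorm(50), 50, 1)
  same <- dynamicFC(makeTs(cbind(d, d), labels = c("GM_01", "GM_02")),
                    windowLength = 10)
  expect_equal(max(abs(fcValues(same) - 1)), 0, tolerance = 1e-12)
  # a constant stretch makes windows degenerate; C set to 0, K unchanged
  z <- rnorm(50); z[1:15] <- 2
  dg <- dynamicFC(makeTs(cbind(z, rnorm(50)), labels = c("GM_01", "GM_02")),
                  windowLength = 10)
  expect_equal(nWindows(dg), 41L)
  expect_true(all(fcValues(dg)[1, 1:6] == 0))
  expect_gt(dg@degenerateWindows, 0L)
})

test_that("RMS summarises windows as the quadratic mean", {
  mk <- function(vals) {
    d <- new("DynamicFCSeries", values = matrix(vals, nrow = 1),
             windowLength = 30L, step = 1L,
             edgeIndex = data.frame(row = "WM_01", col = "GM_01"),
             rowLabels = "WM_01", colLabels = "GM_01", symmetric = FALSE,
             degenerateWindows = 0L)
    fcValues(rmsFC(d))[1, 1]
  }
  expect_equal(mk(rep(0.5, 7)), 0.5)
  expect_equal(mk(c(0.6, -0.8)), sqrt((0.36 + 0.64) / 2))
  expect_equal(mk(c(0.6, -0.8)), 0.70711, tolerance = 5e-6)
  # RMS >= |mean| (quadratic-mean inequality), random cases
  set.seed(14)
  ts <- makeTs(matrix(rnorm(80 * 5), 80, 5))
  d <- dynamicFC(ts, windowLength = 20)
  expect_true(all(sqrt(rowMeans(fcValues(d)^2)) >=
                    abs(rowMeans(fcValues(d))) - 1e-12))
})

test_that("window length T links RMS-dFC to |static r| exactly", {
  set.seed(15)
  ts <- makeTs(matrix(rnorm(60 * 6), 60, 6))
  d <- dynamicFC(ts, windowLength = 60)
  expect_equal(nWindows(d), 1L)
  rms <- fcValues(rmsFC(d))
  stat <- abs(fcValues(staticFCWithin(ts)))
  expect_equal(rms, stat, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fisher z is odd, increasing, invertible and safely clipped", {
  r <- seq(-0.999, 0.999, by = 0.111)
  ts <- makeTs(matrix(rnorm(40), 20, 2))
  asZ <- function(v) fcValues(fisherZ(FCMatrix(matrix(v, 1), "static_r",
                                               "WM_01", "GM_01",
                                               symmetric = FALSE)))[1, 1]
  zs <- vapply(r, asZ, numeric(1))
  expect_equal(asZ(0), 0)
  expect_equal(asZ(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(round(asZ(0.5), 5), 0.54931)
  expect_equal(vapply(-r, asZ, numeric(1)), -zs, tolerance = 1e-12)
  expect_true(all(diff(zs) > 0))
  expect_equal(tanh(zs), r, tolerance = 1e-6)
  expect_true(is.finite(asZ(1)) && is.finite(asZ(-1)))
  expect_error(fisherZ(FCMatrix(matrix(1.2, 1), "fisher_z", "a", "b",
                                symmetric = FALSE)), "outside")
})

test_that("vectorization gives stable row-major edges and round-trips", {
  G <- 5
  set.seed(16)
  ts <- makeTs(matrix(rnorm(40 * G), 40, G))
  fc <- staticFCWithin(ts)
  v <- vectorizeFC(fc)
  expect_equal(length(v$features), G * (G - 1) / 2)
  expect_equal(v$edgeIndex$row[1:4], rep("GM_01", 4))     # row-major order
  expect_equal(v$edgeIndex$col[1:5], c(paste0("GM_0", 2:5), "GM_03"))
  back <- unvectorizeFC(v$features, roiLabels(ts), symmetric = TRUE)
  expect_equal(fcValues(back), fcValues(fc), tolerance = 1e-12)
  # rectangular: row-major W x G flatten
  wm <- makeTs(matrix(rnorm(40 * 3), 40, 3), compartment = "WM")
  cross <- staticFCCross(wm, ts)
  vc <- vectorizeFC(cross)
  expect_equal(length(vc$features), 3 * G)
  expect_equal(vc$features[G + 1],
               fcValues(cross)["WM_02", "GM_01"], ignore_attr = TRUE)
  back2 <- unvectorizeFC(vc$features, roiLabels(wm), roiLabels(ts),
                         symmetric = FALSE)
  expect_equal(fcValues(back2), fcValues(cross), tolerance = 1e-12)
  # canonical label-order guard
  expect_error(vectorizeFC(fc, canon = rev(roiLabels(ts))), "canonical")
})

test_that("group mean and display threshold behave elementwise", {
  m1 <- FCMatrix(matrix(0.2, 2, 2) + diag(0.8, 2), "static_r",
                 c("GM_01", "GM_02"), c("GM_01", "GM_02"), symmetric = TRUE)
  m2 <- FCMatrix(matrix(0.6, 2, 2) + diag(0.4, 2), "static_r",
                 c("GM_01", "GM_02"), c("GM_01", "GM_02"), symmetric = TRUE)
  avg <- groupMeanFC(list(m1, m2))
  expect_equal(fcValues(avg)[1, 2], 0.4)
  expect_equal(fcValues(groupMeanFC(list(m1))), fcValues(m1))
  # mask is strict: |0.5| > 0.5 is FALSE, -0.6 is TRUE
  mm <- FCMatrix(matrix(c(0.5, -0.6, 0, 0.51), 2, 2), "static_r",
                 c("WM_01", "WM_02"), c("GM_01", "GM_02"), symmetric = FALSE)
  mask <- thresholdMask(mm, 0.5)
  expect_equal(as.vector(mask), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(groupMeanFC(list(m1, mm)), "differ")
})
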