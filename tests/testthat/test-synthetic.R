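test_that("identical spec and seed give bit-identical cohorts", {
  a <- smallNullCohort(seed = 42)
  b <- smallNullCohort(seed = 42)
  expect_identical(lapply(a$subjects, tsData), lapply(b$subjects, tsData))
  c <- smallNullCohort(seed = 43)
  expect_false(identical(tsData(a$subjects[[1]]), tsData(c$subjects[[1]])))
})

test_that("null spec gives near-zero mean cross-group correlation difference", {
  coh <- generateCohort(CohortSpec(nPerGroup = 20, nWm = 4, nGm = 8,
                                   nTimepoints = 140, seed = 7))
  isAD <- coh$group == "AD"
  rs <- lapply(coh$subjects, function(s)
    fcValues(staticFCCross(compartmentSubset(s, "WM"),
                           compartmentSubset(s, "GM"))))
  dAD <- Reduce(`+`, rs[isAD]) / sum(isAD)
  dNC <- Reduce(`+`, rs[!isAD]) / sum(!isAD)
  # per-edge SE of a mean difference of correlations, Fisher-z var 1/(T-3)
  se <- sqrt(2 / 20) / sqrt(140 - 3)
  expect_lt(abs(mean(dAD - dNC)), 3 * se)
})

test_that("an injected static effect is recovered within 3 standard errors", {
  delta <- 0.4
  spec <- CohortSpec(nPerGroup = 20, nWm = 4, nGm = 8, nTimepoints = 140,
                     baseCorrelation = 0.1, seed = 21,
                     staticEffectEdges = crossEdges(1, 1, nWm = 4),
                     staticEffectDelta = delta)
  coh <- generateCohort(spec)
  isAD <- coh$group == "AD"
  edgeR <- vapply(coh$subjects, function(s) {
    d <- tsData(s)
    cor(d[, "WM_01"], d[, "GM_01"])
  }, numeric(1))
  dHat <- mean(edgeR[isAD]) - mean(edgeR[!isAD])
  # conservative effective-sample bound from Fisher-z variance 1/(T_eff - 3);
  # the 0.01-0.1 Hz band retains roughly 2 * (0.1 - 0.01) * TR of the
  # spectrum, so T_eff ~ 0.54 * T at TR = 3 s
  tEff <- 2 * (0.1 - 0.01) * 3 * 140
  se <- sqrt(2 / 20) * sqrt(1 / (tEff - 3))
  expect_lt(abs(dHat - delta), 3 * se)
})

test_that("dynamic-only effects raise RMS-dFC group differences, not static", {
  spec <- CohortSpec(nPerGroup = 30, nWm = 4, nGm = 8, nTimepoints = 140,
                     seed = 33, dynamicEffectEdges = crossEdges(1:2, 1:2,
                                                               nWm = 4))
  coh <- generateCohort(spec)
  isAD <- coh$group == "AD"
  fx <- cohortFeatures(coh, methods = c("sWGFC", "dWGFC"))
  edgePos <- c(1L, 8L + 2L)   # WM1-GM1, WM2-GM2 in row-major 4 x 8
  dynDiff <- abs(colMeans(fx$features$dWGFC[isAD, edgePos, drop = FALSE]) -
                 colMeans(fx$features$dWGFC[!isAD, edgePos, drop = FALSE]))
  statDiff <- abs(colMeans(fx$features$sWGFC[isAD, edgePos, drop = FALSE]) -
                  colMeans(fx$features$sWGFC[!isAD, edgePos, drop = FALSE]))
  expect_true(all(dynDiff > statDiff))
})

test_that("non-PSD effect configurations are rejected, naming the edges", {
  # r12 = r13 = 0.9 with r23 swinging to -0.9 violates the triangle bound
  spec <- CohortSpec(nPerGroup = 3, nWm = 2, nGm = 3, nTimepoints = 60,
                     baseCorrelation = 0, seed = 1,
                     staticEffectEdges = rbind(c(1, 2), c(1, 3)),
                     staticEffectDelta = 0.9,
                     dynamicEffectEdges = rbind(c(2, 3)),
                     dynamicEffectDelta = 0.9)
  expect_error(generateCohort(spec), "positive semidefinite|exceed")
})

test_that("cohort CSV round-trip preserves data, labels and groups", {
  coh <- smallNullCohort(nPerGroup = 2, nT = 40, seed = 9)
  dir <- tempfile("cohort_")
  writeCohortCsv(coh, dir)
  back <- readCohortCsv(dir)
  expect_equal(back$group, coh$group)
  expect_equal(roiLabels(back$subjects[[1]]), roiLabels(coh$subjects[[1]]))
  expect_equal(tsData(back$subjects[[3]]), tsData(coh$subjects[[3]]),
               tolerance = 1e-12)
  expect_equal(compartments(back$subjects[[1]]),
               compartments(coh$subjects[[1]]))
  unlink(dir, recursive = TRUE)
})

test_that("image fixture round-trips through extraction and NIfTI", {
  ts <- makeTs(matrix(rnorm(30 * 6), 30, 6),
               compartment = c(rep("WM", 2), rep("GM", 4)),
               labels = c("WM_01", "WM_02", paste0("GM_0", 1:4)))
  fix <- renderImageFixture(ts, gridDim = c(4, 3, 1), voxelsPerRoi = 2)
  exGm <- extractRoiTimeseries(fix$img, fix$atlases$GM, trSeconds = 3)
  expect_equal(tsData(exGm), tsData(compartmentSubset(ts, "GM")),
               tolerance = 1e-12, ignore_attr = TRUE)
  # too-small grid errors
  expect_error(renderImageFixture(ts, gridDim = c(2, 2, 1), voxelsPerRoi = 2),
               "too small")
  # NIfTI files round-trip
  dir <- tempfile("nii_")
  fix2 <- renderImageFixture(ts, gridDim = c(4, 3, 1), voxelsPerRoi = 2,
                             dir = dir)
  exWm <- extractRoiTimeseries(fix2$paths$bold, fix2$paths$atlas_wm,
                               compartment = "WM")
  expect_equal(unname(tsData(exWm)),
               unname(tsData(compartmentSubset(ts, "WM"))),
               tolerance = 1e-5)
  expect_equal(trSeconds(exWm), 3)
  unlink(dir, recursive = TRUE)
})

test_that("voxel averaging suppresses rendering noise", {
  set.seed(4)
  ts <- makeTs(matrix(rnorm(100 * 10), 100, 10))
  fix <- renderImageFixture(ts, gridDim = c(10, 8, 1), voxelsPerRoi = 8,
                            noiseSd = 0.1, seed = 8)
  ex <- extractRoiTimeseries(fix$img, fix$atlases$GM, trSeconds = 3)
  cors <- diag(cor(tsData(ex), tsData(ts)))
  expect_true(all(cors > 0.99))
})
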