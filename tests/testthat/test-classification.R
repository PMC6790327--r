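test_that("metric formulas reproduce hand-computed confusion summaries", {
  m <- computeMetrics(25, 25, 25, 25)
  expect_equal(unname(m[c("acc", "sen", "spe")]), c(50, 50, 50))
  m2 <- computeMetrics(38, 35, 10, 7)
  expect_equal(unname(m2["acc"]), 100 * 73 / 90, tolerance = 1e-12)
  expect_equal(unname(m2["sen"]), 100 * 38 / 45, tolerance = 1e-12)
  expect_equal(unname(m2["spe"]), 100 * 35 / 45, tolerance = 1e-12)
  pr <- 38 / 48; rc <- 38 / 45
  expect_equal(unname(m2["fscore"]), 100 * 2 * pr * rc / (pr + rc),
               tolerance = 1e-12)
  # undefined ratios are NA, never zero
  expect_true(is.na(computeMetrics(0, 10, 0, 0)["sen"]))
  expect_true(is.na(computeMetrics(0, 10, 0, 5)["fscore"]))
  expect_error(computeMetrics(-1, 2, 3, 4), "non-negative")
})

test_that("ROC is monotone from (0,0) to (1,1); AUC equals Mann-Whitney", {
  set.seed(30)
  labels <- rep(c("AD", "NC"), each = 30)
  scores <- rnorm(60) + (labels == "AD") * 1.2
  scores[5] <- scores[35]   # force a cross-class tie
  rp <- rocPoints(scores, labels)
  expect_equal(rp$points$fpr[1], 0)
  expect_equal(rp$points$tpr[1], 0)
  expect_equal(rp$points$fpr[nrow(rp$points)], 1)
  expect_equal(rp$points$tpr[nrow(rp$points)], 1)
  expect_true(all(diff(rp$points$fpr) >= 0))
  expect_true(all(diff(rp$points$tpr) >= 0))
  # brute-force pairwise Mann-Whitney oracle, ties counted 1/2
  pos <- scores[labels == "AD"]; neg <- scores[labels == "NC"]
  u <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(rp$auc, u, tolerance = 1e-12)
  # perfect scores
  expect_equal(rocPoints(as.numeric(labels == "AD"), labels)$auc, 1)
  expect_error(rocPoints(pos, rep("AD", 30)), "both classes")
})

test_that("own AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  labels <- rep(c("AD", "NC"), times = c(20, 25))
  scores <- rnorm(45) + (labels == "AD") * 0.8
  ours <- rocPoints(scores, labels)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("NC", "AD"),
                                              direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("leave-one-out SVM is perfect on separable clouds", {
  set.seed(32)
  x <- rbind(matrix(rnorm(15 * 8, 5), 15, 8), matrix(rnorm(15 * 8, -5), 15, 8))
  y <- rep(c("AD", "NC"), each = 15)
  res <- looSvm(x, y)
  expect_equal(unname(metrics(res)["acc"]), 100)
  expect_equal(unname(metrics(res)["auc"]), 1)
  expect_equal(unname(confusion(res)["TP"] + confusion(res)["FN"]), 15L)
  expect_equal(unname(confusion(res)["TN"] + confusion(res)["FP"]), 15L)
})

test_that("permuted labels on null features classify at chance", {
  set.seed(33)
  n <- 40
  x <- matrix(rnorm(n * 200), n, 200)
  y <- sample(rep(c("AD", "NC"), each = n / 2))
  res <- looSvm(x, y, alpha = 0.05, protocol = "nested")
  # 3-sigma binomial band around chance at this n
  expect_lt(abs(unname(metrics(res)["acc"]) - 50), 100 * 3 * sqrt(0.25 / n))
})

test_that("equal group sizes bound ACC between SEN and SPE", {
  set.seed(34)
  x <- rbind(matrix(rnorm(10 * 6, 0.8), 10, 6),
             matrix(rnorm(10 * 6, -0.8), 10, 6))
  y <- rep(c("AD", "NC"), each = 10)
  m <- metrics(looSvm(x, y))
  expect_gte(m[["acc"]], min(m[["sen"]], m[["spe"]]) - 1e-9)
  expect_lte(m[["acc"]], max(m[["sen"]], m[["spe"]]) + 1e-9)
})

test_that("whole-cohort selection is optimistically biased on null data", {
  set.seed(35)
  accs <- replicate(10, {
    x <- matrix(rnorm(20 * 150), 20, 150)
    y <- rep(c("AD", "NC"), each = 10)
    c(paper = unname(metrics(looSvm(x, y, alpha = 0.1,
                                    protocol = "paper"))["acc"]),
      nested = unname(metrics(looSvm(x, y, alpha = 0.1,
                                     protocol = "nested"))["acc"]))
  })
  expect_lte(mean(accs["nested", ]), mean(accs["paper", ]))
})

test_that("empty selections error informatively; bad inputs are rejected", {
  set.seed(36)
  x <- matrix(rnorm(12 * 10), 12, 10)
  y <- rep(c("AD", "NC"), each = 6)
  expect_error(looSvm(x, y, alpha = 1e-10, protocol = "paper"),
               "no edge selected")
  expect_error(looSvm(x, y, alpha = 1e-10, protocol = "nested"), "fold")
  expect_error(looSvm(x[1:3, ], y[1:3]), "at least 4")
  expect_error(looSvm(x, rep("AD", 12)), "two classes")
})

test_that("reported protocol, alpha and fold feature counts are recorded", {
  set.seed(37)
  x <- rbind(matrix(rnorm(10 * 20, 1), 10, 20),
             matrix(rnorm(10 * 20, -1), 10, 20))
  y <- rep(c("AD", "NC"), each = 10)
  res <- looSvm(x, y, alpha = 0.05, protocol = "paper")
  expect_equal(res@protocol, "paper")
  expect_equal(res@alpha, 0.05)
  expect_equal(length(res@nFeaturesPerFold), 20L)
  expect_true(all(res@nFeaturesPerFold == res@nFeaturesPerFold[1]))
})
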