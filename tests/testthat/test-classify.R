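test_that("the penalty grid spans 1e-8..1e8 in steps of 10^0.8", {
  g <- defaultCGrid()
  expect_length(g, 21L)
  expect_equal(g[1], 1e-8)
  expect_equal(g[21], 1e8)
  expect_equal(unique(round(diff(log10(g)), 10)), 0.8)
})

test_that("class balancing subsamples the majority deterministically", {
  set.seed(1)
  vals <- matrix(runif(117 * 2, 0.5, 1.5), 117, 2)
  ft <- asFeatureTable(vals, rep(c("correct", "error"), c(96, 21)))
  bal <- balanceClasses(ft, seed = 5)
  expect_equal(as.vector(table(trialLabels(bal))), c(21L, 21L))
  # minority class untouched
  expect_equal(featureValues(bal)[trialLabels(bal) == "error", ],
               vals[97:117, ])
  bal2 <- balanceClasses(ft, seed = 5)
  expect_identical(featureValues(bal), featureValues(bal2))

  # below the 20-trial gate: warn and proceed
  ftSmall <- asFeatureTable(vals[1:40, ], rep(c("correct", "error"), c(25, 15)))
  expect_warning(balSmall <- balanceClasses(ftSmall, seed = 2), "minority")
  expect_equal(as.vector(table(trialLabels(balSmall))), c(15L, 15L))

  ftBal <- asFeatureTable(vals[1:40, ], rep(c("error", "correct"), each = 20))
  expect_identical(balanceClasses(ftBal, seed = 1), ftBal)
})

test_that("confusion metrics evaluate the exact ratios", {
  expect_equal(confusionMetrics(9, 8, 2, 1), c(ca = 0.85, se = 0.9, sp = 0.8))
  expect_equal(confusionMetrics(10, 10, 0, 0), c(ca = 1, se = 1, sp = 1))
  expect_equal(confusionMetrics(0, 10, 0, 10), c(ca = 0.5, se = 0, sp = 1))
  expect_error(confusionMetrics(0, 5, 5, 0), "SE undefined")
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  y <- rep(c("error", "correct"), each = 5)
  expect_equal(rocAuc(c(6:10, 1:5), y), 1)
  expect_equal(rocAuc(c(6:10, 1:5), y) + rocAuc(-c(6:10, 1:5), y), 1)
  set.seed(3)
  s <- rnorm(2000); yy <- sample(rep(c("error", "correct"), each = 1000))
  expect_equal(rocAuc(s, yy), 0.5, tolerance = 0.05)
  expect_error(rocAuc(1:4, rep("error", 4)), "both classes")

  if (requireNamespace("pROC", quietly = TRUE)) {
    # independent cross-check, including ties
    s <- round(rnorm(60), 1)
    yy <- sample(rep(c("error", "correct"), each = 30))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = yy, predictor = s, levels = c("correct", "error"),
      direction = "<", quiet = TRUE)))
    expect_equal(rocAuc(s, yy), ref, tolerance = 1e-12)
  }
})

test_that("LOOCV separates well-separated classes perfectly", {
  set.seed(4)
  X <- matrix(c(rnorm(10, -1, 0.01), rnorm(10, 1, 0.01)), ncol = 1)
  y <- rep(c("error", "correct"), each = 10)
  ev <- loocvRbfSvm(X, y, seed = 2)
  expect_equal(ev@ca, 1.0)
  expect_equal(ev@auc, 1.0)
  expect_error(loocvRbfSvm(X[1:4, , drop = FALSE], y[1:4]), "at least 6")
})

test_that("LOOCV metrics always match the pooled per-fold predictions", {
  set.seed(9)
  X <- matrix(rnorm(30 * 2), 30, 2)
  X[1:15, 1] <- X[1:15, 1] + 1.2
  y <- rep(c("error", "correct"), each = 15)
  ev <- loocvRbfSvm(X, y, seed = 7)
  pr <- ev@predictions
  expect_equal(nrow(pr), 30L)
  expect_equal(sum(ev@confusion), 30L)
  expect_equal(unname(ev@confusion["TP"]),
               sum(pr$truth == "error" & pr$predicted == "error"))
  m <- confusionMetrics(ev@confusion["TP"], ev@confusion["TN"],
                        ev@confusion["FP"], ev@confusion["FN"])
  expect_equal(ev@ca, unname(m["ca"]))
  expect_equal(ev@se, unname(m["se"]))
  expect_equal(ev@sp, unname(m["sp"]))
  expect_equal(ev@auc, rocAuc(pr$score, pr$truth))
})

test_that("label-permuted features classify at chance on average", {
  set.seed(15)
  cas <- vapply(1:8, function(r) {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- sample(rep(c("error", "correct"), each = 20))
    loocvRbfSvm(X, y, seed = r)@ca
  }, numeric(1))
  expect_gte(mean(cas), 0.40)
  expect_lte(mean(cas), 0.60)
})
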