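# synthetic feature containers for the LOO classifier
toy_features <- function(n_per_group, sep = 5, seed = 1) {
  set.seed(seed)
  out <- list()
  for (g in c("control", "patient")) {
    mu <- if (g == "control") sep else 0
    for (i in seq_len(n_per_group)) {
      id <- paste0(substr(g, 1, 1), i)
      out[[id]] <- list(group = g,
                        scalars = c(entropy = rnorm(1, mu)),
                        values = list(metric = rnorm(20, mu)))
    }
  }
  out
}

test_that("sensitivity/specificity use predicted-class denominators", {
  # TP = 5, FP = 1, TN = 7, FN = 2
  truth <- c(rep("patient", 5), rep("control", 1),   # predicted patient
             rep("control", 7), rep("patient", 2))   # predicted control
  pred <- c(rep("patient", 6), rep("control", 9))
  r <- predicted_rates(truth, pred)
  expect_equal(r$sensitivity, 5 / 6)
  expect_equal(r$specificity, 7 / 9)
  # empty predicted class -> NA
  r2 <- predicted_rates(truth, rep("patient", 15))
  expect_true(is.na(r2$specificity))
})

test_that("separable groups are classified perfectly and deterministically", {
  feats <- toy_features(8, sep = 5)
  res <- loo_classify(feats, c("entropy", "metric"), runs = 3, steps = 2000,
                      seed = 5)
  expect_equal(res$median_sensitivity, 1)
  expect_equal(res$median_specificity, 1)
  expect_true(all(res$prob >= 0 & res$prob <= 1))
  res2 <- loo_classify(feats, c("entropy", "metric"), runs = 3, steps = 2000,
                       seed = 5)
  expect_identical(res$prob, res2$prob)    # bit-reproducible under the seed
  expect_error(loo_classify(feats, character(0)), "empty feature subset")
})

test_that("permuted labels yield chance-level rates", {
  # no group signal in the features: after permuting the labels, held-out
  # predictions are pure noise and both rates sit near the 0.5 prevalence
  feats <- toy_features(8, sep = 0, seed = 2)
  set.seed(99)
  ids <- names(feats)
  perm <- sample(vapply(feats, function(p) p$group, character(1)))
  for (i in seq_along(ids)) feats[[ids[i]]]$group <- perm[i]
  res <- loo_classify(feats, c("entropy", "metric"), runs = 50, steps = 2000,
                      seed = 7)
  # the protocol must not beat the 0.5 prevalence under the null (that
  # would be leakage); leave-one-out with balanced groups is actually
  # biased *below* chance on null data (the training fold always leans
  # 7-vs-8 against the held-out class), so only the upper bound is a
  # lawful assertion
  expect_lt(res$median_sensitivity, 0.7)
  expect_lt(res$median_specificity, 0.7)
})

test_that("per-fold feature representation never uses the held-out participant", {
  feats <- toy_features(4, sep = 2, seed = 3)
  # give one participant an extreme outlier value; its fold's histogram
  # range must come from the others
  feats$c1$values$metric <- c(feats$c1$values$metric, 1e6)
  X <- mobimark:::fold_design(feats, "metric", bins = 10, test_id = "c1")
  expect_equal(sum(X["c2", ]), 1)     # training histograms normalised
  expect_equal(sum(X["c1", ]), 1)     # held-out row clipped into range
})

test_that("the RBF-SVM separates separable segment classes", {
  set.seed(4)
  seg <- data.frame(
    companionship = rep(c("alone", "accompanied"), each = 100),
    f1 = c(rnorm(100, 0), rnorm(100, 6)),
    f2 = c(rnorm(100, 0), rnorm(100, 6)))
  res <- classify_alone_accompanied(seg, feature_cols = c("f1", "f2"),
                                    repeats = 10, seed = 11)
  expect_equal(res$median_accuracy, 1)

  # identical distributions -> accuracy near chance
  seg0 <- data.frame(companionship = rep(c("alone", "accompanied"), each = 100),
                     f1 = rnorm(200), f2 = rnorm(200))
  res0 <- classify_alone_accompanied(seg0, feature_cols = c("f1", "f2"),
                                     repeats = 20, seed = 12)
  expect_gt(res0$median_accuracy, 0.35)
  expect_lt(res0$median_accuracy, 0.65)

  # duplicating every segment leaves the result unchanged within noise
  seg2 <- rbind(seg, seg)
  res2 <- classify_alone_accompanied(seg2, feature_cols = c("f1", "f2"),
                                     repeats = 10, seed = 13)
  expect_equal(res2$median_accuracy, 1)

  expect_error(classify_alone_accompanied(seg[1:15, ],
                                          feature_cols = c("f1", "f2")),
               "at least 10")
})

test_that("the combination report returns one summary row per subset", {
  feats <- toy_features(5, sep = 4, seed = 6)
  rep_ <- feature_combination_report(
    feats, list("entropy", c("entropy", "metric")),
    runs = 2, steps = 1000, seed = 3)
  expect_equal(nrow(rep_), 2)
  expect_equal(rep_$features, c("entropy", "entropy+metric"))
  empty <- feature_combination_report(feats, list())
  expect_equal(nrow(empty), 0)
})

test_that("the bin sweep reruns the classifier per setting and flags repeats", {
  feats <- toy_features(5, sep = 4, seed = 8)
  sw <- bin_sweep(feats, "metric", c(5, 10, 10), runs = 2, steps = 1000,
                  seed = 3)
  expect_equal(sw$bins, c(5, 10, 10))
  expect_equal(sw$duplicate, c(FALSE, FALSE, TRUE))
  main <- loo_classify(feats, "metric", bins = 10, runs = 2, steps = 1000,
                       seed = 3)
  expect_equal(sw$median_sensitivity[2], main$median_sensitivity)
  expect_equal(nrow(bin_sweep(feats, "metric", integer(0))), 0)
})
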