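# Metrics, curves, cross-validation protocol, split, Welch's t-test.

test_that("confusion_counts tallies the 2x2 table", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unname(unlist(cc)), c(1, 1, 1, 1))
  cc2 <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(cc2$fp + cc2$fn, 0)
  expect_error(confusion_counts(1, c(1, 0)),
               class = "voxppi_error_validation")

  # element-wise counting oracle on random vectors
  withr::with_seed(14, {
    truth <- rbinom(200, 1, 0.4)
    pred <- rbinom(200, 1, 0.5)
  })
  cc3 <- confusion_counts(truth, pred)
  expect_equal(cc3$tp, sum(truth & pred))
  expect_equal(cc3$tn, sum(!truth & !pred))
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 200)
})

test_that("metrics_from_confusion reproduces the defining formulas", {
  perfect <- metrics_from_confusion(
    tibble::tibble(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(unname(unlist(perfect)), c(1, 1, 1, 1, 1, 1))
  coin <- metrics_from_confusion(
    tibble::tibble(tp = 25, fp = 25, tn = 25, fn = 25))
  expect_equal(coin$accuracy, 0.5)
  expect_equal(coin$mcc, 0)

  # random tables against a direct transliteration
  for (s in 1:100) {
    cc <- withr::with_seed(s, tibble::tibble(
      tp = sample(0:30, 1), fp = sample(0:30, 1),
      tn = sample(0:30, 1), fn = sample(0:30, 1)))
    if (sum(cc) == 0) next
    m <- metrics_from_confusion(cc)
    tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
    expect_equal(m$accuracy, (tp + tn) / (tp + fp + tn + fn))
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
      sqrt((tn + fn))
    if (den > 0) expect_equal(m$mcc, (tp * tn - fp * fn) / den)
  }
})

test_that("zero-denominator metrics are flagged undefined, not zeroed", {
  m <- metrics_from_confusion(
    tibble::tibble(tp = 0, fp = 0, tn = 10, fn = 5))
  expect_true(is.na(m$precision))
  expect_true("precision" %in% attr(m, "undefined"))
  expect_error(metrics_from_confusion(
    tibble::tibble(tp = 0, fp = 0, tn = 0, fn = 0)),
    class = "voxppi_error_validation")
})

test_that("MCC is symmetric under class swap", {
  for (s in 1:20) {
    cc <- withr::with_seed(s, tibble::tibble(
      tp = sample(1:30, 1), fp = sample(1:30, 1),
      tn = sample(1:30, 1), fn = sample(1:30, 1)))
    swapped <- tibble::tibble(tp = cc$tn, fp = cc$fn,
                              tn = cc$tp, fn = cc$fp)
    expect_equal(metrics_from_confusion(cc)$mcc,
                 metrics_from_confusion(swapped)$mcc)
  }
})

test_that("auroc handles separation, ties, and matches the oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- sample(10:40, 1)
      scores <- round(runif(n), 1)     # coarse grid forces ties
      labels <- rbinom(n, 1, 0.5)
    })
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
    # complement identity
    expect_equal(auroc(scores, labels) + auroc(-scores, labels), 1)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), class = "voxppi_error_validation")
})

test_that("auroc agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(77, {
    scores <- rnorm(60)
    labels <- rbinom(60, 1, 0.5)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                        direction = "<", quiet = TRUE)))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("auprc integrates the precision-recall steps", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # constant scores collapse to a single step at the prevalence
  expect_equal(auprc(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  # a worked example: scores 4,3,2,1 with labels 1,0,1,0
  # thresholds give (recall, precision) = (.5,1), (.5,.5), (1,2/3), (1,.5)
  expect_equal(auprc(c(4, 3, 2, 1), c(1, 0, 1, 0)), 0.5 * 1 + 0.5 * 2 / 3)
})

test_that("repeated 3-fold CV yields 9 disjoint covering evaluations", {
  withr::with_seed(30, {
    data <- tibble::tibble(xf = rnorm(90),
                           label = rep(c(0, 1), each = 45))
  })
  trainer <- function(train) {
    fit <- stats::glm(label ~ xf, data = train, family = binomial)
    function(test) as.numeric(predict(fit, test, type = "response"))
  }
  cv <- repeated_kfold(data, trainer, k = 3, repeats = 3, seed = 2)
  folds <- tidy(cv)
  expect_equal(nrow(folds), 9)
  expect_equal(unique(folds$`repeat`), 1:3)
  # partition property: each sample tested exactly once per repeat
  for (assign in cv$assignments) {
    expect_equal(sort(unique(assign)), 1:3)
    expect_equal(length(assign), 90)
    # stratification within one per class
    for (f in 1:3) {
      expect_lte(abs(sum(data$label[assign == f]) - 15), 1)
    }
  }
  # summary is mean and sample sd over the 9 folds
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"],
               mean(folds$accuracy))
  expect_equal(cv$summary$sd[cv$summary$metric == "accuracy"],
               sd(folds$accuracy))
  g <- glance(cv)
  expect_equal(g$accuracy_mean, mean(folds$accuracy))
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("a constant-score trainer scores at the class proportion", {
  withr::with_seed(40, {
    data <- tibble::tibble(label = rbinom(120, 1, 0.3))
  })
  while (length(unique(data$label)) < 2) data$label[1] <- 1 - data$label[1]
  trainer <- function(train) function(test) rep(0.9, nrow(test))
  cv <- repeated_kfold(data, trainer, k = 3, repeats = 1, seed = 3)
  prop <- mean(data$label)
  for (acc in tidy(cv)$accuracy) {
    expect_lt(abs(acc - prop), 2 / 40)   # within stratification slack
  }
})

test_that("CV refuses classes smaller than k", {
  data <- tibble::tibble(label = c(1, rep(0, 10)))
  trainer <- function(train) function(test) rep(0.5, nrow(test))
  expect_error(repeated_kfold(data, trainer, k = 3, repeats = 1),
               class = "voxppi_error_stratification")
})

test_that("train_test_split is stratified, covering and deterministic", {
  data <- tibble::tibble(label = rep(c(0, 1), each = 50))
  sp <- train_test_split(data, 0.2, seed = 6)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sum(sp$test$label), 10)   # exact class balance here
  sp2 <- train_test_split(data, 0.2, seed = 6)
  expect_identical(sp$test, sp2$test)
  expect_error(train_test_split(data, 1.2),
               class = "voxppi_error_config")
})

test_that("welch_t_test matches the closed form and flags significance", {
  same <- welch_t_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  got <- welch_t_test(1:5, 2:6)
  want <- oracle_welch(1:5, 2:6)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  expect_false(got$significant)

  withr::with_seed(50, {
    far <- welch_t_test(rnorm(10, 0), rnorm(10, 100))
  })
  expect_lt(far$p_value, 0.05)
  expect_true(far$significant)

  expect_error(welch_t_test(rep(1, 5), rep(1, 5)),
               class = "voxppi_error_undefined_statistic")
  expect_error(welch_t_test(1, c(1, 2)),
               class = "voxppi_error_validation")
})
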