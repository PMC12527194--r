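test_that("labeling follows the 24 h first-adjustment rule", {
  ev <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(time = m[, 1], new_dose = m[, 2])
  }
  # first adjustment raises the dose -> positive
  expect_equal(assign_label(ev(6, 0.3), 0, 48, dose0 = 0.2), 1L)
  # no adjustment within 24 h with full follow-up -> negative
  expect_equal(assign_label(ev(30, 0.3), 0, 48, dose0 = 0.2), 0L)
  expect_equal(assign_label(data.frame(time = numeric(0),
                                       new_dose = numeric(0)), 0, 24), 0L)
  # first adjustment lowers, later one raises -> negative
  expect_equal(assign_label(ev(3, 0.15, 10, 0.4), 0, 48, dose0 = 0.2), 0L)
  # no events and short follow-up -> unlabeled
  expect_true(is.na(assign_label(ev(30, 0.3), 0, 20, dose0 = 0.2)))
  # events before the recording only set the dose in force
  expect_equal(assign_label(ev(-5, 0.4, 6, 0.3), 0, 48, dose0 = 0.2), 0L)
  expect_equal(assign_label(ev(-5, 0.1, 6, 0.3), 0, 48, dose0 = 0.2), 1L)
  # an event exactly at +24 h does not count (half-open window)
  expect_equal(assign_label(ev(24, 0.5), 0, 48, dose0 = 0.2), 0L)
})

test_that("labeling matches a brute-force oracle on all small event patterns", {
  # independent oracle: walk the timeline minute by minute
  oracle <- function(events, t_rec, fu_end, dose0) {
    dose <- dose0
    if (nrow(events)) {
      for (k in seq_len(nrow(events)))
        if (events$time[k] <= t_rec) dose <- events$new_dose[k]
    }
    if (nrow(events)) {
      for (k in seq_len(nrow(events))) {
        tk <- events$time[k]
        if (tk > t_rec && tk < t_rec + 24)
          return(if (events$new_dose[k] > dose) 1L else 0L)
      }
    }
    if (fu_end >= t_rec + 24) 0L else NA_integer_
  }
  times_pool <- c(-2, 1, 5, 12, 23, 25)
  dirs_pool <- list(c(), c(1), c(-1), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1),
                    c(1, -1, 1), c(-1, 1, -1), c(1, 1, -1))
  n_checked <- 0
  for (dirs in dirs_pool) {
    k <- length(dirs)
    time_sets <- if (k == 0) list(numeric(0)) else
      combn(times_pool, k, simplify = FALSE)
    for (ts in time_sets) {
      dose <- 0.2; doses <- numeric(k)
      for (j in seq_len(k)) {
        dose <- max(0.05, dose + dirs[j] * 0.05)
        doses[j] <- dose
      }
      if (k > 1 && any(diff(doses) == 0)) next
      ev <- data.frame(time = sort(ts), new_dose = doses)
      for (fu in c(20, 30)) {
        got <- assign_label(ev, 0, fu, dose0 = 0.2)
        want <- oracle(ev, 0, fu, dose0 = 0.2)
        expect_identical(got, want)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 200)
})

test_that("standardization centres and scales, and transfers to held-out rows", {
  set.seed(2)
  X <- data.frame(a = rnorm(30, 5, 2), b = runif(30, -1, 9))
  s <- standardize(X)
  expect_equal(unname(colMeans(s$X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s$X, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(standardize(cbind(X, k = 1)), "constant")
  # held-out rows standardized with training statistics differ from
  # self-standardization
  new <- data.frame(a = rnorm(5, 9, 1), b = runif(5))
  tr_applied <- standardize(new, transform = s)$X
  self <- standardize(new)$X
  expect_false(isTRUE(all.equal(tr_applied, self)))
  expect_equal(tr_applied$a, (new$a - s$center[["a"]]) / s$scale[["a"]])
})

test_that("with variance zero the mixed model matches plain logistic regression", {
  set.seed(8)
  n <- 120
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.4 + 1.2 * X$x1))
  groups <- seq_len(n)  # one observation per patient
  m <- fit_glmm(X, y, groups)
  g <- glm(y ~ x1 + x2, data = cbind(X, y = y), family = binomial)
  expect_equal(unname(coef(m)), unname(coef(g)), tolerance = 1e-3)
})

test_that("stepwise AIC never co-selects an exact duplicate feature", {
  set.seed(21)
  npat <- 30
  pat <- rep(seq_len(npat), each = 3)
  n <- length(pat)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  X$dup <- X$x1
  y <- rbinom(n, 1, plogis(1.5 * X$x1))
  sel <- stepwise_aic(standardize(X)$X, y, pat)
  expect_false(all(c("x1", "dup") %in% sel$features))
  expect_true(any(c("x1", "dup") %in% sel$features))
})

test_that("LOOCV applies the strict 0.5 threshold and is self-consistent", {
  # threshold rule: probability exactly 0.5 goes to class 0
  expect_equal(as.integer(0.5 > 0.5), 0L)
  set.seed(31)
  npat <- 18
  pat <- rep(seq_len(npat), each = 3)
  n <- length(pat)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X$x1))
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  cv <- loocv(X, y, pat, features = c("x1"))
  expect_equal(cv$class, as.integer(cv$prob > 0.5))
  cm <- confusion_counts(cv$y, cv$class)
  expect_equal(cm$tn + cm$fp + cm$fn + cm$tp, n)
  # reconstructing the confusion matrix from the predictions is exact
  expect_equal(cm$tp, sum(cv$y == 1 & cv$prob > 0.5))
})

test_that("classification metrics reproduce the published confusion matrices", {
  # entire-dataset matrix (tn, fp, fn, tp) = (53, 2, 6, 16)
  m <- classification_metrics(53, 2, 6, 16)
  expect_equal(unname(m$rounded["balanced_accuracy"]), 0.85)
  expect_equal(unname(m$rounded["accuracy"]), 0.90)
  expect_equal(unname(m$rounded["sensitivity"]), 0.73)
  expect_equal(unname(m$rounded["specificity"]), 0.96)
  expect_equal(unname(m$rounded["precision"]), 0.89)
  expect_equal(unname(m$rounded["f1"]), 0.80)
  expect_equal(unname(m$rounded["fpr"]), 0.04)
  expect_equal(m$misclassified, 8)
  # cross-validated matrix (49, 6, 8, 14)
  m2 <- classification_metrics(49, 6, 8, 14)
  expect_equal(unname(m2$rounded["balanced_accuracy"]), 0.76)
  expect_equal(unname(m2$rounded["accuracy"]), 0.82)
  # perfect classifier
  mp <- classification_metrics(10, 0, 0, 5)
  expect_true(all(mp$exact == 1 | names(mp$exact) == "fpr"))
  expect_equal(unname(mp$exact["fpr"]), 0)
  # undefined precision is flagged, not silently zero
  m0 <- classification_metrics(5, 0, 3, 0)
  expect_true(m0$undefined_precision)
  expect_true(is.na(m0$exact["precision"]))
})

test_that("the full-vs-simplified advantage column follows from both matrices", {
  full <- classification_metrics(53, 2, 6, 16)$exact
  simplified <- classification_metrics(52, 3, 10, 12)$exact
  adv <- metric_advantage(full, simplified)
  expect_equal(unname(round(adv["accuracy"], 1)), 7.8)
  expect_equal(unname(round(adv["sensitivity"], 1)), 33.3)
  expect_equal(unname(round(adv["specificity"], 1)), 1.9)
  expect_equal(unname(round(adv["balanced_accuracy"], 1)), 13.4)
  expect_equal(unname(round(adv["fpr"], 1)), -33.3)
  expect_equal(unname(round(adv["precision"], 1)), 11.1)
  expect_equal(unname(round(adv["f1"], 1)), 23.3)
})
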