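# Norepinephrine dose-change prediction: observation labeling from dose
# events, feature standardization, binomial mixed model with per-patient
# random intercept, bidirectional stepwise AIC, leave-one-out
# cross-validation and classification metrics.

#' Label an observation from a norepinephrine dose-event series
#'
#' Looks at the 24 h window following the recording time: label 1 if the
#' first dose change in the window raises the dose relative to the dose in
#' force at recording time, 0 if it lowers it or if the window contains no
#' change and follow-up covers the full 24 h, `NA` (unlabeled) when there
#' is no change and follow-up ends before 24 h.
#'
#' @param events Data frame with columns `time` (hours, numeric,
#'   increasing) and `new_dose`; each row is a documented dose change.
#' @param t_rec Recording time (hours).
#' @param follow_up_end End of available follow-up (hours).
#' @param dose0 Dose in force before the first event (default 0).
#' @param window_h Prediction window length (default 24 h).
#' @return 0, 1 or `NA_integer_`.
#' @export
assign_label <- function(events, t_rec, follow_up_end, dose0 = 0,
                         window_h = 24) {
  stopifnot(t_rec <= follow_up_end)
  if (nrow(events) > 0) {
    stopifnot(!is.unsorted(events$time))
    if (any(diff(events$new_dose) == 0))
      stop("consecutive dose events must differ")
  }
  prior <- events$new_dose[events$time <= t_rec]
  dose_now <- if (length(prior)) tail(prior, 1) else dose0
  # half-open window (t_rec, t_rec + 24h): changes exactly at t_rec define
  # the dose in force, changes exactly at +24h do not count
  inw <- events$time > t_rec & events$time < t_rec + window_h
  if (any(inw)) {
    first <- events$new_dose[which(inw)[1]]
    return(if (first > dose_now) 1L else 0L)
  }
  if (follow_up_end >= t_rec + window_h) 0L else NA_integer_
}

#' Standardize a feature table
#'
#' Per-column z-scores using means and SDs of the supplied rows; the
#' returned transform can be re-applied to held-out rows so that test data
#' is scaled with training statistics only.
#'
#' @param X Numeric data frame or matrix (no missing values).
#' @param transform Optional transform (list with `center`, `scale`) from a
#'   previous call; when given, it is applied instead of re-estimated.
#' @return List with `X` (standardized), `center`, `scale`.
#' @export
standardize <- function(X, transform = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in feature table")
  if (is.null(transform)) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    if (any(scl == 0))
      stop("constant feature column(s): ",
           paste(colnames(X)[scl == 0], collapse = ", "))
  } else {
    ctr <- transform$center; scl <- transform$scale
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(X = as.data.frame(Xs), center = ctr, scale = scl)
}

glmm_formula <- function(features) {
  rhs <- if (length(features) == 0) "1" else
    paste(sprintf("`%s`", features), collapse = " + ")
  as.formula(paste("y ~", rhs, "+ (1 | patient)"))
}

#' Fit the binomial mixed model
#'
#' Logistic regression with a per-patient random intercept, fitted by
#' Laplace-approximate maximum likelihood (lme4).  Suitable for repeated
#' observations per patient, where independence across observations fails.
#'
#' @param X Feature data frame (already standardized).
#' @param y Binary outcome vector (0/1).
#' @param groups Patient identifiers (one per row of `X`).
#' @param features Feature subset to use (default: all columns of `X`).
#' @return An `ne_model` wrapping the lme4 fit.
#' @export
fit_glmm <- function(X, y, groups, features = colnames(X)) {
  stopifnot(length(y) == nrow(X), length(groups) == nrow(X))
  if (length(unique(groups)) < 2) stop("need at least 2 patients")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  dat <- cbind(data.frame(y = y, patient = factor(groups)),
               X[, features, drop = FALSE])
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(glmm_formula(features), data = dat, family = binomial,
                  control = lme4::glmerControl(
                    calc.derivs = FALSE,
                    check.conv.singular = "ignore")))),
    error = function(e) NULL)
  retried <- FALSE
  if (is.null(fit)) {  # retry with the faster, more robust approximation
    retried <- TRUE
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(glmm_formula(features), data = dat, family = binomial,
                    nAGQ = 0,
                    control = lme4::glmerControl(
                      calc.derivs = FALSE,
                      check.conv.singular = "ignore")))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {  # degenerate fallback: variance component pinned at 0
    rhs <- if (length(features) == 0) "1" else
      paste(sprintf("`%s`", features), collapse = " + ")
    fit <- suppressWarnings(
      stats::glm(as.formula(paste("y ~", rhs)), data = dat,
                 family = binomial))
    return(structure(list(fit = fit, features = features, aic = AIC(fit),
                          converged = FALSE, fallback = "glm",
                          retried = TRUE),
                     class = "ne_model"))
  }
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(fit = fit, features = features, aic = AIC(fit),
                 converged = conv, fallback = NULL, retried = retried),
            class = "ne_model")
}

#' @method print ne_model
#' @export
print.ne_model <- function(x, ...) {
  cat("Binomial mixed model (random intercept per patient)\n")
  cat("  features:", if (length(x$features)) paste(x$features, collapse = ", ")
      else "(intercept only)", "\n")
  cat("  AIC:", round(x$aic, 2), "\n")
  print(round(coef(x), 3))
  if (is.null(x$fallback))
    cat("  random-intercept SD:",
        round(sqrt(unlist(lme4::VarCorr(x$fit))[1]), 3), "\n")
  else cat("  (fallback plain logistic fit; variance component 0)\n")
  invisible(x)
}

#' @method summary ne_model
#' @export
summary.ne_model <- function(object, ...) summary(object$fit, ...)

#' @method coef ne_model
#' @export
coef.ne_model <- function(object, ...) {
  if (is.null(object$fallback)) lme4::fixef(object$fit)
  else stats::coef(object$fit)
}

#' Fixed-effect coefficient table with Wald p-values
#'
#' @param model An `ne_model`.
#' @return Data frame with estimate, SE, z and p per fixed effect.
#' @export
coef_table <- function(model) {
  s <- summary(model$fit)$coefficients
  data.frame(feature = rownames(s), estimate = s[, 1], se = s[, 2],
             z = s[, 3], p = s[, 4], row.names = NULL)
}

#' @method predict ne_model
#' @export
predict.ne_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(predict(object$fit, type = "response"))
  predict(object$fit, newdata = newdata, type = "response",
          allow.new.levels = TRUE)
}

#' Bidirectional stepwise AIC feature selection for the mixed model
#'
#' Starts from the intercept-only model; at each step evaluates adding any
#' excluded feature and dropping any included one, and takes the move with
#' the largest AIC decrease.  Stops when no move decreases the AIC.  Near
#' ties (< 1e-9) prefer the smaller model, then the lexicographically
#' earlier feature set.
#'
#' @inheritParams fit_glmm
#' @param candidates Candidate feature names (default: all columns).
#' @param trace Print the moves.
#' @return An `ne_model` for the selected subset, with the selection path
#'   in `$path`.
#' @export
stepwise_aic <- function(X, y, groups, candidates = colnames(X),
                         trace = FALSE) {
  current <- character(0)
  cur_fit <- fit_glmm(X, y, groups, current)
  path <- data.frame(step = 0, move = "start", feature = "",
                     aic = cur_fit$aic)
  step_i <- 0
  repeat {
    step_i <- step_i + 1
    moves <- list()
    for (f in setdiff(candidates, current))
      moves[[length(moves) + 1]] <- list(type = "add", feature = f,
                                         set = c(current, f))
    for (f in current)
      moves[[length(moves) + 1]] <- list(type = "drop", feature = f,
                                         set = setdiff(current, f))
    if (length(moves) == 0) break
    aics <- vapply(moves, function(m) {
      fit <- tryCatch(fit_glmm(X, y, groups, m$set),
                      error = function(e) NULL)
      if (is.null(fit)) Inf else fit$aic
    }, numeric(1))
    best <- which(aics < cur_fit$aic - 1e-9)
    if (length(best) == 0) break
    # largest decrease; ties -> smaller model, then feature name order
    sizes <- vapply(moves, function(m) length(m$set), numeric(1))
    feats <- vapply(moves, `[[`, character(1), "feature")
    ord <- order(aics, sizes, feats)
    pick <- ord[ord %in% best][1]
    current <- moves[[pick]]$set
    cur_fit <- fit_glmm(X, y, groups, current)
    path <- rbind(path, data.frame(step = step_i,
                                   move = moves[[pick]]$type,
                                   feature = moves[[pick]]$feature,
                                   aic = cur_fit$aic))
    if (trace)
      cat("step", step_i, moves[[pick]]$type, moves[[pick]]$feature,
          "AIC", round(cur_fit$aic, 3), "\n")
  }
  cur_fit$path <- path
  cur_fit
}

#' Leave-one-out cross-validation of the dose-change classifier
#'
#' For each labeled observation the model is refitted on the remaining
#' observations (standardizing with training rows only) and the held-out
#' probability is predicted using the fixed effects plus the patient's
#' estimated random intercept when the patient still appears in training
#' (population-level prediction otherwise).  Class 1 requires probability
#' strictly above `threshold`.
#'
#' @param X Raw (unstandardized) feature data frame.
#' @param y Binary labels.
#' @param groups Patient identifiers.
#' @param features Feature subset (typically from [stepwise_aic()] on the
#'   full data); set `reselect = TRUE` to redo selection inside every fold.
#' @param threshold Classification threshold (default 0.5, strict `>`).
#' @param reselect Re-run stepwise selection per fold.
#' @param candidates Candidate set for per-fold reselection.
#' @return Data frame with `prob`, `class`, `y`, `patient`, `flagged`.
#' @export
loocv <- function(X, y, groups, features, threshold = 0.5,
                  reselect = FALSE, candidates = colnames(X)) {
  n <- nrow(X)
  prob <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]; gtr <- groups[-i]
    if (length(unique(ytr)) < 2) {
      prob[i] <- mean(ytr)
      flagged[i] <- TRUE
      next
    }
    # standardize (and fit on) only the columns the fold can use: a column
    # may degenerate to constant when one observation is held out
    usable <- colnames(Xtr)[vapply(Xtr, function(v) sd(v) > 0, logical(1))]
    std <- standardize(Xtr[, usable, drop = FALSE])
    feats <- if (reselect)
      stepwise_aic(std$X, ytr, gtr, intersect(candidates, usable))$features
    else intersect(features, usable)
    fit <- fit_glmm(std$X, ytr, gtr, feats)
    Xte <- standardize(X[i, usable, drop = FALSE], transform = std)$X
    nd <- cbind(data.frame(patient = factor(groups[i],
                                            levels = levels(factor(gtr)))),
                Xte)
    prob[i] <- predict(fit, newdata = nd)
  }
  data.frame(prob = prob, class = as.integer(prob > threshold), y = y,
             patient = groups, flagged = flagged)
}

#' Confusion matrix from predictions
#'
#' @param y True labels (0/1).
#' @param class Predicted classes (0/1).
#' @return Named list `tn`, `fp`, `fn`, `tp`.
#' @export
confusion_counts <- function(y, class) {
  list(tn = sum(y == 0 & class == 0), fp = sum(y == 0 & class == 1),
       fn = sum(y == 1 & class == 0), tp = sum(y == 1 & class == 1))
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, balanced accuracy, false positive
#' rate, precision and F1, each reported exactly and rounded half-up to 2
#' decimals.
#'
#' @param tn,fp,fn,tp Confusion-matrix counts.
#' @return List with `exact` and `rounded` named vectors plus
#'   `misclassified` and `n`.
#' @export
classification_metrics <- function(tn, fp, fn, tp) {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0, tp + fn > 0, tn + fp > 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / (tn + fp + fn + tp)
  bal <- (sens + spec) / 2
  fpr <- fp / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  exact <- c(accuracy = acc, sensitivity = sens, specificity = spec,
             balanced_accuracy = bal, fpr = fpr, precision = prec, f1 = f1)
  list(exact = exact, rounded = round_half_up(exact),
       undefined_precision = tp + fp == 0,
       misclassified = fp + fn, n = tn + fp + fn + tp)
}

#' Relative advantage of one model over another, in percent
#'
#' `100 * (a - b) / b` per metric, as used to compare a full and a
#' simplified classifier.
#'
#' @param a,b Named metric vectors (e.g. `$exact` from
#'   [classification_metrics()]).
#' @return Named vector of percentages.
#' @export
metric_advantage <- function(a, b) 100 * (a - b) / b
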