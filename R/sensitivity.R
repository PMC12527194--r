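# Parameter-selection machinery: Sobol first-order indices (Saltelli
# estimator over Latin-hypercube base samples), relative local sensitivity
# matrix, inverse-Hessian pairwise parameter correlations, and greedy
# subset selection.

#' First-order Sobol sensitivity indices
#'
#' Saltelli-style estimator: two base matrices A and B (Latin hypercube,
#' seeded) and the k cross matrices AB_i give
#' `S1_i = mean(f(B) * (f(AB_i) - f(A))) / var(f)` for every output
#' component.  Outputs with (numerically) zero variance are flagged
#' undefined rather than reported as 0.
#'
#' @param model_fn Function mapping a named parameter vector to a numeric
#'   output vector (constant length).
#' @param ranges Named list of `c(lower, upper)` parameter ranges.
#' @param N Base sample size (>= 64).
#' @param seed RNG seed; the estimate is deterministic given the seed.
#' @return A `sobol_result`: list with `S1` (k x n_out matrix), `defined`
#'   (logical n_out), `N`, `var_y`.
#' @export
sobol_first_order <- function(model_fn, ranges, N = 256, seed = 1) {
  k <- length(ranges)
  stopifnot(N >= 64, k >= 1, !is.null(names(ranges)))
  set.seed(seed)
  UA <- lhs::randomLHS(N, k)
  UB <- lhs::randomLHS(N, k)
  scale_row <- function(U) {
    sapply(seq_len(k), function(j)
      ranges[[j]][1] + U[, j] * diff(ranges[[j]]))
  }
  A <- scale_row(UA); B <- scale_row(UB)
  colnames(A) <- colnames(B) <- names(ranges)
  eval_mat <- function(M) {
    out <- apply(M, 1, function(row) model_fn(setNames(row, names(ranges))))
    if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
  }
  fA <- eval_mat(A); fB <- eval_mat(B)
  n_out <- ncol(fA)
  vy <- apply(rbind(fA, fB), 2, var)
  defined <- vy > 1e-12 * (1 + colMeans(rbind(fA, fB))^2)
  S1 <- matrix(NA_real_, nrow = k, ncol = n_out,
               dimnames = list(names(ranges), colnames(fA)))
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- eval_mat(ABi)
    S1[i, ] <- colMeans(fB * (fABi - fA)) / vy
  }
  S1[, !defined] <- NA_real_
  structure(list(S1 = S1, defined = defined, N = N, var_y = vy),
            class = "sobol_result")
}

#' @method print sobol_result
#' @export
print.sobol_result <- function(x, ...) {
  cat("Sobol first-order indices (N =", x$N, ")\n")
  cat("  peak S1 per parameter:\n")
  print(round(apply(x$S1, 1, max, na.rm = TRUE), 3))
  invisible(x)
}

#' Relative local sensitivity matrix
#'
#' Central finite differences of the model outputs with respect to each
#' parameter, scaled by the parameter value and the output magnitude:
#' entry (i, k) is `(dy_i/dtheta_k) * theta_k / scale_i`, with
#' `scale_i = |y_i|` when nonzero, else 1.
#'
#' @param model_fn Function: named parameter vector -> output vector.
#' @param params0 Named evaluation point (strictly inside the ranges).
#' @param rel_step Relative perturbation (default 1e-2).
#' @return Matrix with one row per output, one column per parameter.
#' @export
local_sensitivity_matrix <- function(model_fn, params0, rel_step = 1e-2) {
  k <- length(params0)
  y0 <- model_fn(params0)
  scale <- ifelse(abs(y0) > 1e-12, abs(y0), 1)
  S <- matrix(NA_real_, nrow = length(y0), ncol = k,
              dimnames = list(names(y0), names(params0)))
  for (j in seq_len(k)) {
    h <- rel_step * abs(params0[[j]])
    if (h == 0) h <- rel_step
    up <- dn <- params0
    up[[j]] <- params0[[j]] + h
    dn[[j]] <- params0[[j]] - h
    yu <- tryCatch(model_fn(up), error = function(e) NULL)
    yd <- tryCatch(model_fn(dn), error = function(e) NULL)
    if (is.null(yu) && is.null(yd))
      stop("model failed on both sides for parameter ", names(params0)[j])
    d <- if (is.null(yu)) {
      warning("one-sided difference for ", names(params0)[j])
      (y0 - yd) / h
    } else if (is.null(yd)) {
      warning("one-sided difference for ", names(params0)[j])
      (yu - y0) / h
    } else (yu - yd) / (2 * h)
    S[, j] <- d * params0[[j]] / scale
  }
  S
}

#' Pairwise parameter correlations from the sensitivity matrix
#'
#' Forms the Gauss-Newton Hessian `H = S'S`, inverts it, and converts the
#' inverse to a correlation matrix; near-singular `H` (exactly collinear
#' parameter pairs) is flagged and the offending pairs reported instead.
#'
#' @param S Sensitivity matrix (outputs x parameters).
#' @return An `identifiability_result`: list with `correlation` (or NULL),
#'   `singular` flag, `collinear_pairs` (data.frame when singular),
#'   `hessian`.
#' @export
identifiability_correlations <- function(S) {
  H <- crossprod(S)
  k <- ncol(H)
  rc <- tryCatch(rcond(H), error = function(e) 0)
  if (rc < 1e-12) {
    # rank the most collinear (normalized) column pairs
    pairs <- NULL
    nrm <- sqrt(colSums(S^2))
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      ca <- abs(sum(S[, a] * S[, b])) / (nrm[a] * nrm[b] + 1e-300)
      pairs <- rbind(pairs, data.frame(
        par1 = colnames(S)[a], par2 = colnames(S)[b], cosine = ca))
    }
    pairs <- pairs[order(-pairs$cosine), ]
    return(structure(list(correlation = NULL, singular = TRUE,
                          collinear_pairs = pairs, hessian = H),
                     class = "identifiability_result"))
  }
  Ci <- solve(H)
  corr <- Ci / sqrt(outer(diag(Ci), diag(Ci)))
  structure(list(correlation = corr, singular = FALSE,
                 collinear_pairs = NULL, hessian = H),
            class = "identifiability_result")
}

#' @method print identifiability_result
#' @export
print.identifiability_result <- function(x, ...) {
  if (x$singular) {
    cat("Identifiability: Hessian singular; most collinear pairs:\n")
    print(head(x$collinear_pairs, 3))
  } else {
    cat("Identifiability correlations:\n")
    print(round(x$correlation, 3))
  }
  invisible(x)
}

#' Greedy sensitivity- and identifiability-based parameter selection
#'
#' Parameters are visited in descending order of their peak first-order
#' Sobol index; a parameter is selected if its peak S1 exceeds `s1_floor`
#' and its |correlation| with every already-selected parameter stays below
#' `corr_ceiling`.
#'
#' @param sobol A `sobol_result`.
#' @param ident An `identifiability_result` (non-singular).
#' @param s1_floor Minimum peak S1 (default 0.05).
#' @param corr_ceiling Maximum tolerated |pairwise correlation| (default
#'   0.9).
#' @return Character vector of selected parameter names.
#' @export
select_parameters <- function(sobol, ident, s1_floor = 0.05,
                              corr_ceiling = 0.9) {
  stopifnot(s1_floor > 0, s1_floor < 1, corr_ceiling > 0, corr_ceiling < 1)
  peak <- apply(sobol$S1, 1, max, na.rm = TRUE)
  ord <- names(sort(peak, decreasing = TRUE))
  sel <- character(0)
  for (p in ord) {
    if (peak[[p]] < s1_floor) next
    if (length(sel) > 0 && !is.null(ident$correlation)) {
      cors <- abs(ident$correlation[p, sel])
      if (any(cors > corr_ceiling)) next
    }
    sel <- c(sel, p)
  }
  sel
}
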