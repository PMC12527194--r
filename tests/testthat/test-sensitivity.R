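test_that("Sobol first-order indices match closed forms on linear models", {
  rng <- list(x1 = c(0, 1), x2 = c(0, 1))
  # additive symmetric model: S1 = S2 = 0.5
  s <- sobol_first_order(function(p) p[["x1"]] + p[["x2"]], rng,
                         N = 2048, seed = 3)
  expect_equal(unname(s$S1[, 1]), c(0.5, 0.5), tolerance = 0.05)
  # y depends on x1 only
  s <- sobol_first_order(function(p) 3 * p[["x1"]] - 1, rng,
                         N = 1024, seed = 4)
  expect_lt(abs(s$S1["x1", 1] - 1), 0.05)
  expect_lt(abs(s$S1["x2", 1]), 0.05)
  # weighted: S1(x1) = a^2 V1 / (a^2 V1 + b^2 V2)
  a <- 2; b <- 1
  rng2 <- list(x1 = c(0, 2), x2 = c(0, 1))
  V1 <- diff(rng2$x1)^2 / 12; V2 <- diff(rng2$x2)^2 / 12
  s <- sobol_first_order(function(p) a * p[["x1"]] + b * p[["x2"]], rng2,
                         N = 2048, seed = 5)
  expect_lt(abs(s$S1["x1", 1] - a^2 * V1 / (a^2 * V1 + b^2 * V2)), 0.05)
})

test_that("Sobol estimates are deterministic given the seed and converge", {
  rng <- list(x1 = c(0, 1), x2 = c(0, 1))
  f <- function(p) p[["x1"]] + 0.5 * p[["x2"]]
  s1 <- sobol_first_order(f, rng, N = 256, seed = 9)
  s2 <- sobol_first_order(f, rng, N = 256, seed = 9)
  expect_identical(s1$S1, s2$S1)
  truth <- 1 / (1 + 0.25)
  eN <- abs(sobol_first_order(f, rng, N = 128, seed = 1)$S1["x1", 1] - truth)
  e4N <- abs(sobol_first_order(f, rng, N = 2048, seed = 1)$S1["x1", 1] - truth)
  expect_lt(e4N, eN + 0.01)
})

test_that("zero-variance outputs are flagged undefined, not zero", {
  rng <- list(x1 = c(0, 1))
  s <- sobol_first_order(function(p) c(p[["x1"]], 7), rng, N = 128, seed = 2)
  expect_false(s$defined[2])
  expect_true(is.na(s$S1[1, 2]))
  expect_false(is.na(s$S1[1, 1]))
})

test_that("relative local sensitivity matrix has the stated scaling", {
  # linear model y = 2 theta at theta = 3: relative sensitivity 2*3/6 = 1
  S <- local_sensitivity_matrix(function(p) c(y = 2 * p[["a"]]),
                                c(a = 3))
  expect_equal(S[1, 1], 1, tolerance = 1e-8)
  # output independent of a parameter gives a zero column
  S <- local_sensitivity_matrix(function(p) c(y1 = p[["a"]]^2, y2 = 5 * p[["a"]]),
                                c(a = 2, b = 1))
  expect_equal(unname(S[, "b"]), c(0, 0), tolerance = 1e-10)
  # central differences agree with an independent forward-difference
  # oracle on a smooth nonlinear model
  f <- function(p) c(y1 = exp(0.3 * p[["a"]]) * p[["b"]],
                     y2 = p[["a"]] / (1 + p[["b"]]^2))
  p0 <- c(a = 1.7, b = 0.8)
  S <- local_sensitivity_matrix(f, p0, rel_step = 1e-3)
  y0 <- f(p0)
  for (j in 1:2) {
    h <- 1e-7 * p0[[j]]
    up <- p0; up[[j]] <- p0[[j]] + h
    fd <- (f(up) - y0) / h * p0[[j]] / abs(y0)
    expect_equal(unname(S[, j]), unname(fd), tolerance = 1e-3)
  }
})

test_that("identifiability correlations follow the inverse Hessian", {
  # orthogonal columns: zero off-diagonal correlation
  S <- cbind(a = c(1, 0, 0, 0), b = c(0, 2, 0, 0))
  r <- identifiability_correlations(S)
  expect_false(r$singular)
  expect_equal(r$correlation["a", "b"], 0)
  expect_equal(diag(r$correlation), c(a = 1, b = 1))
  # two columns at a known angle: |corr| = cos(theta) for a 2x2 system
  theta <- pi / 5
  S2 <- cbind(a = c(1, 0), b = c(cos(theta), sin(theta)))
  r2 <- identifiability_correlations(S2)
  # closed form: corr = -cos(theta) from the 2x2 inverse
  expect_equal(abs(r2$correlation["a", "b"]), cos(theta), tolerance = 1e-10)
  expect_true(all(abs(r2$correlation) <= 1 + 1e-12))
  expect_equal(r2$correlation, t(r2$correlation))
  # duplicated parameters: singular, pair reported
  S3 <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(0, 1, 0))
  r3 <- identifiability_correlations(S3)
  expect_true(r3$singular)
  expect_equal(sort(c(r3$collinear_pairs$par1[1], r3$collinear_pairs$par2[1])),
               c("a", "b"))
})

test_that("greedy selection respects the S1 floor and correlation ceiling", {
  mk_sobol <- function(peaks) {
    structure(list(S1 = matrix(peaks, ncol = 1,
                               dimnames = list(names(peaks), NULL)),
                   defined = TRUE, N = 64), class = "sobol_result")
  }
  mk_ident <- function(corr) {
    structure(list(correlation = corr, singular = FALSE),
              class = "identifiability_result")
  }
  nm <- c("a", "b", "c", "d")
  corr0 <- diag(4); dimnames(corr0) <- list(nm, nm)
  # uncorrelated: top-k by S1 above the floor
  sel <- select_parameters(mk_sobol(c(a = 0.5, b = 0.3, c = 0.2, d = 0.01)),
                           mk_ident(corr0))
  expect_equal(sel, c("a", "b", "c"))
  # two perfectly correlated high-S1 parameters: keep the higher one
  corr1 <- corr0; corr1["a", "b"] <- corr1["b", "a"] <- 0.99
  sel <- select_parameters(mk_sobol(c(a = 0.5, b = 0.45, c = 0.2, d = 0.1)),
                           mk_ident(corr1))
  expect_equal(sel, c("a", "c", "d"))
  # engineered fixture vs exhaustive hand enumeration
  peaks <- c(a = 0.40, b = 0.35, c = 0.30, d = 0.25)
  corr2 <- corr0
  corr2["b", "c"] <- corr2["c", "b"] <- 0.95
  corr2["a", "d"] <- corr2["d", "a"] <- 0.92
  sel <- select_parameters(mk_sobol(peaks), mk_ident(corr2))
  # by hand: a (top), b ok, c blocked by b, d blocked by a
  expect_equal(sel, c("a", "b"))
})

test_that("the five tuned parameters are not mutually collinear in the model", {
  # local sensitivities of the fitted output set (four-site waveforms
  # plus radial SP and DP) at the reference parameter point
  cfg <- sim_config("coarse", max_cycles = 5, tol = 0)
  tr <- build_default_tree(175)
  f <- function(p) {
    o <- forward_observables(p, tr, 75, cfg)
    c(SP = o$SP, DP = o$DP,
      unlist(lapply(o$waveforms, function(w) w[seq(25, 1000, by = 50)])))
  }
  S <- local_sensitivity_matrix(f, fit_init())
  r <- identifiability_correlations(S)
  expect_false(r$singular)
  off <- abs(r$correlation[upper.tri(r$correlation)])
  expect_true(all(off < 0.9))
})
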