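mk_pulse_train <- function(duration_s, bpm, fs = 200, amp = 1,
                           spikes = NULL) {
  t <- seq(0, duration_s, by = 1 / fs)[- (duration_s * fs + 1)]
  T <- 60 / bpm
  u <- (t %% T) / T
  y <- amp * ifelse(u < 0.35, sin(pi * u / 0.35)^2, 0.05 * (1 - u))
  if (!is.null(spikes)) {
    for (ts in spikes) {
      i <- which(t >= ts & t < ts + 0.1)
      y[i] <- y[i] + amp * 1.2 * sin(pi * (t[i] - ts) / 0.1)^2
    }
  }
  y
}

fake_recording <- function(site, sel = NA, bpm = 60, fs = 200) {
  frags <- lapply(CUFF_LADDER <- seq(180, 40, by = -10), function(lev)
    mk_pulse_train(5, bpm, fs, amp = exp(-((lev - 100) / 40)^2)))
  names(frags) <- seq(180, 40, by = -10)
  cuff_recording(site, frags, fs, device_selected_pressure = sel)
}

test_that("common cuff level is the ladder step nearest the mean selection", {
  sites <- c("left wrist", "right wrist", "left ankle", "right ankle")
  rec <- function(sels) mapply(fake_recording, sites, sels, SIMPLIFY = FALSE)
  out <- select_common_pressure_fragments(rec(c(90, 90, 110, 110)))
  expect_equal(out$level, 100)
  out <- select_common_pressure_fragments(rec(c(80, 80, 80, 80)))
  expect_equal(out$level, 80)
  # mean 97.5 -> nearest step is 100
  out <- select_common_pressure_fragments(rec(c(90, 100, 100, 100)))
  expect_equal(out$level, 100)
  # exact tie (mean 95) resolves towards the higher pressure
  out <- select_common_pressure_fragments(rec(c(90, 90, 100, 100)))
  expect_equal(out$level, 100)
  expect_error(select_common_pressure_fragments(rec(c(90, 90, 110, 110))[1:3]),
               "four")
})

test_that("fallback to highest-amplitude level works without device choices", {
  sites <- c("left wrist", "right wrist", "left ankle", "right ankle")
  recs <- lapply(sites, fake_recording)  # no device-selected pressures
  out <- select_common_pressure_fragments(recs)
  # amplitude profile peaks at 100 mmHg by construction
  expect_equal(out$level, 100)
})

test_that("beat detection finds feet and rejects poor-quality fragments", {
  y <- mk_pulse_train(5, 60)
  on <- detect_beats(y, 200)
  expect_gte(length(on), 4)
  expect_equal(median(diff(on)) / 200, 1, tolerance = 0.05)
  expect_error(detect_beats(rep(0.5, 1000), 200),
               class = "pwp_quality_error")
  expect_error(detect_beats(mk_pulse_train(1, 60), 200), "2 s")
  # an artefactual 0.1 s spike adds a short inter-onset interval that the
  # 0.3 s period gate removes
  ys <- mk_pulse_train(5, 60, spikes = 2.45)
  ons <- detect_beats(ys, 200)
  expect_true(all(diff(ons) / 200 >= 0.3))
})

test_that("beat averaging is idempotent on identical beats and denoises", {
  y <- mk_pulse_train(6, 75)
  on <- detect_beats(y, 200)
  avg <- average_beats(y, on, 200, site = "left wrist")
  expect_s3_class(avg, "averaged_waveform")
  expect_equal(length(avg$samples), 1000)
  expect_equal(avg$n_beats_averaged, length(on) - 1)
  # identical repeated beats: average equals a single normalized beat
  single <- normalize_resample(y[on[1]:(on[2] - 1)])
  expect_lt(max(abs(avg$samples - single)), 0.02)
  # exactly two onsets -> two-beat guard
  avg2 <- average_beats(y, on[1:3], 200)
  expect_equal(avg2$n_beats_averaged, 2)
  expect_error(average_beats(y, on[1], 200), class = "pwp_quality_error")
  # zero-mean noise: the average is closer (L2) to the clean template than
  # any individual beat
  set.seed(101)
  noisy <- y + rnorm(length(y), 0, 0.05 * diff(range(y)))
  on_n <- detect_beats(noisy, 200)
  avg_n <- average_beats(noisy, on_n, 200)
  T_b <- avg_n$period_s
  clean <- rotate_to_foot(normalize_resample(y[on_n[1]:(on_n[2] - 1)]), T_b)
  d_avg <- sqrt(sum((rotate_to_foot(avg_n$samples, T_b) - clean)^2))
  d_single <- vapply(seq_len(length(on_n) - 1), function(k) {
    b <- normalize_resample(noisy[on_n[k]:(on_n[k + 1] - 1)])
    sqrt(sum((rotate_to_foot(b, T_b) - clean)^2))
  }, numeric(1))
  expect_lt(d_avg, min(d_single))
})

test_that("normalize_resample yields 1000 samples in [0,1] and is affine-invariant", {
  y <- mk_pulse_train(1, 60)[1:200]
  z <- normalize_resample(y)
  expect_length(z, 1000)
  expect_equal(min(z), 0)
  expect_equal(max(z), 1)
  # identity on an already-normalized 1000-point input
  expect_equal(normalize_resample(z), z, tolerance = 1e-12)
  # positive affine transforms leave the output unchanged
  expect_equal(normalize_resample(3.7 * y + 11), z, tolerance = 1e-12)
  expect_error(normalize_resample(rep(1, 100)), "constant")
})

test_that("normalization is invariant to uniform time re-sampling", {
  y <- mk_pulse_train(1, 60)[1:200]
  z200 <- normalize_resample(y)
  y400 <- approx(seq(0, 1, length.out = 201)[1:200], y,
                 xout = seq(0, 1, length.out = 401)[1:400],
                 rule = 2)$y
  z400 <- normalize_resample(y400)
  expect_lt(max(abs(z200 - z400)), 1e-2)
})

test_that("rise time and rise-to-fall follow their definitions", {
  # asymmetric triangle: rise 0.3 s, fall 0.5 s over a 0.8 s period
  n <- 1000
  rise_n <- round(0.3 / 0.8 * n)
  tri <- c(seq(0, 1, length.out = rise_n),
           seq(1, 0, length.out = n - rise_n + 1)[-1])
  w <- as_awf(tri, 0.8)
  f <- waveform_features(w)
  expect_equal(f$rise_time_s, 0.3, tolerance = 0.01)
  expect_equal(f$rise_to_fall, 0.6, tolerance = 0.03)
  # symmetric triangle: ratio 1
  half <- n / 2
  sym <- c(seq(0, 1, length.out = half), seq(1, 0, length.out = half + 1)[-1])
  fs <- waveform_features(as_awf(sym, 0.8))
  expect_equal(fs$rise_to_fall, 1, tolerance = 0.03)
  # rise + fall partition the period exactly
  expect_equal(f$rise_time_s + f$rise_time_s / f$rise_to_fall, 0.8,
               tolerance = 1e-10)
  # physiological simulated waveform rises faster than it falls
  obs <- ref_observables()
  fr <- waveform_features(as_awf(obs$waveforms[["left wrist"]], 0.8))
  expect_lt(fr$rise_to_fall, 1)
})

test_that("the full preprocessing chain is deterministic", {
  sites <- c("left wrist", "right wrist", "left ankle", "right ankle")
  recs <- mapply(fake_recording, sites, c(90, 100, 100, 110),
                 SIMPLIFY = FALSE)
  a <- process_recordings(recs)
  b <- process_recordings(recs)
  expect_identical(a, b)
})

test_that("cuff recordings round-trip through CSV + JSON", {
  rec <- fake_recording("left ankle", sel = 90)
  path <- tempfile(fileext = ".csv")
  write_cuff_recording(rec, path)
  rec2 <- read_cuff_recording(path)
  expect_equal(rec2$site, rec$site)
  expect_equal(rec2$device_selected_pressure, 90)
  expect_equal(rec2$fragments[["120"]], rec$fragments[["120"]],
               tolerance = 1e-12)
})
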