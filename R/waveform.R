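# Oscillometric waveform processing: fragment selection on the cuff
# pressure ladder, beat detection and averaging, 1000-point min-max
# normalization, and scalar waveform features (rise time, rise-to-fall).

CUFF_LADDER <- seq(180, 40, by = -10)
CUFF_SITES <- c("left wrist", "right wrist", "left ankle", "right ankle")

new_quality_error <- function(msg) {
  structure(class = c("pwp_quality_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Construct a cuff recording
#'
#' A recording from one cuff site: a descending ladder of cuff pressures
#' (180 to 40 mmHg in 10 mmHg steps), each with an approximately 5 s signal
#' fragment sampled at a fixed rate.
#'
#' @param site One of `"left wrist"`, `"right wrist"`, `"left ankle"`,
#'   `"right ankle"`.
#' @param fragments Named list: names are cuff pressures in mmHg (ladder
#'   values), elements are numeric signal vectors.
#' @param sampling_rate Sampling rate in Hz.
#' @param device_selected_pressure Cuff pressure (mmHg) of the fragment the
#'   device picked as highest-amplitude, or `NA`.
#' @return A `cuff_recording` object.
#' @export
cuff_recording <- function(site, fragments, sampling_rate = 200,
                           device_selected_pressure = NA_real_) {
  site <- match.arg(site, CUFF_SITES)
  lev <- as.numeric(names(fragments))
  if (anyNA(lev) || !all(lev %in% CUFF_LADDER))
    stop("fragment names must be cuff-ladder pressures (180, 170, ..., 40)")
  structure(list(site = site, fragments = fragments,
                 sampling_rate = sampling_rate,
                 device_selected_pressure = device_selected_pressure),
            class = "cuff_recording")
}

# highest-amplitude level, mirroring the device's fragment choice
best_amplitude_level <- function(rec) {
  amp <- vapply(rec$fragments, function(y) {
    on <- tryCatch(detect_beats(y, rec$sampling_rate),
                   pwp_quality_error = function(e) integer(0))
    if (length(on) < 2) return(0)
    beats <- mapply(function(a, b) diff(range(y[a:b])),
                    on[-length(on)], on[-1] - 1)
    mean(beats)
  }, numeric(1))
  as.numeric(names(rec$fragments))[which.max(amp)]
}

#' Select fragments at a common cuff pressure across the four sites
#'
#' Picks the ladder level nearest to the mean of the per-site
#' device-selected pressures (ties resolved towards the higher pressure)
#' and returns each site's fragment at that level, falling back to the
#' nearest available level with a warning.
#'
#' @param recordings List of four `cuff_recording`s (one per site).
#' @return List with `level` (mmHg) and `fragments` (named by site).
#' @export
select_common_pressure_fragments <- function(recordings) {
  sites <- vapply(recordings, `[[`, character(1), "site")
  if (!setequal(sites, CUFF_SITES))
    stop("recordings for all four cuff sites are required")
  names(recordings) <- sites
  sel <- vapply(recordings, `[[`, numeric(1), "device_selected_pressure")
  if (anyNA(sel))
    sel <- vapply(recordings, best_amplitude_level, numeric(1))
  target <- mean(sel)
  d <- abs(CUFF_LADDER - target)
  # ties go to the higher pressure; ladder is descending so which.min on
  # the distance vector already prefers the earlier (higher) level
  level <- CUFF_LADDER[which.min(d)]
  frags <- lapply(CUFF_SITES, function(s) {
    rec <- recordings[[s]]
    avail <- as.numeric(names(rec$fragments))
    if (level %in% avail) return(rec$fragments[[as.character(level)]])
    alt <- avail[which.min(abs(avail - level))]
    warning("site ", s, ": level ", level, " mmHg missing, using ", alt)
    rec$fragments[[as.character(alt)]]
  })
  names(frags) <- CUFF_SITES
  list(level = level, fragments = frags,
       sampling_rate = recordings[[1]]$sampling_rate)
}

#' Detect beat onsets (wave feet) in a signal fragment
#'
#' Locates successive wave feet with the intersecting-tangent convention
#' (horizontal line through the inter-beat minimum against the tangent at
#' the steepest upstroke).  Beats with implausible period (< 0.3 s or
#' > 2 s) are discarded.
#'
#' @param fragment Numeric signal vector (>= 2 s).
#' @param sampling_rate Sampling rate in Hz.
#' @return Integer vector of onset sample indices (>= 2), or an error of
#'   class `pwp_quality_error` when fewer than 2 beats are found.
#' @export
detect_beats <- function(fragment, sampling_rate) {
  n <- length(fragment)
  if (n < 2 * sampling_rate) stop("fragment shorter than 2 s")
  rng <- diff(range(fragment))
  if (rng <= 0 || !is.finite(rng))
    stop(new_quality_error("flat or invalid signal"))
  min_gap <- max(1L, as.integer(0.3 * sampling_rate))
  thr <- min(fragment) + 0.5 * rng
  # local maxima above mid-amplitude, separated by >= 0.3 s
  is_pk <- which(fragment > thr &
                 fragment >= c(-Inf, fragment[-n]) &
                 fragment > c(fragment[-1], Inf))
  peaks <- integer(0)
  for (p in is_pk) {
    if (length(peaks) == 0 || p - peaks[length(peaks)] >= min_gap) {
      peaks <- c(peaks, p)
    } else if (fragment[p] > fragment[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- p
    }
  }
  if (length(peaks) < 2)
    stop(new_quality_error("fewer than 2 beats detected"))
  onsets <- integer(0)
  for (k in seq_len(length(peaks) - 1)) {
    a <- peaks[k]; b <- peaks[k + 1]
    seg <- fragment[a:b]
    imin <- a + which.min(seg) - 1L
    # steepest upstroke between the valley and the next peak
    up <- fragment[imin:b]
    if (length(up) < 3) next
    slopes <- diff(up) * sampling_rate
    islp <- which.max(slopes)
    slope <- slopes[islp]
    if (slope <= 0) next
    y_mid <- (up[islp] + up[islp + 1]) / 2
    t_mid <- (islp - 0.5) / sampling_rate
    t_foot <- t_mid - (y_mid - min(up)) / slope
    onsets <- c(onsets, imin + as.integer(round(t_foot * sampling_rate)))
  }
  onsets <- onsets[onsets >= 1 & onsets <= n]
  if (length(onsets) < 2)
    stop(new_quality_error("fewer than 2 beat onsets located"))
  # discard implausible inter-onset periods
  repeat {
    per <- diff(onsets) / sampling_rate
    bad <- which(per < 0.3 | per > 2)
    if (length(bad) == 0) break
    onsets <- onsets[-(bad[1] + 1L)]
    if (length(onsets) < 2)
      stop(new_quality_error("no beats with plausible period"))
  }
  onsets
}

#' Average the beats of a fragment into a single waveform
#'
#' Beats (onset to next onset) are time-normalized to the median beat
#' period, linearly resampled onto a common 1000-point grid, averaged
#' pointwise, and min-max normalized.
#'
#' @param fragment Numeric signal vector.
#' @param onsets Beat onset indices from [detect_beats()].
#' @param sampling_rate Sampling rate in Hz.
#' @param site Site label carried into the result.
#' @return An `averaged_waveform`: list with `site`, `samples` (length
#'   1000, in `[0, 1]`), `period_s`, `n_beats_averaged`.
#' @export
average_beats <- function(fragment, onsets, sampling_rate,
                          site = NA_character_) {
  if (length(onsets) < 2) stop(new_quality_error("need at least 2 onsets"))
  periods <- diff(onsets) / sampling_rate
  med_T <- median(periods)
  grid <- seq(0, 1, length.out = 1000)
  beats <- matrix(NA_real_, nrow = length(onsets) - 1, ncol = 1000)
  for (k in seq_len(length(onsets) - 1)) {
    # the beat spans [onset_k, onset_{k+1}) -- one full period exclusive of
    # the next onset -- so resampling must use the periodic convention
    y <- fragment[onsets[k]:(onsets[k + 1] - 1L)]
    b <- periodic_resample(y, 1000)
    # onsets are integer-sample foot estimates; refine each beat to its
    # exact (fractional) foot so the average is not smeared by sub-sample
    # phase jitter
    beats[k, ] <- tryCatch(rotate_to_foot(b, med_T), error = function(e) b)
  }
  avg <- colMeans(beats)
  structure(list(site = site,
                 samples = normalize_resample(avg),
                 period_s = med_T,
                 n_beats_averaged = nrow(beats)),
            class = "averaged_waveform")
}

#' Normalize a single-beat waveform to 1000 points in [0, 1]
#'
#' Linear resampling to exactly 1000 uniformly spaced points over the beat,
#' then min-max amplitude normalization.
#'
#' @param waveform Numeric vector covering one beat.
#' @return Numeric vector of length 1000 with `min = 0`, `max = 1`.
#' @export
normalize_resample <- function(waveform) {
  if (length(waveform) < 2) stop("waveform too short")
  rng <- diff(range(waveform))
  if (!is.finite(rng) || rng <= 0)
    stop("constant waveform cannot be normalized")
  y <- periodic_resample(waveform, 1000)
  (y - min(y)) / (max(y) - min(y))
}

# resample a periodic beat (n samples covering [0, 1) of the period) onto
# n_out samples covering [0, 1).  Downsampling (or same length) uses
# circular linear interpolation; upsampling uses a periodic spline, since
# the underlying signal is smooth and linear upsampling would flatten the
# upstroke tangent used for foot detection.
periodic_resample <- function(y, n_out) {
  n <- length(y)
  u <- (seq_len(n) - 1) / n
  xout <- (seq_len(n_out) - 1) / n_out
  if (n_out > n)
    stats::spline(c(u, 1), c(y, y[1]), xout = xout,
                  method = "periodic")$y
  else
    approx(c(u, 1), c(y, y[1]), xout = xout)$y
}

#' Rotate a one-beat waveform to start at its foot
#'
#' Circularly shifts the beat so that the wave foot (intersecting-tangent
#' convention) sits at the first sample.  The shift is fractional (circular
#' linear interpolation) so that downstream objectives stay smooth.
#'
#' @param samples One-beat sample vector.
#' @param period_s Beat period in seconds.
#' @return Rotated samples, same length.
#' @export
rotate_to_foot <- function(samples, period_s) {
  n <- length(samples)
  t <- seq(0, period_s, length.out = n + 1)[1:n]
  tf <- wave_foot(t, samples)
  shift <- (tf / period_s * n) %% n
  pos <- (seq_len(n) - 1 + shift) %% n        # fractional sample positions
  i0 <- floor(pos)
  w <- pos - i0
  (1 - w) * samples[i0 %% n + 1] + w * samples[(i0 + 1) %% n + 1]
}

#' Rise time and rise-to-fall ratio of an averaged waveform
#'
#' The waveform is rotated to start at its foot (intersecting-tangent
#' convention); rise time is the time from foot to the global maximum, and
#' rise-to-fall is rise time divided by the remaining (falling) part of the
#' period.
#'
#' @param w An `averaged_waveform` (see [average_beats()]).
#' @return List with `rise_time_s` and `rise_to_fall`.
#' @export
waveform_features <- function(w) {
  y <- rotate_to_foot(w$samples, w$period_s)
  n <- length(y)
  ipk <- which.max(y)
  if (ipk <= 1 || ipk >= n)
    stop("malformed beat: peak at the first or last sample")
  rise <- (ipk - 1) / n * w$period_s
  list(rise_time_s = rise, rise_to_fall = rise / (w$period_s - rise))
}

#' Write / read a cuff recording as CSV + JSON sidecar
#'
#' The CSV holds columns `cuff_pressure_mmHg`, `time_s`, `signal`; the JSON
#' sidecar records site, sampling rate and the device-selected pressure.
#'
#' @param rec A `cuff_recording`.
#' @param csv_path Output CSV path (sidecar gets extension `.json`).
#' @return The CSV path, invisibly.
#' @export
write_cuff_recording <- function(rec, csv_path) {
  rows <- do.call(rbind, lapply(names(rec$fragments), function(lev) {
    y <- rec$fragments[[lev]]
    data.frame(cuff_pressure_mmHg = as.numeric(lev),
               time_s = seq_along(y) / rec$sampling_rate,
               signal = y)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  side <- list(site = rec$site, sampling_rate = rec$sampling_rate,
               device_selected_pressure = rec$device_selected_pressure)
  jsonlite::write_json(side, sub("\\.csv$", ".json", csv_path),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_cuff_recording
#' @param csv_path Path of a CSV written by [write_cuff_recording()].
#' @export
read_cuff_recording <- function(csv_path) {
  rows <- utils::read.csv(csv_path)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", csv_path),
                              simplifyVector = TRUE)
  levs <- unique(rows$cuff_pressure_mmHg)
  frags <- lapply(levs, function(l) rows$signal[rows$cuff_pressure_mmHg == l])
  names(frags) <- levs
  cuff_recording(side$site, frags, side$sampling_rate,
                 side$device_selected_pressure)
}

#' Full preprocessing chain: recordings to averaged waveforms
#'
#' Applies common-pressure fragment selection, beat detection and beat
#' averaging to the four cuff recordings of one session.
#'
#' @param recordings List of four `cuff_recording`s.
#' @return Named list of four `averaged_waveform`s plus the common level as
#'   attribute `"level"`.
#' @export
process_recordings <- function(recordings) {
  sel <- select_common_pressure_fragments(recordings)
  out <- lapply(CUFF_SITES, function(s) {
    frag <- sel$fragments[[s]]
    on <- detect_beats(frag, sel$sampling_rate)
    average_beats(frag, on, sel$sampling_rate, site = s)
  })
  names(out) <- CUFF_SITES
  attr(out, "level") <- sel$level
  out
}
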