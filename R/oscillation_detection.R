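# Detection of fast network oscillations from LFP.
#
# Threshold engine on z-scored band power for ripples (100-250 Hz, 13.3 ms
# RMS windows), HFOs and cRipples (90-180 Hz, 20 ms windows); sharp-waves
# from the 2-40 Hz filtered deep-superficial channel difference; spindles
# from Morlet wavelet power (9-18 Hz, 11 scales) of the channel-averaged
# prelimbic LFP. All power traces are z-scored against NREM time, so
# detection is invariant to overall LFP amplitude scaling.

# Zero-phase band-pass: 4th-order Butterworth, forward-backward.
bandpass <- function(x, fs, band) {
  if (fs <= 2 * band[2]) stop("sampling rate too low for band")
  b <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(b, x)
}

# Centered moving RMS evaluated at every sample (sliding window).
moving_rms <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - 1L - (w %/% 2))
  hi <- pmin(n, seq_len(n) - 1L + ((w + 1L) %/% 2))
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Z-scored band-power trace
#'
#' Zero-phase band-pass filter, sliding RMS with the stated window, then
#' z-scoring by the mean and SD of the trace over baseline (NREM) samples.
#'
#' @param x one LFP channel (numeric vector).
#' @param fs sampling rate, Hz.
#' @param band numeric length-2, Hz.
#' @param rms_window_ms RMS window, ms.
#' @param baseline_intervals interval table (NREM epochs) used for z-scoring.
#' @return a `power_trace` list: `z`, `fs`, `band`, `window_ms`.
#' @export
band_rms_z <- function(x, fs, band, rms_window_ms, baseline_intervals) {
  rms <- moving_rms(bandpass(x, fs, band), round(rms_window_ms / 1000 * fs))
  z_over_baseline(rms, fs, baseline_intervals)
}

z_over_baseline <- function(trace, fs, baseline_intervals) {
  t <- (seq_along(trace) - 1) / fs
  mask <- iv_contains(t, baseline_intervals)
  if (!any(mask)) stop("empty baseline: no samples in baseline intervals")
  mu <- mean(trace[mask]); s <- sd(trace[mask])
  structure(list(z = (trace - mu) / s, fs = fs), class = "power_trace")
}

#' Detector parameters
#'
#' @param band frequency band, Hz.
#' @param rms_window_ms RMS window, ms.
#' @param enter_z threshold entering a candidate (strict `>`).
#' @param peak_z minimum peak z to confirm (`>=`).
#' @param min_dur_ms minimum duration, ms.
#' @param merge_gap_ms merge confirmed events separated by less than this.
#' @param max_dur_ms maximum duration (events at or above are dropped;
#'   `Inf` disables).
#' @param min_dur_strict require duration strictly greater than `min_dur_ms`
#'   (used for spindles) instead of `>=`.
#' @return a `detector_params` list.
#' @export
detector_params <- function(band, rms_window_ms, enter_z, peak_z, min_dur_ms,
                            merge_gap_ms, max_dur_ms = 750,
                            min_dur_strict = FALSE) {
  if (enter_z > peak_z) stop("enter_z must be <= peak_z")
  if (min_dur_ms >= max_dur_ms) stop("min_dur must be < max_dur")
  list(band = band, rms_window_ms = rms_window_ms, enter_z = enter_z,
       peak_z = peak_z, min_dur_ms = min_dur_ms, merge_gap_ms = merge_gap_ms,
       max_dur_ms = max_dur_ms, min_dur_strict = min_dur_strict)
}

#' Default detector parameter sets
#'
#' Ripple: 100-250 Hz, 13.3 ms RMS, enter 1.5 z, peak >= 4 z, >= 30 ms, merge
#' < 10 ms. HFO: 90-180 Hz, 20 ms, enter 2 z, peak >= 4 z, >= 30 ms, merge
#' < 20 ms. cRipple: 90-180 Hz, 20 ms, enter 3 z, peak >= 5 z, >= 50 ms,
#' merge < 30 ms. Spindle: wavelet 9-18 Hz, sustained > 1.4 z for > 350 ms,
#' max >= 2 z. The `stringent` variant raises the peak thresholds to
#' 5/5/6/3 z for robustness re-analysis.
#'
#' @param stringent use the stringent peak thresholds.
#' @return named list of `detector_params` (`ripple`, `HFO`, `cRipple`,
#'   `spindle`) plus sharp-wave settings (`sharpwave`).
#' @export
default_detector_params <- function(stringent = FALSE) {
  list(
    ripple = detector_params(c(100, 250), 13.3, 1.5, if (stringent) 5 else 4,
                             30, 10, max_dur_ms = Inf),
    HFO = detector_params(c(90, 180), 20, 2, if (stringent) 5 else 4, 30, 20,
                          max_dur_ms = 750),
    cRipple = detector_params(c(90, 180), 20, 3, if (stringent) 6 else 5, 50, 30,
                              max_dur_ms = 750),
    spindle = detector_params(c(9, 18), NA, 1.4, if (stringent) 3 else 2, 350,
                              0, max_dur_ms = Inf, min_dur_strict = TRUE),
    sharpwave = list(band = c(2, 40), enter_z = -2.5,
                     min_dur_ms = 20, max_dur_ms = 400)
  )
}

#' Threshold-crossing event detector
#'
#' Supra-threshold runs of the z trace become candidates; candidates failing
#' the peak or minimum-duration criterion are discarded; surviving events
#' separated by less than the merge gap are merged; events reaching the
#' maximum duration are dropped last.
#'
#' @param power a `power_trace` (or list with `z` and `fs`).
#' @param params a [detector_params()].
#' @param allowed_mask optional logical mask over samples; samples outside it
#'   cannot belong to a candidate (state gating).
#' @return event table: `start`, `end`, `peak_time`, `peak_z`.
#' @export
detect_threshold_events <- function(power, params, allowed_mask = NULL) {
  z <- power$z; fs <- power$fs
  above <- z > params$enter_z
  if (!is.null(allowed_mask)) above <- above & allowed_mask
  ev <- mask_to_iv(above, fs)
  if (nrow(ev) == 0) return(empty_events())
  i0 <- round(ev$start * fs) + 1L
  i1 <- round(ev$end * fs)
  pk <- t(vapply(seq_len(nrow(ev)), function(k) {
    seg <- z[i0[k]:i1[k]]
    j <- which.max(seg)
    c(z[i0[k] + j - 1L], (i0[k] + j - 1L - 0.5) / fs)
  }, numeric(2)))
  ev$peak_z <- pk[, 1]; ev$peak_time <- pk[, 2]
  # microsecond tolerance so sample-grid durations compare exactly
  dur_ms <- (ev$end - ev$start) * 1000
  keep <- ev$peak_z >= params$peak_z &
    (if (params$min_dur_strict) dur_ms > params$min_dur_ms + 1e-6
     else dur_ms >= params$min_dur_ms - 1e-6)
  ev <- ev[keep, , drop = FALSE]
  ev <- merge_events(ev, params$merge_gap_ms / 1000)
  ev <- ev[(ev$end - ev$start) * 1000 < params$max_dur_ms - 1e-6, , drop = FALSE]
  rownames(ev) <- NULL
  ev[, c("start", "end", "peak_time", "peak_z")]
}

empty_events <- function() {
  data.frame(start = numeric(0), end = numeric(0), peak_time = numeric(0),
             peak_z = numeric(0))
}

# Merge events whose gap is strictly below gap_s; the merged peak is the
# larger of the two.
merge_events <- function(ev, gap_s) {
  if (nrow(ev) <= 1) return(ev)
  ev <- ev[order(ev$start), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    k <- nrow(out)
    if (ev$start[i] - out$end[k] < gap_s - 1e-9) {
      out$end[k] <- max(out$end[k], ev$end[i])
      if (ev$peak_z[i] > out$peak_z[k]) {
        out$peak_z[k] <- ev$peak_z[i]; out$peak_time[k] <- ev$peak_time[i]
      }
    } else out <- rbind(out, ev[i, , drop = FALSE])
  }
  out
}

# Concatenate events from different channels that overlap in time
# (nonempty intersection); the union span is kept.
concat_overlapping <- function(ev) {
  if (nrow(ev) <= 1) return(ev)
  ev <- ev[order(ev$start), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    k <- nrow(out)
    if (ev$start[i] < out$end[k]) {
      out$end[k] <- max(out$end[k], ev$end[i])
      if (ev$peak_z[i] > out$peak_z[k]) {
        out$peak_z[k] <- ev$peak_z[i]; out$peak_time[k] <- ev$peak_time[i]
      }
    } else out <- rbind(out, ev[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

# Row-wise median, fast for the small channel counts of a shank.
row_medians <- function(m) {
  k <- ncol(m)
  if (k == 1) return(m[, 1])
  if (k == 2) return((m[, 1] + m[, 2]) / 2)
  if (k == 3) return(pmax(pmin(m[, 1], m[, 2]),
                          pmin(pmax(m[, 1], m[, 2]), m[, 3])))
  apply(m, 1, median)
}

state_mask <- function(hypnogram, states, n, fs) {
  iv <- hypnogram[hypnogram$state %in% states, c("start", "end"), drop = FALSE]
  iv_contains((seq_len(n) - 1) / fs, iv)
}

#' Detect sharp-wave ripples (SWRs)
#'
#' Per vCA1 channel, ripple candidates from the 100-250 Hz RMS z trace
#' (enter 1.5 z, peak >= 4 z, >= 30 ms, merge < 10 ms), gated to NREM and
#' wake. Overlapping same-shank candidates are concatenated. Sharp-waves are
#' detected on the 2-40 Hz filtered deep-minus-superficial channel
#' difference as runs below -2.5 z lasting 20-400 ms. Ripple candidates
#' containing at least one same-shank sharp-wave trough become SWR
#' candidates; overlapping candidates across shanks are concatenated, and
#' events shorter than 750 ms are kept.
#'
#' @param lfp an `lfp_set` with vCA1 channels carrying `depth_order`.
#' @param hypnogram normalized hypnogram.
#' @param params parameter list as [default_detector_params()].
#' @return event table `start`, `end`, `peak_time`, `peak_z`, `kind`,
#'   `source`.
#' @export
detect_swr <- function(lfp, hypnogram, params = default_detector_params()) {
  chans <- lfp$channels[lfp$channels$region == "vCA1", , drop = FALSE]
  if (nrow(chans) == 0) stop("no vCA1 channels")
  nrem <- hypnogram[hypnogram$state == "NREM", c("start", "end")]
  n <- nrow(lfp$data)
  nw_mask <- state_mask(hypnogram, c("NREM", "WAKE"), n, lfp$fs)
  all_swr <- list()
  for (sh in unique(chans$shank)) {
    sc <- chans[chans$shank == sh, , drop = FALSE]
    if (nrow(sc) < 2)
      stop("shank ", sh, " lacks a superficial/deep channel pair")
    cand <- lapply(sc$channel, function(ch) {
      pw <- band_rms_z(lfp$data[, ch], lfp$fs, params$ripple$band,
                       params$ripple$rms_window_ms, nrem)
      detect_threshold_events(pw, params$ripple, allowed_mask = nw_mask)
    })
    cand <- concat_overlapping(do.call(rbind, cand))
    # sharp-waves on deep - superficial difference
    sup <- sc$channel[which.min(sc$depth_order)]
    deep <- sc$channel[which.max(sc$depth_order)]
    d <- bandpass(lfp$data[, deep] - lfp$data[, sup], lfp$fs, params$sharpwave$band)
    zt <- z_over_baseline(d, lfp$fs, nrem)
    below <- mask_to_iv(zt$z < params$sharpwave$enter_z, lfp$fs)
    dur_ms <- (below$end - below$start) * 1000
    sw <- below[dur_ms >= params$sharpwave$min_dur_ms &
                  dur_ms <= params$sharpwave$max_dur_ms, , drop = FALSE]
    troughs <- vapply(seq_len(nrow(sw)), function(k) {
      i0 <- round(sw$start[k] * lfp$fs) + 1L; i1 <- round(sw$end[k] * lfp$fs)
      (i0 + which.min(zt$z[i0:i1]) - 1.5) / lfp$fs
    }, numeric(1))
    if (nrow(cand) > 0) {
      has_sw <- vapply(seq_len(nrow(cand)), function(k)
        any(troughs >= cand$start[k] & troughs < cand$end[k]), logical(1))
      swr <- cand[has_sw, , drop = FALSE]
      if (nrow(swr) > 0) { swr$source <- sh; all_swr[[sh]] <- swr }
    }
  }
  if (length(all_swr) == 0) return(cbind(empty_events(), kind = character(0), source = character(0)))
  out <- concat_overlapping(do.call(rbind, all_swr))
  out <- out[(out$end - out$start) * 1000 < 750, , drop = FALSE]
  out$kind <- "SWR"
  rownames(out) <- NULL
  out[, c("start", "end", "peak_time", "peak_z", "kind", "source")]
}

#' Detect HFOs or cRipples
#'
#' Shared 90-180 Hz threshold engine: HFOs on the per-shank median LFP of the
#' amygdala, cRipples on individual prelimbic channels, both restricted to
#' NREM, with events concatenated across shanks/channels and events of 750 ms
#' or longer excluded.
#'
#' @param lfp an `lfp_set`.
#' @param hypnogram normalized hypnogram.
#' @param kind `"HFO"` (BLA) or `"cRipple"` (PL5).
#' @param params parameter list as [default_detector_params()].
#' @return event table as [detect_swr()].
#' @export
detect_fast_osc <- function(lfp, hypnogram, kind = c("HFO", "cRipple"),
                            params = default_detector_params()) {
  kind <- match.arg(kind)
  region <- if (kind == "HFO") "BLA" else "PL5"
  pp <- params[[kind]]
  chans <- lfp$channels[lfp$channels$region == region, , drop = FALSE]
  if (nrow(chans) == 0) stop("no ", region, " channels")
  nrem <- hypnogram[hypnogram$state == "NREM", c("start", "end")]
  n_mask <- state_mask(hypnogram, "NREM", nrow(lfp$data), lfp$fs)
  sources <- if (kind == "HFO") {
    lapply(split(chans$channel, chans$shank), function(chs)
      row_medians(lfp$data[, chs, drop = FALSE]))
  } else {
    setNames(lapply(chans$channel, function(ch) lfp$data[, ch]),
             paste0("ch", chans$channel))
  }
  evs <- lapply(names(sources), function(nm) {
    pw <- band_rms_z(sources[[nm]], lfp$fs, pp$band, pp$rms_window_ms, nrem)
    ev <- detect_threshold_events(pw, pp, allowed_mask = n_mask)
    if (nrow(ev) > 0) ev$source <- nm
    ev
  })
  evs <- evs[vapply(evs, nrow, integer(1)) > 0]
  if (length(evs) == 0)
    return(cbind(empty_events(), kind = character(0), source = character(0)))
  out <- concat_overlapping(do.call(rbind, evs))
  out <- out[(out$end - out$start) * 1000 < 750, , drop = FALSE]
  out$kind <- kind
  rownames(out) <- NULL
  out[, c("start", "end", "peak_time", "peak_z", "kind", "source")]
}

# Morlet (omega0 = 6) continuous wavelet power at given center frequencies,
# computed by FFT convolution (Torrence-Compo style discretized CWT).
morlet_power <- function(x, fs, freqs) {
  n <- length(x)
  omega0 <- 6
  fourier_factor <- (4 * pi) / (omega0 + sqrt(2 + omega0^2))
  scales <- 1 / (freqs * fourier_factor)
  X <- fft(x)
  wk <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * (2 * pi * fs / n)
  vapply(scales, function(s) {
    psi <- sqrt(2 * pi * s * fs) * pi^(-0.25) * exp(-0.5 * (s * wk - omega0)^2)
    psi[wk <= 0] <- 0
    w <- fft(X * psi, inverse = TRUE) / n
    Mod(w)^2
  }, numeric(n))
}

#' Detect sleep spindles
#'
#' Averages all prelimbic channels, computes Morlet wavelet power on 11
#' log-spaced scales with center frequencies spanning 9-18 Hz, z-scores each
#' scale over NREM time, and takes the pointwise maximum across scales as
#' spindle power. Candidates are runs of spindle power > 1.4 z sustained for
#' more than 350 ms inside NREM; a candidate is confirmed if its maximum
#' power reaches 2 z.
#'
#' @param lfp an `lfp_set` with at least one PL5 channel.
#' @param hypnogram normalized hypnogram.
#' @param params parameter list as [default_detector_params()].
#' @return event table as [detect_swr()].
#' @export
detect_spindles <- function(lfp, hypnogram, params = default_detector_params()) {
  chans <- lfp$channels[lfp$channels$region == "PL5", , drop = FALSE]
  if (nrow(chans) == 0) stop("no PL5 channels")
  nrem <- hypnogram[hypnogram$state == "NREM", c("start", "end")]
  if (nrow(nrem) == 0) stop("empty baseline: no NREM epochs")
  x <- rowMeans(lfp$data[, chans$channel, drop = FALSE])
  freqs <- exp(seq(log(9), log(18), length.out = 11))
  t <- (seq_along(x) - 1) / lfp$fs
  mask <- iv_contains(t, nrem)
  pw <- morlet_power(x, lfp$fs, freqs)
  spindle_power <- rep(-Inf, length(x))
  for (j in seq_along(freqs)) {
    zj <- (pw[, j] - mean(pw[mask, j])) / sd(pw[mask, j])
    spindle_power <- pmax(spindle_power, zj)
  }
  pt <- structure(list(z = spindle_power, fs = lfp$fs), class = "power_trace")
  ev <- detect_threshold_events(pt, params$spindle,
                                allowed_mask = state_mask(hypnogram, "NREM",
                                                          length(x), lfp$fs))
  if (nrow(ev) == 0)
    return(cbind(empty_events(), kind = character(0), source = character(0)))
  ev$kind <- "spindle"; ev$source <- "PL5_avg"
  ev[, c("start", "end", "peak_time", "peak_z", "kind", "source")]
}

# Pipeline stage: run all four detectors.
detect_all_oscillations <- function(lfp, hypnogram, params = NULL) {
  if (is.null(params)) params <- default_detector_params()
  out <- rbind(detect_swr(lfp, hypnogram, params),
               detect_fast_osc(lfp, hypnogram, "HFO", params),
               detect_fast_osc(lfp, hypnogram, "cRipple", params),
               detect_spindles(lfp, hypnogram, params))
  rownames(out) <- NULL
  out
}

#' Event duration and occurrence-rate summary
#'
#' @param events event table for one kind.
#' @param state_intervals reference state time (e.g. NREM epochs).
#' @return list with duration quartiles (ms) and `rate_hz`
#'   (events per second of state time, `NA` if the state time is zero).
#' @export
event_summary <- function(events, state_intervals) {
  tot <- iv_duration(state_intervals)
  dur_ms <- (events$end - events$start) * 1000
  q <- if (length(dur_ms) > 0) unname(quantile(dur_ms, c(0.25, 0.5, 0.75)))
  else rep(NA_real_, 3)
  list(n = nrow(events),
       dur_q1_ms = q[1], dur_median_ms = q[2], dur_q3_ms = q[3],
       rate_hz = if (tot > 0) nrow(events) / tot else NA_real_)
}
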