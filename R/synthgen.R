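# Synthetic session generator. Produces a complete recording session --
# hypnogram, state-modulated Poisson spike trains, multi-channel LFP with
# injected oscillatory events, shock schedule -- together with ground truth,
# so every downstream analysis stage can be validated against known
# parameters.

#' Configuration for a synthetic session
#'
#' Defaults describe a ~2 h home-cage recording from three regions (vCA1 with
#' a superficial/deep channel pair, PL5 and BLA with one channel each).
#' Event rates are per minute of eligible state time (NREM for all kinds;
#' NREM plus wake for ripples, since sharp-wave ripples also occur in quiet
#' wakefulness).
#'
#' @param duration_s session length, seconds.
#' @param fs_lfp LFP sampling rate, Hz (must keep the 100-250 Hz ripple band
#'   below Nyquist).
#' @param n_units_per_region units simulated in each of vCA1, PL5, BLA.
#' @param rem_nrem_ratio_range range of the per-unit REM/NREM firing-rate
#'   ratio; ratios are drawn log-uniformly so REM- and NREM-preferring units
#'   are equally common.
#' @param base_rate_lnorm meanlog/sdlog of the log-normal NREM base rate (Hz).
#' @param event_rates named events/min for SWR, HFO, cRipple, spindle.
#' @param event_amp_sd named injected event amplitudes, in units of the
#'   broadband background SD.
#' @param event_gain_range range of the per-unit multiplicative firing-rate
#'   gain inside events of the unit's home region (log-uniform draw).
#' @param ripple_with_sharpwave logical; co-inject a negative sharp-wave
#'   deflection on the deep vCA1 channel with every ripple (TRUE for real
#'   SWRs; FALSE generates ripples that must NOT be accepted as SWRs).
#' @param shock_times onsets (s) of 2-s eyelid-shock presentations.
#' @param cs_times onsets (s) of 30-s conditioned stimuli.
#' @param shock_gain_range range of per-unit rate gain during shocks.
#' @param sleep_arch semi-Markov sleep architecture: log-normal dwell
#'   parameters per state and a transition matrix; see Details.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @details The hypnogram is a semi-Markov chain over WAKE/NREM/REM with
#' log-normal dwell times. Default dwells (median 25 s wake bouts, 250 s NREM,
#' 90 s REM, with a longer initial wake) produce frequent microarousals and
#' make extended sleep (>30 min without a >60 s wake bout) the usual outcome
#' of a 2-h session.
#'
#' @return a `synth_config` list.
#' @export
synth_config <- function(duration_s = 7200, fs_lfp = 1250,
                         n_units_per_region = 30,
                         rem_nrem_ratio_range = c(0.25, 4),
                         base_rate_lnorm = c(meanlog = log(1.5), sdlog = 0.7),
                         event_rates = c(SWR = 12, HFO = 6, cRipple = 6, spindle = 3),
                         event_amp_sd = c(SWR = 5, HFO = 5, cRipple = 5, spindle = 4),
                         event_gain_range = c(0.5, 5),
                         ripple_with_sharpwave = TRUE,
                         shock_times = numeric(0),
                         cs_times = numeric(0),
                         shock_gain_range = c(1, 6),
                         sleep_arch = default_sleep_arch(),
                         seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs_lfp < 600) stop("fs_lfp must be >= 600 Hz (Nyquist above the ripple band)")
  if (any(rem_nrem_ratio_range <= 0) || any(event_gain_range <= 0))
    stop("rate ratios and gains must be positive")
  stopifnot(all(EVENT_KINDS %in% names(event_rates)),
            all(EVENT_KINDS %in% names(event_amp_sd)))
  structure(list(duration_s = duration_s, fs_lfp = fs_lfp,
                 n_units_per_region = n_units_per_region,
                 rem_nrem_ratio_range = rem_nrem_ratio_range,
                 base_rate_lnorm = base_rate_lnorm,
                 event_rates = event_rates, event_amp_sd = event_amp_sd,
                 event_gain_range = event_gain_range,
                 ripple_with_sharpwave = ripple_with_sharpwave,
                 shock_times = shock_times, cs_times = cs_times,
                 shock_gain_range = shock_gain_range,
                 sleep_arch = sleep_arch, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default semi-Markov sleep architecture
#' @return list with `dwell` (lognormal meanlog/sdlog per state), `init`
#'   (initial wake dwell) and `trans` (row-stochastic transition matrix).
#' @export
default_sleep_arch <- function() {
  list(
    dwell = list(WAKE = c(meanlog = log(25), sdlog = 0.8),
                 NREM = c(meanlog = log(250), sdlog = 0.5),
                 REM  = c(meanlog = log(90), sdlog = 0.4)),
    init = c(meanlog = log(180), sdlog = 0.4),
    trans = matrix(c(0, 1, 0,
                     0.35, 0, 0.65,
                     0.3, 0.7, 0), 3, 3, byrow = TRUE,
                   dimnames = list(c("WAKE", "NREM", "REM"),
                                   c("WAKE", "NREM", "REM")))
  )
}

#' Generate a synthetic hypnogram
#'
#' Semi-Markov sampling of WAKE/NREM/REM bouts with log-normal dwell times;
#' the bout sequence partitions `[0, duration_s)` exactly. For sessions of
#' at least 30 min the draw is repeated (up to 100 times) until it contains
#' at least one NREM and one REM epoch longer than 50 s, so downstream epoch
#' analyses always have usable material.
#'
#' @param config a [synth_config()].
#' @param seed optional integer; if given, seeds the RNG locally.
#' @return interval table with columns `start`, `end`, `state`.
#' @export
generate_hypnogram <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$duration_s < 600)
    stop("duration too short to place a sleep cycle (need >= 600 s)")
  arch <- config$sleep_arch
  states <- rownames(arch$trans)
  reachable <- colnames(arch$trans)[colSums(arch$trans) > 0]
  for (attempt in 1:100) {
    st <- "WAKE"; t <- 0
    out_state <- character(0); out_dur <- numeric(0)
    first <- TRUE
    while (t < config$duration_s) {
      p <- if (first && st == "WAKE") arch$init else arch$dwell[[st]]
      d <- rlnorm(1, p[["meanlog"]], p[["sdlog"]])
      first <- FALSE
      out_state <- c(out_state, st); out_dur <- c(out_dur, d)
      t <- t + d
      if (sum(arch$trans[st, ]) == 0) { out_dur[length(out_dur)] <- Inf; break }
      st <- sample(states, 1, prob = arch$trans[st, ])
    }
    ends <- pmin(cumsum(out_dur), config$duration_s)
    starts <- c(0, head(ends, -1))
    keep <- ends > starts
    hyp <- data.frame(start = starts[keep], end = ends[keep],
                      state = out_state[keep])
    dur <- hyp$end - hyp$start
    ok <- config$duration_s < 1800 ||
      ((!"NREM" %in% reachable || any(hyp$state == "NREM" & dur > 50)) &&
         (!"REM" %in% reachable || any(hyp$state == "REM" & dur > 50)))
    if (ok) return(hyp)
  }
  stop("failed to generate a hypnogram with usable NREM and REM epochs")
}

# Absolute refractory period: greedily drop spikes closer than refrac to the
# previous kept spike (sorted-input dead-time filter).
enforce_refractory <- function(t, refrac = 0.002) {
  if (length(t) < 2) return(t)
  keep <- rep(TRUE, length(t))
  last <- t[1]
  for (i in 2:length(t)) {
    if (t[i] - last < refrac) keep[i] <- FALSE else last <- t[i]
  }
  t[keep]
}

# Piecewise-constant-rate Poisson sampler: one rate per interval row.
gen_poisson_piecewise <- function(iv, rates) {
  if (any(rates < 0)) stop("negative firing rate")
  durs <- iv$end - iv$start
  counts <- rpois(nrow(iv), rates * durs)
  if (sum(counts) == 0) return(numeric(0))
  idx <- rep.int(seq_len(nrow(iv)), counts)
  sort(iv$start[idx] + runif(sum(counts)) * durs[idx])
}

#' Generate state-modulated Poisson spike trains
#'
#' Each unit fires as an inhomogeneous Poisson process whose rate is constant
#' within a sleep-state bout: a log-normal NREM base rate, a log-uniform
#' REM/NREM ratio, and a wake rate at the geometric mean of the two (with
#' mild unit-specific jitter). A 2-ms absolute refractory period is imposed
#' afterwards, as in well-isolated sorted units; at the simulated rates this
#' removes well under 1% of spikes.
#'
#' @param config a [synth_config()].
#' @param hypnogram hypnogram from [generate_hypnogram()].
#' @param seed optional local seed.
#' @return list with `spikes` (data.frame `unit_id`, `t`, sorted within unit),
#'   `units` (per-unit table with true rates, region, shank, true cell type).
#' @export
generate_units <- function(config, hypnogram, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_units_per_region
  units <- do.call(rbind, lapply(REGIONS, function(rg) {
    data.frame(unit_id = sprintf("%s_%02d", rg, seq_len(n)),
               region = rg, shank = paste0(rg, "_s1"))
  }))
  nu <- nrow(units)
  units$rate_nrem <- rlnorm(nu, config$base_rate_lnorm[[1]], config$base_rate_lnorm[[2]])
  lr <- log(config$rem_nrem_ratio_range)
  units$rem_nrem_ratio <- exp(runif(nu, lr[1], lr[2]))
  units$rate_rem <- units$rate_nrem * units$rem_nrem_ratio
  units$rate_wake <- sqrt(units$rate_nrem * units$rate_rem) * exp(runif(nu, -0.3, 0.3))
  units$true_type <- ifelse(runif(nu) < 0.8, "excitatory", "inhibitory")
  spk <- lapply(seq_len(nu), function(i) {
    rates <- c(WAKE = units$rate_wake[i], NREM = units$rate_nrem[i],
               REM = units$rate_rem[i])[hypnogram$state]
    enforce_refractory(gen_poisson_piecewise(hypnogram, rates))
  })
  spikes <- data.frame(unit_id = rep(units$unit_id, lengths(spk)), t = unlist(spk))
  list(spikes = spikes, units = units)
}

# Gaussian 1/f^exponent background noise, synthesized in the frequency
# domain and scaled to unit SD.
one_over_f_noise <- function(n, exponent = 1) {
  m <- floor((n - 1) / 2) # positive non-Nyquist frequencies
  f <- (1:m) / n
  half <- f^(-exponent / 2) * complex(real = rnorm(m), imaginary = rnorm(m))
  spec <- if (n %% 2 == 0) {
    c(0, half, 0.5^(-exponent / 2) * rnorm(1), Conj(rev(half)))
  } else {
    c(0, half, Conj(rev(half)))
  }
  x <- Re(fft(spec, inverse = TRUE))
  x / sd(x)
}

# Draw non-overlapping event intervals wholly inside `allowed` intervals.
draw_event_intervals <- function(allowed, n_events, dur_range, margin = 0.05) {
  if (n_events == 0 || nrow(allowed) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), center = numeric(0)))
  allowed <- allowed[allowed$end - allowed$start > max(dur_range) + 2 * margin, , drop = FALSE]
  if (nrow(allowed) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), center = numeric(0)))
  w <- (allowed$end - allowed$start)
  picked <- data.frame(start = numeric(0), end = numeric(0), center = numeric(0))
  tries <- 0
  while (nrow(picked) < n_events && tries < 50 * n_events) {
    tries <- tries + 1
    i <- sample.int(nrow(allowed), 1, prob = w)
    d <- runif(1, dur_range[1], dur_range[2])
    c0 <- runif(1, allowed$start[i] + margin + d / 2, allowed$end[i] - margin - d / 2)
    s <- c0 - d / 2; e <- c0 + d / 2
    if (nrow(picked) == 0 || all(e <= picked$start - 0.2 | s >= picked$end + 0.2)) {
      picked <- rbind(picked, data.frame(start = s, end = e, center = c0))
    }
  }
  picked[order(picked$start), , drop = FALSE]
}

# Gaussian-windowed sinusoid: returns the sample index range and the values
# to add, so the caller can modify the LFP matrix in place.
burst_segment <- function(n, fs, center, dur, freq, amp) {
  sigma <- dur / 6
  i0 <- max(1L, floor((center - dur) * fs) + 1L)
  i1 <- min(n, ceiling((center + dur) * fs))
  tt <- (i0:i1 - 1) / fs - center
  list(idx = i0:i1,
       y = amp * exp(-tt^2 / (2 * sigma^2)) * sin(2 * pi * freq * tt))
}

deflection_segment <- function(n, fs, center, sigma, amp) {
  i0 <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((center + 4 * sigma) * fs))
  tt <- (i0:i1 - 1) / fs - center
  list(idx = i0:i1, y = amp * exp(-tt^2 / (2 * sigma^2)))
}

# Multiply a unit's spike rate by `gain` inside `events` by exact Poisson
# superposition (gain > 1) or thinning (gain < 1). `rate_at` gives the
# baseline rate at any time.
apply_event_gain <- function(spk, events, gain, rate_at) {
  if (nrow(events) == 0 || gain == 1) return(spk)
  inside <- iv_contains(spk, events)
  if (gain < 1) {
    keep <- !inside | runif(length(spk)) < gain
    return(spk[keep])
  }
  extra <- unlist(lapply(seq_len(nrow(events)), function(i) {
    d <- events$end[i] - events$start[i]
    lam <- rate_at((events$start[i] + events$end[i]) / 2) * (gain - 1)
    k <- rpois(1, lam * d)
    events$start[i] + runif(k) * d
  }))
  sort(c(spk, extra))
}

#' Embed oscillatory events into LFP and spike trains
#'
#' Builds a 1/f Gaussian background per channel and injects Gaussian-windowed
#' oscillatory bursts: ripples (150 Hz, 50-100 ms, on both vCA1 channels,
#' optionally with a negative sharp-wave deflection on the deep channel),
#' HFOs (120 Hz, 40-80 ms, BLA), cRipples (120 Hz, 40-80 ms, PL5) and
#' spindles (12 Hz, 0.5-1 s, PL5). HFO/cRipple/spindle are injected only in
#' NREM; ripples in NREM and WAKE. Spike rates of units in an event's source
#' region are multiplied by the unit's event gain inside the event.
#'
#' @param config a [synth_config()].
#' @param hypnogram hypnogram interval table.
#' @param units_obj output of [generate_units()].
#' @param seed optional local seed.
#' @return list with `lfp` (an `lfp_set`), `spikes` (updated spike table),
#'   `truth` (injected event intervals per kind, per-unit gains, shock gains).
#' @export
embed_oscillations <- function(config, hypnogram, units_obj, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$fs_lfp
  n <- round(config$duration_s * fs)
  chans <- data.frame(channel = 1:4,
                      name = c("vCA1_sup", "vCA1_deep", "PL5_ch1", "BLA_ch1"),
                      region = c("vCA1", "vCA1", "PL5", "BLA"),
                      shank = c("vCA1_s1", "vCA1_s1", "PL5_s1", "BLA_s1"),
                      depth_order = c(1, 2, 1, 1))
  data <- vapply(1:4, function(i) one_over_f_noise(n), numeric(n))

  nrem <- hypnogram[hypnogram$state == "NREM", c("start", "end")]
  wake <- hypnogram[hypnogram$state == "WAKE", c("start", "end")]
  kind_specs <- list(
    SWR     = list(allowed = iv_union(rbind(nrem, wake)), dur = c(0.05, 0.10), freq = 150),
    HFO     = list(allowed = nrem, dur = c(0.04, 0.08), freq = 120),
    cRipple = list(allowed = nrem, dur = c(0.08, 0.14), freq = 120),
    spindle = list(allowed = nrem, dur = c(0.5, 1.0), freq = 12)
  )
  max_ripple_dur <- max(kind_specs$SWR$dur, kind_specs$HFO$dur, kind_specs$cRipple$dur)
  if (max_ripple_dur > 0.75) stop("ripple-class event duration exceeds 750 ms")

  truth_events <- list()
  for (kind in EVENT_KINDS) {
    spec <- kind_specs[[kind]]
    n_ev <- round(config$event_rates[[kind]] / 60 * iv_duration(spec$allowed))
    ev <- draw_event_intervals(spec$allowed, n_ev, spec$dur)
    amp <- config$event_amp_sd[[kind]]
    tgt <- switch(kind, SWR = c(1, 2), HFO = 4, cRipple = 3, spindle = 3)
    if (nrow(ev) > 0) for (i in seq_len(nrow(ev))) {
      seg <- burst_segment(n, fs, ev$center[i], ev$end[i] - ev$start[i],
                           spec$freq, amp)
      for (ch in tgt) data[seg$idx, ch] <- data[seg$idx, ch] + seg$y
      if (kind == "SWR" && config$ripple_with_sharpwave) {
        sw <- deflection_segment(n, fs, ev$center[i], 0.03, -6)
        data[sw$idx, 2] <- data[sw$idx, 2] + sw$y
      }
    }
    ev$kind <- kind
    truth_events[[kind]] <- ev
  }
  truth_events <- do.call(rbind, truth_events)
  rownames(truth_events) <- NULL

  # per-unit event gains (home-region kinds only) and spike-rate modulation
  units <- units_obj$units
  lg <- log(config$event_gain_range)
  gain_rows <- list()
  spikes_by_unit <- split(units_obj$spikes$t, units_obj$spikes$unit_id)
  region_kinds <- list(vCA1 = "SWR", PL5 = c("cRipple", "spindle"), BLA = "HFO")
  state_of <- function(tt) hypnogram$state[findInterval(tt, hypnogram$start)]
  for (i in seq_len(nrow(units))) {
    u <- units$unit_id[i]
    spk <- spikes_by_unit[[u]]
    if (is.null(spk)) spk <- numeric(0)
    rate_at <- function(tt) c(WAKE = units$rate_wake[i], NREM = units$rate_nrem[i],
                              REM = units$rate_rem[i])[[state_of(tt)]]
    for (kind in region_kinds[[units$region[i]]]) {
      g <- exp(runif(1, lg[1], lg[2]))
      ev <- truth_events[truth_events$kind == kind, , drop = FALSE]
      spk <- apply_event_gain(spk, ev, g, rate_at)
      gain_rows[[length(gain_rows) + 1]] <-
        data.frame(unit_id = u, kind = kind, gain = g)
    }
    if (length(config$shock_times) > 0) {
      gs <- exp(runif(1, log(config$shock_gain_range[1]), log(config$shock_gain_range[2])))
      shocks <- intervals(config$shock_times, config$shock_times + 2)
      spk <- apply_event_gain(spk, shocks, gs, rate_at)
      gain_rows[[length(gain_rows) + 1]] <-
        data.frame(unit_id = u, kind = "shock", gain = gs)
    }
    spikes_by_unit[[u]] <- enforce_refractory(spk)
  }
  spikes_by_unit <- spikes_by_unit[units$unit_id]
  spikes <- data.frame(unit_id = rep(units$unit_id, lengths(spikes_by_unit)),
                       t = unlist(spikes_by_unit, use.names = FALSE))

  lfp <- structure(list(data = data, fs = fs, channels = chans), class = "lfp_set")
  list(lfp = lfp, spikes = spikes,
       truth = list(events = truth_events, gains = do.call(rbind, gain_rows),
                    hypnogram = hypnogram, units = units))
}

# Synthetic mean waveforms (20 kHz, 64 samples) consistent with the unit's
# true cell type: trough-to-peak width > 0.6 ms for excitatory, < 0.5 ms for
# inhibitory; amplitudes 60-300 uV so units pass the amplitude criterion.
synth_waveforms <- function(units) {
  fs <- 20000
  tt <- (0:63) / fs * 1000 # ms
  t(vapply(seq_len(nrow(units)), function(i) {
    amp <- runif(1, 60, 300)
    width <- if (units$true_type[i] == "excitatory") runif(1, 0.65, 0.95) else runif(1, 0.28, 0.45)
    trough_t <- 1.0
    -amp * exp(-(tt - trough_t)^2 / (2 * 0.12^2)) +
      0.3 * amp * exp(-(tt - trough_t - width)^2 / (2 * 0.25^2))
  }, numeric(64)))
}

# Synthetic 4-D spike feature clouds for isolation-distance computation:
# unit-specific centers, unit covariance = identity.
synth_features <- function(units, spikes, max_per_unit = 1200) {
  centers <- matrix(rnorm(nrow(units) * 4, sd = 7), ncol = 4)
  rows <- lapply(seq_len(nrow(units)), function(i) {
    nsp <- sum(spikes$unit_id == units$unit_id[i])
    k <- max(20L, min(nsp, max_per_unit))
    m <- matrix(rnorm(k * 4), ncol = 4) + rep(centers[i, ], each = k)
    data.frame(unit_id = units$unit_id[i], f1 = m[, 1], f2 = m[, 2],
               f3 = m[, 3], f4 = m[, 4])
  })
  do.call(rbind, rows)
}

#' Generate and write a complete synthetic session
#'
#' Runs [generate_hypnogram()], [generate_units()] and
#' [embed_oscillations()] with seeds derived from `config$seed`, adds
#' synthetic mean waveforms and spike-feature clouds, and writes all
#' artifacts (TSV tables, float32 LFP binary with JSON sidecar, manifest)
#' under `out_dir`. The same config written twice produces byte-identical
#' files.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if missing).
#' @return the session bundle (invisibly), as returned by [load_session()].
#' @export
generate_session <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- config$seed %% 1000000L
  hyp <- generate_hypnogram(config, seed = base + 11L)
  uo <- generate_units(config, hyp, seed = base + 23L)
  emb <- embed_oscillations(config, hyp, uo, seed = base + 37L)
  set.seed(base + 51L)
  wf <- synth_waveforms(emb$truth$units)
  feats <- synth_features(emb$truth$units, emb$spikes)

  p <- function(f) file.path(out_dir, f)
  save_tables(list(
    units = emb$truth$units,
    spikes = emb$spikes,
    hypnogram = hyp,
    truth_events = emb$truth$events,
    truth_gains = emb$truth$gains,
    features = feats
  ), out_dir)
  wf_df <- data.frame(unit_id = emb$truth$units$unit_id, wf)
  names(wf_df) <- c("unit_id", sprintf("s%02d", 1:64))
  save_tables(list(waveforms = wf_df), out_dir)

  shocks <- if (length(config$shock_times) > 0)
    data.frame(start = config$shock_times, end = config$shock_times + 2)
  else data.frame(start = numeric(0), end = numeric(0))
  pulse_on <- if (nrow(shocks) > 0)
    as.vector(outer((0:15) / 8, shocks$start, "+")) else numeric(0)
  pulses <- data.frame(start = sort(pulse_on), end = sort(pulse_on) + 0.002)
  cs <- if (length(config$cs_times) > 0)
    data.frame(start = config$cs_times, end = config$cs_times + 30)
  else data.frame(start = numeric(0), end = numeric(0))
  save_tables(list(shocks = shocks, shock_pulses = pulses, cs = cs), out_dir)

  write_lfp(emb$lfp, p("lfp.bin"), p("lfp_meta.json"))

  manifest <- list(
    format = "sleeposc-session/1",
    fs = config$fs_lfp, duration_s = config$duration_s, seed = config$seed,
    n_units = nrow(emb$truth$units),
    n_lfp_samples_per_channel = nrow(emb$lfp$data),
    n_channels = ncol(emb$lfp$data),
    files = list(units = "units.tsv", spikes = "spikes.tsv",
                 hypnogram = "hypnogram.tsv", lfp = "lfp.bin",
                 lfp_meta = "lfp_meta.json", truth_events = "truth_events.tsv",
                 truth_gains = "truth_gains.tsv", waveforms = "waveforms.tsv",
                 features = "features.tsv", shocks = "shocks.tsv",
                 shock_pulses = "shock_pulses.tsv", cs = "cs.tsv"),
    row_counts = list(spikes = nrow(emb$spikes), units = nrow(emb$truth$units),
                      hypnogram = nrow(hyp),
                      truth_events = nrow(emb$truth$events))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), p("manifest.json"))
  invisible(load_session(p("manifest.json")))
}
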