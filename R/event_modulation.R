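# Peri-event firing, firing-rate gain inside oscillations and shocks,
# sleep-long firing trends, and within-event firing change across extended
# sleep.

#' Peri-event time histogram (PETH)
#'
#' Per-event binned firing rates on a symmetric lag window around event
#' peaks, Gaussian-smoothed along the lag axis, then averaged across events.
#' Ripple-class kinds use 10-ms bins, sigma = 50 ms, +-500 ms; spindles use
#' 50-ms bins, sigma = 250 ms, +-2 s.
#'
#' @param spikes sorted spike times, seconds.
#' @param event_peaks event peak times, seconds.
#' @param kind one of `"SWR"`, `"HFO"`, `"cRipple"`, `"spindle"` (sets bin
#'   width, smoothing and window), or supply `bin_ms`/`sigma_ms`/`window_s`.
#' @param bin_ms,sigma_ms,window_s overrides of the kind defaults.
#' @return list `lag_s` (bin centers), `mean_rate_hz` (smoothed,
#'   event-averaged), `rate_matrix` (events x bins, unsmoothed Hz), `bin_ms`,
#'   `sigma_ms`.
#' @export
peri_event_rate <- function(spikes, event_peaks, kind = "SWR",
                            bin_ms = NULL, sigma_ms = NULL, window_s = NULL) {
  if (length(event_peaks) == 0) stop("need at least one event")
  defaults <- if (kind == "spindle") c(50, 250, 2) else c(10, 50, 0.5)
  bin_ms <- bin_ms %||% defaults[1]
  sigma_ms <- sigma_ms %||% defaults[2]
  window_s <- window_s %||% defaults[3]
  bw <- bin_ms / 1000
  edges <- seq(-window_s, window_s, by = bw)
  centers <- head(edges, -1) + bw / 2
  spikes <- sort(spikes)
  counts <- t(vapply(event_peaks, function(p) {
    n_before <- function(x) findInterval(x, spikes, left.open = TRUE)
    diff(n_before(p + edges))
  }, numeric(length(centers))))
  rate <- counts / bw
  half_k <- max(1L, ceiling(4 * sigma_ms / bin_ms))
  kern <- exp(-0.5 * ((-half_k:half_k) * bin_ms / sigma_ms)^2)
  kern <- kern / sum(kern)
  smooth1 <- function(v) {
    padded <- c(rep(v[1], half_k), v, rep(v[length(v)], half_k))
    vapply(seq_along(v), function(i) sum(padded[i:(i + 2 * half_k)] * kern),
           numeric(1))
  }
  mean_rate <- smooth1(colMeans(rate))
  list(lag_s = centers, mean_rate_hz = mean_rate, rate_matrix = rate,
       bin_ms = bin_ms, sigma_ms = sigma_ms)
}

#' Firing-rate gain inside oscillatory events
#'
#' `fr_in` = spikes inside events / total event duration; `fr_out` = spikes
#' in the reference state time excluding events / that duration; gain is the
#' ratio. The reference is NREM time for sleep oscillations and wake time
#' for awake SWRs.
#'
#' @param spikes sorted spike times.
#' @param events event table (`start`, `end`).
#' @param reference_intervals interval table of reference state time.
#' @return list `fr_in`, `fr_out`, `gain` (NA with `flag` when `fr_out` is
#'   0 or durations vanish).
#' @export
fr_gain <- function(spikes, events, reference_intervals) {
  spikes <- sort(spikes)
  ev <- iv_intersect(events, reference_intervals)
  out_iv <- iv_setdiff(reference_intervals, events)
  d_in <- iv_duration(ev); d_out <- iv_duration(out_iv)
  fr_in <- if (d_in > 0) sum(iv_count(spikes, ev)) / d_in else NA_real_
  fr_out <- if (d_out > 0) sum(iv_count(spikes, out_iv)) / d_out else NA_real_
  flag <- NA_character_
  gain <- NA_real_
  if (is.na(fr_in) || is.na(fr_out)) flag <- "empty in/out time"
  else if (fr_out == 0) flag <- "zero outside rate"
  else gain <- fr_in / fr_out
  list(fr_in = fr_in, fr_out = fr_out, gain = gain, flag = flag)
}

#' Firing-rate trend across extended sleep
#'
#' For every extended-sleep period with at least two NREM epochs: the mean
#' firing rate of each unit in each NREM epoch, z-scored within unit over
#' all NREM epochs of all periods; Spearman rho of z-rate against time from
#' the period's sleep onset to the epoch midpoint; the first-to-last epoch
#' z-rate difference per unit and period; and a summary over 10 equal-count
#' time bins.
#'
#' @param spikes_by_unit named list of sorted spike-time vectors.
#' @param extended_sleep interval table from [find_extended_sleep()].
#' @param hypnogram normalized hypnogram.
#' @return list `epochs` (unit x epoch z-rates), `trend` (per unit rho),
#'   `delta` (per unit-period last-minus-first z-rate), `time_bins`
#'   (10-bin mean z-rate).
#' @export
sleep_fr_trend <- function(spikes_by_unit, extended_sleep, hypnogram) {
  nrem <- hypnogram[hypnogram$state == "NREM" & hypnogram$usable, , drop = FALSE]
  ep_rows <- list()
  for (p in seq_len(nrow(extended_sleep))) {
    ep <- nrem[nrem$start >= extended_sleep$start[p] &
                 nrem$end <= extended_sleep$end[p], , drop = FALSE]
    if (nrow(ep) < 2) next # single-epoch periods are skipped
    for (u in names(spikes_by_unit)) {
      cnt <- iv_count(sort(spikes_by_unit[[u]]), ep)
      ep_rows[[length(ep_rows) + 1]] <- data.frame(
        unit_id = u, period = p, epoch = seq_len(nrow(ep)),
        t_mid = (ep$start + ep$end) / 2 - extended_sleep$start[p],
        fr = cnt / (ep$end - ep$start))
    }
  }
  if (length(ep_rows) == 0) stop("no extended-sleep period with >= 2 NREM epochs")
  epochs <- do.call(rbind, ep_rows)
  epochs$fr_z <- stats::ave(epochs$fr, epochs$unit_id, FUN = function(v)
    if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0)
  trend <- do.call(rbind, lapply(split(epochs, epochs$unit_id), function(d) {
    data.frame(unit_id = d$unit_id[1],
               rho = if (nrow(d) >= 3 && sd(d$fr_z) > 0)
                 cor(d$t_mid, d$fr_z, method = "spearman") else NA_real_)
  }))
  delta <- do.call(rbind, lapply(split(epochs, list(epochs$unit_id, epochs$period),
                                       drop = TRUE), function(d) {
    d <- d[order(d$epoch), ]
    data.frame(unit_id = d$unit_id[1], period = d$period[1],
               delta_z = d$fr_z[nrow(d)] - d$fr_z[1])
  }))
  qs <- quantile(epochs$t_mid, seq(0, 1, 0.1))
  bin <- cut(epochs$t_mid, unique(qs), include.lowest = TRUE, labels = FALSE)
  time_bins <- data.frame(bin = sort(unique(bin)),
                          mean_z = tapply(epochs$fr_z, bin, mean))
  rownames(trend) <- rownames(delta) <- rownames(time_bins) <- NULL
  list(epochs = epochs, trend = trend, delta = delta, time_bins = time_bins)
}

#' Within-event firing change across extended sleep
#'
#' Within-event firing rate of a unit in the first and last NREM epoch of an
#' extended-sleep period, z-scored within unit across all NREM epochs of the
#' period, returned as last minus first.
#'
#' @param spikes sorted spike times.
#' @param events event table of one kind.
#' @param nrem_epochs NREM epochs (interval table, time-ordered) of one
#'   extended-sleep period.
#' @return list `delta_z`, `per_epoch` (within-event FR per epoch); `NA`
#'   with a flag when the first or last epoch has no events.
#' @export
within_event_fr_change <- function(spikes, events, nrem_epochs) {
  spikes <- sort(spikes)
  per <- vapply(seq_len(nrow(nrem_epochs)), function(i) {
    ev <- iv_intersect(events, nrem_epochs[i, , drop = FALSE])
    if (nrow(ev) == 0 || iv_duration(ev) == 0) return(NA_real_)
    sum(iv_count(spikes, ev)) / iv_duration(ev)
  }, numeric(1))
  if (is.na(per[1]) || is.na(per[length(per)]))
    return(list(delta_z = NA_real_, per_epoch = per,
                flag = "first or last epoch has no events"))
  ok <- !is.na(per)
  s <- sd(per[ok])
  z <- if (s > 0) (per - mean(per[ok])) / s else per * 0
  list(delta_z = z[length(z)] - z[1], per_epoch = per, flag = NA_character_)
}

#' Firing-rate gain during shock presentation
#'
#' Peri-shock time histogram in 0.1-s bins averaged across 2-s shock
#' presentations; the gain is the PSTH peak within the shock window divided
#' by the mean firing rate during the 20 s preceding the first conditioned
#' stimulus.
#'
#' @param spikes sorted spike times.
#' @param shock_intervals interval table of 2-s shock windows.
#' @param first_cs_time onset of the first CS, seconds.
#' @return list `peak_fr`, `baseline_fr`, `gain` (`NA` + flag when the
#'   baseline rate is zero).
#' @export
shock_gain <- function(spikes, shock_intervals, first_cs_time) {
  if (nrow(shock_intervals) == 0) stop("need at least one shock")
  spikes <- sort(spikes)
  edges <- seq(0, 2, by = 0.1)
  psth <- rowMeans(vapply(shock_intervals$start, function(s0) {
    n_before <- function(x) findInterval(x, spikes, left.open = TRUE)
    diff(n_before(s0 + edges)) / 0.1
  }, numeric(length(edges) - 1)))
  base_iv <- intervals(first_cs_time - 20, first_cs_time)
  baseline <- sum(iv_count(spikes, base_iv)) / 20
  if (baseline == 0)
    return(list(peak_fr = max(psth), baseline_fr = 0, gain = NA_real_,
                flag = "zero baseline rate"))
  list(peak_fr = max(psth), baseline_fr = baseline,
       gain = max(psth) / baseline, flag = NA_character_)
}

#' Censor spikes around shock pulses
#'
#' Removes spikes from 0.1 ms before the onset to 5 ms after the offset of
#' each shock pulse (half-open window).
#'
#' @param spikes spike times, seconds.
#' @param shock_pulses interval table of pulse `[onset, offset)` windows.
#' @return censored spike times.
#' @export
censor_shock_artifacts <- function(spikes, shock_pulses) {
  if (nrow(shock_pulses) == 0) return(spikes)
  win <- intervals(shock_pulses$start - 1e-4, shock_pulses$end + 5e-3)
  spikes[!iv_contains(spikes, win)]
}

# Pipeline stage: FR gain per unit per kind during NREM, plus awake SWRs.
gain_table <- function(spikes_by_unit, events, hypnogram) {
  nrem <- select_state_time(hypnogram[hypnogram$usable, , drop = FALSE], "NREM")
  wake <- select_state_time(hypnogram[hypnogram$usable, , drop = FALSE], "WAKE")
  rows <- list()
  for (kind in unique(events$kind)) {
    ev <- events[events$kind == kind, , drop = FALSE]
    for (u in names(spikes_by_unit)) {
      g <- fr_gain(spikes_by_unit[[u]], ev, nrem)
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = u, kind = kind, reference = "NREM",
        fr_in = g$fr_in, fr_out = g$fr_out, gain = g$gain)
      if (kind == "SWR" && iv_duration(wake) > 0) {
        ga <- fr_gain(spikes_by_unit[[u]], ev, wake)
        rows[[length(rows) + 1]] <- data.frame(
          unit_id = u, kind = "awakeSWR", reference = "WAKE",
          fr_in = ga$fr_in, fr_out = ga$fr_out, gain = ga$gain)
      }
    }
  }
  do.call(rbind, rows)
}
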