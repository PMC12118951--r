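# Cluster-quality and waveform metrics, and the four inclusion criteria:
# isolation distance > 15, (ISI index < 0.2 OR contamination rate < 0.05),
# mean firing rate > 0.01 Hz, spike amplitude > 50 uV.

# Count autocorrelogram entries with lag in [lo, hi) ms, over ordered pairs
# (positive lags only; ratios of such counts are unaffected by sidedness).
acg_count <- function(spike_times, lo_ms, hi_ms) {
  t <- sort(spike_times)
  lo <- lo_ms / 1000; hi <- hi_ms / 1000
  n_before <- function(x) findInterval(x, t, left.open = TRUE)
  sum(n_before(t + hi) - n_before(t + lo))
}

#' Inter-spike-interval index
#'
#' Ratio of the ISI rate in the refractory window `[0.5, 2)` ms to the rate
#' in the baseline window `[2, 10)` ms, i.e.
#' `(ISI_[0.5,2) / ISI_[2,10)) * (8 / 1.5)`; the factor normalizes the two
#' window lengths (1.5 ms vs 8 ms). A well-isolated unit has few refractory
#' ISIs and an index near 0.
#'
#' @param spike_times sorted spike times, seconds.
#' @return dimensionless index; `NA` (flagged) when the baseline window is
#'   empty.
#' @export
isi_index <- function(spike_times) {
  if (length(spike_times) < 2) stop("need at least 2 spikes")
  isi_ms <- diff(sort(spike_times)) * 1000
  c1 <- sum(isi_ms >= 0.5 & isi_ms < 2)
  c2 <- sum(isi_ms >= 2 & isi_ms < 10)
  if (c2 == 0) return(NA_real_)
  (c1 / c2) * (8 / 1.5)
}

#' Autocorrelogram contamination rate
#'
#' For refractory windows `[0.5, n)` ms with `n` stepping 1.5, 2.5, ..., 9.5,
#' computes the window-length-normalized ratio of autocorrelogram counts in
#' the refractory window to counts in each of two baseline windows
#' (`[0.5, 49.5)` ms, length 49, and `[250, 500)` ms, length 250), and
#' returns the minimum over both baselines and all `n`. Near 0 for clean
#' refractoriness; near 1 for a homogeneous (refractoriness-free) train.
#'
#' @param spike_times sorted spike times, seconds.
#' @return dimensionless rate; `NA` (flagged) when both baselines are empty.
#' @export
contamination_rate <- function(spike_times) {
  if (length(spike_times) < 2) stop("need at least 2 spikes")
  base49 <- acg_count(spike_times, 0.5, 49.5)
  base250 <- acg_count(spike_times, 250, 500)
  if (base49 == 0 && base250 == 0) return(NA_real_)
  vals <- vapply(seq(1.5, 9.5, by = 1), function(n) {
    ref <- acg_count(spike_times, 0.5, n)
    terms <- c(if (base49 > 0) ref / base49 * 49 / (n - 0.5),
               if (base250 > 0) ref / base250 * 250 / (n - 0.5))
    min(terms)
  }, numeric(1))
  min(vals)
}

#' Isolation distance
#'
#' Squared Mahalanobis distance (with respect to the cluster's own
#' covariance) from the cluster center to the `n_c`-th nearest noise spike,
#' where `n_c` is the cluster size. Larger is better separated.
#'
#' @param cluster_features numeric matrix, cluster spikes x features.
#' @param noise_features numeric matrix of same-shank non-cluster spikes.
#' @return dimensionless distance; `NA` (flagged) if the noise set is smaller
#'   than the cluster.
#' @export
isolation_distance <- function(cluster_features, noise_features) {
  cluster_features <- as.matrix(cluster_features)
  noise_features <- as.matrix(noise_features)
  nc <- nrow(cluster_features)
  if (nrow(noise_features) < nc) return(NA_real_)
  ctr <- colMeans(cluster_features)
  S <- var(cluster_features)
  d2 <- tryCatch(stats::mahalanobis(noise_features, ctr, S),
                 error = function(e) stop("singular cluster covariance: ",
                                          conditionMessage(e)))
  sort(d2, partial = nc)[nc]
}

#' Waveform amplitude and trough-to-peak width
#'
#' Cubic-spline upsamples the mean waveform to 200 kHz, takes amplitude as
#' trough depth below baseline (baseline = mean of the first 20% of samples)
#' and width as the time from the trough to the largest subsequent peak.
#'
#' @param mean_waveform numeric vector, one mean waveform (uV).
#' @param fs sampling rate of the waveform, Hz.
#' @return list with `amplitude_uv`, `width_ms`, `monophasic` (TRUE when no
#'   rebound rises more than 5% of the amplitude above baseline; width then
#'   uses the global post-trough maximum and is flagged atypical).
#' @export
waveform_metrics <- function(mean_waveform, fs) {
  if (all(mean_waveform == mean_waveform[1])) stop("flat waveform")
  n <- length(mean_waveform)
  t <- (seq_len(n) - 1) / fs
  up <- spline(t, mean_waveform, n = max(2L, round((n - 1) * 200000 / fs) + 1L))
  base <- mean(up$y[seq_len(max(1L, floor(0.2 * length(up$y))))])
  i_tr <- which.min(up$y)
  amplitude <- base - up$y[i_tr]
  if (i_tr == length(up$y)) stop("waveform has no post-trough samples")
  tail_y <- up$y[(i_tr + 1):length(up$y)]
  i_pk <- i_tr + which.max(tail_y)
  width_ms <- (up$x[i_pk] - up$x[i_tr]) * 1000
  list(amplitude_uv = amplitude, width_ms = width_ms,
       monophasic = max(tail_y) <= base + 0.05 * amplitude)
}

#' Apply the four unit inclusion criteria
#'
#' A unit is included iff isolation distance > 15, (ISI index < 0.2 OR
#' contamination rate < 0.05), mean firing rate > 0.01 Hz, and spike
#' amplitude > 50 uV. An `NA` metric fails its branch.
#'
#' @param isolation_distance,isi_index,contamination_rate,mean_fr,amplitude_uv
#'   the unit's metrics (scalars, `NA` allowed).
#' @return logical.
#' @export
apply_inclusion_criteria <- function(isolation_distance, isi_index,
                                     contamination_rate, mean_fr, amplitude_uv) {
  ok <- function(x) !is.na(x) & x
  ok(isolation_distance > 15) &
    (ok(isi_index < 0.2) | ok(contamination_rate < 0.05)) &
    ok(mean_fr > 0.01) &
    ok(amplitude_uv > 50)
}

# Full quality table for a session bundle (pipeline stage).
quality_table <- function(session) {
  units <- session$units
  dur <- session$manifest$duration_s %||% max(session$hypnogram$end)
  spl <- split(session$spikes$t, session$spikes$unit_id)
  rows <- lapply(seq_len(nrow(units)), function(i) {
    u <- units$unit_id[i]
    spk <- spl[[u]] %||% numeric(0)
    isi <- if (length(spk) >= 2) isi_index(spk) else NA_real_
    cont <- if (length(spk) >= 2) contamination_rate(spk) else NA_real_
    mfr <- length(spk) / dur
    amp <- NA_real_; wid <- NA_real_
    if (!is.null(session$waveforms)) {
      wf <- as.numeric(session$waveforms[session$waveforms$unit_id == u, -1])
      wm <- waveform_metrics(wf, 20000)
      amp <- wm$amplitude_uv; wid <- wm$width_ms
    }
    id <- NA_real_
    if (!is.null(session$features)) {
      f <- session$features
      same_shank <- units$unit_id[units$shank == units$shank[i]]
      cl <- as.matrix(f[f$unit_id == u, -1])
      noi <- as.matrix(f[f$unit_id != u & f$unit_id %in% same_shank, -1])
      if (nrow(cl) > 5 && nrow(noi) >= nrow(cl))
        id <- isolation_distance(cl, noi)
    }
    data.frame(unit_id = u, isolation_distance = id, isi_index = isi,
               contamination_rate = cont, amplitude_uv = amp,
               spike_width_ms = wid, mean_fr = mfr)
  })
  qt <- do.call(rbind, rows)
  qt$included <- apply_inclusion_criteria(qt$isolation_distance, qt$isi_index,
                                          qt$contamination_rate, qt$mean_fr,
                                          qt$amplitude_uv)
  qt
}
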