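# REM/NREM state firing rates, the REM-preference index and its shuffle-null
# classification, triplet firing profiles, and cross-session correlation /
# bootstrap analyses.

#' Per-state 1-s bin grid
#'
#' Partitions usable state epochs into whole 1-s bins; a bin straddling an
#' epoch boundary is truncated and dropped when shorter than 1 s.
#'
#' @param state_iv interval table of usable epochs of one state.
#' @return interval table of 1-s bins.
#' @keywords internal
state_bins <- function(state_iv) {
  if (nrow(state_iv) == 0) return(intervals(numeric(0), numeric(0)))
  starts <- unlist(lapply(seq_len(nrow(state_iv)), function(i) {
    k <- floor(state_iv$end[i] - state_iv$start[i])
    if (k < 1) return(numeric(0))
    state_iv$start[i] + 0:(k - 1)
  }))
  data.frame(start = starts, end = starts + 1)
}

#' Mean firing rates during REM and NREM sleep
#'
#' FRs are computed in 1-s bins over usable (> 50 s) epochs; the state rate
#' is the mean of that state's bin counts (Hz, since bins are 1 s).
#'
#' @param spikes sorted spike times, seconds.
#' @param hypnogram normalized hypnogram (with `usable`).
#' @return list `fr_rem`, `fr_nrem`, plus the bin counts and labels used
#'   (`bin_counts`, `bin_states`). A state with no usable bins yields `NA`.
#' @export
state_rates <- function(spikes, hypnogram) {
  us <- hypnogram[hypnogram$usable, , drop = FALSE]
  bins_n <- state_bins(us[us$state == "NREM", , drop = FALSE])
  bins_r <- state_bins(us[us$state == "REM", , drop = FALSE])
  cn <- iv_count(sort(spikes), bins_n)
  cr <- iv_count(sort(spikes), bins_r)
  list(fr_rem = if (length(cr) > 0) mean(cr) else NA_real_,
       fr_nrem = if (length(cn) > 0) mean(cn) else NA_real_,
       bin_counts = c(cr, cn),
       bin_states = c(rep("REM", length(cr)), rep("NREM", length(cn))))
}

#' REM-preference index
#'
#' `(FR_R - FR_N) / (FR_R + FR_N)`, bounded in `[-1, 1]`; positive values
#' mean REM-preferring firing.
#'
#' @param fr_rem,fr_nrem mean state firing rates, Hz.
#' @return dimensionless index; `NA` when both rates are zero.
#' @export
rem_preference_index <- function(fr_rem, fr_nrem) {
  s <- fr_rem + fr_nrem
  ifelse(s > 0, (fr_rem - fr_nrem) / s, NA_real_)
}

#' Classify a neuron's state preference against a shuffle null
#'
#' Permutes the REM/NREM labels across 1-s bins (preserving the number of
#' each label), recomputes the REM-preference index for each surrogate, and
#' labels the neuron REM-preferring if its actual index exceeds the
#' `1 - alpha/2` surrogate percentile, NREM-preferring if it falls below the
#' `alpha/2` percentile, and non-significant (`NS`) otherwise. Percentiles
#' use linear interpolation; an index exactly at a threshold is `NS`.
#'
#' @param bin_counts integer spike counts per 1-s bin.
#' @param bin_states `"REM"`/`"NREM"` label per bin.
#' @param n_shuffles number of label shuffles.
#' @param alpha two-sided criterion (0.05 default; 0.01 and 0.002 give the
#'   stricter variants).
#' @param seed optional local seed.
#' @return a `preference_result` list: `fr_rem`, `fr_nrem`, `index`,
#'   `null_lo`, `null_hi`, `label`, `n_shuffles`, `flag`.
#' @export
classify_preference <- function(bin_counts, bin_states, n_shuffles = 1000,
                                alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  is_rem <- bin_states == "REM"
  n_r <- sum(is_rem); n_n <- sum(!is_rem)
  if (n_r == 0 || n_n == 0) stop("need at least one REM and one NREM bin")
  fr_r <- mean(bin_counts[is_rem]); fr_n <- mean(bin_counts[!is_rem])
  total <- sum(bin_counts)
  res <- list(fr_rem = fr_r, fr_nrem = fr_n,
              index = rem_preference_index(fr_r, fr_n),
              null_lo = NA_real_, null_hi = NA_real_,
              label = "NS", n_shuffles = n_shuffles, flag = NA_character_)
  if (total == 0) {
    res$flag <- "all-zero counts"
    return(structure(res, class = "preference_result"))
  }
  s_r <- shuffle_subset_sums_cpp(as.numeric(bin_counts), n_r, n_shuffles)
  idx_null <- (s_r / n_r - (total - s_r) / n_n) / (s_r / n_r + (total - s_r) / n_n)
  res$null_lo <- unname(quantile(idx_null, alpha / 2))
  res$null_hi <- unname(quantile(idx_null, 1 - alpha / 2))
  if (!is.na(res$index)) {
    if (res$index > res$null_hi) res$label <- "REM"
    else if (res$index < res$null_lo) res$label <- "NREM"
  }
  structure(res, class = "preference_result")
}

#' Triplet firing profile
#'
#' Firing rate in each third of the NREM1, REM and NREM2 epochs of every
#' NREM-REM-NREM triplet (9 values per triplet), averaged across triplets
#' and z-scored within the neuron across the 9 bins.
#'
#' @param spikes sorted spike times.
#' @param triplets triplet table from [find_triplets()].
#' @return list with `profile_z` (9 values: NREM1 thirds, REM thirds, NREM2
#'   thirds), `profile_hz` (unnormalized), `n_triplets`.
#' @export
triplet_profile <- function(spikes, triplets) {
  if (nrow(triplets) == 0) stop("no triplets")
  spikes <- sort(spikes)
  thirds <- function(s, e) {
    b <- seq(s, e, length.out = 4)
    data.frame(start = b[1:3], end = b[2:4])
  }
  prof <- vapply(seq_len(nrow(triplets)), function(i) {
    iv <- rbind(thirds(triplets$n1_start[i], triplets$n1_end[i]),
                thirds(triplets$rem_start[i], triplets$rem_end[i]),
                thirds(triplets$n2_start[i], triplets$n2_end[i]))
    iv_count(spikes, iv) / (iv$end - iv$start)
  }, numeric(9))
  m <- rowMeans(prof)
  z <- if (sd(m) > 0) (m - mean(m)) / sd(m) else rep(0, 9)
  list(profile_z = z, profile_hz = m, n_triplets = nrow(triplets))
}

#' Spearman correlation matrix of preference indices across sessions
#'
#' @param indices_by_session named list (or data.frame columns) of
#'   REM-preference index vectors, aligned on the same neurons; all neurons
#'   (including non-significant) are included.
#' @param min_shared minimum complete pairs per session pair (default 3).
#' @return symmetric matrix of Spearman rho (NA where undefined).
#' @export
preference_correlation <- function(indices_by_session, min_shared = 3) {
  m <- as.data.frame(indices_by_session)
  k <- ncol(m)
  rho <- matrix(NA_real_, k, k, dimnames = list(names(m), names(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(m[[i]], m[[j]])
    if (sum(ok) >= min_shared)
      rho[i, j] <- cor(m[[i]][ok], m[[j]][ok], method = "spearman")
  }
  rho
}

#' Bootstrap comparison of cross-session preference-index correlations
#'
#' Three resampling analyses, each with `n_boot` draws of `n_resample`
#' neurons with replacement: (i) the bootstrap distribution of Spearman rho
#' per session pair per region (with a two-sided bootstrap p against 0);
#' (ii) differences in rho between temporally adjacent session pairs within
#' a region, with 95% CI; (iii) differences in rho between regions for the
#' same session pair, with 95% CI.
#'
#' @param indices_by_session_by_region named list (region) of data.frames
#'   (neurons x sessions) of REM-preference indices.
#' @param n_resample neurons drawn per bootstrap replicate (with
#'   replacement).
#' @param n_boot bootstrap replicates.
#' @param seed optional local seed.
#' @return list of three data.frames: `rho`, `adjacent_diff`, `region_diff`.
#' @export
bootstrap_correlation_compare <- function(indices_by_session_by_region,
                                          n_resample = 92, n_boot = 5000,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- names(indices_by_session_by_region)
  boot_rho <- list() # [[region]][[pair]] = n_boot vector
  rho_rows <- list()
  for (rg in regions) {
    m <- as.data.frame(indices_by_session_by_region[[rg]])
    if (nrow(m) < n_resample)
      warning("region ", rg, " has fewer than ", n_resample,
              " neurons; resampling with replacement remains valid")
    sess <- names(m)
    pairs <- utils::combn(sess, 2, simplify = FALSE)
    boot_rho[[rg]] <- list()
    for (pr in pairs) {
      key <- paste(pr, collapse = "|")
      draws <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(m), n_resample, replace = TRUE)
        suppressWarnings(cor(m[[pr[1]]][idx], m[[pr[2]]][idx],
                             method = "spearman"))
      }, numeric(1))
      boot_rho[[rg]][[key]] <- draws
      p_boot <- 2 * min(mean(draws <= 0), mean(draws >= 0))
      rho_rows[[length(rho_rows) + 1]] <- data.frame(
        region = rg, pair = key, rho_mean = mean(draws, na.rm = TRUE),
        ci_lo = unname(quantile(draws, 0.025, na.rm = TRUE)),
        ci_hi = unname(quantile(draws, 0.975, na.rm = TRUE)),
        p_boot = min(1, p_boot))
    }
  }
  adj_rows <- list(); reg_rows <- list()
  for (rg in regions) {
    keys <- names(boot_rho[[rg]])
    sess <- names(as.data.frame(indices_by_session_by_region[[rg]]))
    adj <- paste(head(sess, -1), tail(sess, -1), sep = "|")
    adj <- adj[adj %in% keys]
    if (length(adj) >= 2) for (i in seq_len(length(adj) - 1)) {
      d <- boot_rho[[rg]][[adj[i + 1]]] - boot_rho[[rg]][[adj[i]]]
      adj_rows[[length(adj_rows) + 1]] <- data.frame(
        region = rg, pair_a = adj[i], pair_b = adj[i + 1],
        diff_mean = mean(d, na.rm = TRUE),
        ci_lo = unname(quantile(d, 0.025, na.rm = TRUE)),
        ci_hi = unname(quantile(d, 0.975, na.rm = TRUE)))
    }
  }
  if (length(regions) >= 2) {
    shared <- Reduce(intersect, lapply(boot_rho, names))
    cmb <- utils::combn(regions, 2, simplify = FALSE)
    for (key in shared) for (pr in cmb) {
      d <- boot_rho[[pr[1]]][[key]] - boot_rho[[pr[2]]][[key]]
      reg_rows[[length(reg_rows) + 1]] <- data.frame(
        pair = key, region_a = pr[1], region_b = pr[2],
        diff_mean = mean(d, na.rm = TRUE),
        ci_lo = unname(quantile(d, 0.025, na.rm = TRUE)),
        ci_hi = unname(quantile(d, 0.975, na.rm = TRUE)))
    }
  }
  list(rho = do.call(rbind, rho_rows),
       adjacent_diff = if (length(adj_rows)) do.call(rbind, adj_rows),
       region_diff = if (length(reg_rows)) do.call(rbind, reg_rows))
}

# Pipeline stage: classify every unit.
preference_table <- function(spikes_by_unit, hypnogram, n_shuffles = 1000,
                             alpha = 0.05) {
  rows <- lapply(names(spikes_by_unit), function(u) {
    sr <- state_rates(spikes_by_unit[[u]] %||% numeric(0), hypnogram)
    if (is.na(sr$fr_rem) || is.na(sr$fr_nrem))
      return(data.frame(unit_id = u, fr_rem = sr$fr_rem, fr_nrem = sr$fr_nrem,
                        index = NA_real_, null_lo = NA_real_,
                        null_hi = NA_real_, label = "dropped"))
    pr <- classify_preference(sr$bin_counts, sr$bin_states,
                              n_shuffles = n_shuffles, alpha = alpha)
    data.frame(unit_id = u, fr_rem = pr$fr_rem, fr_nrem = pr$fr_nrem,
               index = pr$index, null_lo = pr$null_lo, null_hi = pr$null_hi,
               label = pr$label)
  })
  do.call(rbind, rows)
}
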