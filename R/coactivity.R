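# Pairwise coactivation during oscillatory events. Under independent
# activity the number of events in which both neurons are active follows a
# hypergeometric distribution, which gives the closed-form expectation and
# variance behind the coactivity Z-score.

#' Coactivity Z-score of a neuron pair
#'
#' A neuron is active in an event if it emits at least one spike within the
#' event's `[start, end)` interval. With `n_A`, `n_B` active-event counts
#' out of `N` events and `R` events where both are active,
#' `E = n_A n_B / N`, `sigma^2 = n_A n_B (N - n_A)(N - n_B) / (N^2 (N - 1))`,
#' and `Z = (R - E) / sigma`.
#'
#' @param spikes_a,spikes_b sorted spike times of the two neurons.
#' @param events event table (`start`, `end`).
#' @return a `coactivity_result` list: `n_a`, `n_b`, `n_events`, `r`,
#'   `expected`, `sigma`, `z`, `excluded_reason` (`NA` unless `sigma = 0` or
#'   `N = 1`, in which case `z` is `NA`).
#' @export
coactivity_z <- function(spikes_a, spikes_b, events) {
  N <- nrow(events)
  if (N < 1) stop("need at least one event")
  act_a <- iv_count(sort(spikes_a), events) > 0
  act_b <- iv_count(sort(spikes_b), events) > 0
  N <- as.numeric(N) # double arithmetic: the variance product overflows int
  n_a <- as.numeric(sum(act_a)); n_b <- as.numeric(sum(act_b))
  r <- sum(act_a & act_b)
  e <- n_a * n_b / N
  sig2 <- if (N > 1) n_a * n_b * (N - n_a) * (N - n_b) / (N^2 * (N - 1)) else 0
  reason <- NA_character_
  z <- NA_real_
  if (N == 1) reason <- "single event"
  else if (sig2 == 0) reason <- sprintf("sigma = 0 (n_A = %.0f, n_B = %.0f, N = %.0f)",
                                        n_a, n_b, N)
  else z <- (r - e) / sqrt(sig2)
  structure(list(n_a = n_a, n_b = n_b, n_events = N, r = r, expected = e,
                 sigma = sqrt(sig2), z = z, excluded_reason = reason),
            class = "coactivity_result")
}

#' Pair type from preference labels and regions
#'
#' `NN`/`RR` for same-label pairs; cross-regional mixed pairs are ordered by
#' the fixed region order vCA1, PL5, BLA (`NR` means the NREM-preferring
#' member sits in the earlier region); within-region mixed pairs are
#' unordered `NR`; any non-significant member gives `other`.
#'
#' @param label_a,label_b preference labels (`NREM`, `REM`, `NS`).
#' @param region_a,region_b region names.
#' @return one of `"NN"`, `"RR"`, `"NR"`, `"RN"`, `"other"`.
#' @export
pair_type <- function(label_a, region_a, label_b, region_b) {
  if (any(is.na(c(label_a, label_b))) ||
      !all(c(label_a, label_b) %in% c("NREM", "REM")))
    return("other")
  if (label_a == label_b) return(if (label_a == "NREM") "NN" else "RR")
  if (region_a == region_b) return("NR")
  ord <- match(c(region_a, region_b), REGIONS)
  first_label <- if (ord[1] < ord[2]) label_a else label_b
  if (first_label == "NREM") "NR" else "RN"
}

#' NREM-preferring neuron response index
#'
#' For each event `i`, `X(i)` is the fraction of active NREM-preferring
#' neurons among active preference-labeled neurons of the source region, and
#' `Y(i)` is the target neuron's firing rate during the event. The index is
#' the Pearson correlation of `X` and `Y` over events where `X` is defined.
#'
#' @param source_spikes named list of spike-time vectors for the source
#'   region's labeled neurons.
#' @param source_labels matching character vector (`NREM`/`REM`).
#' @param target_spikes spike times of the target neuron.
#' @param events event table.
#' @return list `r`, `n_events_used`, `x`, `y`; `r` is `NA` with a flag when
#'   fewer than 3 usable events or zero variance.
#' @export
response_index <- function(source_spikes, source_labels, target_spikes, events) {
  stopifnot(length(source_spikes) == length(source_labels))
  act <- vapply(source_spikes, function(s) iv_count(sort(s), events) > 0,
                logical(nrow(events)))
  if (nrow(events) == 1) act <- matrix(act, nrow = 1)
  n_n <- rowSums(act[, source_labels == "NREM", drop = FALSE])
  n_r <- rowSums(act[, source_labels == "REM", drop = FALSE])
  ok <- (n_n + n_r) > 0
  x <- n_n[ok] / (n_n[ok] + n_r[ok])
  y <- (iv_count(sort(target_spikes), events) /
          (events$end - events$start))[ok]
  if (sum(ok) < 3)
    return(list(r = NA_real_, n_events_used = sum(ok), x = x, y = y,
                flag = "fewer than 3 usable events"))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, n_events_used = sum(ok), x = x, y = y,
                flag = "zero variance"))
  list(r = cor(x, y), n_events_used = sum(ok), x = x, y = y,
       flag = NA_character_)
}

#' Coactivity versus preference-index products
#'
#' Spearman correlation between per-pair REM-preference index products and
#' coactivity Z-scores (all pairs, including those with non-significant
#' members), plus group means per pair type and a Kruskal-Wallis +
#' Steel-Dwass comparison across pair types.
#'
#' @param pairs data.frame with columns `z`, `index_product`, `pair_type`.
#' @return list `rho` (with `tie_flag`), `group_means`, `omnibus`,
#'   `posthoc`.
#' @export
coactivity_vs_preference <- function(pairs) {
  ok <- stats::complete.cases(pairs$z, pairs$index_product)
  d <- pairs[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 pairs")
  tie_flag <- sd(d$index_product) == 0 || sd(d$z) == 0
  rho <- if (tie_flag) NA_real_
  else cor(d$index_product, d$z, method = "spearman")
  grp <- d[d$pair_type %in% c("NN", "RR", "NR", "RN"), , drop = FALSE]
  groups <- split(grp$z, grp$pair_type)
  groups <- groups[lengths(groups) >= 2]
  comparison <- if (length(groups) >= 2)
    kruskal_steel_dwass(groups) else NULL
  gm <- if (nrow(grp) > 0)
    data.frame(pair_type = names(tapply(grp$z, grp$pair_type, mean)),
               mean_z = as.numeric(tapply(grp$z, grp$pair_type, mean)),
               n = as.integer(table(grp$pair_type)[names(tapply(grp$z, grp$pair_type, mean))]))
  else NULL
  list(rho = rho, tie_flag = tie_flag, group_means = gm,
       omnibus = comparison$omnibus, posthoc = comparison$pairwise)
}

# Pipeline stage: coactivity for all within- and cross-regional excitatory
# pairs over every event kind.
coactivity_table <- function(spikes_by_unit, units, events, preference) {
  ids <- units$unit_id
  if (length(ids) < 2 || nrow(events) == 0)
    return(data.frame(unit_a = character(0), unit_b = character(0),
                      region_a = character(0), region_b = character(0),
                      kind = character(0), pair_type = character(0),
                      n_a = integer(0), n_b = integer(0), n_events = integer(0),
                      r = integer(0), expected = numeric(0), sigma = numeric(0),
                      z = numeric(0), index_product = numeric(0)))
  lab <- setNames(preference$label, preference$unit_id)
  idx <- setNames(preference$index, preference$unit_id)
  cmb <- utils::combn(ids, 2)
  rows <- list()
  for (kind in unique(events$kind)) {
    ev <- events[events$kind == kind, , drop = FALSE]
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      cz <- coactivity_z(spikes_by_unit[[a]], spikes_by_unit[[b]], ev)
      ra <- units$region[units$unit_id == a]
      rb <- units$region[units$unit_id == b]
      rows[[length(rows) + 1]] <- data.frame(
        unit_a = a, unit_b = b, region_a = ra, region_b = rb, kind = kind,
        pair_type = pair_type(lab[[a]] %||% "NS", ra, lab[[b]] %||% "NS", rb),
        n_a = cz$n_a, n_b = cz$n_b, n_events = cz$n_events, r = cz$r,
        expected = cz$expected, sigma = cz$sigma, z = cz$z,
        index_product = (idx[[a]] %||% NA_real_) * (idx[[b]] %||% NA_real_))
    }
  }
  do.call(rbind, rows)
}
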