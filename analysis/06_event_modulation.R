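#!/usr/bin/env Rscript
# Step 06 -- firing-rate modulation: gain inside each oscillation class
# (checked against injected gains), peri-event rates, sleep-long firing
# trends, and shock-evoked gains after artifact censoring.

suppressPackageStartupMessages(library(sleeposc))

s <- load_session("results/session/manifest.json")
hyp <- read_table("results/epochs.tsv")
ev <- read_table("results/events.tsv")
ext <- read_table("results/extended_sleep.tsv")
quality <- read_table("results/quality.tsv")
included <- quality$unit_id[quality$included %in% TRUE]
spl <- split(s$spikes$t, s$spikes$unit_id)[included]

gains <- sleeposc:::gain_table(spl, ev, hyp)
tg <- s$truth_gains
tg <- tg[tg$kind != "shock" & tg$unit_id %in% included, ]
m <- merge(gains, tg, by = c("unit_id", "kind"))
ok <- is.finite(m$gain.x)
message(sprintf(
  "FR gain vs injected gain over %d unit-kind pairs: median |rel err| %.2f",
  sum(ok), median(abs(m$gain.x[ok] - m$gain.y[ok]) / m$gain.y[ok])))

# mean PETH of vCA1 units around SWR peaks
swr_peaks <- ev$peak_time[ev$kind == "SWR"]
ca1 <- included[grepl("^vCA1", included)]
peth <- NULL
if (length(swr_peaks) > 0 && length(ca1) > 0) {
  peth <- do.call(rbind, lapply(ca1, function(u) {
    p <- peri_event_rate(spl[[u]], swr_peaks, kind = "SWR")
    data.frame(unit_id = u, lag_s = p$lag_s, rate_hz = p$mean_rate_hz)
  }))
}

trend <- NULL
if (nrow(ext) > 0) {
  tr <- try(sleep_fr_trend(spl, ext, hyp), silent = TRUE)
  if (!inherits(tr, "try-error")) {
    trend <- tr$trend
    message(sprintf("Sleep FR trend: median rho %.2f over %d units",
                    median(trend$rho, na.rm = TRUE), nrow(trend)))
  }
}

shock <- NULL
if (nrow(s$shocks) > 0) {
  first_cs <- min(s$cs$start)
  shock <- do.call(rbind, lapply(included, function(u) {
    spk <- censor_shock_artifacts(spl[[u]], s$shock_pulses)
    g <- shock_gain(spk, s$shocks, first_cs)
    data.frame(unit_id = u, peak_fr = g$peak_fr, baseline_fr = g$baseline_fr,
               gain = g$gain)
  }))
  truth_sg <- s$truth_gains[s$truth_gains$kind == "shock", ]
  ms <- merge(shock, truth_sg, by = "unit_id")
  ok2 <- is.finite(ms$gain.x)
  message(sprintf("Shock gain vs injected over %d units: rank correlation %.2f",
                  sum(ok2), cor(ms$gain.x[ok2], ms$gain.y[ok2],
                                method = "spearman")))
}

save_tables(c(list(gains = gains),
              if (!is.null(peth)) list(swr_peth = peth),
              if (!is.null(trend)) list(fr_trend = trend),
              if (!is.null(shock)) list(shock_gains = shock)),
            "results")
message("Wrote results/gains.tsv (+ swr_peth / fr_trend / shock_gains where defined)")
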