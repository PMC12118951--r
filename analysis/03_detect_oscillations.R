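#!/usr/bin/env Rscript
# Step 03 -- detect the four fast-oscillation classes from the LFP and
# compare against the injected ground truth; summarize durations and rates.

suppressPackageStartupMessages(library(sleeposc))

s <- load_session("results/session/manifest.json")
hyp <- read_table("results/epochs.tsv")

ev <- rbind(detect_swr(s$lfp, hyp),
            detect_fast_osc(s$lfp, hyp, "HFO"),
            detect_fast_osc(s$lfp, hyp, "cRipple"),
            detect_spindles(s$lfp, hyp))
nrem <- select_state_time(hyp[hyp$usable, ], "NREM")

summ <- lapply(split(ev, ev$kind), function(e) event_summary(e, nrem))
summary_df <- do.call(rbind, lapply(names(summ), function(k)
  cbind(kind = k, as.data.frame(summ[[k]]))))

for (k in unique(ev$kind)) {
  tr <- s$truth_events[s$truth_events$kind == k, ]
  de <- ev[ev$kind == k, ]
  recall <- mean(vapply(seq_len(nrow(tr)), function(i)
    any(de$start < tr$end[i] & de$end > tr$start[i]), logical(1)))
  message(sprintf(
    "%-8s %4d detected / %4d injected (recall %.3f); median dur %.0f ms, %.3f /s in NREM",
    k, nrow(de), nrow(tr), recall,
    summ[[k]]$dur_median_ms, summ[[k]]$rate_hz))
}

save_tables(list(events = ev, event_summary = summary_df), "results")
message("Wrote results/events.tsv, results/event_summary.tsv")
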