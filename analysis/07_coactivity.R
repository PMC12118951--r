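#!/usr/bin/env Rscript
# Step 07 -- pairwise coactivation during oscillatory events (hypergeometric
# Z-score) for excitatory pairs, and NREM-preferring neuron response indices
# for cross-regional events.

suppressPackageStartupMessages(library(sleeposc))

s <- load_session("results/session/manifest.json")
ev <- read_table("results/events.tsv")
pref <- read_table("results/preference.tsv")
types <- read_table("results/cell_types.tsv")
exc <- types$unit_id[types$label == "excitatory"]
spl <- split(s$spikes$t, s$spikes$unit_id)[exc]

pairs <- sleeposc:::coactivity_table(
  spl, s$units[match(exc, s$units$unit_id), ], ev, pref)
message(nrow(pairs), " pair-kind rows over ", length(exc),
        " excitatory units; Z defined for ",
        sum(is.finite(pairs$z)), " rows")
message("Pair types: ",
        paste(names(table(pairs$pair_type)), table(pairs$pair_type),
              sep = "=", collapse = ", "))

# response indices: source region = the region each oscillation is detected
# in; targets are labeled units of the other regions
src_region <- c(SWR = "vCA1", HFO = "BLA", cRipple = "PL5", spindle = "PL5")
resp <- list()
for (k in unique(ev$kind)) {
  evk <- ev[ev$kind == k, ]
  src_ids <- pref$unit_id[pref$label %in% c("NREM", "REM") &
                            grepl(paste0("^", src_region[[k]]), pref$unit_id)]
  if (length(src_ids) < 2 || nrow(evk) < 3) next
  labels <- pref$label[match(src_ids, pref$unit_id)]
  tgt_ids <- exc[!grepl(paste0("^", src_region[[k]]), exc)]
  for (u in tgt_ids) {
    ri <- response_index(split(s$spikes$t, s$spikes$unit_id)[src_ids],
                         labels, spl[[u]], evk)
    resp[[length(resp) + 1]] <- data.frame(
      unit_id = u, kind = k, r = ri$r, n_events = ri$n_events_used)
  }
}
resp <- do.call(rbind, resp)
if (!is.null(resp))
  message("Response indices computed for ", nrow(resp), " unit-kind pairs")

save_tables(c(list(coactivity = pairs),
              if (!is.null(resp)) list(response_indices = resp)), "results")
message("Wrote results/coactivity.tsv",
        if (!is.null(resp)) " and results/response_indices.tsv" else "")
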