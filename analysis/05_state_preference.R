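#!/usr/bin/env Rscript
# Step 05 -- classify units as REM- or NREM-preferring with the shuffle-null
# REM-preference index, and compute triplet firing profiles.

suppressPackageStartupMessages(library(sleeposc))
set.seed(20240915L)

s <- load_session("results/session/manifest.json")
hyp <- read_table("results/epochs.tsv")
trip <- read_table("results/triplets.tsv")
quality <- read_table("results/quality.tsv")
included <- quality$unit_id[quality$included %in% TRUE]
spl <- split(s$spikes$t, s$spikes$unit_id)[included]

pref <- sleeposc:::preference_table(spl, hyp, n_shuffles = 1000, alpha = 0.05)
message("Preference labels: ",
        paste(names(table(pref$label)), table(pref$label),
              sep = "=", collapse = ", "))

# how well does the classification recover the generator's rate ratios?
truth_ratio <- s$units$rem_nrem_ratio[match(pref$unit_id, s$units$unit_id)]
strong <- abs(log(truth_ratio)) > log(2)
ok <- pref$label[strong] == ifelse(truth_ratio[strong] > 1, "REM", "NREM")
message(sprintf("Recovery among units with a >2-fold true ratio: %.2f (n = %d)",
                mean(ok), sum(strong)))

profiles <- NULL
if (nrow(trip) > 0) {
  profiles <- do.call(rbind, lapply(names(spl), function(u) {
    tp <- triplet_profile(spl[[u]], trip)
    data.frame(unit_id = u, third = 1:9,
               segment = rep(c("NREM1", "REM", "NREM2"), each = 3),
               fr_hz = tp$profile_hz, fr_z = tp$profile_z)
  }))
  message("Triplet profiles over ", nrow(trip), " triplet(s)")
}

save_tables(c(list(preference = pref),
              if (!is.null(profiles)) list(triplet_profiles = profiles)),
            "results")
message("Wrote results/preference.tsv",
        if (!is.null(profiles)) " and results/triplet_profiles.tsv" else "")
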