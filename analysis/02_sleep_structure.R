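#!/usr/bin/env Rscript
# Step 02 -- sleep architecture: microarousal merging, short-epoch
# exclusion, extended-sleep periods, NREM-REM-NREM triplets.

suppressPackageStartupMessages(library(sleeposc))

s <- load_session("results/session/manifest.json")
hyp <- normalize_hypnogram(s$hypnogram)
ext <- find_extended_sleep(hyp)
trip <- find_triplets(hyp)

message(nrow(s$hypnogram), " raw bouts -> ", nrow(hyp),
        " normalized epochs (", sum(!hyp$usable), " flagged <= 50 s)")
message(nrow(ext), " extended-sleep period(s), total ",
        round(iv_duration(ext) / 60, 1), " min")
message(nrow(trip), " NREM-REM-NREM triplet(s)")

save_tables(list(epochs = hyp, extended_sleep = ext, triplets = trip),
            "results")
message("Wrote results/epochs.tsv, results/extended_sleep.tsv, results/triplets.tsv")
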