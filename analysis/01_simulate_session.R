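#!/usr/bin/env Rscript
# Step 01 -- simulate a complete 2-h recording session.
#
# Generates the synthetic session all later steps analyze: a semi-Markov
# hypnogram, state-modulated Poisson spike trains for 30 units in each of
# vCA1, PL5 and BLA, LFP with injected SWRs/HFOs/cRipples/spindles, and a
# conditioning-style schedule of three 2-s shocks with preceding tones.

suppressPackageStartupMessages(library(sleeposc))

out_dir <- "results/session"
cfg <- synth_config(
  duration_s = 7200,
  n_units_per_region = 30,
  shock_times = c(600, 840, 1080),
  cs_times = c(569, 809, 1049),
  seed = 20240915L
)
message("Simulating a ", cfg$duration_s / 3600, "-h session into ", out_dir)
s <- generate_session(cfg, out_dir)

hyp <- s$hypnogram
dur_by_state <- tapply(hyp$end - hyp$start, hyp$state, sum) / 60
message(sprintf("State minutes: NREM %.1f, REM %.1f, WAKE %.1f",
                dur_by_state[["NREM"]], dur_by_state[["REM"]],
                dur_by_state[["WAKE"]]))
message("Injected events: ",
        paste(names(table(s$truth_events$kind)), table(s$truth_events$kind),
              sep = "=", collapse = ", "))
message("Units: ", nrow(s$units), "; spikes: ", nrow(s$spikes))
message("Done. Manifest at ", file.path(out_dir, "manifest.json"))
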