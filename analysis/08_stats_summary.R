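#!/usr/bin/env Rscript
# Step 08 -- statistical summary: gain comparisons between NREM- and
# REM-preferring units (Mann-Whitney), gain/coactivity versus preference
# (Spearman), and pair-type comparisons (Kruskal-Wallis + Steel-Dwass).
# Writes results/stats.tsv and a short markdown report.

suppressPackageStartupMessages(library(sleeposc))

pref <- read_table("results/preference.tsv")
gains <- read_table("results/gains.tsv")
pairs <- read_table("results/coactivity.tsv")

stats <- sleeposc:::pipeline_stats(list(preference = pref, gains = gains,
                                        coactivity = pairs))
save_tables(list(stats = stats), "results")

lines <- c("# Session statistics", "",
           sprintf("- %d units classified: %s", nrow(pref),
                   paste(names(table(pref$label)), table(pref$label),
                         sep = "=", collapse = ", ")),
           sprintf("- %d tests computed (see stats.tsv)", nrow(stats)), "")
sig <- stats[stats$p_value < 0.05, ]
lines <- c(lines, sprintf("%d tests with p < 0.05:", nrow(sig)),
           sprintf("- %s: %s statistic %.3g, p = %.3g (n = %s)",
                   sig$analysis, sig$method, sig$statistic, sig$p_value, sig$n))
writeLines(lines, "results/report.md")

message(nrow(stats), " tests written to results/stats.tsv; report in results/report.md")
for (i in seq_len(min(nrow(sig), 12)))
  message(sprintf("  %-50s p = %.3g", sig$analysis[i], sig$p_value[i]))
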