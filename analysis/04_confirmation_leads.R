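#!/usr/bin/env Rscript
# Confirmation qHTS and lead triage, two ways:
#  (a) the bundled reference IC50 outcome table -> IC50 <= 1 uM leads
#      and per-line categories;
#  (b) a simulated confirmation screen (5-point 1:5 series from 10 uM,
#      screen 1 singlet + screen 2 duplicate, screens averaged, 4PL fit)
#      for the reference potencies, checking parameter recovery.

suppressPackageStartupMessages(library(estroscreen))

out <- "results"
dir.create(out, showWarnings = FALSE)

# (a) triage of the bundled reference outcomes
ref <- read_ic50_table(system.file("extdata", "confirmation_ic50.csv",
                                   package = "estroscreen"))
leads <- designate_leads(ref)
cats <- categorize_leads(leads)
cat(sprintf("Reference outcomes: %d compounds, %d leads\n",
            nrow(leads), cats$n_leads))
cat(sprintf("  1455 only: %d   1458 only: %d   both: %d   neither: %d\n",
            cats[["1455_only"]], cats[["1458_only"]], cats$both,
            cats$neither))
utils::write.csv(leads, file.path(out, "lead_table.csv"), row.names = FALSE)

# (b) simulated confirmation for two reference potencies
truths <- data.frame(
  compound_id = c("SN01006330", "SN01005061"),
  cell_line = c("1455", "1458"),
  top = 100, bottom = 0, hill = 1,
  log10_ic50 = log10(c(0.08, 0.37)))
cfg <- generator_config(seed = 1)
conf <- run_confirmation_screen(simulate_confirmation_screen(truths, cfg))
print(conf$ic50_table[, c("compound_id", "cell_line", "ic50", "status")])

medians <- vapply(seq_len(nrow(truths)), function(k) {
  stats::median(vapply(1:100, function(i) {
    ci <- generator_config(seed = 1 + i)
    avg <- average_screens(
      simulate_confirmation_screen(truths[k, , drop = FALSE], ci))
    fit_4pl(avg$dose_uM, avg$response_pct)$ic50
  }, numeric(1)), na.rm = TRUE)
}, numeric(1))
cat(sprintf("Median fitted IC50 over 100 seeds: %s = %.3f uM (truth %.2f), %s = %.3f uM (truth %.2f)\n",
            truths$compound_id[1], medians[1], 10^truths$log10_ic50[1],
            truths$compound_id[2], medians[2], 10^truths$log10_ic50[2]))
utils::write.csv(conf$ic50_table, file.path(out, "confirmation_fits.csv"),
                 row.names = FALSE)
cat("Wrote lead_table.csv, confirmation_fits.csv\n")
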