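#!/usr/bin/env Rscript
# Generate the synthetic primary screen: 10 library plates x 352
# compounds x 2 cell lines (1455, 1458), paired vehicle/estrogen plates
# with the canonical control block, at the default noise and effect
# rates. Writes the count tables and the generator truth ledger.

suppressPackageStartupMessages(library(estroscreen))

out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- generator_config(seed = 1)
ds <- simulate_primary_screen(cfg)

cat(sprintf("Simulated %d plates (%d layouts x %d lines x 2 conditions)\n",
            length(ds$plates), length(ds$layouts),
            length(cfg$cell_lines)))
cat(sprintf("Library: %d compounds; programmed toxic %d, programmed hits %d\n",
            length(unique(ds$truth$compound_id)),
            sum(ds$truth$is_toxic[!duplicated(ds$truth$compound_id)]),
            sum(ds$truth$is_hit[!duplicated(ds$truth$compound_id)])))

write_count_table(ds$plates, file.path(out, "primary_counts.csv"))
write_plate_layout(ds$layouts[[1]], file.path(out, "layout_P01.csv"))
write_truth_ledger(ds$truth, file.path(out, "truth_ledger.csv"))
cat("Wrote primary_counts.csv, layout_P01.csv, truth_ledger.csv\n")
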