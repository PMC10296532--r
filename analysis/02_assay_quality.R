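#!/usr/bin/env Rscript
# Assay quality of the simulated screen: per-plate Z-prime for each
# (DMSO vs QC-positive) pairing and %CV of every control group, with the
# Z' >= 0.5 and %CV < 25 gates. Also demonstrates the QC-compound
# acceptance rules on noise-free titrations of an accepted inhibitor, an
# estrogen-specific inhibitor (rejected), and an inert negative.

suppressPackageStartupMessages(library(estroscreen))

out <- "results"
dir.create(out, showWarnings = FALSE)

ds <- simulate_primary_screen(generator_config(seed = 1))
qc <- qc_report(ds)
utils::write.csv(qc, file.path(out, "qc_report.csv"), row.names = FALSE)

zp <- qc[qc$metric == "zprime", ]
cv <- qc[qc$metric == "pcv", ]
cat(sprintf("Z' over %d pairings: min %.3f, median %.3f (gate >= 0.5: %s)\n",
            nrow(zp), min(zp$value), stats::median(zp$value),
            if (all(zp$pass)) "all pass" else "FAILURES"))
cat(sprintf("%%CV over %d groups: max %.2f (gate < 25: %s)\n",
            nrow(cv), max(cv$value),
            if (all(cv$pass)) "all pass" else "FAILURES"))
cat(sprintf("QC-negative groups: max %%CV %.2f\n",
            max(cv$value[cv$class == "qc_negative"])))

# QC-compound acceptance on titrations
profiles <- list(
  panobinostat = list(  # potent in both conditions -> accept
    vehicle = list(top = 100, bottom = 5, hill = 1, log10_ic50 = log10(0.5)),
    estrogen = list(top = 100, bottom = 5, hill = 1, log10_ic50 = log10(0.5))),
  tamoxifen = list(     # estrogen-specific -> reject as QC positive
    vehicle = list(top = 100, bottom = 95, hill = 1, log10_ic50 = log10(1)),
    estrogen = list(top = 100, bottom = 5, hill = 1, log10_ic50 = log10(1))),
  fulvestrant = list(   # inert at 10 uM -> accept as QC negative
    vehicle = list(top = 100, bottom = 98, hill = 1, log10_ic50 = log10(30)),
    estrogen = list(top = 100, bottom = 98, hill = 1, log10_ic50 = log10(30))))
cfg0 <- generator_config(seed = 1, well_noise_cv = 0)
tt <- simulate_qc_titration(cfg0, profiles)
for (cmp in names(profiles)) {
  role <- if (cmp == "fulvestrant") "negative" else "positive"
  sub <- tt[tt$compound_id == cmp, ]
  agg <- stats::aggregate(response_pct ~ dose_uM + condition, sub, mean)
  v <- agg[agg$condition == "vehicle", ]
  e <- agg[agg$condition == "estrogen", ]
  a <- qc_compound_acceptance(v$dose_uM, 100 - v$response_pct,
                              100 - e$response_pct, role = role)
  cat(sprintf("QC %-12s as %-8s: %s%s\n", cmp, role,
              if (a$accept) "accepted" else "rejected",
              if (length(a$reasons)) paste0(" (", a$reasons[1], ")") else ""))
}
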