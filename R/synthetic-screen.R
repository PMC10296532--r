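#' Synthetic screen generator configuration
#'
#' Parameters of the simulated primary screen. The generator emulates the
#' paired vehicle/estrogen 384-well design: library compounds at 10 uM in
#' columns 1--22, the canonical control block in columns 23--24,
#' estrogen-driven growth stimulation of the DMSO baseline, a small
#' fraction of vehicle-toxic compounds, a rare tail of strong
#' estrogen-specific inhibitors, and multiplicative lognormal well noise
#' (cell counts are positive with variance growing with the mean; the
#' noise sigma is `sqrt(log(1 + cv^2))`, scaled to unit mean).
#'
#' @param n_library_plates number of library plates.
#' @param compounds_per_plate library compounds per plate (at most 352).
#' @param cell_lines character vector of cell line ids.
#' @param baseline_count expected vehicle DMSO-control nuclei count.
#' @param estrogen_growth_factor multiplicative growth stimulation under
#'   estrogen (> 0; > 1 for an estrogen-responsive line).
#' @param well_noise_cv coefficient of variation of the multiplicative
#'   lognormal well noise (>= 0; 0 gives noise-free plates).
#' @param toxic_fraction fraction of compounds toxic under vehicle
#'   (true vehicle viability drawn uniformly in `toxic_viability_range`,
#'   below the 0.5 triage cutoff).
#' @param hit_fraction fraction of compounds with strong
#'   estrogen-specific inhibition. Toxicity and hit status are drawn
#'   independently (a compound can be both, exercising the triage order)
#'   and are compound-level traits shared across cell lines; effect
#'   magnitudes are drawn per line.
#' @param background_inhibition_mean,background_inhibition_sd normal
#'   distribution (percent) of the estrogen-driven inhibition of
#'   non-hits.
#' @param hit_inhibition_range uniform range (percent) of the
#'   estrogen-driven inhibition of true hits.
#' @param toxic_viability_range uniform range of the true vehicle
#'   viability of toxic compounds.
#' @param qc_positive_residual residual survival of QC-positive control
#'   wells (fraction of the DMSO signal, both conditions).
#' @param qc_positive,qc_negative QC compound names on every plate.
#' @param seed integer seed; every plate gets its own RNG stream keyed by
#'   (seed, layout, cell line, condition) so plates can be regenerated
#'   independently.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_library_plates = 10L,
                             compounds_per_plate = 352L,
                             cell_lines = c("1455", "1458"),
                             baseline_count = 1000,
                             estrogen_growth_factor = 1.6,
                             well_noise_cv = 0.08,
                             toxic_fraction = 0.08,
                             hit_fraction = 0.015,
                             background_inhibition_mean = 5,
                             background_inhibition_sd = 12,
                             hit_inhibition_range = c(75, 98),
                             toxic_viability_range = c(0.1, 0.45),
                             qc_positive_residual = 0.05,
                             qc_positive = c("panobinostat", "salinomycin"),
                             qc_negative = "fulvestrant",
                             seed = 1L) {
  if (compounds_per_plate > 352L) {
    stop("compounds_per_plate must be <= 352 (columns 1-22)", call. = FALSE)
  }
  stopifnot(n_library_plates >= 1L, length(cell_lines) >= 1L,
            baseline_count > 0, estrogen_growth_factor > 0,
            well_noise_cv >= 0,
            toxic_fraction >= 0, toxic_fraction <= 1,
            hit_fraction >= 0, hit_fraction <= 1,
            background_inhibition_sd >= 0,
            length(hit_inhibition_range) == 2L,
            qc_positive_residual >= 0)
  structure(list(
    n_library_plates = as.integer(n_library_plates),
    compounds_per_plate = as.integer(compounds_per_plate),
    cell_lines = as.character(cell_lines),
    baseline_count = baseline_count,
    estrogen_growth_factor = estrogen_growth_factor,
    well_noise_cv = well_noise_cv,
    toxic_fraction = toxic_fraction,
    hit_fraction = hit_fraction,
    background_inhibition_mean = background_inhibition_mean,
    background_inhibition_sd = background_inhibition_sd,
    hit_inhibition_range = hit_inhibition_range,
    toxic_viability_range = toxic_viability_range,
    qc_positive_residual = qc_positive_residual,
    qc_positive = qc_positive, qc_negative = qc_negative,
    seed = as.integer(seed)), class = "generator_config")
}

# Deterministic per-stream seed from a base seed and a string key
# (31-polynomial hash mod 2^31 - 1, so set.seed always gets a valid int).
stream_seed <- function(seed, ...) {
  key <- paste(..., sep = "|")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + as.numeric(seed) * 1000003) %% 2147483647)
}

# Multiplicative lognormal noise with mean 1 and the requested CV.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate a primary screen
#'
#' Builds a full [screen_dataset()]: for each library plate and cell
#' line, a paired vehicle/estrogen [raw_plate()] with the canonical
#' control layout. The expected count of a well is
#' `baseline x growth(condition) x survival_effect x lognormal(1, cv)`,
#' rounded to an integer nuclei count; growth is
#' `estrogen_growth_factor` on estrogen plates and 1 on vehicle plates.
#' QC-negative wells carry survival effect 1 in both conditions,
#' QC-positive wells the configured residual in both conditions. The
#' per-compound true effects are returned as the `truth` ledger so every
#' downstream stage can be checked against what was programmed.
#'
#' @param config a [generator_config()].
#' @return A [screen_dataset()] whose `truth` is a data.frame with one
#'   row per (compound, cell line): `compound_id`, `layout_id`,
#'   `cell_line`, `vehicle_effect`, `estrogen_effect` (relative to the
#'   estrogen-stimulated baseline), `true_edi` (percent), `is_toxic`,
#'   `is_hit`.
#' @export
simulate_primary_screen <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n_total <- config$n_library_plates * config$compounds_per_plate
  compound_ids <- sprintf("C%05d", seq_len(n_total))
  layout_ids <- sprintf("P%02d", seq_len(config$n_library_plates))

  # compound-level traits: one stream, independent Bernoulli draws
  set.seed(stream_seed(config$seed, "traits"))
  is_toxic <- stats::runif(n_total) < config$toxic_fraction
  is_hit <- stats::runif(n_total) < config$hit_fraction

  layouts <- list()
  plates <- list()
  truth <- list()
  for (p in seq_len(config$n_library_plates)) {
    lid <- layout_ids[p]
    idx <- (p - 1L) * config$compounds_per_plate +
      seq_len(config$compounds_per_plate)
    layout <- make_library_layout(lid, compound_ids[idx],
                                  qc_positive = config$qc_positive,
                                  qc_negative = config$qc_negative)
    layouts[[lid]] <- layout
    for (line in config$cell_lines) {
      # per-line true effect magnitudes, shared by the condition pair
      set.seed(stream_seed(config$seed, lid, line, "effects"))
      n_p <- length(idx)
      veh <- ifelse(is_toxic[idx],
                    stats::runif(n_p, config$toxic_viability_range[1],
                                 config$toxic_viability_range[2]), 1)
      edi <- ifelse(is_hit[idx],
                    stats::runif(n_p, config$hit_inhibition_range[1],
                                 config$hit_inhibition_range[2]),
                    stats::rnorm(n_p, config$background_inhibition_mean,
                                 config$background_inhibition_sd))
      edi <- pmin(edi, 100)
      est <- veh * (1 - edi / 100)
      truth[[paste(lid, line)]] <- data.frame(
        compound_id = compound_ids[idx], layout_id = lid, cell_line = line,
        vehicle_effect = veh, estrogen_effect = est, true_edi = edi,
        is_toxic = is_toxic[idx], is_hit = is_hit[idx],
        stringsAsFactors = FALSE)
      effect_of <- list(vehicle = veh, estrogen = est)
      for (cond in c("vehicle", "estrogen")) {
        growth <- if (cond == "estrogen") config$estrogen_growth_factor else 1
        nonempty <- layout[layout$role != "empty", ]
        eff <- numeric(nrow(nonempty))
        lib <- nonempty$role == "library_compound"
        eff[lib] <- effect_of[[cond]][match(nonempty$compound_id[lib],
                                            compound_ids[idx])]
        eff[nonempty$role %in% c("vehicle_control", "media_control",
                                 "qc_negative")] <- 1
        eff[nonempty$role == "qc_positive"] <- config$qc_positive_residual
        expected <- config$baseline_count * growth * eff
        set.seed(stream_seed(config$seed, lid, line, cond))
        counts <- round(expected * lognormal_noise(length(expected),
                                                   config$well_noise_cv))
        pid <- paste(lid, line, cond, sep = "_")
        plates[[pid]] <- raw_plate(pid, lid, line, cond,
                                   stats::setNames(counts, nonempty$well))
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  screen_dataset(layouts, plates, truth = truth, config = config)
}

#' @rdname simulate_primary_screen
#' @param truth the truth ledger of a simulated screen.
#' @param file output CSV path.
#' @export
write_truth_ledger <- function(truth, file) {
  utils::write.csv(truth, file, row.names = FALSE)
  invisible(file)
}

#' Simulate a QC-compound titration
#'
#' 10-dose 1:2 series from 50 uM (50, 25, ..., 50/2^9 ~ 0.0977 uM; the
#' exact geometric series is used even though the terminal dose is often
#' quoted rounded as 0.05 uM), in triplicate, under both conditions.
#' Responses are percent survival from each condition's true
#' four-parameter logistic curve times multiplicative lognormal noise.
#'
#' @param config a [generator_config()] (supplies `well_noise_cv`, seed).
#' @param qc_compound_profiles named list: compound -> list(vehicle =,
#'   estrogen =) where each entry is a list with `top`, `bottom`, `hill`,
#'   `log10_ic50` (the 4PL truth for that condition).
#' @return Long data.frame: `compound_id`, `condition`, `replicate`,
#'   `dose_uM`, `response_pct`.
#' @export
simulate_qc_titration <- function(config, qc_compound_profiles) {
  doses <- 50 * 2^-(0:9)
  rows <- list()
  for (cmp in names(qc_compound_profiles)) {
    for (cond in c("vehicle", "estrogen")) {
      tr <- qc_compound_profiles[[cmp]][[cond]]
      mu <- four_pl(doses, B = tr$bottom, T_ = tr$top, h = tr$hill,
                    log10_ic50 = tr$log10_ic50)
      set.seed(stream_seed(config$seed, "qc_titration", cmp, cond))
      for (rep in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = cmp, condition = cond, replicate = rep,
          dose_uM = doses,
          response_pct = mu * lognormal_noise(length(doses),
                                              config$well_noise_cv),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the confirmation (cherry-pick) screens
#'
#' Two independent qHTS screens over a 5-point 1:5 dilution series from
#' 10 uM (10, 2, 0.4, 0.08, 0.016 uM; the exact series, though the
#' terminal dose is often quoted rounded as 0.02 uM): screen 1 without
#' replicates, screen 2 in duplicate. Responses are percent survival from
#' each compound's true 4PL times multiplicative lognormal noise.
#'
#' @param truths data.frame with columns `compound_id`, `cell_line`,
#'   `top`, `bottom`, `hill`, `log10_ic50`.
#' @param config a [generator_config()] (supplies `well_noise_cv`, seed).
#' @return Long data.frame: `compound_id`, `cell_line`, `screen`,
#'   `replicate`, `dose_uM`, `response_pct`.
#' @export
simulate_confirmation_screen <- function(truths, config) {
  doses <- confirmation_doses()
  rows <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    mu <- four_pl(doses, B = tr$bottom, T_ = tr$top, h = tr$hill,
                  log10_ic50 = tr$log10_ic50)
    set.seed(stream_seed(config$seed, "confirmation", tr$compound_id,
                         tr$cell_line))
    for (scr in 1:2) {
      for (rep in seq_len(scr)) {  # screen 1 singlet, screen 2 duplicate
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = tr$compound_id, cell_line = tr$cell_line,
          screen = scr, replicate = rep, dose_uM = doses,
          response_pct = mu * lognormal_noise(length(doses),
                                              config$well_noise_cv),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname simulate_confirmation_screen
#' @export
confirmation_doses <- function() 10 * 5^-(0:4)
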