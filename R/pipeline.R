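#' Run the primary screen analysis
#'
#' Full triage of a [screen_dataset()], in the fixed stage order:
#' image-flag exclusion, DMSO control-outlier removal and per-plate
#' normalization, assay QC report, vehicle-toxicity triage, %E-DI,
#' threshold derivation, hit calling, summary. Every stage conserves
#' counts: retained + removed + unevaluable always equals the input.
#'
#' The toxicity decision is taken per (compound, cell line), but a
#' compound toxic in at least one line is removed from all further
#' analysis (compound-level exclusion), so per-line hit lists only ever
#' contain compounds analyzed everywhere.
#'
#' @param dataset a [screen_dataset()], real (via [read_count_table()])
#'   or simulated (via [simulate_primary_screen()]).
#' @param edi_form `"inhibition"` (default) or `"as_printed"`; see
#'   [edi()].
#' @param threshold `"derived"` for mean + `threshold_multiplier` x SD of
#'   all analyzed samples, or a fixed number (the campaign modelled here
#'   used 70).
#' @param threshold_multiplier SD multiple for the derived threshold.
#' @param toxicity_cutoff vehicle-viability cutoff (strict `<`).
#' @param outlier_k SD multiple of the control-outlier rule.
#' @param zprime_gate,cv_gate assay-quality gates.
#' @return List with `qc` (QC report), `threshold`, `hit_table`,
#'   `summary`, `toxicity` (per-line filter output), `edi_form`, and
#'   `normalized` (per-plate normalized values).
#' @export
run_primary_screen <- function(dataset,
                               edi_form = c("inhibition", "as_printed"),
                               threshold = "derived",
                               threshold_multiplier = 2.5,
                               toxicity_cutoff = 0.5,
                               outlier_k = 3,
                               zprime_gate = 0.5, cv_gate = 25) {
  edi_form <- match.arg(edi_form)
  stopifnot(inherits(dataset, "screen_dataset"))
  qc <- qc_report(dataset, zprime_gate = zprime_gate, cv_gate = cv_gate)
  normalized <- lapply(dataset$plates, function(p) {
    normalize_plate(p, dataset$layouts[[p$layout_id]],
                    outlier_k = outlier_k)
  })

  # per (compound, line): alpha from the vehicle plate, beta from the
  # paired estrogen plate of the same library plate
  pairs <- dataset$pairing
  ab <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    layout <- dataset$layouts[[pairs$layout_id[i]]]
    lib <- layout[layout$role == "library_compound", ]
    v <- normalized[[pairs$vehicle_plate[i]]]$normalized
    e <- normalized[[pairs$estrogen_plate[i]]]$normalized
    data.frame(compound_id = lib$compound_id,
               cell_line = pairs$cell_line[i],
               layout_id = pairs$layout_id[i],
               alpha = unname(v[lib$well]), beta = unname(e[lib$well]),
               stringsAsFactors = FALSE)
  }))

  tox <- vehicle_toxicity_filter(
    data.frame(compound_id = ab$compound_id, cell_line = ab$cell_line,
               viability = ab$alpha, stringsAsFactors = FALSE),
    cutoff = toxicity_cutoff)
  excluded_compounds <- unique(c(tox$excluded$compound_id,
                                 tox$unevaluable$compound_id))
  keep <- !(ab$compound_id %in% excluded_compounds) &
    !is.na(ab$alpha) & !is.na(ab$beta) & ab$alpha > 0
  analyzed <- ab[keep, , drop = FALSE]
  analyzed$edi <- as.numeric(edi(analyzed$alpha, analyzed$beta,
                                 form = edi_form))

  edi_inh <- if (edi_form == "inhibition") analyzed$edi
             else 100 - analyzed$edi  # thresholds live on the inhibition scale
  thr <- derive_threshold(edi_inh, multiplier = threshold_multiplier,
                          fixed = if (identical(threshold, "derived")) NULL
                                  else as.numeric(threshold))
  hit_table <- call_hits(
    data.frame(analyzed[c("compound_id", "cell_line", "alpha", "beta")],
               edi = edi_inh, stringsAsFactors = FALSE), thr)
  n_library <- length(unique(ab$compound_id))
  summary <- summarize_screen(hit_table, n_library, excluded_compounds)
  list(qc = qc, threshold = thr, hit_table = hit_table, summary = summary,
       toxicity = tox, edi_form = edi_form, normalized = normalized)
}

#' Run the confirmation screen analysis
#'
#' Averages the two qHTS screens per compound and cell line
#' ([average_screens()]), fits the 4PL ([fit_4pl()]), adjudicates the
#' IC50 and designates leads and per-line categories.
#'
#' @param responses long data.frame (`compound_id`, `cell_line`,
#'   `screen`, `replicate`, `dose_uM`, `response_pct`), e.g. from
#'   [simulate_confirmation_screen()] or a cherry-pick CSV.
#' @param lead_cutoff_uM IC50 cutoff for lead designation (inclusive).
#' @return List with `fits` (per compound x line), `ic50_table` (long),
#'   `leads` (a `lead_table`) and `categories` (counts).
#' @export
run_confirmation_screen <- function(responses, lead_cutoff_uM = 1) {
  if (!nrow(responses)) {
    empty <- designate_leads(data.frame(compound_id = character(),
                                        cell_line = character(),
                                        ic50 = character()),
                             cutoff_uM = lead_cutoff_uM)
    return(list(fits = list(), ic50_table = data.frame(),
                leads = empty, categories = categorize_leads(empty)))
  }
  groups <- split(responses,
                  list(responses$compound_id, responses$cell_line),
                  drop = TRUE)
  fits <- lapply(groups, function(g) {
    avg <- average_screens(g)
    fit_4pl(avg$dose_uM, avg$response_pct)
  })
  ic50_table <- do.call(rbind, lapply(names(fits), function(k) {
    g <- groups[[k]]
    data.frame(compound_id = g$compound_id[1L],
               cell_line = g$cell_line[1L],
               ic50 = fits[[k]]$ic50_display,
               status = fits[[k]]$status,
               B = fits[[k]]$B, T = fits[[k]]$T, h = fits[[k]]$h,
               stringsAsFactors = FALSE)
  }))
  leads <- designate_leads(ic50_table[, c("compound_id", "cell_line",
                                          "ic50")],
                           cutoff_uM = lead_cutoff_uM)
  list(fits = fits, ic50_table = ic50_table, leads = leads,
       categories = categorize_leads(leads))
}

#' End-to-end synthetic demonstration
#'
#' Generates a primary screen with the default generator configuration,
#' runs the full primary triage, then simulates a confirmation qHTS for
#' the called hits (4PL truths: potent inhibitors for true hits, inactive
#' curves for any false positives) and runs the lead triage. Fully
#' reproducible from the seed.
#'
#' @param seed integer seed.
#' @param config optional [generator_config()] override (its seed is
#'   replaced by `seed`).
#' @param threshold passed to [run_primary_screen()].
#' @return List with `dataset`, `primary`, `confirmation`.
#' @export
demo_screen <- function(seed = 1L, config = NULL, threshold = "derived") {
  if (is.null(config)) config <- generator_config(seed = seed)
  else config$seed <- as.integer(seed)
  dataset <- simulate_primary_screen(config)
  primary <- run_primary_screen(dataset, threshold = threshold)
  hits <- primary$summary$hit_compounds
  confirmation <- NULL
  if (length(hits)) {
    truth <- dataset$truth
    rows <- truth[truth$compound_id %in% hits, ]
    set.seed(stream_seed(seed, "demo", "confirmation_truth"))
    truths <- data.frame(
      compound_id = rows$compound_id, cell_line = rows$cell_line,
      top = 100,
      bottom = ifelse(rows$is_hit, stats::runif(nrow(rows), 0, 10), 90),
      hill = ifelse(rows$is_hit, stats::runif(nrow(rows), 0.7, 2), 1),
      log10_ic50 = ifelse(rows$is_hit,
                          stats::runif(nrow(rows), log10(0.02), log10(2)),
                          log10(50)),
      stringsAsFactors = FALSE)
    responses <- simulate_confirmation_screen(truths, config)
    confirmation <- run_confirmation_screen(responses)
    confirmation$truths <- truths
  }
  list(dataset = dataset, primary = primary, confirmation = confirmation)
}
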