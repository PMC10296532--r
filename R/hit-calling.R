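#' Percent estrogen-driven inhibition (%E-DI)
#'
#' Compares a compound's normalized viability under estrogen (`beta`) to
#' its normalized viability under vehicle (`alpha`), both from the paired
#' plates of the same library plate and cell line. The default
#' `"inhibition"` form is `100 * (1 - beta/alpha)`: 0 when estrogen-grown
#' cells match vehicle-grown cells, 100 at complete kill under estrogen.
#' The `"as_printed"` form, `100 * beta/alpha`, is the same quantity
#' expressed as relative survival; the two forms sum to 100. Which form
#' was used is recorded in the `"form"` attribute because hit thresholds
#' quoted as "percent inhibition" only make sense on the inhibition
#' scale.
#'
#' @param alpha normalized vehicle-condition viability (> 0).
#' @param beta normalized estrogen-condition viability (>= 0).
#' @param form `"inhibition"` (default) or `"as_printed"` (relative
#'   survival).
#' @return Numeric vector of the same length with attribute `form`.
#' @examples
#' edi(1, 0.25)            # 75 percent inhibition
#' edi(1, 0.25, "as_printed")  # 25 percent relative survival
#' @export
edi <- function(alpha, beta, form = c("inhibition", "as_printed")) {
  form <- match.arg(form)
  if (any(is.na(alpha)) || any(alpha <= 0)) {
    stop("alpha (vehicle viability) must be > 0; compound unevaluable",
         call. = FALSE)
  }
  if (any(beta < 0, na.rm = TRUE)) {
    stop("beta (estrogen viability) must be >= 0", call. = FALSE)
  }
  value <- if (form == "inhibition") 100 * (1 - beta / alpha)
           else 100 * beta / alpha
  attr(value, "form") <- form
  value
}

#' Derive the adaptive hit threshold
#'
#' The screen-wide hit threshold is the mean %E-DI of all analyzed
#' samples plus `multiplier` sample standard deviations. A fixed override
#' (the screening campaign modelled here rounded its derived threshold to
#' 70) can be recorded; reports always show both.
#'
#' @param edi_values %E-DI (inhibition form) of every analyzed sample
#'   (at least 2), pooled over cell lines by default.
#' @param multiplier SD multiple (default 2.5).
#' @param fixed optional fixed override applied instead of the derived
#'   value.
#' @return A `hit_threshold`: list with `mean_edi`, `sd_edi`,
#'   `multiplier`, `derived_threshold`, `applied_threshold`.
#' @export
derive_threshold <- function(edi_values, multiplier = 2.5, fixed = NULL) {
  edi_values <- edi_values[!is.na(edi_values)]
  if (length(edi_values) < 2L) {
    stop("need at least 2 %E-DI values to derive a threshold", call. = FALSE)
  }
  m <- mean(edi_values)
  s <- stats::sd(edi_values)
  derived <- m + multiplier * s
  structure(list(mean_edi = m, sd_edi = s, multiplier = multiplier,
                 derived_threshold = derived,
                 applied_threshold = if (is.null(fixed)) derived else fixed),
            class = "hit_threshold")
}

#' @export
print.hit_threshold <- function(x, ...) {
  cat(sprintf(
    "<hit_threshold> mean %.2f + %.1f x sd %.2f = %.2f; applied %.2f\n",
    x$mean_edi, x$multiplier, x$sd_edi, x$derived_threshold,
    x$applied_threshold))
  invisible(x)
}

#' Call hits
#'
#' A compound is a hit for a cell line when its %E-DI (inhibition form)
#' strictly exceeds the applied threshold; a value exactly at the
#' threshold is not a hit. Only compounds that survived the
#' vehicle-toxicity triage are eligible (the caller passes an already
#' filtered table). Raising the threshold can never add a hit.
#'
#' @param edi_table data.frame with columns `compound_id`, `cell_line`,
#'   `alpha`, `beta`, `edi`.
#' @param threshold a [derive_threshold()] object or a single number.
#' @return The table with logical `is_hit` and numeric `threshold`
#'   columns added.
#' @export
call_hits <- function(edi_table, threshold) {
  thr <- if (inherits(threshold, "hit_threshold")) {
    threshold$applied_threshold
  } else {
    threshold
  }
  stopifnot(is.finite(thr))
  edi_table$threshold <- thr
  edi_table$is_hit <- !is.na(edi_table$edi) & edi_table$edi > thr
  edi_table
}

# Half-away-from-zero rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a primary screen
#'
#' Compound-level accounting of the screen: library size, compounds
#' excluded by the vehicle-toxicity triage, compounds analyzed, hits per
#' cell line and the union hit count. Percentages are recomputed from
#' the counts (removed over library, union hits over analyzed) and
#' rounded half-away-from-zero to one decimal.
#'
#' @param hit_table output of [call_hits()] over all analyzed
#'   (compound, cell line) pairs.
#' @param n_library total library compounds tested.
#' @param excluded_compounds character vector of compound ids excluded by
#'   the toxicity triage (compound level).
#' @return A `screen_summary` list.
#' @export
summarize_screen <- function(hit_table, n_library, excluded_compounds) {
  excluded_compounds <- unique(excluded_compounds)
  n_excl <- length(excluded_compounds)
  n_analyzed <- n_library - n_excl
  hits <- hit_table[hit_table$is_hit, , drop = FALSE]
  hits_per_line <- lapply(split(hits$compound_id, hits$cell_line), unique)
  union_hits <- unique(hits$compound_id)
  structure(list(
    n_library = n_library,
    n_excluded_toxicity = n_excl,
    n_analyzed = n_analyzed,
    hits_per_line = hits_per_line,
    n_hits_per_line = vapply(hits_per_line, length, integer(1)),
    n_hits_total = length(union_hits),
    hit_compounds = union_hits,
    pct_removed = round_half_up(100 * n_excl / n_library, 1),
    pct_analyzed = round_half_up(100 * n_analyzed / n_library, 1),
    pct_hits = round_half_up(100 * length(union_hits) / n_analyzed, 1)),
    class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("<screen_summary> %d library compounds\n", x$n_library))
  cat(sprintf("  vehicle-toxic, removed: %d (%.1f%%)\n",
              x$n_excluded_toxicity, x$pct_removed))
  cat(sprintf("  analyzed: %d (%.1f%%)\n", x$n_analyzed, x$pct_analyzed))
  for (line in names(x$hits_per_line)) {
    cat(sprintf("  hits, line %s: %d\n", line,
                length(x$hits_per_line[[line]])))
  }
  cat(sprintf("  hits (union): %d (%.1f%% of analyzed)\n",
              x$n_hits_total, x$pct_hits))
  invisible(x)
}

#' @rdname summarize_screen
#' @param hit_table the table returned by [call_hits()].
#' @param file output CSV path.
#' @export
write_hit_table <- function(hit_table, file) {
  utils::write.csv(hit_table, file, row.names = FALSE)
  invisible(file)
}
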