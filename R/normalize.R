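#' Remove outlier control wells
#'
#' Single-pass 3-SD rule: the mean and sample SD are computed once over
#' all control wells on the plate, and wells more than `k` SD above or
#' below that mean are removed. The rule is deliberately not iterated; it
#' is one criterion applied once. With zero variance nothing is removed.
#'
#' @param control_counts named numeric vector of vehicle (DMSO) control
#'   counts (at least 3 wells).
#' @param k SD multiple (default 3).
#' @return List with `retained` and `removed` (both named vectors);
#'   their union is always the input.
#' @export
remove_control_outliers <- function(control_counts, k = 3) {
  if (length(control_counts) < 3L) {
    stop("need at least 3 control wells, got ", length(control_counts),
         call. = FALSE)
  }
  m <- mean(control_counts)
  s <- stats::sd(control_counts)
  out <- abs(control_counts - m) > k * s
  list(retained = control_counts[!out], removed = control_counts[out])
}

#' Normalize a plate to its vehicle-control wells
#'
#' Per-plate normalization: image-flagged wells are excluded first, then
#' outlier DMSO wells are removed by the 3-SD rule, then every remaining
#' well count is divided by the mean of the retained DMSO wells. "Vehicle
#' control wells" are the DMSO (compound-solvent) wells; media wells are
#' background checks only and never enter normalization. The rule applies
#' identically to vehicle- and estrogen-condition plates (each plate is
#' normalized to its own DMSO wells).
#'
#' @param raw a [raw_plate()].
#' @param layout the [plate_layout()] the plate was stamped from.
#' @param outlier_k SD multiple for control-outlier removal.
#' @return A `normalized_plate`: list with `plate_id`, `layout_id`,
#'   `cell_line_id`, `condition`, `normalized` (named vector over
#'   retained non-empty wells), `control_summary`
#'   (mean, sd, n_retained, n_removed) and `excluded` (flagged wells).
#' @export
normalize_plate <- function(raw, layout, outlier_k = 3) {
  if (!identical(raw$layout_id, attr(layout, "plate_id"))) {
    stop("plate ", raw$plate_id, " was stamped from layout ", raw$layout_id,
         ", not ", attr(layout, "plate_id"), call. = FALSE)
  }
  flagged <- flagged_wells(raw)
  counts <- raw$counts[setdiff(names(raw$counts), flagged)]
  dmso_wells <- layout$well[layout$role == "vehicle_control"]
  ctrl <- counts[names(counts) %in% dmso_wells]
  if (length(ctrl) < 3L) {
    stop("plate ", raw$plate_id, ": fewer than 3 usable DMSO control wells",
         call. = FALSE)
  }
  o <- remove_control_outliers(ctrl, k = outlier_k)
  if (length(o$retained) < 1L || mean(o$retained) == 0) {
    stop("plate ", raw$plate_id, ": no usable DMSO controls after ",
         "outlier removal", call. = FALSE)
  }
  ctrl_mean <- mean(o$retained)
  keep <- setdiff(names(counts),
                  c(names(o$removed),
                    layout$well[layout$role == "empty"]))
  normalized <- counts[keep] / ctrl_mean
  structure(list(
    plate_id = raw$plate_id, layout_id = raw$layout_id,
    cell_line_id = raw$cell_line_id, condition = raw$condition,
    normalized = normalized,
    control_summary = list(mean = ctrl_mean, sd = stats::sd(o$retained),
                           n_retained = length(o$retained),
                           n_removed = length(o$removed)),
    excluded = flagged), class = "normalized_plate")
}

#' @export
print.normalized_plate <- function(x, ...) {
  cat(sprintf(
    "<normalized_plate %s> %s, line %s; %d wells; DMSO mean %.1f (n=%d, %d outliers)\n",
    x$plate_id, x$condition, x$cell_line_id, length(x$normalized),
    x$control_summary$mean, x$control_summary$n_retained,
    x$control_summary$n_removed))
  invisible(x)
}

#' @rdname normalize_plate
#' @param normalized a `normalized_plate`.
#' @param file output CSV path.
#' @export
write_normalized_plate <- function(normalized, layout, file) {
  i <- match(names(normalized$normalized), layout$well)
  utils::write.csv(data.frame(
    plate_id = normalized$plate_id, condition = normalized$condition,
    well = names(normalized$normalized),
    compound_id = layout$compound_id[i],
    normalized_value = unname(normalized$normalized),
    status = "retained", stringsAsFactors = FALSE),
    file, row.names = FALSE, na = "")
  invisible(file)
}

#' Vehicle-toxicity triage
#'
#' A compound whose normalized viability under the vehicle condition
#' falls below the cutoff (strictly `< 0.5` by default) is toxic
#' regardless of estrogen and is excluded; exactly 0.5 is retained. The
#' decision is per compound per cell line; with replicate vehicle wells
#' the mean is used. Compounds with no vehicle measurement cannot be
#' judged and are reported separately as unevaluable.
#'
#' @param vehicle_viability data.frame with columns `compound_id`,
#'   `cell_line`, `viability` (normalized vehicle-condition value; `NA`
#'   for missing).
#' @param cutoff viability cutoff (strict `<`).
#' @return List of data.frames `retained`, `excluded`, `unevaluable`;
#'   their row counts always sum to the input's.
#' @export
vehicle_toxicity_filter <- function(vehicle_viability, cutoff = 0.5) {
  stopifnot(all(c("compound_id", "cell_line", "viability") %in%
                names(vehicle_viability)))
  agg <- stats::aggregate(viability ~ compound_id + cell_line,
                          data = vehicle_viability, FUN = mean,
                          na.action = stats::na.pass)
  # aggregate drops NA groups under the formula interface unless na.pass
  una <- is.na(agg$viability)
  tox <- !una & agg$viability < cutoff
  list(retained = agg[!una & !tox, , drop = FALSE],
       excluded = agg[tox, , drop = FALSE],
       unevaluable = agg[una, , drop = FALSE])
}
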