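#' Z-prime factor
#'
#' Plate-quality statistic for an inhibition assay,
#' Z' = 1 - 3(sd_n + sd_p) / (mean_n - mean_p), where the negative
#' control is the MAX signal (uninhibited growth, here the DMSO wells)
#' and the positive control is the MIN signal (a QC inhibitor). Classes:
#' 1 ideal; [0.5, 1) excellent; [0, 0.5) marginal (but acceptable);
#' below 0 unacceptable.
#'
#' Sample (n-1) standard deviations are used throughout; control groups
#' are small (4--8 wells).
#'
#' @param negative,positive numeric vectors of control-well signals
#'   (at least 2 each); `negative` must have the larger mean.
#' @return A list with `value` and `class`.
#' @examples
#' zprime(c(100, 100), c(0, 0))     # ideal
#' @export
zprime <- function(negative, positive) {
  if (length(negative) < 2L || length(positive) < 2L) {
    stop("each control group needs at least 2 wells", call. = FALSE)
  }
  zprime_from_stats(mean(negative), stats::sd(negative),
                    mean(positive), stats::sd(positive))
}

#' @rdname zprime
#' @param mu_n,sd_n,mu_p,sd_p control-group means and standard deviations
#'   (negative = MAX signal, positive = MIN signal).
#' @export
zprime_from_stats <- function(mu_n, sd_n, mu_p, sd_p) {
  if (sd_n < 0 || sd_p < 0) stop("standard deviations must be >= 0",
                                 call. = FALSE)
  if (mu_n <= mu_p) {
    stop("controls inverted: negative (MAX) control mean must exceed ",
         "positive (MIN) control mean", call. = FALSE)
  }
  value <- 1 - 3 * (sd_n + sd_p) / (mu_n - mu_p)
  list(value = value, class = zprime_class(value))
}

#' @rdname zprime
#' @param value a Z-prime value.
#' @export
zprime_class <- function(value) {
  ifelse(value == 1, "ideal",
         ifelse(value >= 0.5, "excellent",
                ifelse(value >= 0, "marginal", "unacceptable")))
}

#' Percent coefficient of variation
#'
#' \%CV = 100 sd/mean (sample sd), the replicate-well reproducibility
#' measure; a group passes when \%CV is below the gate (25 by default).
#' \%CV is invariant under positive scaling of the signal but not under
#' shifts.
#'
#' @param values numeric vector of at least 2 measurements with non-zero
#'   mean.
#' @param gate acceptability threshold (strict `<`).
#' @return A list with `value` and `pass`.
#' @export
percent_cv <- function(values, gate = 25) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("%CV undefined: mean is zero", call. = FALSE)
  value <- 100 * stats::sd(values) / m
  list(value = value, pass = value < gate)
}

#' QC-compound acceptance
#'
#' Adjudicates a QC compound from its titration at the screening dose
#' (10 uM) under both conditions. A QC-positive (growth inhibitor) is
#' accepted when it inhibits more than 70\% under estrogen *and* the
#' effect is not estrogen-specific (inhibition under vehicle within
#' `max_condition_gap` percentage points of the estrogen value) -- an
#' estrogen-specific control would itself look like a screen hit. A
#' QC-negative is accepted when inhibition at the screening dose stays at
#' or below `neg_tolerance` in both conditions.
#'
#' @param doses_uM numeric vector of doses.
#' @param inhibition_vehicle,inhibition_estrogen percent inhibition at
#'   each dose (same length as `doses_uM`; replicate means).
#' @param role `"positive"` or `"negative"`.
#' @param screening_dose_uM dose at which acceptance is judged; the
#'   closest available dose within 2-fold is used.
#' @param min_inhibition acceptance bound for positives (strict `>`).
#' @param neg_tolerance maximum inhibition tolerated for negatives.
#' @param max_condition_gap maximum |estrogen - vehicle| inhibition gap
#'   (percentage points) before a positive is rejected as
#'   estrogen-specific.
#' @return List with `accept`, `reasons`, and the inhibition values used.
#' @export
qc_compound_acceptance <- function(doses_uM, inhibition_vehicle,
                                   inhibition_estrogen,
                                   role = c("positive", "negative"),
                                   screening_dose_uM = 10,
                                   min_inhibition = 70,
                                   neg_tolerance = 10,
                                   max_condition_gap = 25) {
  role <- match.arg(role)
  stopifnot(length(doses_uM) == length(inhibition_vehicle),
            length(doses_uM) == length(inhibition_estrogen))
  rel <- abs(log(doses_uM / screening_dose_uM))
  i <- which.min(rel)
  if (!length(i) || rel[i] > log(2)) {
    stop("no dose near the screening dose (", screening_dose_uM,
         " uM) in the titration", call. = FALSE)
  }
  inh_v <- inhibition_vehicle[i]
  inh_e <- inhibition_estrogen[i]
  reasons <- character()
  if (role == "positive") {
    if (inh_e <= min_inhibition) {
      reasons <- c(reasons, sprintf(
        "inhibition %.1f%% under estrogen at %g uM does not exceed %g%%",
        inh_e, doses_uM[i], min_inhibition))
    }
    if (abs(inh_e - inh_v) > max_condition_gap) {
      reasons <- c(reasons, sprintf(
        "estrogen-specific response: inhibition %.1f%% (estrogen) vs %.1f%% (vehicle)",
        inh_e, inh_v))
    }
  } else {
    if (inh_e > neg_tolerance || inh_v > neg_tolerance) {
      reasons <- c(reasons, sprintf(
        "inhibition at %g uM (%.1f%% vehicle, %.1f%% estrogen) exceeds the %g%% tolerance",
        doses_uM[i], inh_v, inh_e, neg_tolerance))
    }
  }
  list(accept = length(reasons) == 0L, reasons = reasons,
       dose_uM = doses_uM[i], inhibition_vehicle = inh_v,
       inhibition_estrogen = inh_e)
}

#' Assay-quality report for a screen
#'
#' For every plate and condition: one Z-prime per (DMSO vs QC-positive
#' compound) pairing -- DMSO wells are the negative/MAX group -- and one
#' \%CV per control group (DMSO and each QC compound). Image-flagged
#' wells are excluded before anything is computed.
#'
#' @param dataset a [screen_dataset()].
#' @param zprime_gate minimum acceptable Z-prime.
#' @param cv_gate maximum acceptable \%CV (strict `<`).
#' @return A `data.frame` with columns `plate_id`, `condition`,
#'   `cell_line`, `group`, `metric`, `value`, `class`, `pass`, plus an
#'   overall `attr(, "all_pass")`.
#' @export
qc_report <- function(dataset, zprime_gate = 0.5, cv_gate = 25) {
  rows <- list()
  for (p in dataset$plates) {
    layout <- dataset$layouts[[p$layout_id]]
    counts <- p$counts[setdiff(names(p$counts), flagged_wells(p))]
    grp <- function(role, compound = NULL) {
      w <- layout$well[layout$role == role &
        (is.null(compound) | layout$compound_id %in% compound)]
      counts[names(counts) %in% w]
    }
    dmso <- grp("vehicle_control")
    qc <- unique(layout[layout$role %in% c("qc_positive", "qc_negative"),
                        c("role", "compound_id")])
    for (i in seq_len(nrow(qc))) {
      vals <- grp(qc$role[i], qc$compound_id[i])
      if (qc$role[i] == "qc_positive" && length(dmso) >= 2L &&
          length(vals) >= 2L) {
        z <- zprime(dmso, vals)
        rows[[length(rows) + 1L]] <- data.frame(
          plate_id = p$plate_id, condition = p$condition,
          cell_line = p$cell_line_id,
          group = paste0("DMSO_vs_", qc$compound_id[i]),
          metric = "zprime", value = z$value, class = z$class,
          pass = z$value >= zprime_gate, stringsAsFactors = FALSE)
      }
      if (length(vals) >= 2L && mean(vals) != 0) {
        cv <- percent_cv(vals, gate = cv_gate)
        rows[[length(rows) + 1L]] <- data.frame(
          plate_id = p$plate_id, condition = p$condition,
          cell_line = p$cell_line_id, group = qc$compound_id[i],
          metric = "pcv", value = cv$value,
          class = if (qc$role[i] == "qc_positive") "qc_positive" else "qc_negative",
          pass = cv$pass, stringsAsFactors = FALSE)
      }
    }
    if (length(dmso) >= 2L) {
      cv <- percent_cv(dmso, gate = cv_gate)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = p$plate_id, condition = p$condition,
        cell_line = p$cell_line_id, group = "DMSO", metric = "pcv",
        value = cv$value, class = "qc_negative", pass = cv$pass,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "all_pass") <- all(out$pass)
  out
}
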