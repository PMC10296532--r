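#' Four-parameter logistic (Hill) dose-response model
#'
#' Percent survival at dose `c`:
#' `B + (T - B) / (1 + (c / IC50)^h)` with bottom `B`, top `T`, Hill
#' slope `h > 0` (response decreases with dose for an inhibitor) and the
#' IC50 carried as `log10_ic50` (log10 uM). At `c = IC50` the response is
#' the midpoint `(B + T) / 2`; the asymptotes are `T` as `c -> 0` and `B`
#' as `c -> Inf`.
#'
#' @param c_uM dose vector (uM, > 0).
#' @param B,T_ bottom and top percent survival (`B <= T_`).
#' @param h Hill slope (> 0).
#' @param log10_ic50 log10 of the IC50 in uM.
#' @return Percent survival at each dose.
#' @examples
#' four_pl(0.4, B = 0, T_ = 100, h = 1, log10_ic50 = log10(0.4))  # 50
#' @export
four_pl <- function(c_uM, B, T_, h, log10_ic50) {
  if (any(c_uM <= 0)) stop("dose must be > 0", call. = FALSE)
  B + (T_ - B) / (1 + 10^(h * (log10(c_uM) - log10_ic50)))
}

#' Average the two confirmation screens
#'
#' Screen 2's duplicate wells are averaged per dose first, then the two
#' screens are averaged with equal weight, so both screens count equally
#' despite unequal replication. Both screens must cover the same dose
#' grid.
#'
#' @param responses long data.frame with columns `screen`, `replicate`,
#'   `dose_uM`, `response_pct` (one compound and cell line).
#' @return data.frame `dose_uM`, `response_pct`, doses decreasing.
#' @export
average_screens <- function(responses) {
  stopifnot(all(c("screen", "dose_uM", "response_pct") %in%
                names(responses)))
  per_screen <- stats::aggregate(response_pct ~ screen + dose_uM,
                                 data = responses, FUN = mean)
  grids <- split(per_screen$dose_uM, per_screen$screen)
  ref <- sort(grids[[1L]])
  same <- vapply(grids, function(g) {
    length(g) == length(ref) && isTRUE(all.equal(sort(g), ref))
  }, logical(1))
  if (!all(same)) {
    stop("screens cover different dose grids", call. = FALSE)
  }
  out <- stats::aggregate(response_pct ~ dose_uM, data = per_screen,
                          FUN = mean)
  out[order(-out$dose_uM), , drop = FALSE]
}

# Initial values: T = max response, B = min response, h = 1, log10_ic50
# at the log-dose where the response first crosses the midpoint (linear
# interpolation); falls back to the median log dose if there is no
# crossing.
init_4pl <- function(ld, y) {
  T0 <- max(y); B0 <- min(y)
  mid <- (T0 + B0) / 2
  o <- order(ld)
  ld <- ld[o]; y <- y[o]
  lic <- stats::median(ld)
  below <- y <= mid
  i <- which(below)[1L]  # doses ascending, response decreasing
  if (!is.na(i) && i > 1L && y[i - 1L] != y[i]) {
    lic <- ld[i - 1L] + (y[i - 1L] - mid) / (y[i - 1L] - y[i]) *
      (ld[i] - ld[i - 1L])
  } else if (!is.na(i)) {
    lic <- ld[i]
  }
  c(B = B0, T_ = T0, h = 1, log10_ic50 = unname(lic))
}

#' Fit the 4PL model to a dose series
#'
#' Bounded Levenberg-Marquardt least squares
#' (0 <= B, T <= 150 percent; 0.2 <= h <= 5; log10 IC50 in [-4, 3] log10
#' uM), started from data-driven initial values with up to three
#' perturbed restarts on failure. The fit is adjudicated by
#' [adjudicate_ic50()]: flat series or failed/uninformative fits are ND,
#' series that never reach 50 percent inhibition are reported as
#' `>` the top dose, and an IC50 below the lowest dose is flagged
#' `extrapolated_low` but still reported numerically.
#'
#' @param doses_uM dose vector (uM); at least 4 informative points.
#' @param response_pct percent survival at each dose (replicate-averaged;
#'   see [average_screens()]).
#' @return A `dose_response_fit`: list with `B`, `T`, `h`, `log10_ic50`,
#'   `ic50`, `rss`, `se_log10_ic50`, `converged`, `status`,
#'   `ic50_display`, `doses_uM`, `response_pct`.
#' @export
fit_4pl <- function(doses_uM, response_pct) {
  stopifnot(length(doses_uM) == length(response_pct))
  if (length(doses_uM) < 4L) {
    stop("need at least 4 dose points to fit a 4PL", call. = FALSE)
  }
  if (any(response_pct < 0)) stop("responses must be >= 0", call. = FALSE)
  fit <- structure(list(B = NA_real_, T = NA_real_, h = NA_real_,
                        log10_ic50 = NA_real_, ic50 = NA_real_,
                        rss = NA_real_, se_log10_ic50 = NA_real_,
                        converged = FALSE, status = "nd",
                        reason = NULL, ic50_display = "ND",
                        doses_uM = doses_uM, response_pct = response_pct),
                   class = "dose_response_fit")
  if (stats::sd(response_pct) == 0) {
    fit$reason <- "no dose dependence"
    return(adjudicate_ic50(fit))
  }
  ld <- log10(doses_uM)
  y <- response_pct
  start <- init_4pl(ld, y)
  lower <- c(B = 0, T_ = 0, h = 0.2, log10_ic50 = -4)
  upper <- c(B = 150, T_ = 150, h = 5, log10_ic50 = 3)
  clamp <- function(s) pmin(pmax(s, lower), upper)
  starts <- list(clamp(start))
  for (j in 1:3) {  # deterministic perturbed restarts
    s <- start * c(1, 1, c(0.5, 2, 1.5)[j], 1)
    s["log10_ic50"] <- start["log10_ic50"] + c(-0.5, 0.5, 0)[j]
    starts[[j + 1L]] <- clamp(s)
  }
  resid_fn <- function(p) {
    y - (p["B"] + (p["T_"] - p["B"]) /
           (1 + 10^(p["h"] * (ld - p["log10_ic50"]))))
  }
  best <- NULL
  for (s in starts) {
    m <- tryCatch(
      minpack.lm::nls.lm(
        par = s, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(m) && m$info %in% 1:4) {
      rss <- m$deviance
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(m = m, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    fit$reason <- "nonlinear least squares did not converge"
    return(adjudicate_ic50(fit))
  }
  cf <- stats::coef(best$m)
  # SE of log10 IC50 from the Jacobian at the solution:
  # cov = rss/(n - p) * (J'J)^-1; NA when J'J is (near-)singular
  se <- tryCatch({
    dof <- length(y) - length(cf)
    if (dof < 1L) NA_real_ else {
      covm <- solve(best$m$hessian) * best$rss / dof
      sqrt(covm["log10_ic50", "log10_ic50"])
    }
  }, error = function(e) NA_real_)
  fit$B <- unname(cf["B"]); fit$T <- unname(cf["T_"])
  fit$h <- unname(cf["h"]); fit$log10_ic50 <- unname(cf["log10_ic50"])
  fit$ic50 <- 10^fit$log10_ic50
  fit$rss <- best$rss
  fit$se_log10_ic50 <- unname(se)
  fit$converged <- TRUE
  if (fit$B > fit$T) fit$converged <- FALSE  # inverted curve
  adjudicate_ic50(fit)
}

#' Adjudicate an IC50 from a completed fit attempt
#'
#' Decision rules (in order): series that never vary are ND ("no dose
#' dependence"); if the maximum observed inhibition (100 minus the lowest
#' response) is under 50 percent, the IC50 is beyond the tested range and
#' is displayed as `">{top dose}"`; a fit that did not converge, spans
#' fewer than 25 percentage points top-to-bottom, or carries a log10-IC50
#' standard error above 1 log10 unit (a ten-fold uncertainty -- the SE on
#' the log scale is the relative uncertainty of the IC50) is ND; an IC50
#' below the lowest tested dose is reported numerically but flagged
#' `extrapolated_low`; anything else is `converged` with a numeric IC50.
#'
#' @param fit a `dose_response_fit` (normally called via [fit_4pl()]).
#' @param min_span minimum top-to-bottom span (percent points).
#' @param max_se_log10 maximum admissible SE of log10 IC50.
#' @param min_max_inhibition minimum observed inhibition (percent) for an
#'   in-range IC50.
#' @return The fit with `status` and `ic50_display` set.
#' @export
adjudicate_ic50 <- function(fit, min_span = 25, max_se_log10 = 1,
                            min_max_inhibition = 50) {
  doses <- fit$doses_uM
  y <- fit$response_pct
  if (stats::sd(y) == 0) {
    fit$status <- "nd"
    fit$reason <- fit$reason %||% "no dose dependence"
    fit$ic50_display <- "ND"
    return(fit)
  }
  max_inh <- 100 - min(y)
  if (max_inh < min_max_inhibition) {
    fit$status <- "above_range"
    fit$ic50_display <- paste0(">", format(max(doses)))
    return(fit)
  }
  nd_reason <- NULL
  if (!fit$converged) {
    nd_reason <- fit$reason %||% "fit did not converge"
  } else if ((fit$T - fit$B) < min_span) {
    nd_reason <- sprintf("fitted span %.1f below %g points",
                         fit$T - fit$B, min_span)
  } else if (is.finite(fit$se_log10_ic50) &&
             fit$se_log10_ic50 > max_se_log10) {
    nd_reason <- sprintf("log10 IC50 SE %.2f above %g",
                         fit$se_log10_ic50, max_se_log10)
  }
  if (!is.null(nd_reason)) {
    fit$status <- "nd"
    fit$reason <- nd_reason
    fit$ic50_display <- "ND"
    return(fit)
  }
  if (fit$ic50 < min(doses)) {
    fit$status <- "extrapolated_low"
  } else {
    fit$status <- "converged"
  }
  fit$ic50_display <- format(signif(fit$ic50, 3))
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> status %s, IC50 %s uM (B=%.1f T=%.1f h=%.2f)\n",
    x$status, x$ic50_display, x$B, x$T, x$h))
  invisible(x)
}

# "ND" and ">x" tokens never yield a numeric IC50.
parse_ic50_token <- function(x) {
  x <- trimws(as.character(x))
  ifelse(toupper(x) == "ND" | startsWith(x, ">"), NA_real_,
         suppressWarnings(as.numeric(x)))
}

#' Designate lead compounds
#'
#' A compound is a lead for a cell line when its IC50 outcome there is
#' numeric and at most `cutoff_uM` (1 uM by default); `ND` and `">x"`
#' outcomes are never leads, whatever the number after `>`. A compound is
#' an overall lead when it is a lead in at least one line, and each
#' compound falls in exactly one category: first-line-only,
#' second-line-only, both, or neither.
#'
#' @param ic50_table data.frame with columns `compound_id`, `cell_line`,
#'   `ic50` (numeric, or string tokens including `"ND"` / `">10"`).
#' @param cutoff_uM lead cutoff (inclusive).
#' @return A `lead_table` data.frame, one row per compound: per-line
#'   `ic50_<line>` display columns, per-line `lead_<line>` flags, `lead`
#'   (overall) and `category`.
#' @export
designate_leads <- function(ic50_table, cutoff_uM = 1) {
  stopifnot(all(c("compound_id", "cell_line", "ic50") %in%
                names(ic50_table)))
  lines <- sort(unique(as.character(ic50_table$cell_line)))
  compounds <- unique(ic50_table$compound_id)
  num <- parse_ic50_token(ic50_table$ic50)
  out <- data.frame(compound_id = compounds, stringsAsFactors = FALSE)
  lead_mat <- matrix(FALSE, nrow = length(compounds), ncol = length(lines),
                     dimnames = list(compounds, lines))
  for (ln in lines) {
    sel <- ic50_table$cell_line == ln
    i <- match(compounds, ic50_table$compound_id[sel])
    disp <- as.character(ic50_table$ic50[sel])[i]
    v <- num[sel][i]
    lead_mat[, ln] <- !is.na(v) & v <= cutoff_uM
    out[[paste0("ic50_", ln)]] <- disp
    out[[paste0("lead_", ln)]] <- lead_mat[, ln]
  }
  out$lead <- rowSums(lead_mat) > 0
  if (length(lines) == 2L) {
    out$category <- ifelse(lead_mat[, 1L] & lead_mat[, 2L], "both",
                    ifelse(lead_mat[, 1L], paste0(lines[1L], "_only"),
                    ifelse(lead_mat[, 2L], paste0(lines[2L], "_only"),
                           "neither")))
  } else {
    out$category <- ifelse(out$lead, "lead", "neither")
  }
  attr(out, "cell_lines") <- lines
  attr(out, "cutoff_uM") <- cutoff_uM
  class(out) <- c("lead_table", "data.frame")
  out
}

#' @rdname designate_leads
#' @param lead_table output of `designate_leads()`.
#' @return `categorize_leads()` returns a named list of category counts
#'   (`<lineA>_only`, `<lineB>_only`, `both`, `neither`, plus `n_leads`);
#'   the categories partition the table.
#' @export
categorize_leads <- function(lead_table) {
  lines <- attr(lead_table, "cell_lines")
  cats <- if (length(lines) == 2L) {
    c(paste0(lines[1L], "_only"), paste0(lines[2L], "_only"),
      "both", "neither")
  } else {
    c("lead", "neither")
  }
  counts <- lapply(cats, function(k) sum(lead_table$category == k))
  names(counts) <- cats
  counts$n_leads <- sum(lead_table$lead)
  counts
}

#' Read a per-line IC50 outcome table
#'
#' Wide CSV with a `compound_id` column and one `ic50_<cell line>` column
#' per line (entries numeric or the `ND` / `>x` tokens), as written for
#' the bundled reference confirmation-screen outcomes in
#' `system.file("extdata", "confirmation_ic50.csv", package = "estroscreen")`.
#'
#' @param file path to the CSV.
#' @return Long data.frame `compound_id`, `cell_line`, `ic50` ready for
#'   [designate_leads()].
#' @export
read_ic50_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        check.names = FALSE)
  ic <- grep("^ic50_", names(df), value = TRUE)
  if (!length(ic)) stop("no ic50_<cell_line> columns in ", file,
                        call. = FALSE)
  long <- do.call(rbind, lapply(ic, function(col) {
    data.frame(compound_id = df$compound_id,
               cell_line = sub("^ic50_", "", col),
               ic50 = as.character(df[[col]]), stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
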