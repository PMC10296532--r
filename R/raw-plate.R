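#' Raw plates and screen datasets
#'
#' A `raw_plate` holds the per-well nuclei counts of one physical plate:
#' one library layout, one cell line, one condition (the whole plate is
#' either vehicle, 0.3\% DMSO, or estrogen, 10 uM estradiol-17beta,
#' because the medium is replaced plate-wide before compounds are added).
#' Image-QC flags (`acquisition_error`, `artefact`, `low_control`, or any
#' new token) mark wells that must never be used downstream.
#'
#' @param plate_id physical plate identifier (unique per layout x line x
#'   condition).
#' @param layout_id id of the [plate_layout()] this plate was stamped from.
#' @param cell_line_id cell line identifier (e.g. `"1455"`, `"1458"`).
#' @param condition `"vehicle"` or `"estrogen"`.
#' @param counts named numeric vector of non-negative well counts, names
#'   are canonical well addresses.
#' @param flags named list mapping well addresses to character vectors of
#'   flag tokens; unlisted wells are unflagged.
#' @return A `raw_plate` object (list).
#' @export
raw_plate <- function(plate_id, layout_id, cell_line_id, condition, counts,
                      flags = list()) {
  condition <- match.arg(condition, c("vehicle", "estrogen"))
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by well address", call. = FALSE)
  }
  names(counts) <- parse_well_address(names(counts))$well
  if (any(counts < 0)) {
    stop("negative well count on plate ", plate_id, call. = FALSE)
  }
  if (length(flags)) names(flags) <- parse_well_address(names(flags))$well
  structure(list(plate_id = plate_id, layout_id = layout_id,
                 cell_line_id = as.character(cell_line_id),
                 condition = condition, counts = counts, flags = flags),
            class = "raw_plate")
}

#' @export
print.raw_plate <- function(x, ...) {
  cat(sprintf("<raw_plate %s> layout %s, line %s, %s; %d wells, %d flagged\n",
              x$plate_id, x$layout_id, x$cell_line_id, x$condition,
              length(x$counts), length(x$flags)))
  invisible(x)
}

flagged_wells <- function(plate) names(plate$flags)

#' Read or write a per-well count table CSV
#'
#' Long-format interchange for high-content imaging output: header columns
#' `plate_id, layout_id, cell_line, condition, well, count, flags`; flags
#' are a semicolon-separated set (empty for clean wells). One `raw_plate`
#' is built per `(plate_id, cell_line, condition)` group.
#'
#' @param file path to a counts CSV.
#' @return `read_count_table()` returns a list of [raw_plate()] objects.
#' @export
read_count_table <- function(file) {
  if (!file.exists(file)) stop("counts file not found: ", file, call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(well = "character"))
  need <- c("plate_id", "cell_line", "condition", "well", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("counts file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"layout_id" %in% names(df)) df$layout_id <- df$plate_id
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  bad_cond <- !df$condition %in% c("vehicle", "estrogen")
  if (any(bad_cond)) {
    stop("unknown condition token at row ", which(bad_cond)[1L], ": ",
         df$condition[which(bad_cond)[1L]], call. = FALSE)
  }
  if (any(is.na(df$count) | df$count < 0)) {
    stop("negative or missing count at row ",
         which(is.na(df$count) | df$count < 0)[1L], call. = FALSE)
  }
  df$well <- parse_well_address(df$well)$well
  key <- paste(df$plate_id, df$cell_line, df$condition, sep = "\r")
  dup <- duplicated(paste(key, df$well, sep = "\r"))
  if (any(dup)) {
    stop("well ", df$well[which(dup)[1L]], " repeated within plate at row ",
         which(dup)[1L], call. = FALSE)
  }
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    counts <- stats::setNames(g$count, g$well)
    fl <- g$flags != ""
    flags <- stats::setNames(
      lapply(strsplit(g$flags[fl], ";", fixed = TRUE), trimws), g$well[fl])
    raw_plate(g$plate_id[1L], g$layout_id[1L], g$cell_line[1L],
              g$condition[1L], counts, flags)
  })
}

#' @rdname read_count_table
#' @param plates a list of [raw_plate()] objects.
#' @export
write_count_table <- function(plates, file) {
  rows <- lapply(plates, function(p) {
    fl <- vapply(names(p$counts), function(w) {
      if (w %in% names(p$flags)) paste(p$flags[[w]], collapse = ";") else ""
    }, character(1))
    data.frame(plate_id = p$plate_id, layout_id = p$layout_id,
               cell_line = p$cell_line_id, condition = p$condition,
               well = names(p$counts), count = unname(p$counts),
               flags = unname(fl), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Assemble a screen dataset
#'
#' Bundles layouts, plates and the vehicle/estrogen pairing of a primary
#' screen. Each pairing joins the two condition plates of one library
#' plate on one cell line; both must share the layout and differ in
#' condition.
#'
#' @param layouts named list of [plate_layout()] objects (names =
#'   layout ids).
#' @param plates list of [raw_plate()] objects.
#' @param truth optional generator truth ledger (data.frame), carried for
#'   parameter-recovery checks on synthetic screens.
#' @param config optional generator configuration used to build the data.
#' @return A `screen_dataset`: list with `layouts`, `plates` (named by
#'   plate id), `pairing` (data.frame layout_id, cell_line,
#'   vehicle_plate, estrogen_plate), plus any `truth`/`config`.
#' @export
screen_dataset <- function(layouts, plates, truth = NULL, config = NULL) {
  names(plates) <- vapply(plates, `[[`, character(1), "plate_id")
  key <- data.frame(
    layout_id = vapply(plates, `[[`, character(1), "layout_id"),
    cell_line = vapply(plates, `[[`, character(1), "cell_line_id"),
    condition = vapply(plates, `[[`, character(1), "condition"),
    plate_id = names(plates), stringsAsFactors = FALSE)
  pairs <- unique(key[, c("layout_id", "cell_line")])
  pairing <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sel <- key[key$layout_id == pairs$layout_id[i] &
               key$cell_line == pairs$cell_line[i], ]
    v <- sel$plate_id[sel$condition == "vehicle"]
    e <- sel$plate_id[sel$condition == "estrogen"]
    if (length(v) != 1L || length(e) != 1L) {
      stop("layout ", pairs$layout_id[i], ", line ", pairs$cell_line[i],
           " lacks a unique vehicle/estrogen plate pair", call. = FALSE)
    }
    data.frame(layout_id = pairs$layout_id[i], cell_line = pairs$cell_line[i],
               vehicle_plate = v, estrogen_plate = e,
               stringsAsFactors = FALSE)
  }))
  miss <- setdiff(pairing$layout_id, names(layouts))
  if (length(miss)) {
    stop("plates reference unknown layouts: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(layouts = layouts, plates = plates, pairing = pairing,
                 truth = truth, config = config),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("<screen_dataset> %d layouts, %d plates, %d pairings\n",
              length(x$layouts), length(x$plates), nrow(x$pairing)))
  invisible(x)
}
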