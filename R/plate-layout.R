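#' Plate layouts
#'
#' A plate layout assigns every one of the 384 wells a role: library
#' compound (columns 1--22), vehicle control (DMSO), media control,
#' QC-positive or QC-negative control compound (columns 23--24 only), or
#' empty. Library wells carry a compound id and a positive concentration
#' (10 uM in the screening design modelled here).
#'
#' @param plate_id single string identifying the library plate.
#' @param wells data.frame with columns `well`, `role`, `compound_id`,
#'   `concentration_uM`; wells not listed default to `empty`.
#' @return A `plate_layout`: a data.frame of 384 rows with columns `well`,
#'   `row`, `column`, `role`, `compound_id`, `concentration_uM`, and
#'   attribute `plate_id`.
#' @seealso [read_plate_layout()], [validate_control_layout()],
#'   [make_library_layout()]
#' @export
plate_layout <- function(plate_id, wells) {
  stopifnot(is.character(plate_id), length(plate_id) == 1L)
  need <- c("well", "role", "compound_id", "concentration_uM")
  miss <- setdiff(need, names(wells))
  if (length(miss)) {
    stop("layout is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(wells)) {
    addr <- parse_well_address(wells$well)
    wells$well <- addr$well
    if (anyDuplicated(wells$well)) {
      stop("duplicate well rows in layout: ",
           paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "),
           call. = FALSE)
    }
    bad_role <- setdiff(unique(wells$role), well_roles())
    if (length(bad_role)) {
      stop("unknown role token: ", paste(bad_role, collapse = ", "),
           call. = FALSE)
    }
    ctrl <- wells$role %in% control_roles()
    if (any(ctrl & addr$column < 23L)) {
      off <- wells$well[ctrl & addr$column < 23L]
      stop("control role outside columns 23-24 at well: ",
           paste(off, collapse = ", "), call. = FALSE)
    }
    lib <- wells$role == "library_compound"
    if (any(lib & (is.na(wells$compound_id) | !nzchar(wells$compound_id)))) {
      stop("library_compound well without compound_id", call. = FALSE)
    }
    if (any(lib & (is.na(wells$concentration_uM) |
                   wells$concentration_uM <= 0))) {
      stop("library_compound well without positive concentration",
           call. = FALSE)
    }
  }
  full <- data.frame(well = all_wells(), stringsAsFactors = FALSE)
  full$row <- substr(full$well, 1L, 1L)
  full$column <- well_column(full$well)
  i <- match(full$well, wells$well)
  full$role <- ifelse(is.na(i), "empty", wells$role[i])
  full$compound_id <- ifelse(is.na(i), NA_character_, wells$compound_id[i])
  full$concentration_uM <- ifelse(is.na(i), NA_real_,
                                  wells$concentration_uM[i])
  structure(full, plate_id = plate_id,
            class = c("plate_layout", "data.frame"))
}

#' @rdname plate_layout
#' @export
well_roles <- function() {
  c("library_compound", "vehicle_control", "media_control",
    "qc_positive", "qc_negative", "empty")
}

control_roles <- function() {
  c("vehicle_control", "media_control", "qc_positive", "qc_negative")
}

#' Read or write a plate layout CSV
#'
#' Long-format interchange: one row per non-empty well, header columns
#' `well, role, compound_id, concentration_uM`. Wells absent from the file
#' default to `empty`; a plate-matrix format is deliberately not supported
#' (row/column orientation would be ambiguous).
#'
#' @param file path to a layout CSV.
#' @param plate_id plate identifier; defaults to the file name stem.
#' @return A [plate_layout()].
#' @export
read_plate_layout <- function(file, plate_id = NULL) {
  if (!file.exists(file)) stop("layout file not found: ", file, call. = FALSE)
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(file))
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(well = "character"))
  if (!nrow(df)) {
    df <- data.frame(well = character(), role = character(),
                     compound_id = character(),
                     concentration_uM = numeric())
  }
  if (!"compound_id" %in% names(df)) df$compound_id <- NA_character_
  df$compound_id <- as.character(df$compound_id)
  df$compound_id[!is.na(df$compound_id) & df$compound_id == ""] <-
    NA_character_
  plate_layout(plate_id, df)
}

#' @rdname read_plate_layout
#' @param layout a [plate_layout()].
#' @export
write_plate_layout <- function(layout, file) {
  keep <- layout$role != "empty"
  utils::write.csv(
    layout[keep, c("well", "role", "compound_id", "concentration_uM")],
    file, row.names = FALSE, na = "")
  invisible(file)
}

#' Check the control-well block of a layout
#'
#' The screening design reserves columns 23--24 for controls: 8 DMSO
#' (vehicle) wells, 4 media wells and 4 wells of each QC compound. This is
#' a report-only check; it never errors on a failing layout.
#'
#' @param layout a [plate_layout()].
#' @param n_dmso,n_media,n_per_qc expected control-well counts.
#' @return A list with `pass` (logical), `counts` (role/compound counts in
#'   columns 23--24) and `issues` (character vector, empty when passing).
#' @export
validate_control_layout <- function(layout, n_dmso = 8L, n_media = 4L,
                                    n_per_qc = 4L) {
  ctrl <- layout[layout$column >= 23L, ]
  issues <- character()
  n_d <- sum(ctrl$role == "vehicle_control")
  n_m <- sum(ctrl$role == "media_control")
  if (n_d != n_dmso) {
    issues <- c(issues, sprintf("expected %d DMSO wells, found %d",
                                n_dmso, n_d))
  }
  if (n_m != n_media) {
    issues <- c(issues, sprintf("expected %d media wells, found %d",
                                n_media, n_m))
  }
  qc <- ctrl[ctrl$role %in% c("qc_positive", "qc_negative"), ]
  per_qc <- integer()
  if (nrow(qc)) {
    per_qc <- table(qc$compound_id)
    off <- per_qc[per_qc != n_per_qc]
    for (nm in names(off)) {
      issues <- c(issues, sprintf("expected %d wells of QC compound %s, found %d",
                                  n_per_qc, nm, off[[nm]]))
    }
  } else {
    issues <- c(issues, "no QC compounds declared in columns 23-24")
  }
  misplaced <- layout$role %in% control_roles() & layout$column < 23L
  if (any(misplaced)) {
    issues <- c(issues, paste("control wells outside columns 23-24:",
                              paste(layout$well[misplaced], collapse = ", ")))
  }
  list(pass = length(issues) == 0L,
       counts = list(dmso = n_d, media = n_m,
                     per_qc = as.list(per_qc)),
       issues = issues)
}

#' Build the canonical library-plate layout
#'
#' Library compounds fill columns 1--22 row-major at a single screening
#' concentration; columns 23--24 carry the canonical control block
#' (8 DMSO, 4 media, 4 wells per QC compound). Used by the synthetic
#' generator and available for real screens laid out the same way.
#'
#' @param plate_id plate identifier.
#' @param compound_ids character vector (at most 352) of library compound
#'   ids, filled row-major into columns 1--22; remaining wells are empty.
#' @param qc_positive,qc_negative names of QC compounds dispensed into the
#'   control block (4 wells each; at most 5 compounds in total).
#' @param concentration_uM final screening concentration (uM).
#' @return A [plate_layout()].
#' @export
make_library_layout <- function(plate_id, compound_ids,
                                qc_positive = c("panobinostat", "salinomycin"),
                                qc_negative = "fulvestrant",
                                concentration_uM = 10) {
  n <- length(compound_ids)
  if (n > 352L) {
    stop("a 384-well plate holds at most 352 library compounds (columns 1-22), got ",
         n, call. = FALSE)
  }
  lib_wells <- as.vector(t(outer(LETTERS[1:16], 1:22, paste0)))[seq_len(n)]
  lib <- data.frame(well = lib_wells, role = "library_compound",
                    compound_id = compound_ids,
                    concentration_uM = concentration_uM,
                    stringsAsFactors = FALSE)
  qc_ids <- c(qc_positive, qc_negative)
  qc_role <- rep(c("qc_positive", "qc_negative"),
                 c(length(qc_positive), length(qc_negative)))
  if (length(qc_ids) > 5L) {
    stop("control block fits at most 5 QC compounds (4 wells each)",
         call. = FALSE)
  }
  ctrl_wells <- c(paste0(LETTERS[1:16], 23), paste0(LETTERS[1:16], 24))
  ctrl <- data.frame(
    well = ctrl_wells[seq_len(12L + 4L * length(qc_ids))],
    role = c(rep("vehicle_control", 8L), rep("media_control", 4L),
             rep(qc_role, each = 4L)),
    compound_id = c(rep(NA_character_, 12L), rep(qc_ids, each = 4L)),
    concentration_uM = c(rep(NA_real_, 12L),
                         rep(concentration_uM, 4L * length(qc_ids))),
    stringsAsFactors = FALSE)
  plate_layout(plate_id, rbind(lib, ctrl))
}
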