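#' Well addressing on a 384-well plate
#'
#' 384-well plates are addressed by a row letter A--P and a 1-based column
#' number 1--24, printed as `"A1"`..`"P24"` (plate-vendor convention; no
#' 0-based indices appear anywhere in this package).
#'
#' @param x character vector of well addresses, e.g. `"A1"`, `"P24"`.
#' @return `parse_well_address()` returns a data.frame with columns
#'   `well` (canonical string), `row` (letter) and `column` (integer).
#' @examples
#' parse_well_address(c("A1", "p24"))
#' @export
parse_well_address <- function(x) {
  if (length(x) == 0L || any(is.na(x)) || any(!nzchar(x))) {
    stop("well address must be a non-empty string", call. = FALSE)
  }
  x <- toupper(trimws(x))
  m <- regexec("^([A-Z])([0-9]{1,2})$", x)
  parts <- regmatches(x, m)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well address: ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(parts, `[`, character(1), 2L)
  col <- as.integer(vapply(parts, `[`, character(1), 3L))
  if (any(!row %in% LETTERS[1:16])) {
    off <- x[!row %in% LETTERS[1:16]]
    stop("row out of range (A-P) in well address: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  if (any(col < 1L | col > 24L)) {
    off <- x[col < 1L | col > 24L]
    stop("column out of range (1-24) in well address: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  data.frame(well = paste0(row, col), row = row, column = col,
             stringsAsFactors = FALSE)
}

#' @rdname parse_well_address
#' @param row,column vectors of row letters and column numbers.
#' @return `format_well_address()` returns the canonical `"A1"` strings.
#' @export
format_well_address <- function(row, column) {
  paste0(toupper(row), as.integer(column))
}

#' @rdname parse_well_address
#' @return `all_wells()` returns the 384 canonical addresses in row-major
#'   order (A1, A2, ..., P24).
#' @export
all_wells <- function() {
  as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
}

#' @rdname parse_well_address
#' @return `well_column()` returns the integer column of each address.
#' @export
well_column <- function(x) {
  parse_well_address(x)$column
}
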