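#' Well positions on a 96-well microplate
#'
#' Helpers mapping between well labels ("A1".."H12"), row/column indices and
#' the instrument reading order. The Luminex reader acquires wells row-major:
#' A1..A12, then B1..B12, down to H12, so the reading index also encodes how
#' long a well sat on the plate before acquisition.
#'
#' @param well character vector of well labels such as "A1", "B07", "h12".
#'   Zero-padded columns and lower-case rows are accepted; the normalized
#'   form is unpadded upper case.
#' @return `normalize_well()` returns normalized labels; `reading_index()`
#'   returns the 0-based row-major acquisition index (A1 = 0, A12 = 11,
#'   B1 = 12, ..., H12 = 95); `well_row()`/`well_col()` return the row letter
#'   and column number.
#' @examples
#' normalize_well(c("a01", "H12"))
#' reading_index(c("A1", "B1", "H12"))
#' @export
normalize_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-H])0*([1-9][0-9]?)$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well label(s): ", paste(unique(well[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col > 12L)) {
    stop("well column out of range 1-12: ",
         paste(unique(well[col > 12L]), collapse = ", "), call. = FALSE)
  }
  paste0(row, col)
}

#' @rdname normalize_well
#' @export
well_row <- function(well) substr(normalize_well(well), 1L, 1L)

#' @rdname normalize_well
#' @export
well_col <- function(well) {
  w <- normalize_well(well)
  as.integer(substring(w, 2L))
}

#' @rdname normalize_well
#' @export
reading_index <- function(well) {
  w <- normalize_well(well)
  row <- match(substr(w, 1L, 1L), LETTERS[1:8]) - 1L
  col <- as.integer(substring(w, 2L))
  12L * row + (col - 1L)
}

#' All 96 well labels in reading (row-major) order
#' @return character vector of length 96, "A1" ... "H12".
#' @export
well_labels <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}
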