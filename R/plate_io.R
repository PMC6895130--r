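#' Plate export dialect description
#'
#' The reader supports a minimal two-block delimited export: a line
#' `DataType: Median` followed by a header row `Location,Sample,<epitopes...>`
#' and one row per well, then the same layout under `DataType: Count` for the
#' per-well bead counts. A one-block-per-file mode is selected by pointing
#' `count_path` at a second file when calling [read_plate_export()].
#'
#' @param delimiter field separator, default ",".
#' @param median_header,count_header literal lines opening each block.
#' @param decimal_mark,grouping_mark numeric locale: `grouping_mark` (for
#'   exports written with thousands separators, e.g. "1,204" with
#'   `grouping_mark = ","` and `delimiter = ";"`) is stripped before parsing.
#' @param nsb_label reserved sample label marking buffer-only
#'   (non-specific-binding) wells.
#' @return a `bbea_format` list used by the IO functions.
#' @export
plate_format <- function(delimiter = ",",
                         median_header = "DataType: Median",
                         count_header = "DataType: Count",
                         decimal_mark = ".",
                         grouping_mark = "",
                         nsb_label = "NSB") {
  structure(list(delimiter = delimiter, median_header = median_header,
                 count_header = count_header, decimal_mark = decimal_mark,
                 grouping_mark = grouping_mark, nsb_label = nsb_label),
            class = "bbea_format")
}

parse_locale_number <- function(x, format) {
  x <- trimws(x)
  x[x %in% c("", "NA", "NaN")] <- NA_character_
  if (nzchar(format$grouping_mark)) {
    x <- gsub(format$grouping_mark, "", x, fixed = TRUE)
  }
  if (!identical(format$decimal_mark, ".")) {
    x <- gsub(format$decimal_mark, ".", x, fixed = TRUE)
  }
  suppressWarnings(out <- as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("non-numeric value(s) in export: ",
         paste(utils::head(unique(x[bad]), 5L), collapse = ", "), call. = FALSE)
  }
  out
}

split_fields <- function(lines, delim) strsplit(lines, delim, fixed = TRUE)

# Parse one block (header row + well rows) into a list(sample=, values=matrix)
parse_block <- function(lines, format, what, path) {
  if (length(lines) < 2L) {
    stop("block '", what, "' in ", path, " has no data rows", call. = FALSE)
  }
  rows <- split_fields(lines, format$delimiter)
  header <- trimws(rows[[1L]])
  if (length(header) < 3L || toupper(header[1L]) != "LOCATION") {
    stop("block '", what, "' in ", path,
         ": expected header 'Location,Sample,<epitopes...>'", call. = FALSE)
  }
  analytes <- header[-(1:2)]
  wells <- character(0); samples <- character(0)
  vals <- matrix(NA_real_, nrow = length(rows) - 1L, ncol = length(analytes),
                 dimnames = list(NULL, analytes))
  for (i in seq_along(rows)[-1L]) {
    r <- trimws(rows[[i]])
    if (length(r) != length(header)) {
      stop("line ", i, " of block '", what, "' in ", path,
           ": expected ", length(header), " fields, found ", length(r),
           call. = FALSE)
    }
    lab <- tryCatch(normalize_well(r[1L]), error = function(e) {
      stop("block '", what, "' in ", path, ", data row ", i - 1L, ": ",
           conditionMessage(e), call. = FALSE)
    })
    wells <- c(wells, lab)
    samples <- c(samples, r[2L])
    vals[i - 1L, ] <- parse_locale_number(r[-(1:2)], format)
  }
  dup <- wells[duplicated(wells)]
  if (length(dup)) {
    stop("duplicate well(s) in block '", what, "' of ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  rownames(vals) <- wells
  list(wells = wells, samples = stats::setNames(samples, wells), values = vals)
}

map_regions <- function(analytes, library, warn = TRUE) {
  if (is.null(library)) return(analytes)
  numeric_like <- grepl("^[0-9]+$", analytes)
  out <- analytes
  if (any(numeric_like)) {
    idx <- match(as.integer(analytes[numeric_like]), library$bead_region)
    unmapped <- analytes[numeric_like][is.na(idx)]
    if (length(unmapped) && warn) {
      warning("bead region(s) not in epitope library, kept under numeric name: ",
              paste(unmapped, collapse = ", "), call. = FALSE)
    }
    out[numeric_like][!is.na(idx)] <- library$epitope_id[idx[!is.na(idx)]]
  } else {
    known <- analytes %in% library$epitope_id
    if (!all(known)) {
      stop("epitope column(s) absent from the library: ",
           paste(analytes[!known], collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Read a plate export into per-well readings
#'
#' Parses an instrument export holding a median-fluorescence block and a
#' bead-count block (see [plate_format()]). Wells present in only one block
#' are kept with NA in the other and reported in the `missing` attribute
#' rather than silently dropped.
#'
#' @param path export file (two-block dialect), or the Median-block file when
#'   `count_path` is given.
#' @param plate_id plate identifier; defaults to the file name without
#'   extension.
#' @param library optional epitope library from [read_epitope_library()];
#'   numeric bead-region column names are mapped to epitope ids through it.
#' @param format a [plate_format()].
#' @param count_path optional separate Count-block file (one-block-per-file
#'   mode).
#' @return a `bbea_plate`: list with `plate_id`, `wells` (data.frame of well,
#'   sample, reading_index), numeric matrices `mfi` and `counts`
#'   (wells x epitopes), and a `missing` data.frame naming wells absent from
#'   either block.
#' @export
read_plate_export <- function(path, plate_id = NULL, library = NULL,
                              format = plate_format(), count_path = NULL) {
  if (is.null(plate_id)) {
    plate_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(count_path)) {
    m_at <- which(trimws(lines) == format$median_header)
    c_at <- which(trimws(lines) == format$count_header)
    if (length(m_at) != 1L || length(c_at) != 1L) {
      stop("expected exactly one '", format$median_header, "' and one '",
           format$count_header, "' block in ", path, call. = FALSE)
    }
    bounds <- sort(c(m_at, c_at, length(lines) + 1L))
    take <- function(at) {
      end <- bounds[which(bounds == at) + 1L] - 1L
      lines[(at + 1L):end]
    }
    med <- parse_block(take(m_at), format, "Median", path)
    cnt <- parse_block(take(c_at), format, "Count", path)
  } else {
    strip_title <- function(ls, title) {
      if (length(ls) && trimws(ls[1L]) == title) ls[-1L] else ls
    }
    cl <- readLines(count_path, warn = FALSE)
    cl <- cl[nzchar(trimws(cl))]
    med <- parse_block(strip_title(lines, format$median_header),
                       format, "Median", path)
    cnt <- parse_block(strip_title(cl, format$count_header),
                       format, "Count", count_path)
  }
  colnames(med$values) <- map_regions(colnames(med$values), library)
  colnames(cnt$values) <- map_regions(colnames(cnt$values), library,
                                      warn = FALSE)
  if (!setequal(colnames(med$values), colnames(cnt$values))) {
    stop("Median and Count blocks report different analytes", call. = FALSE)
  }
  cnt$values <- cnt$values[, colnames(med$values), drop = FALSE]

  wells <- union(med$wells, cnt$wells)
  wells <- wells[order(reading_index(wells))]
  missing <- data.frame(
    well = c(setdiff(wells, med$wells), setdiff(wells, cnt$wells)),
    absent_from = c(rep("Median", length(setdiff(wells, med$wells))),
                    rep("Count", length(setdiff(wells, cnt$wells)))),
    stringsAsFactors = FALSE)
  epi <- colnames(med$values)
  mfi <- matrix(NA_real_, length(wells), length(epi),
                dimnames = list(wells, epi))
  counts <- mfi
  mfi[med$wells, ] <- med$values
  counts[cnt$wells, ] <- cnt$values
  if (any(mfi < 0, na.rm = TRUE)) {
    stop("negative MFI in ", path, call. = FALSE)
  }
  samples <- ifelse(wells %in% med$wells, med$samples[wells], cnt$samples[wells])
  structure(list(
    plate_id = plate_id,
    wells = data.frame(well = wells, sample = unname(samples),
                       reading_index = reading_index(wells),
                       stringsAsFactors = FALSE),
    mfi = mfi, counts = counts, missing = missing),
    class = "bbea_plate")
}

#' Write a plate back to the two-block export dialect
#'
#' @param plate a `bbea_plate`.
#' @param path output file.
#' @param format a [plate_format()].
#' @return `path`, invisibly.
#' @export
write_plate_export <- function(plate, path, format = plate_format()) {
  d <- format$delimiter
  hdr <- paste(c("Location", "Sample", colnames(plate$mfi)), collapse = d)
  fmt_num <- function(x) {
    out <- formatC(x, format = "fg", digits = 15)
    out[is.na(x)] <- "NA"
    trimws(out)
  }
  block <- function(title, m) {
    rows <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(plate$wells$well[i], plate$wells$sample[i], fmt_num(m[i, ])),
            collapse = d)
    }, "")
    c(title, hdr, rows)
  }
  writeLines(c(block(format$median_header, plate$mfi),
               block(format$count_header, plate$counts)), path)
  invisible(path)
}

#' @export
print.bbea_plate <- function(x, ...) {
  cat("<bbea_plate> ", x$plate_id, ": ", nrow(x$mfi), " wells x ",
      ncol(x$mfi), " epitopes", sep = "")
  if (nrow(x$missing)) cat(" (", nrow(x$missing), " wells missing a block)", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a plate-layout / study-design table
#'
#' @param path delimited file with required columns `sample_id`, `plate_id`,
#'   `well`, `replicate` and arbitrary additional factor columns
#'   (e.g. subject_id, visit, treatment, diagnosis, group).
#' @param nsb_label reserved `sample_id` marking buffer-only wells; every
#'   plate must carry at least one such well.
#' @param sep field separator.
#' @return a `bbea_design` data.frame with normalized wells, a logical
#'   `is_nsb` column and a `factors` attribute naming the extra columns.
#' @export
read_design <- function(path, nsb_label = "NSB", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_design(df, nsb_label = nsb_label)
}

#' @rdname read_design
#' @param df a data.frame already holding the design columns.
#' @export
as_design <- function(df, nsb_label = "NSB") {
  req <- c("sample_id", "plate_id", "well", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("design lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$well <- normalize_well(df$well)
  key <- paste(df$plate_id, df$well)
  if (anyDuplicated(key)) {
    stop("well(s) referenced twice in design: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  df$is_nsb <- df$sample_id == nsb_label
  no_nsb <- setdiff(unique(df$plate_id), unique(df$plate_id[df$is_nsb]))
  if (length(no_nsb)) {
    stop("plate(s) without any ", nsb_label, " well: ",
         paste(no_nsb, collapse = ", "), call. = FALSE)
  }
  factors <- setdiff(names(df), c(req, "is_nsb"))
  for (f in factors) {
    lv <- unique(df[[f]][!df$is_nsb])
    if (length(lv) == 1L) {
      warning("design factor '", f, "' has a single level (", lv,
              "); it cannot be used as a model term", call. = FALSE)
    }
  }
  structure(df, factors = factors, nsb_label = nsb_label,
            class = c("bbea_design", "data.frame"))
}

#' Read an epitope library table
#'
#' @param path delimited file with columns `epitope_id`, `protein`,
#'   `sequence`, `bead_region`.
#' @param sep field separator.
#' @return validated data.frame.
#' @export
read_epitope_library <- function(path, sep = ",") {
  lib <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("epitope_id", "protein", "sequence", "bead_region")
  miss <- setdiff(req, names(lib))
  if (length(miss)) {
    stop("epitope library lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(lib$bead_region)) {
    stop("bead_region values must be unique within a library", call. = FALSE)
  }
  if (anyDuplicated(lib$epitope_id)) {
    stop("epitope_id values must be unique within a library", call. = FALSE)
  }
  seqs <- toupper(lib$sequence)
  if (any(!nzchar(seqs)) || any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs))) {
    stop("sequences must be non-empty amino-acid strings", call. = FALSE)
  }
  lib$sequence <- seqs
  lib
}

#' Assemble readings and design into a tidy long table
#'
#' One row per well x epitope, joining the design's sample annotation and the
#' library's protein annotation onto the measured MFI and bead count.
#'
#' @param plates a `bbea_plate` or list of them.
#' @param design a `bbea_design`.
#' @param library optional epitope library (adds a `protein` column).
#' @return data.frame with columns plate, well, reading_index, sample,
#'   replicate, is_nsb, epitope, protein, mfi, bead_count plus the design's
#'   factor columns.
#' @export
to_long_table <- function(plates, design, library = NULL) {
  if (inherits(plates, "bbea_plate")) plates <- list(plates)
  design_key <- paste(design$plate_id, design$well)
  out <- lapply(plates, function(pl) {
    wells <- pl$wells$well
    epi <- colnames(pl$mfi)
    idx <- match(paste(pl$plate_id, wells), design_key)
    if (anyNA(idx)) {
      missing_wells <- wells[is.na(idx)]
      non_nsb <- missing_wells  # design must list every measured well
      stop("well(s) on plate ", pl$plate_id, " absent from design: ",
           paste(non_nsb, collapse = ", "), call. = FALSE)
    }
    n_w <- length(wells); n_e <- length(epi)
    df <- data.frame(
      plate = pl$plate_id,
      well = rep(wells, times = n_e),
      reading_index = rep(pl$wells$reading_index, times = n_e),
      sample = rep(design$sample_id[idx], times = n_e),
      replicate = rep(design$replicate[idx], times = n_e),
      is_nsb = rep(design$is_nsb[idx], times = n_e),
      epitope = rep(epi, each = n_w),
      mfi = as.vector(pl$mfi),
      bead_count = as.vector(pl$counts),
      stringsAsFactors = FALSE)
    for (f in attr(design, "factors")) df[[f]] <- rep(design[[f]][idx], times = n_e)
    df
  })
  long <- do.call(rbind, out)
  rownames(long) <- NULL
  if (!is.null(library)) {
    long$protein <- library$protein[match(long$epitope, library$epitope_id)]
  }
  long
}

#' Pivot a long table to a wells x epitopes wide matrix
#'
#' @param long a long table from [to_long_table()].
#' @param value which measured column to spread.
#' @return numeric matrix with `plate:well` rownames and epitope colnames,
#'   rows ordered by plate then reading index.
#' @export
long_to_wide <- function(long, value = c("mfi", "bead_count", "b", "y")) {
  value <- match.arg(value)
  uid <- paste(long$plate, long$well, sep = ":")
  ord <- order(long$plate, long$reading_index)
  rows <- unique(uid[ord])
  cols <- unique(long$epitope)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(uid, rows), match(long$epitope, cols))] <- long[[value]]
  m
}
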