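#' Log2 signal transform
#'
#' The per-well, per-epitope median fluorescence is moved to the log2 scale
#' with a small shift so that zero MFI maps to a finite value:
#' `y = log2(mfi + shift)`. With the default shift of 0.5, MFI 0 gives
#' y = -1 and MFI 1023.5 gives y = 10.
#'
#' @param mfi non-negative numeric vector/matrix of median fluorescence
#'   intensities.
#' @param shift additive constant inside the log, default 0.5.
#' @return object of the same shape as `mfi` on the log2 scale.
#' @export
log2_shift <- function(mfi, shift = 0.5) {
  if (any(mfi < 0, na.rm = TRUE)) stop("MFI must be non-negative", call. = FALSE)
  log2(mfi + shift)
}

#' Per-plate non-specific-binding baseline
#'
#' Buffer-only (NSB) wells measure the background signal of the secondary
#' antibody on each bead region. The baseline for epitope j on a plate is the
#' arithmetic mean of the log2 signals of that plate's NSB wells — the mean of
#' the log-transformed values, not the log of the mean MFI.
#'
#' @param y numeric matrix of log2 signals, wells x epitopes.
#' @param is_nsb logical vector, one per row of `y`.
#' @param plate character/factor vector, one per row of `y`.
#' @return a `bbea_nsb` list: `baseline` (plates x epitopes matrix of mean NSB
#'   log2 signal) and `n_nsb` (NSB wells used per plate).
#' @export
nsb_baseline <- function(y, is_nsb, plate = rep("plate1", nrow(y))) {
  plate <- as.character(plate)
  plates <- sort(unique(plate))
  no_nsb <- plates[!plates %in% unique(plate[is_nsb])]
  if (length(no_nsb)) {
    stop("no NSB wells on plate(s) ", paste(no_nsb, collapse = ", "),
         "; supply a baseline explicitly or quantify with nsb = FALSE",
         call. = FALSE)
  }
  baseline <- t(vapply(plates, function(p) {
    colMeans(y[is_nsb & plate == p, , drop = FALSE])
  }, numeric(ncol(y))))
  dimnames(baseline) <- list(plates, colnames(y))
  structure(list(baseline = baseline,
                 n_nsb = stats::setNames(as.integer(table(plate[is_nsb])[plates]),
                                         plates)),
            class = "bbea_nsb")
}

#' Binding scores from log2 signals and an NSB baseline
#'
#' The binding score is the NSB-corrected log2 signal floored at zero:
#' zero when the signal does not exceed its plate's background baseline,
#' otherwise the difference from it. Floored cells are flagged so downstream
#' QC can distinguish "no binding" from "subtracted".
#'
#' @param y log2-signal matrix, wells x epitopes.
#' @param nsb a `bbea_nsb` from [nsb_baseline()], or a single numeric vector
#'   of per-epitope baselines.
#' @param plate plate id per row of `y` (used to pick each well's baseline).
#' @return list with `b` (non-negative binding matrix) and `floored`
#'   (logical matrix, TRUE where the raw difference was negative).
#' @export
binding_scores <- function(y, nsb, plate = rep("plate1", nrow(y))) {
  if (inherits(nsb, "bbea_nsb")) {
    base <- nsb$baseline
  } else {
    base <- matrix(nsb, nrow = 1L, dimnames = list("plate1", names(nsb)))
  }
  if (!all(colnames(y) %in% colnames(base))) {
    stop("baseline lacks epitope(s): ",
         paste(setdiff(colnames(y), colnames(base)), collapse = ", "),
         call. = FALSE)
  }
  plate <- as.character(plate)
  if (!all(plate %in% rownames(base))) {
    stop("baseline lacks plate(s): ",
         paste(setdiff(plate, rownames(base)), collapse = ", "), call. = FALSE)
  }
  per_row_base <- base[plate, colnames(y), drop = FALSE]
  diff <- y - per_row_base
  floored <- diff < 0
  b <- diff
  b[floored] <- 0
  list(b = b, floored = floored)
}

#' Bead-count quality control
#'
#' Wells whose bead count, averaged across epitopes, falls strictly below the
#' threshold are excluded (a well averaging exactly the threshold is kept).
#' An optional stricter mode additionally excludes wells whose minimum
#' per-epitope count falls below `min_per_epitope`.
#'
#' @param counts bead-count matrix, wells x epitopes.
#' @param sample sample id per row (used to report samples whose wells all
#'   failed).
#' @param threshold exclusion threshold on the per-well average, default 30.
#' @param min_per_epitope optional per-epitope minimum count (e.g. 25); NULL
#'   disables the check.
#' @return a `bbea_qc` list: `well_avg`, `excluded_wells`, `excluded_samples`,
#'   `keep` (logical per row), `per_epitope_min`, `threshold`.
#' @export
bead_count_filter <- function(counts, sample = rownames(counts),
                              threshold = 30, min_per_epitope = NULL) {
  well_avg <- rowMeans(counts, na.rm = TRUE)
  keep <- well_avg >= threshold
  if (!is.null(min_per_epitope)) {
    keep <- keep & apply(counts, 1L, min, na.rm = TRUE) >= min_per_epitope
  }
  excluded_wells <- rownames(counts)[!keep]
  ok_samples <- unique(sample[keep])
  excluded_samples <- setdiff(unique(sample[!keep]), ok_samples)
  if (!any(keep)) warning("all wells excluded by bead-count QC", call. = FALSE)
  structure(list(well_avg = well_avg, keep = keep,
                 excluded_wells = excluded_wells,
                 excluded_samples = excluded_samples,
                 per_epitope_min = apply(counts, 2L, min, na.rm = TRUE),
                 threshold = threshold),
            class = "bbea_qc")
}

#' @export
print.bbea_qc <- function(x, ...) {
  cat("<bbea_qc> ", sum(x$keep), "/", length(x$keep),
      " wells pass (average bead count >= ", x$threshold, ")\n", sep = "")
  if (length(x$excluded_wells)) {
    cat("  excluded wells:", paste(x$excluded_wells, collapse = ", "), "\n")
  }
  invisible(x)
}

moment_skew_kurt <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(c(skewness = NA_real_, kurtosis = NA_real_))
  c(skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2 - 3)
}

#' Distribution shape diagnostics (skewness/kurtosis with bootstrap)
#'
#' Computes sample skewness and excess kurtosis of the input together with
#' bootstrap resamples of the pair, the ingredients of a Cullen-Frey style
#' skewness-squared versus kurtosis plot used to judge how far raw MFI and
#' binding-score distributions sit from the normal/log-normal references.
#'
#' @param values numeric vector (>= 3 finite values).
#' @param n_boot number of bootstrap resamples, default 100.
#' @param seed integer seed making the resampling reproducible.
#' @return a `bbea_shape` list: `skewness`, `kurtosis` (excess), `boot`
#'   (n_boot x 2 matrix), `n`.
#' @export
distribution_diagnostics <- function(values, n_boot = 100, seed = 1L) {
  x <- values[is.finite(values)]
  if (length(x) < 3L) stop("need at least 3 finite values", call. = FALSE)
  pt <- moment_skew_kurt(x)
  if (anyNA(pt)) {
    warning("constant input: skewness/kurtosis undefined", call. = FALSE)
  }
  boot <- matrix(NA_real_, n_boot, 2L,
                 dimnames = list(NULL, c("skewness", "kurtosis")))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (i in seq_len(n_boot)) {
    boot[i, ] <- moment_skew_kurt(sample(x, length(x), replace = TRUE))
  }
  structure(list(skewness = unname(pt[1L]), kurtosis = unname(pt[2L]),
                 boot = boot, n = length(x)),
            class = "bbea_shape")
}

# Seed handling: save/restore .Random.seed so diagnostics are reproducible
# without clobbering the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Quantify a BBEA experiment: MFI to binding scores with QC
#'
#' Runs the quantification chain on one or more plates: bead-count QC,
#' log2 transform, per-plate NSB baseline from the surviving buffer-only
#' wells, and zero-floored baseline subtraction. NSB wells are QC'd first,
#' so a failing NSB well never contributes to the baseline.
#'
#' @param plates a `bbea_plate` or list of them (see [read_plate_export()]
#'   and [simulate_study()]).
#' @param design a `bbea_design`.
#' @param library optional epitope library.
#' @param bead_threshold bead-count QC threshold (see [bead_count_filter()]).
#' @param nsb if FALSE, skip NSB subtraction (b = y, nothing floored).
#' @param shift log2 shift constant, default 0.5.
#' @param isotype optional label ("IgE", "IgG4") carried on the result.
#' @return a `bbea_binding` object at well level: matrices `b`, `y`,
#'   `floored`, `counts` over non-NSB wells passing QC; `meta` data.frame
#'   (plate, well, reading_index, sample, replicate + design factors) aligned
#'   with rows; `baseline` (`bbea_nsb`); `qc` (`bbea_qc`); `level = "well"`.
#' @export
quantify <- function(plates, design, library = NULL, bead_threshold = 30,
                     nsb = TRUE, shift = 0.5, isotype = NULL) {
  if (inherits(plates, "bbea_plate")) plates <- list(plates)
  long <- to_long_table(plates, design, library)
  mfi <- long_to_wide(long, "mfi")
  counts <- long_to_wide(long, "bead_count")
  first <- !duplicated(paste(long$plate, long$well, sep = ":"))
  meta <- long[first, intersect(
    c("plate", "well", "reading_index", "sample", "replicate", "is_nsb",
      attr(design, "factors")), names(long))]
  rownames(meta) <- paste(meta$plate, meta$well, sep = ":")
  meta <- meta[rownames(mfi), ]

  qc <- bead_count_filter(counts, sample = meta$sample,
                          threshold = bead_threshold)
  keep <- qc$keep
  if (!any(keep)) {
    stop("no wells pass bead-count QC (threshold ", bead_threshold, ")",
         call. = FALSE)
  }
  mfi <- mfi[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]

  y <- log2_shift(mfi, shift)
  if (nsb) {
    base <- nsb_baseline(y, meta$is_nsb, meta$plate)
    bs <- binding_scores(y, base, meta$plate)
  } else {
    base <- NULL
    bs <- list(b = y, floored = y < -Inf)
  }
  keep_sample <- !meta$is_nsb
  structure(list(
    b = bs$b[keep_sample, , drop = FALSE],
    y = y[keep_sample, , drop = FALSE],
    floored = bs$floored[keep_sample, , drop = FALSE],
    counts = counts[keep_sample, , drop = FALSE],
    meta = meta[keep_sample, , drop = FALSE],
    baseline = base, qc = qc, level = "well", isotype = isotype),
    class = "bbea_binding")
}

#' @export
print.bbea_binding <- function(x, ...) {
  cat("<bbea_binding> ", nrow(x$b), " ", x$level, "s x ", ncol(x$b),
      " epitopes", sep = "")
  if (!is.null(x$isotype)) cat(" [", x$isotype, "]", sep = "")
  cat("\n  binding range: [", round(min(x$b), 3), ", ", round(max(x$b), 3),
      "]; floored cells: ", sum(x$floored), "\n", sep = "")
  invisible(x)
}

#' Average technical replicates
#'
#' Collapses a well-level binding object to one row per sample by the
#' arithmetic mean of the already-floored binding scores (flooring is not
#' re-applied after averaging).
#'
#' @param binding a well-level `bbea_binding`.
#' @return a sample-level `bbea_binding`; `meta` keeps one row per sample
#'   (factor values from its first replicate) plus the group size `n_rep`.
#' @export
replicate_average <- function(binding) {
  stopifnot(inherits(binding, "bbea_binding"))
  if (binding$level != "well") {
    stop("binding is already replicate-averaged", call. = FALSE)
  }
  samples <- unique(binding$meta$sample)
  idx <- split(seq_len(nrow(binding$b)), binding$meta$sample)[samples]
  sizes <- lengths(idx)
  if (any(sizes == 0L)) stop("empty replicate group", call. = FALSE)
  avg <- function(m) {
    out <- do.call(rbind, lapply(idx, function(i) colMeans(m[i, , drop = FALSE])))
    rownames(out) <- samples
    out
  }
  meta <- binding$meta[vapply(idx, `[`, 1L, 1L), , drop = FALSE]
  meta$n_rep <- as.integer(sizes)
  meta$well <- meta$reading_index <- meta$replicate <- NULL
  rownames(meta) <- samples
  structure(list(b = avg(binding$b), y = avg(binding$y),
                 floored = NULL, counts = avg(binding$counts),
                 meta = meta, baseline = binding$baseline, qc = binding$qc,
                 level = "sample", isotype = binding$isotype),
            class = "bbea_binding")
}
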