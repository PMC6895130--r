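#' Microarray spot log-ratio signal
#'
#' `S = log2(median_spot / median_local_background)`: a spot at background
#' level scores 0, a spot at four times background scores 2.
#'
#' @param median_spot,median_background non-negative spot and local
#'   background median fluorescences; background must be positive.
#' @param epsilon optional positive offset added to both medians for slides
#'   with zero backgrounds; off (0) by default.
#' @return numeric vector of log-ratio signals.
#' @export
spot_signal <- function(median_spot, median_background, epsilon = 0) {
  if (any(median_spot < 0) || any(median_background < 0)) {
    stop("medians must be non-negative", call. = FALSE)
  }
  if (epsilon > 0) {
    median_spot <- median_spot + epsilon
    median_background <- median_background + epsilon
  }
  if (any(median_background == 0)) {
    stop("zero local background; supply epsilon > 0 to offset", call. = FALSE)
  }
  log2(median_spot / median_background)
}

#' Robust z-scores against blank spots
#'
#' Standardizes signals by the blank (PBS+DMSO) spot distribution:
#' `Z = (S - median(S_blank)) / MAD(S_blank)` with
#' `MAD = median(|Y - median(Y)|)` — the raw median absolute deviation,
#' deliberately without the 1.4826 normal-consistency factor (enable it with
#' `scaled_mad` for comparison). By construction the blank signals
#' themselves have median Z of exactly zero.
#'
#' @param signals numeric vector of log-ratio signals `S`.
#' @param blank_signals `S` values of the blank spots (>= 2, non-degenerate).
#' @param scaled_mad if TRUE, multiply the MAD by 1.4826.
#' @return numeric vector of z-scores.
#' @export
robust_z <- function(signals, blank_signals, scaled_mad = FALSE) {
  if (length(blank_signals) < 2L) stop("need >= 2 blank spots", call. = FALSE)
  ctr <- stats::median(blank_signals)
  mad0 <- stats::median(abs(blank_signals - ctr))
  if (scaled_mad) mad0 <- mad0 * 1.4826
  if (mad0 == 0) {
    stop("MAD of blank spots is zero (degenerate blanks); cannot standardize",
         call. = FALSE)
  }
  (signals - ctr) / mad0
}

#' Collapse replicate spots per peptide
#'
#' Each peptide is printed in several replicate spots per slide (up to 6);
#' they are collapsed with the median by default, which tolerates a single
#' aberrant spot.
#'
#' @param z numeric vector of spot-level values.
#' @param peptide peptide id per spot.
#' @param stat `"median"` (default) or `"mean"`.
#' @return named vector, one value per peptide (input order of first
#'   appearance).
#' @export
collapse_replicates <- function(z, peptide, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  peps <- unique(peptide)
  vapply(peps, function(p) f(z[peptide == p]), numeric(1L))
}

#' Quantify a microarray spot table as per-peptide z-scores
#'
#' Full comparator chain within each slide: spot log-ratio signals, robust
#' z-scores against that slide's blank spots, and replicate-spot collapse.
#'
#' @param spots data.frame with columns `slide_id`, `peptide_id` (NA or ""
#'   for blanks), `median_spot`, `median_background`, and optionally
#'   `is_blank` (otherwise blanks are rows with empty/NA peptide_id).
#' @param stat replicate collapse statistic, see [collapse_replicates()].
#' @param scaled_mad see [robust_z()].
#' @return data.frame: slide_id, peptide_id, z (collapsed), n_spots.
#' @export
mia_zscores <- function(spots, stat = "median", scaled_mad = FALSE) {
  req <- c("slide_id", "peptide_id", "median_spot", "median_background")
  miss <- setdiff(req, names(spots))
  if (length(miss)) {
    stop("spot table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(spots$is_blank)) {
    spots$is_blank <- is.na(spots$peptide_id) | spots$peptide_id == ""
  }
  out <- lapply(unique(spots$slide_id), function(sl) {
    s <- spots[spots$slide_id == sl, ]
    if (!any(s$is_blank)) stop("slide ", sl, " has no blank spots", call. = FALSE)
    sig <- spot_signal(s$median_spot, s$median_background)
    z <- robust_z(sig, sig[s$is_blank], scaled_mad = scaled_mad)
    pep <- s$peptide_id[!s$is_blank]
    zc <- collapse_replicates(z[!s$is_blank], pep, stat = stat)
    data.frame(slide_id = sl, peptide_id = names(zc), z = unname(zc),
               n_spots = as.integer(table(pep)[names(zc)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
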