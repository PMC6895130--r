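two_way_ms <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(x)) stop("ratings matrix must be complete", call. = FALSE)
  grand <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

#' Two-way intraclass correlation coefficient
#'
#' Single-measure two-way ICC from the ANOVA decomposition of a complete
#' subjects x raters matrix. The consistency form
#' `(MSR - MSE) / (MSR + (k-1) MSE)` ignores systematic rater shifts; the
#' agreement form adds the rater variance term
#' `(k/n)(MSC - MSE)` to the denominator and so penalizes them. 95%
#' confidence limits use the exact F interval for consistency and the
#' approximate-F (Satterthwaite) interval for agreement.
#'
#' @param ratings numeric matrix, subjects in rows, raters/replicates in
#'   columns, no missing cells.
#' @param type `"agreement"` or `"consistency"`.
#' @param unit `"single"` (default) for the reliability of one measurement,
#'   `"average"` for the mean of the k columns.
#' @param conf_level confidence level, default 0.95.
#' @return a `bbea_icc`: estimate, ci_low, ci_high, type, unit, n_subjects,
#'   k_raters, band (see [icc_band()]), and the mean squares.
#' @export
icc <- function(ratings, type = c("agreement", "consistency"),
                unit = c("single", "average"), conf_level = 0.95) {
  type <- match.arg(type); unit <- match.arg(unit)
  ms <- two_way_ms(ratings)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf_level
  if (ms$msr == 0 && ms$mse == 0 && ms$msc == 0) {
    out <- list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                type = type, unit = unit, n_subjects = n, k_raters = k,
                band = NA_character_, ms = ms,
                note = "constant ratings: between-subject variance is zero, ICC undefined")
    return(structure(out, class = "bbea_icc"))
  }
  if (type == "consistency") {
    est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    if (ms$mse == 0) {
      lo <- hi <- 1
    } else {
      f0 <- ms$msr / ms$mse
      fl <- f0 / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- f0 * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
    if (unit == "average") {
      avg <- function(r) k * r / (1 + (k - 1) * r)
      est <- avg(est); lo <- avg(lo); hi <- avg(hi)
    }
  } else {
    est <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    if (est >= 1) {
      lo <- hi <- 1
    } else {
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      v <- (a * ms$msc + b * ms$mse)^2 /
        ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
      f1 <- stats::qf(1 - alpha / 2, n - 1, v)
      f2 <- stats::qf(1 - alpha / 2, v, n - 1)
      denom_c <- k * ms$msc + (k * n - k - n) * ms$mse
      lo <- n * (ms$msr - f1 * ms$mse) / (f1 * denom_c + n * ms$msr)
      hi <- n * (f2 * ms$msr - ms$mse) / (denom_c + n * f2 * ms$msr)
    }
    if (unit == "average") {
      avg <- function(r) k * r / (1 + (k - 1) * r)
      est <- avg(est); lo <- avg(lo); hi <- avg(hi)
    }
  }
  structure(list(estimate = est, ci_low = lo, ci_high = hi,
                 type = type, unit = unit, n_subjects = n, k_raters = k,
                 band = icc_band(est), ms = ms, note = NULL),
            class = "bbea_icc")
}

#' @export
print.bbea_icc <- function(x, ...) {
  if (is.na(x$estimate)) {
    cat("<bbea_icc> undefined (", x$note, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("<bbea_icc> ICC(%s, %s) = %.3f, 95%% CI [%.3f, %.3f] (%s); n = %d subjects x %d raters\n",
              substr(x$type, 1, 1), x$unit, x$estimate, x$ci_low, x$ci_high,
              x$band, x$n_subjects, x$k_raters))
  invisible(x)
}

#' Qualitative ICC band
#'
#' Published reliability guideline bands: excellent 0.75-1.00, good
#' 0.60-0.74, fair 0.40-0.59, poor below 0.40. A value exactly on a printed
#' lower bound falls into the higher band.
#'
#' @param estimate finite ICC estimate(s).
#' @return character vector of band labels.
#' @export
icc_band <- function(estimate) {
  ifelse(is.na(estimate), NA_character_,
  ifelse(estimate >= 0.75, "excellent",
  ifelse(estimate >= 0.60, "good",
  ifelse(estimate >= 0.40, "fair", "poor"))))
}

#' Reliability across technical replicates
#'
#' For each sample, arranges its replicate wells into an epitopes x k
#' ratings matrix (epitopes as subjects, replicates as raters) and computes
#' the agreement ICC. Samples whose binding sits at the zero floor (e.g. a
#' non-allergic control) have almost no between-epitope variance and are
#' expected to return low or undefined ICCs; they are flagged, not errors.
#'
#' @param binding a well-level `bbea_binding`.
#' @param type ICC type, default `"agreement"`.
#' @param conf_level confidence level.
#' @return data.frame with one row per sample: estimate, ci_low, ci_high,
#'   band, k, n_epitopes; skipped samples (unbalanced or k = 1) carry NA and
#'   a warning is raised. Attribute `mean_icc` holds the across-sample mean.
#' @export
replicate_reliability <- function(binding, type = "agreement",
                                  conf_level = 0.95) {
  stopifnot(inherits(binding, "bbea_binding"))
  if (binding$level != "well") stop("need well-level binding", call. = FALSE)
  samples <- unique(binding$meta$sample)
  ks <- table(binding$meta$sample)[samples]
  # the design's replicate count: the most common group size (ties -> larger)
  tab <- table(as.integer(ks))
  usable_k <- max(as.integer(names(tab)[tab == max(tab)]))
  rows <- lapply(samples, function(s) {
    i <- which(binding$meta$sample == s)
    if (length(i) < 2L || length(i) != usable_k) {
      warning("sample ", s, " skipped: replicate group of size ", length(i),
              call. = FALSE)
      return(data.frame(sample = s, estimate = NA, ci_low = NA, ci_high = NA,
                        band = NA_character_, k = length(i),
                        n_epitopes = ncol(binding$b)))
    }
    m <- t(binding$b[i, , drop = FALSE])  # epitopes x replicates
    r <- icc(m, type = type, conf_level = conf_level)
    data.frame(sample = s, estimate = r$estimate, ci_low = r$ci_low,
               ci_high = r$ci_high, band = r$band, k = length(i),
               n_epitopes = ncol(binding$b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_icc") <- mean(out$estimate, na.rm = TRUE)
  out
}

#' Reproducibility across centers or runs
#'
#' Takes replicate-averaged binding from several centers (laboratories,
#' days, instruments) and computes per-sample (epitopes x centers) or
#' per-epitope (samples x centers) ICCs. Consistency is the default: an
#' additive center shift is a batch effect, removable by
#' [remove_plate_effects()] with center as the batch, after which the
#' agreement ICC is the relevant metric.
#'
#' @param center_bindings named list of sample-level `bbea_binding` objects
#'   (or samples x epitopes matrices), one per center.
#' @param by `"sample"` or `"epitope"`.
#' @param type ICC type, default `"consistency"`.
#' @param conf_level confidence level.
#' @return data.frame as in [replicate_reliability()], one row per unit.
#' @export
center_reproducibility <- function(center_bindings, by = c("sample", "epitope"),
                                   type = "consistency", conf_level = 0.95) {
  by <- match.arg(by)
  mats <- lapply(center_bindings, function(x) {
    if (inherits(x, "bbea_binding")) x$b else as.matrix(x)
  })
  if (length(mats) < 2L) stop("need >= 2 centers", call. = FALSE)
  common_s <- Reduce(intersect, lapply(mats, rownames))
  common_e <- Reduce(intersect, lapply(mats, colnames))
  if (any(vapply(mats, function(m) ncol(m) != length(common_e) ||
                 nrow(m) != length(common_s), TRUE))) {
    warning("centers measured different samples/epitopes; intersecting to ",
            length(common_s), " samples x ", length(common_e), " epitopes",
            call. = FALSE)
  }
  mats <- lapply(mats, function(m) m[common_s, common_e, drop = FALSE])
  units <- if (by == "sample") common_s else common_e
  rows <- lapply(units, function(u) {
    ratings <- vapply(mats, function(m) {
      if (by == "sample") m[u, ] else m[, u]
    }, numeric(if (by == "sample") length(common_e) else length(common_s)))
    r <- icc(ratings, type = type, conf_level = conf_level)
    data.frame(unit = u, estimate = r$estimate, ci_low = r$ci_low,
               ci_high = r$ci_high, band = r$band,
               k = ncol(ratings), n_subjects = nrow(ratings))
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- by
  rownames(out) <- NULL
  attr(out, "mean_icc") <- mean(out$estimate, na.rm = TRUE)
  out
}

#' Spearman-distance hierarchical clustering of replicates
#'
#' Clusters binding profiles with distance `1 - Spearman rho` (average ranks
#' for ties) and UPGMA (average-linkage) agglomeration. Technical replicates
#' of one sample should merge into their own clade; the tree serializes to
#' Newick for external viewers.
#'
#' @param binding a `bbea_binding` or units x epitopes matrix (>= 3 rows).
#' @param labels optional tip labels; defaults to rownames.
#' @return a `bbea_tree`: `phylo` (ape tree), `hclust`, `dist`.
#' @export
replicate_tree <- function(binding, labels = NULL) {
  m <- if (inherits(binding, "bbea_binding")) binding$b else as.matrix(binding)
  if (!is.null(labels)) rownames(m) <- labels
  constant <- apply(m, 1L, function(r) stats::sd(r) == 0)
  if (any(constant)) {
    warning("dropping constant row(s) with undefined correlation: ",
            paste(rownames(m)[constant], collapse = ", "), call. = FALSE)
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("need >= 3 non-constant rows", call. = FALSE)
  rho <- stats::cor(t(m), method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  structure(list(phylo = ape::as.phylo(hc), hclust = hc, dist = d),
            class = "bbea_tree")
}

#' @rdname replicate_tree
#' @param tree a `bbea_tree`.
#' @param path output Newick file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' @export
print.bbea_tree <- function(x, ...) {
  cat("<bbea_tree> UPGMA over 1 - Spearman rho, ",
      length(x$phylo$tip.label), " tips\n", sep = "")
  invisible(x)
}
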