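# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to match the spread of log sample variances to an F prior.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  repeat {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-8) break
  }
  y
}

#' Empirical-Bayes shrinkage of per-epitope variances
#'
#' Models the per-epitope sample variances as scaled chi-square draws around
#' epitope variances that follow a scaled inverse chi-square prior with
#' `d0` degrees of freedom and scale `s0_sq`. The prior is estimated by
#' matching the mean and variance of `log(s2)` to their theoretical digamma/
#' trigamma moments (the trigamma equation is solved by Newton iteration);
#' each variance is then shrunk toward the prior:
#' `s_tilde2 = (d0 s0_sq + df s2) / (d0 + df)`. Borrowing strength this way
#' is what makes the moderated t-test stable at very small replicate counts.
#'
#' @param s_sq non-negative vector of per-epitope sample variances (>= 2).
#' @param df residual degrees of freedom shared by the variances (>= 1).
#' @param d0 optional fixed prior df, bypassing estimation: `0` disables
#'   shrinkage (`s_tilde2 = s2`), `Inf` shrinks fully to the common value.
#' @return list with `d0`, `s0_sq`, and `s_tilde_sq` (same length as `s_sq`).
#' @export
ebayes_shrink <- function(s_sq, df, d0 = NULL) {
  if (any(s_sq < 0)) stop("variances must be non-negative", call. = FALSE)
  if (df < 1) stop("need residual df >= 1", call. = FALSE)
  if (length(s_sq) < 2L) stop("need >= 2 epitopes", call. = FALSE)
  if (any(s_sq == 0)) {
    warning("zero variance(s) offset by a small positive constant",
            call. = FALSE)
    eps <- if (any(s_sq > 0)) min(s_sq[s_sq > 0]) * 1e-6 else 1e-12
    s_sq <- pmax(s_sq, eps)
  }
  if (!is.null(d0)) {
    if (d0 == 0) {
      return(list(d0 = 0, s0_sq = mean(s_sq), s_tilde_sq = s_sq))
    }
    if (is.infinite(d0)) {
      s0 <- mean(s_sq)
      return(list(d0 = Inf, s0_sq = s0, s_tilde_sq = rep(s0, length(s_sq))))
    }
  }
  if (length(unique(s_sq)) < 2L) {
    warning("all variances identical: prior df set to Inf", call. = FALSE)
    return(list(d0 = Inf, s0_sq = s_sq[1L],
                s_tilde_sq = rep(s_sq[1L], length(s_sq))))
  }
  z <- log(s_sq)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.null(d0)) {
    if (evar <= 0) {
      d0 <- Inf
      s0_sq <- exp(emean)
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(s_sq)) else {
    (d0 * s0_sq + df * s_sq) / (d0 + df)
  }
  list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde_sq)
}

detection_table <- function(delta_bar, sd_delta, s_sq, shrink, n, df, p, fdr,
                            detected, mode) {
  out <- data.frame(
    epitope = names(delta_bar) %||% paste0("ep", seq_along(delta_bar)),
    delta_bar = unname(delta_bar), sd_delta = unname(sd_delta),
    s_sq = unname(s_sq), s_tilde_sq = unname(shrink$s_tilde_sq),
    t_mod = unname(delta_bar / sqrt(shrink$s_tilde_sq / n)),
    df_total = df + min(shrink$d0, 1e6),
    p = unname(p), fdr = unname(fdr),
    effect_size = unname(delta_bar / sd_delta),
    fch = unname(sign(delta_bar) * 2^abs(delta_bar)),
    detected = unname(detected),
    stringsAsFactors = FALSE)
  structure(out, d0 = shrink$d0, s0_sq = shrink$s0_sq, mode = mode,
            class = c("bbea_detection", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moderated paired t-test for epitope detection
#'
#' Tests, per epitope, whether a positive pool binds above a negative
#' control across paired replicates: `delta = pos - neg` per pair, a
#' moderated one-sample t on the mean difference using the shrunken variance
#' from [ebayes_shrink()], with `df + d0` degrees of freedom. Detection mode
#' uses the nominal two-sided p < `alpha` with no multiplicity adjustment —
#' the deliberate choice for small replicate counts — but the BH-adjusted
#' values are still reported.
#'
#' @param pos,neg epitopes x replicates matrices on the log2 binding scale.
#' @param pairing explicit pairing, a two-column data.frame/matrix whose
#'   rows give matching (pos, neg) column names or indices. Pairing is never
#'   inferred; omitting it is an error.
#' @param d0 optional fixed prior df passed to [ebayes_shrink()] (0 gives the
#'   classical paired t-test).
#' @param alpha detection threshold on the nominal p-value, default 0.05.
#' @return a `bbea_detection` data.frame: delta_bar, sd_delta, s_sq,
#'   s_tilde_sq, t_mod, df_total, p, fdr, effect_size (= delta_bar/SD(delta)),
#'   fch (signed 2^|delta_bar|), detected.
#' @export
moderated_paired_test <- function(pos, neg, pairing, d0 = NULL, alpha = 0.05) {
  if (missing(pairing) || is.null(pairing)) {
    stop("explicit pairing of pos and neg replicates is required ",
         "(two-column data.frame of matching column ids)", call. = FALSE)
  }
  pairing <- as.data.frame(pairing)
  if (ncol(pairing) != 2L || nrow(pairing) < 2L) {
    stop("pairing needs two columns and >= 2 pairs", call. = FALSE)
  }
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (!identical(rownames(pos), rownames(neg))) {
    stop("pos and neg must cover identical epitopes", call. = FALSE)
  }
  delta <- pos[, pairing[[1L]], drop = FALSE] - neg[, pairing[[2L]], drop = FALSE]
  n <- ncol(delta)
  delta_bar <- rowMeans(delta)
  s_sq <- apply(delta, 1L, stats::var)
  df <- n - 1
  shrink <- ebayes_shrink(s_sq, df, d0 = d0)
  df_total <- df + min(shrink$d0, 1e6)
  t_mod <- delta_bar / sqrt(shrink$s_tilde_sq / n)
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  detection_table(delta_bar, sqrt(s_sq), s_sq, shrink, n, df,
                  p, bh_fdr(p), p < alpha, mode = "detection")
}

#' Differential binding between groups
#'
#' Per-epitope linear model of log2 binding on a two-level group (plus
#' optional covariates), with one shared empirical-Bayes prior across
#' epitopes and BH false-discovery-rate control. An epitope is significant
#' only when both gates pass: fold change `2^|delta| >= fch_threshold` and
#' `FDR < fdr_threshold` — a small-p, small-fold epitope is not called.
#'
#' @param binding sample-level `bbea_binding` or samples x epitopes matrix.
#' @param group two-level factor (or name of a meta column).
#' @param covariates optional data.frame (or meta column names) of
#'   adjustment covariates.
#' @param fch_threshold fold-change gate, default 1.5.
#' @param fdr_threshold FDR gate, default 0.05.
#' @param d0 optional fixed prior df for [ebayes_shrink()].
#' @return a `bbea_detection` data.frame (mode "differential"); `delta_bar`
#'   is the second-group-minus-first contrast on the log2 scale.
#' @export
differential_binding <- function(binding, group, covariates = NULL,
                                 fch_threshold = 1.5, fdr_threshold = 0.05,
                                 d0 = NULL) {
  if (inherits(binding, "bbea_binding")) {
    m <- binding$b
    if (is.character(group) && length(group) == 1L) {
      group <- binding$meta[[group]]
    }
    if (is.character(covariates)) {
      covariates <- binding$meta[, covariates, drop = FALSE]
    }
  } else {
    m <- as.matrix(binding)
  }
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  if (any(table(group) < 2L)) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  dat <- data.frame(.group = group)
  rhs <- ".group"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) dat[[nm]] <- covariates[[nm]]
    rhs <- paste(c(".group", names(covariates)), collapse = " + ")
  }
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    stop("covariate(s) confounded with group: design matrix is rank ",
         "deficient", call. = FALSE)
  }
  fit <- stats::lm.fit(mm, m)
  df <- nrow(mm) - qr_mm$rank
  if (df < 1L) stop("no residual degrees of freedom", call. = FALSE)
  s_sq <- colSums(as.matrix(fit$residuals)^2) / df
  g_col <- paste0(".group", levels(group)[2L])
  coefs <- as.matrix(fit$coefficients)
  delta <- coefs[g_col, ]
  v_g <- chol2inv(chol(crossprod(mm)))[which(colnames(mm) == g_col),
                                       which(colnames(mm) == g_col)]
  shrink <- ebayes_shrink(s_sq, df, d0 = d0)
  df_total <- df + min(shrink$d0, 1e6)
  t_mod <- delta / sqrt(v_g * shrink$s_tilde_sq)
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  fdr <- bh_fdr(p)
  detected <- (2^abs(delta) >= fch_threshold) & (fdr < fdr_threshold)
  # 1/v_g is the effective n of the contrast, so detection_table's
  # t = delta / sqrt(s_tilde2 / n) reproduces t_mod above.
  out <- detection_table(delta, sqrt(s_sq), s_sq, shrink, 1 / v_g, df,
                         p, fdr, detected, mode = "differential")
  out$effect_size <- unname(delta / sqrt(s_sq))
  out
}

#' @export
print.bbea_detection <- function(x, ...) {
  mode <- attr(x, "mode")
  cat("<bbea_detection> ", nrow(x), " epitopes (", mode, " mode): ",
      sum(x$detected), " ", if (mode == "detection") "detected" else "significant",
      "; prior df d0 = ", signif(attr(x, "d0"), 4),
      ", s0^2 = ", signif(attr(x, "s0_sq"), 4), "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement, preserving
#' ties and the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' IgG4 minus IgE contrast
#'
#' The blocking-to-sensitizing antibody comparison is computed as a
#' difference on the log2 binding scale (not a quotient of raw signals),
#' element-wise over matched samples and epitopes.
#'
#' @param igg4,ige matched samples x epitopes matrices (or `bbea_binding`
#'   objects) on the log2 binding scale.
#' @return matrix of IgG4 - IgE differences with attribute
#'   `isotype = "IgG4-IgE"`.
#' @export
igg4_ige_contrast <- function(igg4, ige) {
  g <- if (inherits(igg4, "bbea_binding")) igg4$b else as.matrix(igg4)
  e <- if (inherits(ige, "bbea_binding")) ige$b else as.matrix(ige)
  if (!identical(dim(g), dim(e))) {
    stop("IgG4 and IgE matrices must have matching dimensions", call. = FALSE)
  }
  out <- g - e
  attr(out, "isotype") <- "IgG4-IgE"
  out
}
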