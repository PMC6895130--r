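#' Per-epitope plate-effect model
#'
#' Fits, for every epitope, the additive model
#' `b ~ 1 + plate + <experimental terms> (+ subject random intercept)`.
#' Plate coefficients are indicator-coded against the reference plate (the
#' first in sorted order), so they estimate the batch shift each later plate
#' adds to all of its wells. Random allocation of samples to plates is what
#' makes plate and experimental terms jointly estimable; complete confounding
#' is detected by a rank test on the combined design and reported as an
#' error, because no model can then separate batch from biology.
#'
#' The mixed variant (`random_subject`) adds a subject-level random intercept
#' fitted by REML, inducing a compound-symmetric correlation among repeated
#' measures of one subject. An epitope whose mixed fit fails to converge
#' falls back to the fixed-effects fit with a warning.
#'
#' @param binding a `bbea_binding` (well- or sample-level).
#' @param terms optional RHS formula string of experimental factors from the
#'   design, e.g. `"visit*treatment"`; their effects are estimated alongside
#'   the plate coefficients (and are never removed by
#'   [remove_plate_effects()]).
#' @param random_subject optional name of a meta column identifying subjects
#'   for the random intercept.
#' @return a `bbea_plate_fit`: matrices `gamma` and `gamma_se`
#'   (epitopes x plates-1), `beta`/`beta_se` for the experimental terms,
#'   `residuals`, `df_residual`, `plates`, `reference`, `method`.
#' @export
fit_plate_model <- function(binding, terms = NULL, random_subject = NULL) {
  stopifnot(inherits(binding, "bbea_binding"))
  meta <- binding$meta
  plates <- sort(unique(as.character(meta$plate)))
  if (length(plates) < 2L) stop("plate factor needs >= 2 levels", call. = FALSE)
  dat <- data.frame(plate = factor(meta$plate, levels = plates))
  rhs <- "plate"
  if (!is.null(terms)) {
    tv <- all.vars(stats::as.formula(paste("~", terms)))
    for (v in tv) dat[[v]] <- factor_or_numeric(meta[[v]], v)
    rhs <- paste("plate +", terms)
  }
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("plate is confounded with experimental term(s); cannot reliably ",
         "estimate the plate effect. Aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  is_plate_col <- grepl("^plate", colnames(mm)) & colnames(mm) != "(Intercept)"
  Y <- binding$b
  epitopes <- colnames(Y)

  if (is.null(random_subject)) {
    fit <- stats::lm.fit(mm, Y)
    df <- nrow(mm) - qr_mm$rank
    rss <- colSums(as.matrix(fit$residuals)^2)
    s2 <- rss / df
    xtx_inv <- chol2inv(chol(crossprod(mm)))
    se_unit <- sqrt(diag(xtx_inv))
    coefs <- as.matrix(fit$coefficients)
    ses <- outer(se_unit, sqrt(s2))
    dimnames(ses) <- dimnames(coefs)
    gamma <- t(coefs[is_plate_col, , drop = FALSE])
    gamma_se <- t(ses[is_plate_col, , drop = FALSE])
    beta <- t(coefs[!is_plate_col, , drop = FALSE])
    beta_se <- t(ses[!is_plate_col, , drop = FALSE])
    resid <- as.matrix(fit$residuals)
    dimnames(resid) <- dimnames(Y)
    method <- "ols"
    df_residual <- rep(df, length(epitopes))
  } else {
    subj <- meta[[random_subject]]
    if (is.null(subj)) stop("no meta column '", random_subject, "'", call. = FALSE)
    dat$.subject <- factor(subj)
    p_idx <- which(is_plate_col)
    gamma <- gamma_se <- matrix(NA_real_, length(epitopes), sum(is_plate_col),
                                dimnames = list(epitopes, colnames(mm)[is_plate_col]))
    beta <- beta_se <- matrix(NA_real_, length(epitopes), sum(!is_plate_col),
                              dimnames = list(epitopes, colnames(mm)[!is_plate_col]))
    resid <- matrix(NA_real_, nrow(Y), length(epitopes), dimnames = dimnames(Y))
    df_residual <- numeric(length(epitopes))
    form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .subject)"))
    for (j in seq_along(epitopes)) {
      dat$.y <- Y[, j]
      fm <- tryCatch(
        suppressMessages(lme4::lmer(form, data = dat, REML = TRUE)),
        error = function(e) NULL)
      if (is.null(fm)) {
        warning("mixed fit failed for epitope ", epitopes[j],
                "; falling back to fixed effects", call. = FALSE)
        lf <- stats::lm(stats::as.formula(paste(".y ~", rhs)), dat)
        cf <- summary(lf)$coefficients
        df_residual[j] <- lf$df.residual
        resid[, j] <- stats::residuals(lf)
      } else {
        cf <- summary(fm)$coefficients[, 1:2, drop = FALSE]
        df_residual[j] <- nrow(dat) - qr_mm$rank
        resid[, j] <- stats::residuals(fm)
      }
      gamma[j, ] <- cf[colnames(gamma), 1L]
      gamma_se[j, ] <- cf[colnames(gamma), 2L]
      beta[j, ] <- cf[colnames(beta), 1L]
      beta_se[j, ] <- cf[colnames(beta), 2L]
    }
    method <- "mixed"
  }
  colnames(gamma) <- colnames(gamma_se) <- plates[-1L]
  structure(list(gamma = gamma, gamma_se = gamma_se,
                 beta = beta, beta_se = beta_se,
                 residuals = resid, df_residual = df_residual,
                 plates = plates, reference = plates[1L],
                 terms = terms, method = method),
            class = "bbea_plate_fit")
}

factor_or_numeric <- function(x, name) {
  if (is.numeric(x)) return(x)
  f <- factor(x)
  if (nlevels(f) < 2L) {
    stop("model term '", name, "' has a single level", call. = FALSE)
  }
  f
}

#' @export
print.bbea_plate_fit <- function(x, ...) {
  cat("<bbea_plate_fit> ", nrow(x$gamma), " epitopes, plates: ",
      paste(x$plates, collapse = ", "), " (reference ", x$reference, "), ",
      x$method, " fit\n", sep = "")
  cat("  mean |plate effect| per plate:\n")
  print(round(colMeans(abs(x$gamma)), 4))
  invisible(x)
}

#' Subtract estimated plate effects
#'
#' Removes the estimated batch shift from each well/sample:
#' `b* = b - gamma_hat[plate]` per epitope. Only the plate coefficients are
#' subtracted — experimental-factor effects stay in the data — and adjusted
#' values are deliberately left unfloored, so within-plate contrasts are
#' untouched and reference-plate rows are returned unchanged.
#'
#' @param binding a `bbea_binding`.
#' @param fit a `bbea_plate_fit` estimated on the same plates and epitopes.
#' @return the adjusted `bbea_binding` (attribute `plate_adjusted = TRUE`).
#' @export
remove_plate_effects <- function(binding, fit) {
  stopifnot(inherits(binding, "bbea_binding"), inherits(fit, "bbea_plate_fit"))
  plate <- as.character(binding$meta$plate)
  unseen <- setdiff(unique(plate), fit$plates)
  if (length(unseen)) {
    stop("plate(s) not seen at fit time: ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  if (!all(colnames(binding$b) %in% rownames(fit$gamma))) {
    stop("fit lacks epitope(s) present in binding", call. = FALSE)
  }
  shift <- matrix(0, nrow(binding$b), ncol(binding$b),
                  dimnames = dimnames(binding$b))
  for (p in colnames(fit$gamma)) {
    rows <- plate == p
    if (any(rows)) {
      shift[rows, ] <- matrix(fit$gamma[colnames(binding$b), p],
                              sum(rows), ncol(binding$b), byrow = TRUE)
    }
  }
  binding$b <- binding$b - shift
  attr(binding, "plate_adjusted") <- TRUE
  binding
}

#' Well-position diagnostic model
#'
#' Estimates a coefficient for each of the 95 non-reference wells (reference
#' A1) jointly with sample and plate effects, for designs in which technical
#' replicates were randomized across well positions. The output is ordered by
#' reading index (A1..A12, B1.., .., H12) so row/column/acquisition-order
#' trends are visible. This is a diagnostic: well coefficients are never
#' subtracted from the data.
#'
#' @param binding a well-level `bbea_binding` from a replicate-randomized
#'   design spanning >= 2 plates (each well position must be observed more
#'   than once to be separable from residual noise).
#' @param conf_level confidence level for the intervals, default 0.95.
#' @return a `bbea_well_fit` data.frame: epitope, well, reading_index,
#'   estimate, se, ci_low, ci_high.
#' @export
fit_well_effects <- function(binding, conf_level = 0.95) {
  stopifnot(inherits(binding, "bbea_binding"))
  if (binding$level != "well") stop("need well-level binding", call. = FALSE)
  meta <- binding$meta
  wells_present <- unique(meta$well)
  ref <- wells_present[which.min(reading_index(wells_present))]
  dat <- data.frame(
    well = factor(meta$well,
                  levels = wells_present[order(reading_index(wells_present))]),
    sample = factor(meta$sample),
    plate = factor(meta$plate))
  rhs <- if (nlevels(dat$plate) > 1L) "sample + plate + well" else "sample + well"
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), dat)
  qr_mm <- qr(mm)
  df <- nrow(mm) - qr_mm$rank
  if (qr_mm$rank < ncol(mm) || df < 1L) {
    stop("well effects are confounded: each well must host replicated ",
         "samples across plates to be estimable", call. = FALSE)
  }
  fit <- stats::lm.fit(mm, binding$b)
  s2 <- colSums(as.matrix(fit$residuals)^2) / df
  xtx_inv <- chol2inv(chol(crossprod(mm)))
  se_unit <- sqrt(diag(xtx_inv))
  coefs <- as.matrix(fit$coefficients)
  is_well <- grepl("^well", rownames(coefs))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  out <- do.call(rbind, lapply(colnames(binding$b), function(e) {
    est <- coefs[is_well, e]
    se <- se_unit[is_well] * sqrt(s2[e])
    wl <- sub("^well", "", rownames(coefs)[is_well])
    data.frame(epitope = e, well = wl, reading_index = reading_index(wl),
               estimate = est, se = se,
               ci_low = est - tq * se, ci_high = est + tq * se,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out <- out[order(out$epitope, out$reading_index), ]
  rownames(out) <- NULL
  structure(out, reference_well = ref, df = df,
            class = c("bbea_well_fit", "data.frame"))
}

#' Principal variance component analysis (PVCA)
#'
#' Attributes overall variance to experimental factors by (1) eigen-
#' decomposing the between-unit correlation matrix of the epitope-centered
#' binding matrix, (2) keeping the smallest set of leading principal
#' components whose cumulative eigenvalue share reaches `pc_threshold`,
#' (3) regressing each retained PC on random intercepts for every factor,
#' (4) normalizing the variance components (negatives truncated at zero,
#' residual included) into proportions per PC, and (5) averaging the
#' proportions across PCs with eigenvalue weights. The result, the weighted
#' average proportion variance (WAPV), sums to one across factors plus
#' residual.
#'
#' @param binding a `bbea_binding`, or a units x epitopes numeric matrix.
#' @param factors character vector of meta column names (when `binding` is a
#'   `bbea_binding`), or a data.frame of factors aligned with the matrix rows.
#' @param pc_threshold cumulative eigenvalue-proportion threshold, default
#'   0.8.
#' @param interactions if TRUE, add pairwise interaction random effects.
#' @param use_cor use the correlation (TRUE, default) or covariance matrix of
#'   the centered data for the PCA step.
#' @return a `bbea_pvca`: `wapv` (named proportions incl. "residual"),
#'   `per_pc` proportions matrix, `eigenvalues`, `n_pcs`, `pc_threshold`.
#' @export
pvca <- function(binding, factors, pc_threshold = 0.8, interactions = FALSE,
                 use_cor = TRUE) {
  if (inherits(binding, "bbea_binding")) {
    X <- binding$b
    fdat <- binding$meta[, factors, drop = FALSE]
  } else {
    X <- as.matrix(binding)
    fdat <- as.data.frame(factors)
    factors <- names(fdat)
  }
  keep <- vapply(factors, function(f) length(unique(fdat[[f]])) > 1L, TRUE)
  if (!all(keep)) {
    warning("dropping single-level factor(s): ",
            paste(factors[!keep], collapse = ", "), call. = FALSE)
    factors <- factors[keep]
  }
  if (!length(factors)) stop("no usable factors for PVCA", call. = FALSE)
  fdat <- data.frame(lapply(fdat[, factors, drop = FALSE], factor))

  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- if (use_cor) stats::cor(t(Xc)) else stats::cov(t(Xc))
  ev <- eigen(S, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  prop <- lambda / sum(lambda)
  n_pcs <- which(cumsum(prop) >= pc_threshold)[1L]
  scores <- ev$vectors[, seq_len(n_pcs), drop = FALSE]

  terms <- paste0("(1 | ", factors, ")")
  if (interactions && length(factors) > 1L) {
    pairs <- utils::combn(factors, 2L)
    terms <- c(terms, apply(pairs, 2L, function(p) {
      paste0("(1 | ", p[1L], ":", p[2L], ")")
    }))
  }
  form <- stats::as.formula(paste(".pc ~", paste(terms, collapse = " + ")))
  comp_names <- c(factors,
                  if (interactions && length(factors) > 1L) {
                    apply(utils::combn(factors, 2L), 2L, paste, collapse = ":")
                  }, "residual")
  per_pc <- matrix(0, n_pcs, length(comp_names),
                   dimnames = list(paste0("PC", seq_len(n_pcs)), comp_names))
  for (i in seq_len(n_pcs)) {
    d <- fdat
    d$.pc <- scores[, i]
    fm <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fm))
    v <- stats::setNames(pmax(vc$vcov, 0),
                         ifelse(vc$grp == "Residual", "residual", vc$grp))
    per_pc[i, names(v)] <- v
    per_pc[i, ] <- per_pc[i, ] / sum(per_pc[i, ])
  }
  w <- lambda[seq_len(n_pcs)] / sum(lambda[seq_len(n_pcs)])
  wapv <- colSums(per_pc * w)
  structure(list(wapv = wapv, per_pc = per_pc,
                 eigenvalues = lambda, n_pcs = n_pcs,
                 pc_threshold = pc_threshold),
            class = "bbea_pvca")
}

#' @export
print.bbea_pvca <- function(x, ...) {
  cat("<bbea_pvca> ", x$n_pcs, " PC(s) at threshold ", x$pc_threshold,
      "; weighted average proportion variance:\n", sep = "")
  print(round(x$wapv, 4))
  invisible(x)
}
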