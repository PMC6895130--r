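#' Configuration for a synthetic BBEA experiment
#'
#' Encodes the additive log2-scale generative model the pipeline assumes:
#' latent signal `Y = nsb_mean + reactivity * (mu_j + a_i + Delta_j * g_i)
#' + gamma_plate + omega_well + eps`, with `a_i ~ N(0, sample_sd)` the
#' biological sample effect and `eps ~ N(0, noise_sd)` replicate noise;
#' `MFI = max(0, 2^Y - 0.5)` rounded to instrument precision. Buffer-only
#' NSB wells carry only `nsb_mean` plus noise; the plate shift is applied to
#' serum wells, so NSB subtraction does not absorb the batch effect.
#'
#' @param n_samples number of distinct samples.
#' @param n_epitopes epitopes on the bead panel (default 50, a peanut-style
#'   library; use 66 for a milk-style one).
#' @param n_replicates technical replicates per sample, default 3.
#' @param n_plates number of plates; capacity is checked.
#' @param plate_effects numeric length `n_plates`, additive log2 plate
#'   shifts (first entry is the reference and should be 0).
#' @param well_effects numeric length 96 in reading order, default zeros.
#' @param group optional sample group assignment (length `n_samples`);
#'   NULL for none.
#' @param group_effects per-epitope log2 effect `Delta_j` added to group-2
#'   samples (scalar or length `n_epitopes`).
#' @param mu per-epitope mean reactive signal above background (log2);
#'   default evenly spaced on [3, 8] so the panel spans weak to strong
#'   binders.
#' @param reactivity per-sample multiplier in [0, 1] on the biological
#'   signal (0 = non-reactive control whose wells sit at background).
#' @param sample_sd SD of the scalar biological sample effect, default 1.
#' @param profile_sd SD of the sample-by-epitope interaction (each sample's
#'   own binding profile, the biologically meaningful signal), default 0.5.
#' @param noise_sd replicate (residual) noise SD, default 0.3.
#' @param noise_df if finite, draw noise from a scaled t with this df
#'   (heavy-tailed option); Inf (default) gives Normal noise.
#' @param nsb_mean,nsb_sd log2 background level and its SD (defaults 1 and
#'   0.2, i.e. background MFI near 1.5).
#' @param bead_mean,bead_dispersion negative-binomial bead-count mean
#'   (default 50) and size parameter.
#' @param n_nsb_wells NSB wells per plate, default 3.
#' @param randomize_wells if TRUE, scatter all replicates randomly across
#'   the available wells of all plates (the completely randomized layout
#'   used for well-effect diagnostics); default keeps a sample's replicates
#'   in adjacent wells on one plate.
#' @param allocation `"blocked"` (randomized, group-balanced) or
#'   `"confounded"` (samples assigned to plates in group order, to exercise
#'   the confounding error path).
#' @param round_mfi round MFI to integers (instrument-like), default TRUE.
#' @param seed integer seed; mandatory, all randomness flows through it.
#' @return a `bbea_sim_config` list.
#' @export
sim_config <- function(n_samples = 24, n_epitopes = 50, n_replicates = 3,
                       n_plates = 1,
                       plate_effects = rep(0, n_plates),
                       well_effects = rep(0, 96),
                       group = NULL, group_effects = 0,
                       mu = seq(3, 8, length.out = n_epitopes),
                       reactivity = rep(1, n_samples),
                       sample_sd = 1, profile_sd = 0.5,
                       noise_sd = 0.3, noise_df = Inf,
                       nsb_mean = 1, nsb_sd = 0.2,
                       bead_mean = 50, bead_dispersion = 20,
                       n_nsb_wells = 3, randomize_wells = FALSE,
                       allocation = c("blocked", "confounded"),
                       round_mfi = TRUE, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility", call. = FALSE)
  allocation <- match.arg(allocation)
  if (length(plate_effects) != n_plates) {
    stop("plate_effects must have length n_plates", call. = FALSE)
  }
  if (length(well_effects) != 96) {
    stop("well_effects must have length 96 (reading order)", call. = FALSE)
  }
  if (length(mu) != n_epitopes) stop("mu must have length n_epitopes", call. = FALSE)
  if (length(reactivity) != n_samples) {
    stop("reactivity must have length n_samples", call. = FALSE)
  }
  if (!is.null(group) && length(group) != n_samples) {
    stop("group must have length n_samples", call. = FALSE)
  }
  if (length(group_effects) == 1L) group_effects <- rep(group_effects, n_epitopes)
  if (length(group_effects) != n_epitopes) {
    stop("group_effects must be scalar or length n_epitopes", call. = FALSE)
  }
  if (any(c(sample_sd, profile_sd, noise_sd, nsb_sd) < 0)) {
    stop("SDs must be non-negative", call. = FALSE)
  }
  capacity <- (96 - n_nsb_wells) %/% n_replicates * n_plates
  if (n_samples > capacity) {
    stop("layout needs ", n_samples, " samples but ", n_plates,
         " plate(s) hold at most ", capacity, call. = FALSE)
  }
  structure(as.list(environment()), class = "bbea_sim_config")
}

rnoise <- function(n, sd, df) {
  if (is.infinite(df)) stats::rnorm(n, 0, sd)
  else stats::rt(n, df) * sd / sqrt(df / (df - 2))
}

# Allocate samples to plates. Blocked: shuffle within each group and deal its
# members round-robin across plates, so every group is balanced over plates.
# Confounded: fill plates in group order (deliberately pathological, to
# exercise the downstream confounding error).
allocate_plates <- function(cfg) {
  per_plate <- (96 - cfg$n_nsb_wells) %/% cfg$n_replicates
  ids <- seq_len(cfg$n_samples)
  plate_of <- integer(cfg$n_samples)
  if (cfg$allocation == "confounded" && !is.null(cfg$group)) {
    ord <- ids[order(cfg$group)]
    plate_of[ord] <- rep(seq_len(cfg$n_plates),
                         each = ceiling(cfg$n_samples / cfg$n_plates),
                         length.out = cfg$n_samples)
    return(plate_of)
  }
  grp <- if (is.null(cfg$group)) rep(1L, cfg$n_samples) else cfg$group
  start <- 0L
  for (g in split(ids, grp)) {
    gs <- if (length(g) > 1L) sample(g) else g
    plate_of[gs] <- 1L + (start + seq_along(gs) - 1L) %% cfg$n_plates
    start <- start + length(gs)
  }
  # round-robin keeps loads within one of each other, but re-check capacity
  load <- tabulate(plate_of, cfg$n_plates)
  while (any(load > per_plate)) {
    over <- which.max(load); under <- which.min(load)
    mv <- sample(which(plate_of == over), 1L)
    plate_of[mv] <- under
    load <- tabulate(plate_of, cfg$n_plates)
  }
  plate_of
}

#' Simulate a complete BBEA study
#'
#' Draws a study from the generative model in [sim_config()] and packages it
#' exactly as real data enter the pipeline: a list of plate objects (also
#' writable to the instrument export dialect), a study design, and the
#' realized ground truth for recovery checks.
#'
#' @param config a `bbea_sim_config`.
#' @param dir optional directory; when given, plate exports (`plateN.csv`),
#'   `design.csv` and `truth.json` are written there.
#' @return list with `plates` (list of `bbea_plate`), `design`
#'   (`bbea_design`), and `truth` (gamma, omega, delta, mu, sample_effects,
#'   group, plate_of, latent `y` per plate).
#' @export
simulate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "bbea_sim_config"))
  cfg <- config
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))

  epi <- sprintf("ep%02d", seq_len(cfg$n_epitopes))
  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  a <- stats::rnorm(cfg$n_samples, 0, cfg$sample_sd)
  profile <- matrix(stats::rnorm(cfg$n_samples * cfg$n_epitopes,
                                 0, cfg$profile_sd),
                    cfg$n_samples, cfg$n_epitopes,
                    dimnames = list(sample_ids, epi))
  g <- if (is.null(cfg$group)) rep(0, cfg$n_samples) else {
    as.integer(factor(cfg$group)) - 1L
  }
  plate_of <- allocate_plates(cfg)
  wl <- well_labels()

  # per-plate well layout
  layouts <- vector("list", cfg$n_plates)
  if (cfg$randomize_wells) {
    slots <- do.call(rbind, lapply(seq_len(cfg$n_plates), function(p) {
      data.frame(plate = p, well = wl[seq_len(96 - cfg$n_nsb_wells)])
    }))
    need <- cfg$n_samples * cfg$n_replicates
    pick <- slots[sample(nrow(slots), need), ]
    assign_df <- data.frame(
      sample = rep(sample_ids, each = cfg$n_replicates),
      replicate = rep(seq_len(cfg$n_replicates), cfg$n_samples),
      plate = pick$plate, well = pick$well, stringsAsFactors = FALSE)
  } else {
    assign_df <- do.call(rbind, lapply(seq_len(cfg$n_samples), function(i) {
      data.frame(sample = sample_ids[i], replicate = seq_len(cfg$n_replicates),
                 plate = plate_of[i], well = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    for (p in seq_len(cfg$n_plates)) {
      rows <- which(assign_df$plate == p)
      assign_df$well[rows] <- wl[seq_along(rows)]  # adjacent, reading order
    }
  }
  nsb_df <- do.call(rbind, lapply(seq_len(cfg$n_plates), function(p) {
    data.frame(sample = "NSB", replicate = seq_len(cfg$n_nsb_wells),
               plate = p, well = wl[96 - cfg$n_nsb_wells + seq_len(cfg$n_nsb_wells)],
               stringsAsFactors = FALSE)
  }))
  if (cfg$randomize_wells) {
    # NSB wells must not collide with sampled slots
    taken <- paste(assign_df$plate, assign_df$well)
    stopifnot(!any(paste(nsb_df$plate, nsb_df$well) %in% taken))
  }
  all_df <- rbind(assign_df, nsb_df)

  plates <- vector("list", cfg$n_plates)
  y_store <- list()
  for (p in seq_len(cfg$n_plates)) {
    rows <- all_df[all_df$plate == p, ]
    n_w <- nrow(rows)
    y <- matrix(NA_real_, n_w, cfg$n_epitopes, dimnames = list(rows$well, epi))
    for (r in seq_len(n_w)) {
      w_idx <- reading_index(rows$well[r]) + 1L
      if (rows$sample[r] == "NSB") {
        y[r, ] <- cfg$nsb_mean + stats::rnorm(cfg$n_epitopes, 0, cfg$nsb_sd)
      } else {
        i <- match(rows$sample[r], sample_ids)
        signal <- cfg$mu + a[i] + profile[i, ] + cfg$group_effects * g[i]
        y[r, ] <- cfg$nsb_mean + cfg$reactivity[i] * signal +
          cfg$plate_effects[p] + cfg$well_effects[w_idx] +
          rnoise(cfg$n_epitopes, cfg$noise_sd, cfg$noise_df)
      }
    }
    mfi <- pmax(2^y - 0.5, 0)
    if (cfg$round_mfi) mfi <- round(mfi)
    counts <- matrix(stats::rnbinom(n_w * cfg$n_epitopes,
                                    mu = cfg$bead_mean,
                                    size = cfg$bead_dispersion),
                     n_w, cfg$n_epitopes, dimnames = dimnames(y))
    ord <- order(reading_index(rows$well))
    plates[[p]] <- structure(list(
      plate_id = paste0("plate", p),
      wells = data.frame(well = rows$well[ord], sample = rows$sample[ord],
                         reading_index = reading_index(rows$well[ord]),
                         stringsAsFactors = FALSE),
      mfi = mfi[ord, , drop = FALSE], counts = counts[ord, , drop = FALSE],
      missing = data.frame(well = character(0), absent_from = character(0))),
      class = "bbea_plate")
    y_store[[paste0("plate", p)]] <- y[ord, , drop = FALSE]
  }

  des <- data.frame(sample_id = all_df$sample,
                    plate_id = paste0("plate", all_df$plate),
                    well = all_df$well, replicate = all_df$replicate,
                    stringsAsFactors = FALSE)
  if (!is.null(cfg$group)) {
    des$group <- as.character(cfg$group)[match(all_df$sample, sample_ids)]
  }
  design <- as_design(des)

  truth <- list(gamma = cfg$plate_effects, omega = cfg$well_effects,
                delta = cfg$group_effects, mu = cfg$mu,
                sample_effects = stats::setNames(a, sample_ids),
                profile = profile,
                reactivity = stats::setNames(cfg$reactivity, sample_ids),
                group = if (is.null(cfg$group)) NULL else
                  stats::setNames(cfg$group, sample_ids),
                plate_of = stats::setNames(plate_of, sample_ids),
                y = y_store, seed = cfg$seed)
  study <- list(plates = plates, design = design, truth = truth)
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a simulated study to disk in the supported export dialect
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pl in study$plates) {
    write_plate_export(pl, file.path(dir, paste0(pl$plate_id, ".csv")))
  }
  utils::write.csv(as.data.frame(study$design)[
    setdiff(names(study$design), "is_nsb")],
    file.path(dir, "design.csv"), row.names = FALSE, quote = FALSE)
  truth <- study$truth
  truth$y <- NULL  # latent matrices stay in memory; files carry parameters
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate one study measured by several centers
#'
#' Shares one biological truth (sample effects, epitope means, groups)
#' across centers; each center re-runs the assay with its own additive shift
#' and fresh technical noise — the design used to separate consistency from
#' agreement in reproducibility analyses.
#'
#' @param config a `bbea_sim_config` (its seed drives the shared truth).
#' @param n_centers number of centers, default 3.
#' @param center_shifts additive log2 shift per center, default zeros.
#' @return named list of studies (one per center), each as from
#'   [simulate_study()]; centers differ only in shift and noise.
#' @export
simulate_multicenter <- function(config, n_centers = 3,
                                 center_shifts = rep(0, n_centers)) {
  stopifnot(inherits(config, "bbea_sim_config"))
  if (length(center_shifts) != n_centers) {
    stop("center_shifts must have length n_centers", call. = FALSE)
  }
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  a <- stats::rnorm(config$n_samples, 0, config$sample_sd)
  profile <- matrix(stats::rnorm(config$n_samples * config$n_epitopes,
                                 0, config$profile_sd),
                    config$n_samples, config$n_epitopes)
  out <- lapply(seq_len(n_centers), function(cc) {
    cfg <- config
    cfg$sample_sd <- 0                 # shared biology injected below
    cfg$profile_sd <- 0
    cfg$seed <- config$seed + 7919L * cc
    st <- simulate_study(cfg)
    add_sample_effects(st, cfg, a, profile, center_shifts[cc])
  })
  names(out) <- paste0("center", seq_len(n_centers))
  out
}

# Inject frozen sample effects/profiles and an additive center shift into the
# latent serum-well signal of a study generated without them, then rebuild MFI.
add_sample_effects <- function(st, cfg, a, profile, shift) {
  sample_ids <- names(st$truth$sample_effects)
  for (p in seq_along(st$plates)) {
    pl <- st$plates[[p]]
    y <- st$truth$y[[pl$plate_id]]
    for (r in seq_len(nrow(pl$mfi))) {
      s <- pl$wells$sample[r]
      if (s != "NSB") {
        i <- match(s, sample_ids)
        y[r, ] <- y[r, ] + cfg$reactivity[i] * (a[i] + profile[i, ]) + shift
      }
    }
    mfi <- pmax(2^y - 0.5, 0)
    if (cfg$round_mfi) mfi <- round(mfi)
    st$plates[[p]]$mfi <- mfi
    st$truth$y[[pl$plate_id]] <- y
  }
  st$truth$sample_effects[] <- a
  st$truth$profile <- profile
  st$truth$center_shift <- shift
  st
}

#' Simulate a paired detection experiment (positive pool vs negative control)
#'
#' Emulates the benchmarking design: a reactive positive pool (PP) and a
#' non-reactive negative control (NC) measured in paired replicates across
#' days, with a known set of truly reactive epitopes. Values are on the
#' binding-score scale.
#'
#' @param n_epitopes panel size.
#' @param n_pairs paired PP/NC replicates (e.g. 4 replicates x 2 days = 8).
#' @param delta true PP-minus-NC log2 effect (scalar or per epitope); 0
#'   makes an epitope a true negative.
#' @param noise_sd replicate noise SD, default 0.2.
#' @param day_shift additive batch shift applied to both PP and NC wells of
#'   the second half of the pairs (a day effect), default 0.
#' @param baseline NC-side mean binding, default 0.1 (near the zero floor).
#' @param seed integer seed.
#' @return list with matrices `pos` and `neg` (epitopes x pairs), `pairing`
#'   data.frame, `day` per pair, and `truth` (`delta`, `true_positive`).
#' @export
simulate_detection_experiment <- function(n_epitopes = 66, n_pairs = 8,
                                          delta = 1, noise_sd = 0.2,
                                          day_shift = 0, baseline = 0.1,
                                          seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (length(delta) == 1L) delta <- rep(delta, n_epitopes)
  stopifnot(length(delta) == n_epitopes)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  epi <- sprintf("ep%02d", seq_len(n_epitopes))
  day <- rep(1:2, each = ceiling(n_pairs / 2))[seq_len(n_pairs)]
  shift <- ifelse(day == 2L, day_shift, 0)
  pos <- matrix(baseline + delta, n_epitopes, n_pairs) +
    matrix(shift, n_epitopes, n_pairs, byrow = TRUE) +
    matrix(stats::rnorm(n_epitopes * n_pairs, 0, noise_sd), n_epitopes)
  neg <- matrix(baseline, n_epitopes, n_pairs) +
    matrix(shift, n_epitopes, n_pairs, byrow = TRUE) +
    matrix(stats::rnorm(n_epitopes * n_pairs, 0, noise_sd), n_epitopes)
  dimnames(pos) <- dimnames(neg) <- list(epi, paste0("rep", seq_len(n_pairs)))
  list(pos = pos, neg = neg,
       pairing = data.frame(pos = colnames(pos), neg = colnames(neg)),
       day = day,
       truth = list(delta = stats::setNames(delta, epi),
                    true_positive = stats::setNames(delta != 0, epi)))
}

#' Study presets
#'
#' Ready-made configurations mirroring the package's reference designs:
#' `"milk-oit"` (66 epitopes, 4 plates with moderate plate shifts),
#' `"multicenter"` (8 pooled samples of graded reactivity including one
#' non-reactive control, triplicates, 50 epitopes), and `"pp-nc"` is handled
#' by [simulate_detection_experiment()].
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a `bbea_sim_config`.
#' @export
sim_preset <- function(name = c("milk-oit", "multicenter"), seed) {
  name <- match.arg(name)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  switch(name,
    "milk-oit" = sim_config(
      n_samples = 60, n_epitopes = 66, n_replicates = 3, n_plates = 4,
      plate_effects = c(0, 0.5, -0.3, 0.8),
      group = rep(c("placebo", "treated"), length.out = 60),
      group_effects = c(rep(1, 10), rep(0, 56)),
      seed = seed),
    "multicenter" = sim_config(
      n_samples = 8, n_epitopes = 50, n_replicates = 3, n_plates = 1,
      reactivity = c(seq(1, 0.3, length.out = 7), 0),
      sample_sd = 0.5, seed = seed))
}
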