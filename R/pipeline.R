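pipeline_stage_order <- c("quantify", "adjust", "pvca", "icc", "detect", "diff")

#' Run the BBEA pipeline end to end
#'
#' Orchestrates the stages in their fixed order — quantify (with bead-count
#' QC and NSB normalization), plate adjustment, then any of PVCA, ICC and
#' detection — recording every input, seed and output in a run manifest so a
#' rerun with the same configuration reproduces the outputs byte for byte.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{seed}{integer; drives any simulation stage.}
#'     \item{simulate}{optional: `list(preset = "multicenter"|"milk-oit")` or
#'       a full [sim_config()] argument list; generates the inputs.}
#'     \item{inputs}{alternatively: `list(plates = <paths>, design = <path>,
#'       library = <path>)`.}
#'     \item{stages}{character vector of stages after quantify, in order;
#'       subset of `c("adjust", "pvca", "icc", "detect")`. Listing them out
#'       of order, or a stage that needs an earlier one you omitted, is a
#'       validation error.}
#'     \item{bead_threshold, nsb}{quantify options.}
#'     \item{adjust}{`list(terms = NULL, random_subject = NULL)`.}
#'     \item{pvca}{`list(factors = c(...), pc_threshold = 0.8)`.}
#'     \item{icc}{`list(type = "agreement")`.}
#'     \item{out_dir}{where outputs and the manifest are written.}
#'   }
#' @return a `bbea_manifest` list: config snapshot, input hashes, package
#'   version, seed, per-stage status, output paths, and the in-memory stage
#'   results in `$results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% "adjust"
  bad <- setdiff(stages, pipeline_stage_order)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(match(stages, pipeline_stage_order))) {
    stop("stages out of order; required order is ",
         paste(pipeline_stage_order, collapse = " -> "), call. = FALSE)
  }
  out_dir <- config$out_dir %||% tempfile("bbea_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("bbea")),
                   seed = config$seed, config = config,
                   stages = list(), outputs = list(), input_hashes = list())
  results <- list()
  record <- function(name, status) {
    manifest$stages[[name]] <<- status
  }

  # inputs
  if (!is.null(config$simulate)) {
    if (is.null(config$seed)) stop("simulate stage needs a seed", call. = FALSE)
    sim <- config$simulate
    cfg <- if (!is.null(sim$preset)) {
      sim_preset(sim$preset, seed = config$seed)
    } else {
      do.call(sim_config, c(sim, list(seed = config$seed)))
    }
    study <- simulate_study(cfg)
    plates <- study$plates; design <- study$design
    results$truth <- study$truth
    record("simulate", "ok")
  } else if (!is.null(config$inputs)) {
    library_tab <- if (!is.null(config$inputs$library)) {
      read_epitope_library(config$inputs$library)
    }
    plates <- lapply(config$inputs$plates, read_plate_export,
                     library = library_tab)
    design <- read_design(config$inputs$design)
    manifest$input_hashes <- as.list(tools::md5sum(
      c(unlist(config$inputs$plates), config$inputs$design)))
    record("read", "ok")
  } else {
    stop("config needs either 'simulate' or 'inputs'", call. = FALSE)
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      record(name, paste("failed:", conditionMessage(e)))
      manifest$results <- results
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  binding <- run_stage("quantify", {
    b <- quantify(plates, design,
                  bead_threshold = config$bead_threshold %||% 30,
                  nsb = config$nsb %||% TRUE)
    record("quantify", "ok")
    b
  })
  results$binding <- binding
  write_matrix <- function(m, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(round(m, 10), path, quote = FALSE)
    manifest$outputs[[file]] <<- path
    path
  }
  write_matrix(binding$b, "binding.csv")
  qc_list <- list(threshold = binding$qc$threshold,
                  excluded_wells = binding$qc$excluded_wells,
                  excluded_samples = binding$qc$excluded_samples)
  jsonlite::write_json(qc_list, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$outputs[["qc.json"]] <- file.path(out_dir, "qc.json")

  if ("adjust" %in% stages) {
    fit <- run_stage("adjust", {
      f <- fit_plate_model(binding, terms = config$adjust$terms,
                           random_subject = config$adjust$random_subject)
      record("adjust", "ok")
      f
    })
    results$plate_fit <- fit
    binding_adj <- remove_plate_effects(binding, fit)
    results$binding_adjusted <- binding_adj
    write_matrix(binding_adj$b, "binding_adjusted.csv")
  }

  if ("pvca" %in% stages) {
    results$pvca <- run_stage("pvca", {
      factors <- config$pvca$factors %||% "plate"
      pv <- pvca(binding, factors,
                 pc_threshold = config$pvca$pc_threshold %||% 0.8)
      record("pvca", "ok")
      pv
    })
    jsonlite::write_json(as.list(results$pvca$wapv),
                         file.path(out_dir, "pvca.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$outputs[["pvca.json"]] <- file.path(out_dir, "pvca.json")
  }

  if ("icc" %in% stages) {
    results$icc <- run_stage("icc", {
      r <- replicate_reliability(binding,
                                 type = config$icc$type %||% "agreement")
      record("icc", "ok")
      r
    })
    utils::write.csv(results$icc, file.path(out_dir, "icc.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest$outputs[["icc.csv"]] <- file.path(out_dir, "icc.csv")
  }

  if ("detect" %in% stages || "diff" %in% stages) {
    results$differential <- run_stage("detect", {
      avg <- replicate_average(binding)
      d <- differential_binding(avg, config$detect$group %||% "group")
      record("detect", "ok")
      d
    })
    utils::write.csv(results$differential, file.path(out_dir, "detect.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest$outputs[["detect.csv"]] <- file.path(out_dir, "detect.csv")
  }

  manifest$results <- results
  snap <- manifest[c("package_version", "seed", "stages", "input_hashes")]
  snap$outputs <- names(manifest$outputs)
  jsonlite::write_json(snap, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$out_dir <- out_dir
  structure(manifest, class = "bbea_manifest")
}

#' Human-readable pipeline summary
#'
#' @param manifest a `bbea_manifest` from [run_pipeline()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
summary_report <- function(manifest) {
  stopifnot(inherits(manifest, "bbea_manifest"))
  r <- manifest$results
  lines <- c(
    sprintf("BBEA pipeline run (package %s, seed %s)",
            manifest$package_version, manifest$seed %||% "none"),
    sprintf("stages: %s",
            paste(names(manifest$stages),
                  unlist(manifest$stages), sep = "=", collapse = ", ")))
  if (!is.null(r$binding)) {
    qc <- r$binding$qc
    lines <- c(lines,
      sprintf("QC: %d/%d wells pass bead-count threshold %s; excluded: %s",
              sum(qc$keep), length(qc$keep), qc$threshold,
              if (length(qc$excluded_wells)) {
                paste(qc$excluded_wells, collapse = ", ")
              } else "none"))
  }
  if (!is.null(r$plate_fit)) {
    m <- colMeans(abs(r$plate_fit$gamma))
    lines <- c(lines, sprintf("plate effects (mean |gamma|): %s",
                              paste(names(m), round(m, 3), sep = "=",
                                    collapse = ", ")))
  }
  if (!is.null(r$pvca)) {
    lines <- c(lines, sprintf("PVCA WAPV: %s",
                              paste(names(r$pvca$wapv),
                                    round(r$pvca$wapv, 4), sep = "=",
                                    collapse = ", ")))
  }
  if (!is.null(r$icc)) {
    lines <- c(lines, sprintf("ICC: mean %.3f; bands: %s",
                              attr(r$icc, "mean_icc"),
                              paste(r$icc$band, collapse = ", ")))
  }
  if (!is.null(r$differential)) {
    lines <- c(lines, sprintf("differential binding: %d/%d significant",
                              sum(r$differential$detected),
                              nrow(r$differential)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.bbea_manifest <- function(x, ...) {
  summary_report(x)
  invisible(x)
}
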