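#' Write a kinetic dataset as tidy CSV
#'
#' Columns: `compound`, `ph`, `replicate`, `time_min`, `channel`,
#' `peak_area`. A sidecar JSON (`<path>.json`) records the experiment
#' descriptor, the noise settings and the generating truth when present.
#'
#' @param dataset a `kinetic_dataset`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  obs <- dataset$observations
  out <- data.frame(compound = dataset$compound, ph = dataset$ph,
                    replicate = obs$replicate, time_min = obs$time_min,
                    channel = obs$channel, peak_area = obs$peak_area)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  d <- dataset$descriptor
  side <- list(descriptor = list(
    s0 = d$s0, eqv = d$eqv, mode = d$mode, t_max = d$t_max,
    sample_times = d$sample_times, n_replicates = d$n_replicates,
    response_scale = d$response_scale))
  if (!is.null(dataset$truth))
    side$truth <- c(dataset$truth,
                    list(variant = attr(dataset$truth, "variant")))
  if (!is.null(dataset$noise))
    side$noise <- dataset$noise[c("cv", "floor", "seed")]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a kinetic dataset from tidy CSV
#'
#' Expects the column layout of [write_dataset()]. Validation rejects
#' missing columns, negative peak areas and duplicated
#' (replicate, time, channel) rows, naming the offending rows. When no
#' descriptor is supplied and no sidecar JSON is found, a descriptor is
#' reconstructed from the observed sampling grid (`s0` from the earliest
#' mean area, continuous dosing with 10 equivalents over the last sample
#' time).
#'
#' @param path CSV file path.
#' @param descriptor optional [experiment_descriptor()] override.
#' @return A `kinetic_dataset` (with `truth` when the sidecar records it).
#' @export
read_dataset <- function(path, descriptor = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("compound", "ph", "replicate", "time_min", "channel",
              "peak_area")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(raw)) stop("dataset contains no observations", call. = FALSE)
  bad <- which(!is.finite(raw$peak_area) | raw$peak_area < 0)
  if (length(bad))
    stop("negative or non-finite peak areas at rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  key <- paste(raw$replicate, raw$time_min, raw$channel)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (replicate, time, channel) rows at rows ",
         paste(dup, collapse = ", "), call. = FALSE)
  truth <- NULL
  noise <- NULL
  sidecar <- paste0(path, ".json")
  if (is.null(descriptor) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    d <- side$descriptor
    descriptor <- experiment_descriptor(
      s0 = d$s0, eqv = d$eqv, mode = d$mode, t_max = d$t_max,
      sample_times = d$sample_times, n_replicates = d$n_replicates,
      response_scale = d$response_scale)
    if (!is.null(side$truth)) {
      tr <- side$truth
      truth <- if (identical(tr[["variant"]], "extended"))
        rate_constants(as.numeric(tr[["k1"]]), as.numeric(tr[["k2"]]),
                       as.numeric(tr[["k3"]]), as.numeric(tr[["k4"]]))
      else rate_constants(as.numeric(tr[["k1"]]), as.numeric(tr[["k2"]]),
                          as.numeric(tr[["k3"]]))
    }
  }
  if (is.null(descriptor)) {
    times <- sort(unique(raw$time_min))
    descriptor <- experiment_descriptor(
      s0 = mean(raw$peak_area[raw$time_min == times[1] &
                                raw$channel == "substrate"]),
      eqv = 10, mode = "continuous", t_max = max(times) * 60,
      sample_times = times,
      n_replicates = length(unique(raw$replicate)), response_scale = 1)
  }
  obs <- raw[order(raw$channel, raw$replicate, raw$time_min),
             c("replicate", "time_min", "channel", "peak_area")]
  rownames(obs) <- NULL
  structure(list(compound = raw$compound[1], ph = as.character(raw$ph[1]),
                 descriptor = descriptor, observations = obs,
                 truth = truth, noise = noise),
            class = "kinetic_dataset")
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror [run_pipeline()] arguments: `dataset` (path) or
#' `generate` (truth constants + noise), `out_dir`, `seed`, `n_draws`,
#' `refine_s0`, `n_starts`, and an optional `clearance` block
#' (`cl`, `cl_unit`).
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Run the pipeline from a configuration list
#'
#' Convenience wrapper mapping a configuration (typically from
#' [read_run_config()]) onto [run_pipeline()]: `dataset` names the input
#' CSV; `generate` (with `truth` = list of rate constants and optional
#' `cv`, `noise_seed`) synthesizes one instead; remaining fields pass
#' through.
#'
#' @param config named list, see [read_run_config()].
#' @return The [run_pipeline()] result.
#' @export
run_from_config <- function(config) {
  dataset <- if (!is.null(config$dataset)) read_dataset(config$dataset)
  else if (!is.null(config$generate)) {
    g <- config$generate
    tr <- g$truth
    params <- if (!is.null(tr$k4))
      rate_constants(tr$k1, tr$k2, tr$k3, tr$k4)
    else rate_constants(tr$k1, tr$k2, tr$k3)
    generate_dataset(params, default_design(),
                     noise_model(cv = if (is.null(g$cv)) 0.05 else g$cv,
                                 seed = if (is.null(g$noise_seed)) 1L
                                 else g$noise_seed))
  } else stop("config needs either a dataset path or a generate block",
              call. = FALSE)
  run_pipeline(dataset,
               out_dir = config$out_dir,
               seed = if (is.null(config$seed)) 1L else config$seed,
               n_draws = if (is.null(config$n_draws)) 100 else config$n_draws,
               n_starts = if (is.null(config$n_starts)) 16 else
                 config$n_starts,
               refine_s0 = isTRUE(config$refine_s0),
               cl = config$clearance$cl,
               cl_unit = if (is.null(config$clearance$cl_unit)) "L_h_kg"
               else config$clearance$cl_unit)
}

#' Run the full analysis pipeline on one dataset
#'
#' Fits the standard and extended model variants, applies the parsimony
#' model-selection rule, computes diagnostics, Wald intervals and Monte
#' Carlo trajectory bands for the selected fit, evaluates the steady-state
#' exclusion rule, and (when a literature clearance is supplied) the
#' normalized k2/CL record. All tabular outputs are written under
#' `out_dir` together with a JSON manifest recording the seed, options and
#' stage status; rerunning with the same inputs and seed reproduces
#' identical numbers.
#'
#' @param dataset a `kinetic_dataset` (e.g. from [read_dataset()] or
#'   [generate_dataset()]).
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed global seed for multistart draws and Monte Carlo bands.
#' @param n_draws Monte Carlo draws; 0 skips the bands stage.
#' @param n_starts multistart count for each variant fit.
#' @param refine_s0 refine the initial response after fitting.
#' @param cl,cl_unit optional literature intrinsic clearance for the
#'   normalization stage.
#' @return List of class `pipeline_result`: `fit_standard`, `fit_extended`,
#'   `selection`, `fit` (the selected one), `diagnostics`, `wald`,
#'   `bands` (or NULL), `steady_state`, `clearance` (or NULL), `manifest`.
#' @export
run_pipeline <- function(dataset, out_dir = NULL, seed = 1L, n_draws = 100,
                         n_starts = 16, refine_s0 = FALSE,
                         cl = NULL, cl_unit = "L_h_kg") {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  stages <- list()
  both <- fit_both_variants(dataset,
                            fit_options(n_starts = n_starts, seed = seed,
                                        refine_s0 = refine_s0))
  fit_std <- both$standard
  fit_ext <- both$extended
  stages$fit <- "ok"
  # an unconverged variant defers selection; the pipeline then proceeds
  # with the parsimonious standard model and records the deferral
  selection <- tryCatch(select_model(fit_std, fit_ext), error = function(e)
    list(variant = "standard", aic_standard = NA_real_,
         aic_extended = NA_real_, k4_flux_fraction = NA_real_,
         rationale = paste("selection deferred:", conditionMessage(e))))
  fit <- if (selection$variant == "extended") fit_ext else fit_std
  stages$selection <- paste0(selection$variant,
                             if (grepl("deferred", selection$rationale))
                               " (deferred)" else "")
  diagnostics <- diagnostics_report(fit)
  wald <- if (fit$converged) wald_ci(fit) else NULL
  stages$diagnostics <- "ok"
  bands <- NULL
  if (n_draws > 0) {
    bands <- tryCatch(monte_carlo_bands(fit, n_draws = n_draws, seed = seed),
                      error = function(e) e)
    if (inherits(bands, "error")) {
      stages$bands <- paste("failed:", conditionMessage(bands))
      bands <- NULL
    } else stages$bands <- "ok"
  } else stages$bands <- "skipped: n_draws = 0"
  fd <- .fit_descriptor(dataset$descriptor, fit$s0_fit)
  traj <- integrate_kinetics(fit$estimates, fd)
  steady <- steady_state_check(traj, fit$estimates)
  clearance <- NULL
  if (!is.null(cl)) {
    clearance <- clearance_record(dataset$compound, dataset$ph,
                                  k2 = fit$estimates$k2, cl = cl,
                                  cl_unit = cl_unit, traj = traj)
    stages$clearance <- "ok"
  } else stages$clearance <- "skipped: no clearance supplied"
  manifest <- list(
    package_version = as.character(utils::packageVersion("mimoxkin")),
    seed = seed, n_starts = n_starts, n_draws = n_draws,
    refine_s0 = refine_s0, compound = dataset$compound, ph = dataset$ph,
    selected_variant = selection$variant, stages = stages,
    config_hash = .config_hash(list(seed, n_starts, n_draws, refine_s0,
                                    dataset$compound, dataset$ph)))
  result <- structure(list(fit_standard = fit_std, fit_extended = fit_ext,
                           selection = selection, fit = fit,
                           diagnostics = diagnostics, wald = wald,
                           bands = bands, steady_state = steady,
                           clearance = clearance, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(result, traj, out_dir)
  result
}

# Deterministic short hash of the run configuration (no wall clock, no
# locale): sum of byte values of the serialized config, base36.
.config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, ascii = TRUE))
  sprintf("%08x", sum(bytes * seq_along(bytes)) %% .Machine$integer.max)
}

.write_pipeline_outputs <- function(result, traj, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- result$fit
  report <- list(
    variant = fit$variant,
    estimates = unlist(fit$estimates),
    log_se = as.list(fit$log_se),
    covariance = unclass(fit$covariance),
    ssr = fit$ssr, n_obs = fit$n_obs, n_params = fit$n_params,
    s0_fit = fit$s0_fit, converged = fit$converged,
    aic = result$diagnostics$aic, r2_adj = result$diagnostics$r2_adj,
    identifiability_warning = fit$identifiability_warning,
    seed = result$manifest$seed, config_hash = result$manifest$config_hash)
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$diagnostics$standardized_residuals,
                   file.path(out_dir, "residuals.csv"), row.names = FALSE)
  if (!is.null(result$wald))
    utils::write.csv(result$wald, file.path(out_dir, "wald_ci.csv"),
                     row.names = FALSE)
  write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
  if (!is.null(result$bands))
    write_bands(result$bands, file.path(out_dir, "bands.csv"))
  if (!is.null(result$clearance))
    utils::write.csv(result$clearance, file.path(out_dir, "clearance.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result: selected", x$selection$variant, "model\n")
  print(x$fit)
  invisible(x)
}
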