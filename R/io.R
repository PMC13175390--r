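#' Read and write parameter sets
#'
#' Parameter sets serialize to flat YAML: one key per parameter plus the
#' `circadian_enabled` switch, with a `category` sidecar block mapping
#' each parameter to its evidence category. The bundled
#' `extdata/parameters/baseline.yaml` reproduces the default set exactly.
#'
#' @param params A `fotsim_params` object.
#' @param path File path.
#' @return `read_parameters()` returns a validated `fotsim_params`;
#'   `write_parameters()` returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  vals <- params[parameter_names(params)]
  doc <- list(parameters = vals,
              circadian_enabled = isTRUE(params$circadian_enabled),
              category = as.list(parameter_categories(params)))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  doc <- yaml::read_yaml(path)
  p <- doc$parameters
  p$circadian_enabled <- isTRUE(doc$circadian_enabled)
  attr(p, "categories") <- unlist(doc$category)
  validate_parameters(p)
}

#' Read and write patient profiles and treatment protocols
#'
#' Profiles and protocols serialize to the same flat YAML dialect. The
#' bundled `extdata/profiles/*.yaml` and `extdata/protocols/*.yaml`
#' reproduce the study's four profiles and five protocols; objects
#' round-trip losslessly.
#'
#' @param profile A `fotsim_profile`.
#' @param protocol A `fotsim_protocol`.
#' @param path File path.
#' @name protocol_io
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(unclass(profile), path, precision = 15)
  invisible(path)
}

#' @rdname protocol_io
#' @export
read_profile <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- patient_profile(doc$name)
  out <- structure(doc[names(known)], class = "fotsim_profile")
  out
}

#' @rdname protocol_io
#' @export
write_protocol <- function(protocol, path) {
  doc <- list(
    name = protocol$name,
    resistance_multiplier = protocol$resistance_multiplier,
    schedules = lapply(protocol$schedules, unclass),
    hyperthermia = if (is.null(protocol$hyperthermia)) NULL else
      unclass(protocol$hyperthermia)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname protocol_io
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  sched <- lapply(doc$schedules, function(s) {
    do.call(dose_schedule, s[c("drug_type", "kind", "treatment_days",
                               "rest_days", "dose", "start_day",
                               "monitoring_period", "target_ratio",
                               "min_dose", "max_dose", "step")])
  })
  hyper <- if (is.null(doc$hyperthermia)) NULL else
    do.call(hyperthermia_session, doc$hyperthermia)
  structure(list(name = doc$name, schedules = sched, hyperthermia = hyper,
                 resistance_multiplier = doc$resistance_multiplier),
            class = "fotsim_protocol")
}

#' Export a trajectory to tidy CSV
#'
#' Writes one row per sample with columns `time`, the 15 state names,
#' one applied-dose column per drug (`dose_<type>`), and `temperature`.
#'
#' @param result A `fotsim_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(result, path) {
  df <- data.frame(time = result$time, result$state,
                   check.names = FALSE)
  if (!is.null(result$dose)) {
    dose <- as.data.frame(result$dose)
    names(dose) <- paste0("dose_", colnames(result$dose))
    df <- cbind(df, dose)
  }
  df$temperature <- result$temperature
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Summarizes a simulation for provenance: package version, a hash of
#' the parameter values, the configuration echo, solver diagnostics and
#' the outcome metrics. Manifests round-trip losslessly through their
#' JSON serialization.
#'
#' @param result A `fotsim_result`.
#' @param params The `fotsim_params` used.
#' @param extra Optional named list merged into the manifest.
#' @param path Optional path; when given the manifest is also written as
#'   JSON.
#' @return Named list (the manifest).
#' @export
run_manifest <- function(result, params, extra = list(), path = NULL) {
  vals <- unlist(params[parameter_names(params)])
  key <- utf8ToInt(paste(names(vals), format(vals, digits = 15),
                         collapse = ";"))
  hash <- sprintf("%08x",
                  sum(key * (seq_along(key) %% 97 + 1)) %% 2147483647)
  man <- c(list(
    artifact = "fotsim",
    version = as.character(utils::packageVersion("fotsim")),
    parameter_hash = hash,
    config = list(duration = result$config$duration,
                  n_points = result$config$n_points,
                  alpha = result$config$alpha,
                  rtol = result$config$rtol, atol = result$config$atol,
                  method_chain = result$config$method_chain,
                  seed = result$config$seed),
    protocol = result$protocol,
    solver = list(method_used = result$method_used,
                  fallback_level = result$fallback_level,
                  converged = result$converged, is_dummy = result$is_dummy)
  ), extra)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  man
}

#' Write the bundled study definitions
#'
#' Writes the baseline parameter set, the four patient profiles and the
#' five treatment protocols as YAML under `dir`, reproducing the bundled
#' `inst/extdata` files.
#'
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_definitions <- function(dir) {
  for (d in file.path(dir, c("parameters", "profiles", "protocols"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  write_parameters(default_parameters(),
                   file.path(dir, "parameters", "baseline.yaml"))
  for (pr in profile_names()) {
    write_profile(patient_profile(pr),
                  file.path(dir, "profiles", paste0(pr, ".yaml")))
  }
  for (pt in protocol_names()) {
    write_protocol(treatment_protocol(pt),
                   file.path(dir, "protocols", paste0(pt, ".yaml")))
  }
  invisible(dir)
}

#' Generate test fixtures
#'
#' Emits, reproducibly for a given seed: (a) the baseline parameter set,
#' profiles and protocols; (b) randomized-but-valid parameter sets for
#' property tests (each parameter jittered multiplicatively within
#' +/- 20%, bounded parameters kept in range); and (c) short 10-day
#' reference trajectories computed with the fixed-step reference
#' integrator for oracle comparison.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param n_random Number of randomized parameter sets.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(seed = 0, dir = tempfile("fotsim-fixtures"),
                          n_random = 3) {
  set.seed(seed)
  write_study_definitions(dir)
  rdir <- file.path(dir, "random_parameters")
  dir.create(rdir, showWarnings = FALSE)
  for (i in seq_len(n_random)) {
    write_parameters(random_parameters(),
                     file.path(rdir, sprintf("set%02d.yaml", i)))
  }
  tdir <- file.path(dir, "reference_trajectories")
  dir.create(tdir, showWarnings = FALSE)
  cfg <- simulation_config(duration = 10, n_points = 11, alpha = 0.9)
  params <- default_parameters()
  for (pt in c("standard", "continuous")) {
    res <- reference_integrate(cfg, params, treatment_protocol(pt, params),
                               dt = 0.01)
    export_trajectory(res, file.path(tdir, paste0(pt, "_10d.csv")))
  }
  invisible(dir)
}

#' Randomized valid parameter set
#'
#' Multiplicative jitter of the baseline by U(0.8, 1.2) per parameter,
#' with bounded parameters (`hypoxia_threshold`, `bioavailability`,
#' `circadian_amplitude`) clamped to their valid ranges and
#' `circadian_phase` left untouched. Intended for property tests; uses
#' the session RNG.
#'
#' @param baseline Baseline `fotsim_params`.
#' @return A validated `fotsim_params`.
#' @export
random_parameters <- function(baseline = default_parameters()) {
  p <- baseline
  for (nm in parameter_names(baseline)) {
    if (nm == "circadian_phase") next
    p[[nm]] <- p[[nm]] * stats::runif(1, 0.8, 1.2)
  }
  p$hypoxia_threshold <- min(max(p$hypoxia_threshold, 0.05), 0.95)
  p$bioavailability <- min(p$bioavailability, 1.0)
  p$circadian_amplitude <- min(p$circadian_amplitude, 0.95)
  validate_parameters(p)
}
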