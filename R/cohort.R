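PROFILE_TABLE <- list(
  average = list(age_factor = 1.0, performance_status = 1.0,
                 immune_status = 1.0, liver_function = 1.0,
                 kidney_function = 1.0, mutation_rate = 0.0001,
                 genetic_instability = 1.0),
  young = list(age_factor = 1.2, performance_status = 1.2,
               immune_status = 1.3, liver_function = 1.1,
               kidney_function = 1.1, mutation_rate = 0.00008,
               genetic_instability = 1.0),
  elderly = list(age_factor = 0.8, performance_status = 0.8,
                 immune_status = 0.7, liver_function = 0.9,
                 kidney_function = 0.85, mutation_rate = 0.00015,
                 genetic_instability = 1.0),
  compromised = list(age_factor = 0.8, performance_status = 0.7,
                     immune_status = 0.6, liver_function = 0.7,
                     kidney_function = 0.7, mutation_rate = 0.00015,
                     genetic_instability = 1.2)
)

#' Virtual patient profiles
#'
#' Four discrete patient archetypes: `average` (baseline), `young`
#' (enhanced immune function, faster clearance, better genetic
#' stability), `elderly` (reduced immune function, slower clearance,
#' higher mutation rate) and `compromised` (markedly reduced immune and
#' organ function, elevated genetic instability). Each profile is a fixed
#' set of multiplicative patient factors plus replacement values for the
#' mutation rate and genetic instability.
#'
#' @param name One of `"average"`, `"young"`, `"elderly"`, `"compromised"`.
#' @return Object of class `fotsim_profile` (named list with a `name`
#'   field).
#' @export
#' @examples
#' patient_profile("young")$immune_status  # 1.3
patient_profile <- function(name = c("average", "young", "elderly",
                                     "compromised")) {
  name <- match.arg(name)
  structure(c(list(name = name), PROFILE_TABLE[[name]]),
            class = "fotsim_profile")
}

#' @rdname patient_profile
#' @export
profile_names <- function() names(PROFILE_TABLE)

#' Apply a patient profile to a parameter set
#'
#' Produces a patient-specific parameter set: `mutation_rate` and
#' `genetic_instability` are replaced by the profile values;
#' `liver_function` and `kidney_function` are stored and act through the
#' adjusted drug elimination rate; `immune_status` scales the immune
#' production rates `phi1` and `phi2`; `age_factor` and
#' `performance_status` are stored but inert (no governing equation in
#' the model). The input is never modified, and applying the average
#' profile returns a set identical to the baseline.
#'
#' @param baseline A validated `fotsim_params` object.
#' @param profile A `fotsim_profile` object or profile name.
#' @return A new `fotsim_params` object.
#' @export
#' @examples
#' p <- apply_profile(default_parameters(), "young")
#' p$phi1  # 0.13
apply_profile <- function(baseline, profile) {
  if (is.character(profile)) profile <- patient_profile(profile)
  out <- baseline
  out$age_factor <- profile$age_factor
  out$performance_status <- profile$performance_status
  out$immune_status <- profile$immune_status
  out$liver_function <- profile$liver_function
  out$kidney_function <- profile$kidney_function
  out$mutation_rate <- profile$mutation_rate
  out$genetic_instability <- profile$genetic_instability
  out$phi1 <- baseline$phi1 * profile$immune_status
  out$phi2 <- baseline$phi2 * profile$immune_status
  validate_parameters(out)
}

#' Treatment protocols
#'
#' Builds one of the five named treatment protocols:
#'
#' * `standard`: cyclic hormone + HER2 therapy, 14 days on / 7 off,
#'   dose 0.8.
#' * `continuous`: hormone + HER2 without breaks, dose 0.8.
#' * `adaptive`: response-guided hormone + HER2 dosing within
#'   `[0.6, 0.9]` (initial dose 0.75, reviewed every 21 days); carries the
#'   `adaptive_resist_dev` resistance multiplier.
#' * `immuno_combo`: chemotherapy 7 on / 14 off at 0.6 plus immunotherapy
#'   2 on / 19 off at 0.7.
#' * `hyperthermia`: cyclic hormone + HER2 at 0.7 (14 on / 7 off) with
#'   38.5 C thermal sessions, 2 days every 21.
#'
#' The `continuous` protocol carries the `continuous_resist_dev`
#' multiplier on resistance induction (rapid resistance under continuous
#' selection pressure), `adaptive` carries `adaptive_resist_dev`, and all
#' others 1.
#'
#' @param name One of `"standard"`, `"continuous"`, `"adaptive"`,
#'   `"immuno_combo"`, `"hyperthermia"`.
#' @param params Parameter set supplying the protocol resistance
#'   multipliers and adaptive controller defaults.
#' @param adaptive_initial_dose Starting dose for the adaptive protocol
#'   (default 0.75, the midpoint of the dose band).
#' @return Object of class `fotsim_protocol`: name, list of
#'   `fotsim_schedule`s, optional `fotsim_hyperthermia` session, and
#'   `resistance_multiplier`.
#' @export
#' @examples
#' treatment_protocol("continuous")$resistance_multiplier  # 2
treatment_protocol <- function(name = c("standard", "continuous", "adaptive",
                                        "immuno_combo", "hyperthermia"),
                               params = default_parameters(),
                               adaptive_initial_dose = 0.75) {
  name <- match.arg(name)
  sched <- switch(name,
    standard = list(
      dose_schedule("hormone", "cyclic", 14, 7, dose = 0.8),
      dose_schedule("her2", "cyclic", 14, 7, dose = 0.8)
    ),
    continuous = list(
      dose_schedule("hormone", "continuous", dose = 0.8),
      dose_schedule("her2", "continuous", dose = 0.8)
    ),
    adaptive = list(
      dose_schedule("hormone", "adaptive", dose = adaptive_initial_dose,
                    monitoring_period = 21, target_ratio = 1.0,
                    min_dose = 0.6, max_dose = 0.9, step = 0.1),
      dose_schedule("her2", "adaptive", dose = adaptive_initial_dose,
                    monitoring_period = 21, target_ratio = 1.0,
                    min_dose = 0.6, max_dose = 0.9, step = 0.1)
    ),
    immuno_combo = list(
      dose_schedule("chemo", "cyclic", 7, 14, dose = 0.6),
      dose_schedule("immuno", "cyclic", 2, 19, dose = 0.7)
    ),
    hyperthermia = list(
      dose_schedule("hormone", "cyclic", 14, 7, dose = 0.7),
      dose_schedule("her2", "cyclic", 14, 7, dose = 0.7)
    )
  )
  hyper <- if (name == "hyperthermia") hyperthermia_session(38.5, 2, 21) else
    NULL
  rmult <- switch(name,
    continuous = params$continuous_resist_dev,
    adaptive = params$adaptive_resist_dev,
    1.0
  )
  structure(list(name = name, schedules = sched, hyperthermia = hyper,
                 resistance_multiplier = rmult),
            class = "fotsim_protocol")
}

#' @rdname treatment_protocol
#' @export
protocol_names <- function() {
  c("standard", "continuous", "adaptive", "immuno_combo", "hyperthermia")
}

#' @export
print.fotsim_protocol <- function(x, ...) {
  cat("<fotsim_protocol>", x$name, "\n")
  for (s in x$schedules) {
    cat(sprintf("  %s [%s] dose %.2f", s$drug_type, s$kind, s$dose))
    if (s$kind == "cyclic") {
      cat(sprintf(" (%gd on / %gd off)", s$treatment_days, s$rest_days))
    }
    if (s$kind == "adaptive") {
      cat(sprintf(" in [%.2f, %.2f], review every %g d",
                  s$min_dose, s$max_dose, s$monitoring_period))
    }
    cat("\n")
  }
  if (!is.null(x$hyperthermia)) {
    cat(sprintf("  hyperthermia %.1f C, %g d every %g d\n",
                x$hyperthermia$temperature, x$hyperthermia$duration_days,
                x$hyperthermia$period_days))
  }
  cat("  resistance multiplier:", x$resistance_multiplier, "\n")
  invisible(x)
}
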