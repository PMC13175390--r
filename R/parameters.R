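#' Baseline model parameters
#'
#' Returns the full set of 58 named model parameters with their baseline
#' values, grouped by evidence category. The set covers tumor growth,
#' immune interaction, resistance development, dormancy, microenvironment,
#' metastasis/angiogenesis, genetics, pharmacokinetics, treatment-efficacy
#' coefficients, scheduling defaults, circadian modulation, and
#' patient-specific factors. Time unit is days throughout; the circadian
#' period of 24 h is stored as 1 day.
#'
#' Each parameter carries a source category: `"experimental"` (direct
#' laboratory measurement), `"clinical"` (guidelines/pharmacokinetic
#' studies), `"literature"` (published mathematical models), or
#' `"hypothetical"` (plausibility-based). The default set partitions as
#' 11 / 21 / 19 / 7 across those categories.
#'
#' @return An object of class `fotsim_params`: a named list of 58 numeric
#'   values plus the logical switch `circadian_enabled` (not counted among
#'   the 58), with a `categories` attribute mapping each parameter to its
#'   source category.
#' @export
#' @examples
#' p <- default_parameters()
#' length(parameter_names(p))      # 58
#' table(parameter_categories(p))
default_parameters <- function() {
  p <- list(
    # tumor growth
    lambda1 = 0.003,            # sensitive-cell growth rate (1/day)
    lambda2 = 0.002,            # partially resistant growth rate (1/day)
    lambda_R1 = 0.006,          # type-1 resistant growth rate (1/day)
    lambda_R2 = 0.005,          # type-2 resistant growth rate (1/day)
    K = 1000,                   # shared carrying capacity
    acidosis_factor = 0.01,     # metabolic acidosis growth penalty
    # immune interaction
    beta1 = 0.005,              # cytotoxic killing rate (1/day)
    beta2 = 0.001,              # regulatory suppression rate (1/day)
    phi1 = 0.1,                 # baseline cytotoxic production (1/day)
    phi2 = 0.001,               # tumor-driven cytotoxic recruitment
    phi3 = 0.0003,              # tumor-driven regulatory recruitment
    delta_I = 0.04,             # immune cell death rate (1/day)
    immune_resist_factor1 = 0.10,
    immune_resist_factor2 = 0.05,
    # resistance development
    omega_R1 = 0.004,           # type-1 resistance induction
    omega_R2 = 0.003,           # type-2 resistance induction
    continuous_resist_dev = 2.0,
    adaptive_resist_dev = 1.2,
    immuno_resist_boost = 0.5,
    resistance_floor = 0.01,    # pre-existing resistant subclones
    # quiescence / senescence
    kappa_Q = 0.001,            # quiescence entry (1/day)
    lambda_Q = 0.0005,          # quiescence exit (1/day)
    kappa_S = 0.0005,           # therapy-induced senescence (1/day)
    delta_S = 0.005,            # senescent-cell clearance (1/day)
    # microenvironment
    hypoxia_threshold = 0.3,    # burden fraction of K where hypoxia starts
    metabolic_switch_rate = 0.02,
    microenv_stress_factor = 1.0,
    # metastasis / angiogenesis
    gamma_met = 0.0001,         # metastatic seeding rate (1/day)
    delta_P = 0.01,             # metastatic potential decay (1/day)
    alpha_A = 0.01,             # angiogenesis stimulation
    delta_A = 0.1,              # angiogenic factor degradation (1/day)
    # genetics
    mutation_rate = 0.0001,
    genetic_instability = 1.0,
    epigenetic_silencing = 0.002,
    # pharmacokinetics
    absorption_rate = 0.5,      # (1/day)
    elimination_rate = 0.1,     # (1/day)
    bioavailability = 0.85,
    ec50 = 0.3,                 # half-maximal effect concentration
    hill_coef = 1.5,
    max_drug_effect = 1.0,
    distribution_vol = 70,      # L
    # treatment efficacy coefficients
    eta_E = 0.01,               # endocrine/hormone
    eta_H = 0.01,               # HER2-targeted
    eta_C = 0.01,               # chemotherapy
    # scheduling defaults
    treatment_cycle_period = 21,
    treatment_active_days = 7,
    rest_period_days = 14,
    treatment_intensity = 1.0,
    # circadian modulation (period stored in days: 24 h == 1 day)
    circadian_amplitude = 0.2,
    circadian_period = 1.0,
    circadian_phase = 0.0,
    # patient-specific factors
    age_factor = 1.0,
    performance_status = 1.0,
    bmi_factor = 1.0,
    immune_status = 1.0,
    liver_function = 1.0,
    kidney_function = 1.0,
    prior_treatment_factor = 1.0,
    # switch, not one of the 58 counted parameters
    circadian_enabled = TRUE
  )
  attr(p, "categories") <- parameter_category_map()
  class(p) <- "fotsim_params"
  validate_parameters(p)
}

#' @rdname default_parameters
#' @param params A `fotsim_params` object.
#' @export
parameter_names <- function(params = default_parameters()) {
  setdiff(names(params), "circadian_enabled")
}

#' @rdname default_parameters
#' @export
parameter_categories <- function(params = default_parameters()) {
  attr(params, "categories")[parameter_names(params)]
}

parameter_category_map <- function() {
  experimental <- c("lambda1", "lambda2", "beta1", "omega_R1", "omega_R2",
                    "mutation_rate", "metabolic_switch_rate",
                    "hypoxia_threshold", "circadian_amplitude",
                    "circadian_period", "circadian_phase")
  clinical <- c("absorption_rate", "elimination_rate", "bioavailability",
                "ec50", "hill_coef", "max_drug_effect", "distribution_vol",
                "eta_E", "eta_H", "eta_C",
                "treatment_cycle_period", "treatment_active_days",
                "rest_period_days", "treatment_intensity",
                "age_factor", "performance_status", "bmi_factor",
                "immune_status", "liver_function", "kidney_function",
                "prior_treatment_factor")
  literature <- c("K", "phi1", "phi2", "phi3", "beta2", "delta_I",
                  "lambda_R1", "lambda_R2", "gamma_met", "delta_P",
                  "alpha_A", "delta_A", "kappa_Q", "lambda_Q", "kappa_S",
                  "delta_S", "epigenetic_silencing", "genetic_instability",
                  "acidosis_factor")
  hypothetical <- c("immune_resist_factor1", "immune_resist_factor2",
                    "continuous_resist_dev", "adaptive_resist_dev",
                    "immuno_resist_boost", "resistance_floor",
                    "microenv_stress_factor")
  cats <- c(
    stats::setNames(rep("experimental", length(experimental)), experimental),
    stats::setNames(rep("clinical", length(clinical)), clinical),
    stats::setNames(rep("literature", length(literature)), literature),
    stats::setNames(rep("hypothetical", length(hypothetical)), hypothetical)
  )
  cats
}

#' Functional group of each parameter
#'
#' Maps parameters to coarse functional categories (growth, immune,
#' resistance, dormancy, microenvironment, metastasis, genetics,
#' pharmacokinetics, treatment efficacy, scheduling, circadian, patient),
#' used when aggregating sensitivity coefficients by functional group.
#'
#' @param params A `fotsim_params` object.
#' @return Named character vector over the 58 parameters.
#' @export
parameter_groups <- function(params = default_parameters()) {
  grp <- c(
    lambda1 = "growth", lambda2 = "growth", lambda_R1 = "growth",
    lambda_R2 = "growth", K = "growth", acidosis_factor = "microenvironment",
    beta1 = "immune", beta2 = "immune", phi1 = "immune", phi2 = "immune",
    phi3 = "immune", delta_I = "immune",
    immune_resist_factor1 = "resistance", immune_resist_factor2 = "resistance",
    omega_R1 = "resistance", omega_R2 = "resistance",
    continuous_resist_dev = "resistance", adaptive_resist_dev = "resistance",
    immuno_resist_boost = "resistance", resistance_floor = "resistance",
    kappa_Q = "dormancy", lambda_Q = "dormancy", kappa_S = "dormancy",
    delta_S = "dormancy",
    hypoxia_threshold = "microenvironment",
    metabolic_switch_rate = "microenvironment",
    microenv_stress_factor = "microenvironment",
    gamma_met = "metastasis", delta_P = "metastasis",
    alpha_A = "metastasis", delta_A = "metastasis",
    mutation_rate = "genetics", genetic_instability = "genetics",
    epigenetic_silencing = "genetics",
    absorption_rate = "pharmacokinetics", elimination_rate = "pharmacokinetics",
    bioavailability = "pharmacokinetics", ec50 = "pharmacokinetics",
    hill_coef = "pharmacokinetics", max_drug_effect = "pharmacokinetics",
    distribution_vol = "pharmacokinetics",
    eta_E = "treatment efficacy", eta_H = "treatment efficacy",
    eta_C = "treatment efficacy",
    treatment_cycle_period = "scheduling", treatment_active_days = "scheduling",
    rest_period_days = "scheduling", treatment_intensity = "scheduling",
    circadian_amplitude = "circadian", circadian_period = "circadian",
    circadian_phase = "circadian",
    age_factor = "patient", performance_status = "patient",
    bmi_factor = "patient", immune_status = "patient",
    liver_function = "patient", kidney_function = "patient",
    prior_treatment_factor = "patient"
  )
  grp[parameter_names(params)]
}

#' Validate a parameter set
#'
#' Checks positivity of all rates, factors and capacities, range
#' constraints (`hypoxia_threshold` in (0,1), `bioavailability` in (0,1],
#' `circadian_amplitude` below 1 so modulated rates stay positive), and
#' the presence of all 58 named parameters with category annotations.
#'
#' @param params A `fotsim_params` object (or plain named list).
#' @return The validated object, invisibly classed as `fotsim_params`.
#' @export
validate_parameters <- function(params) {
  expected <- names(parameter_category_map())
  missing <- setdiff(expected, names(params))
  if (length(missing) > 0) {
    stop("missing parameters: ", paste(missing, collapse = ", "))
  }
  num <- params[expected]
  bad <- expected[!vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                            is.finite(x), logical(1))]
  if (length(bad) > 0) {
    stop("non-finite or non-scalar parameters: ", paste(bad, collapse = ", "))
  }
  # circadian_phase may legitimately be zero (and is, at baseline)
  positive <- setdiff(expected, "circadian_phase")
  nonpos <- positive[vapply(params[positive], function(x) x <= 0, logical(1))]
  if (length(nonpos) > 0) {
    stop("parameters must be strictly positive: ",
         paste(nonpos, collapse = ", "))
  }
  if (params$circadian_phase < 0) stop("circadian_phase must be >= 0")
  if (params$hypoxia_threshold <= 0 || params$hypoxia_threshold >= 1) {
    stop("hypoxia_threshold must lie in (0, 1)")
  }
  if (params$bioavailability > 1) stop("bioavailability must lie in (0, 1]")
  if (params$circadian_amplitude >= 1) {
    stop("circadian_amplitude must be < 1 (modulated rates would become ",
         "nonpositive)")
  }
  if (is.null(params$circadian_enabled)) params$circadian_enabled <- TRUE
  if (is.null(attr(params, "categories"))) {
    attr(params, "categories") <- parameter_category_map()
  }
  class(params) <- "fotsim_params"
  invisible(params)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named values replaced, revalidated.
#'
#' @param params A `fotsim_params` object.
#' @param ... Named scalar replacements, e.g. `beta1 = 0.0055`.
#' @return A new `fotsim_params` object; the input is not modified.
#' @export
set_parameters <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(params)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  }
  params[names(repl)] <- repl
  validate_parameters(params)
}

#' @export
print.fotsim_params <- function(x, ...) {
  cats <- parameter_categories(x)
  cat("<fotsim_params> ", length(parameter_names(x)), " parameters (",
      paste(sprintf("%s: %d", names(table(cats)), as.integer(table(cats))),
            collapse = ", "),
      ")\n", sep = "")
  cat("circadian_enabled:", x$circadian_enabled, "\n")
  invisible(x)
}
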