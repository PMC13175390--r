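#' Dose schedule constructor
#'
#' Describes one drug's dosing pattern. `kind = "cyclic"` alternates
#' `treatment_days` on at `dose` with `rest_days` off; `"continuous"` is
#' always on from `start_day`; `"adaptive"` starts at `dose` and is
#' adjusted at monitoring boundaries based on the recent tumor-burden
#' ratio, confined to `[min_dose, max_dose]`.
#'
#' @param drug_type One of `"hormone"`, `"her2"`, `"chemo"`, `"immuno"`.
#' @param kind One of `"cyclic"`, `"continuous"`, `"adaptive"`.
#' @param treatment_days,rest_days On/off period lengths (days) for cyclic
#'   schedules.
#' @param dose Nominal (or initial, for adaptive) dose, dimensionless.
#' @param start_day Day the schedule begins.
#' @param monitoring_period Days between adaptive dose reviews.
#' @param target_ratio Burden ratio above which the adaptive dose is
#'   raised; below its reciprocal the dose is lowered.
#' @param min_dose,max_dose Adaptive dose bounds.
#' @param step Adaptive dose increment/decrement.
#' @return Object of class `fotsim_schedule`.
#' @export
dose_schedule <- function(drug_type = c("hormone", "her2", "chemo", "immuno"),
                          kind = c("cyclic", "continuous", "adaptive"),
                          treatment_days = 14, rest_days = 7, dose = 0.8,
                          start_day = 0, monitoring_period = 21,
                          target_ratio = 1.0, min_dose = 0.6, max_dose = 0.9,
                          step = 0.1) {
  drug_type <- match.arg(drug_type)
  kind <- match.arg(kind)
  if (dose < 0) stop("dose must be >= 0")
  if (treatment_days < 0 || rest_days < 0) {
    stop("treatment_days and rest_days must be >= 0")
  }
  if (kind == "cyclic" && treatment_days + rest_days <= 0) {
    stop("cyclic schedule requires treatment_days + rest_days > 0")
  }
  if (kind == "adaptive") {
    if (monitoring_period <= 0) stop("monitoring_period must be > 0")
    if (min_dose > max_dose) stop("min_dose must be <= max_dose")
    if (dose < min_dose || dose > max_dose) {
      stop("adaptive initial dose must lie in [min_dose, max_dose]")
    }
    if (target_ratio < 1) stop("target_ratio must be >= 1")
  }
  structure(list(drug_type = drug_type, kind = kind,
                 treatment_days = treatment_days, rest_days = rest_days,
                 dose = dose, start_day = start_day,
                 monitoring_period = monitoring_period,
                 target_ratio = target_ratio, min_dose = min_dose,
                 max_dose = max_dose, step = step),
            class = "fotsim_schedule")
}

#' Cyclic dose at a time point
#'
#' Returns `dose` when `(t - start_day) mod (treatment_days + rest_days)`
#' falls in the on-period, 0 otherwise (and 0 before `start_day`). With
#' `rest_days = 0` this is the continuous limit.
#'
#' @param t Time (days), scalar or vector.
#' @param schedule A cyclic `fotsim_schedule`.
#' @return Dose value(s).
#' @export
#' @examples
#' s <- dose_schedule("hormone", "cyclic", 14, 7, dose = 0.8)
#' cyclic_dose(c(10, 15, 21), s)  # 0.8 0.0 0.8
cyclic_dose <- function(t, schedule) {
  cycle <- schedule$treatment_days + schedule$rest_days
  if (cycle <= 0) stop("cyclic schedule has zero cycle length")
  phase <- (t - schedule$start_day) %% cycle
  out <- ifelse(t >= schedule$start_day & phase < schedule$treatment_days,
                schedule$dose, 0)
  out
}

#' Scheduled dose at a time point
#'
#' Dispatches on the schedule kind. Adaptive schedules are piecewise
#' constant between monitoring boundaries; the currently active dose is
#' supplied by the integrator via `current_dose`.
#'
#' @param t Time (days).
#' @param schedule A `fotsim_schedule`.
#' @param current_dose Active dose for adaptive schedules (defaults to the
#'   schedule's initial dose).
#' @return Dose value(s).
#' @export
dose_at <- function(t, schedule, current_dose = schedule$dose) {
  switch(schedule$kind,
    cyclic = cyclic_dose(t, schedule),
    continuous = ifelse(t >= schedule$start_day, schedule$dose, 0),
    adaptive = ifelse(t >= schedule$start_day, current_dose, 0)
  )
}

#' One adaptive-controller update
#'
#' Response-guided dose adjustment: if the burden ratio over the last
#' monitoring period exceeds `target_ratio` the dose is raised by `step`
#' (capped at `max_dose`); if it falls below `1 / target_ratio` the dose
#' is lowered by `step` (floored at `min_dose`); otherwise it is held.
#'
#' @param current_dose Active dose.
#' @param ratio `burden(t) / burden(t - monitoring_period)`.
#' @param schedule An adaptive `fotsim_schedule`.
#' @return Updated dose in `[min_dose, max_dose]`.
#' @export
adaptive_dose_update <- function(current_dose, ratio, schedule) {
  if (!is.finite(ratio) || ratio < 0) stop("invalid burden ratio")
  if (ratio > schedule$target_ratio) {
    min(current_dose + schedule$step, schedule$max_dose)
  } else if (ratio < 1 / schedule$target_ratio) {
    max(current_dose - schedule$step, schedule$min_dose)
  } else {
    current_dose
  }
}

#' Adaptive dose at a time point given a burden history
#'
#' Replays the controller over all monitoring boundaries up to `t` using
#' the supplied tumor-burden history, then returns the dose active at `t`.
#' Dose changes occur only at boundaries `start_day + k * monitoring_period`.
#'
#' @param t Time (days).
#' @param schedule An adaptive `fotsim_schedule`.
#' @param burden_history Data frame with columns `time` and `burden`
#'   covering `[start_day, t]`.
#' @return Dose active at `t`.
#' @export
adaptive_dose <- function(t, schedule, burden_history) {
  if (schedule$kind != "adaptive") stop("schedule is not adaptive")
  if (is.null(burden_history) || nrow(burden_history) == 0) {
    stop("empty burden history at an adaptive evaluation boundary")
  }
  bound <- seq(schedule$start_day + schedule$monitoring_period, t,
               by = schedule$monitoring_period)
  dose <- schedule$dose
  for (tb in bound) {
    b_now <- stats::approx(burden_history$time, burden_history$burden,
                           xout = tb, rule = 2)$y
    b_prev <- stats::approx(burden_history$time, burden_history$burden,
                            xout = tb - schedule$monitoring_period,
                            rule = 2)$y
    if (!is.finite(b_prev) || b_prev <= 0) {
      stop("burden history does not cover the monitoring window")
    }
    dose <- adaptive_dose_update(dose, b_now / b_prev, schedule)
  }
  dose
}

#' Per-drug pharmacokinetic input flux
#'
#' Converts scheduled doses to absorption fluxes into the drug
#' concentration compartment: per drug,
#' `absorption_rate * dose(t) * bioavailability / distribution_vol`
#' (the dose is divided by the distribution volume to convert to
#' concentration units). Elimination uses the organ-function-adjusted
#' rate `elimination_rate * liver_function * kidney_function`.
#'
#' @param t Time (days).
#' @param schedules List of `fotsim_schedule` objects.
#' @param params A `fotsim_params` object.
#' @param current_doses Named numeric vector of active adaptive doses
#'   (by drug type); defaults to each schedule's nominal dose.
#' @return Named numeric vector of absorption fluxes, one per schedule,
#'   named by drug type.
#' @export
pk_input <- function(t, schedules, params, current_doses = NULL) {
  vapply(schedules, function(s) {
    d <- if (!is.null(current_doses) && s$drug_type %in% names(current_doses))
      dose_at(t, s, current_doses[[s$drug_type]]) else dose_at(t, s)
    if (d < 0) stop("negative dose")
    params$absorption_rate * d * params$bioavailability /
      params$distribution_vol
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(schedules, `[[`, character(1), "drug_type"))
}

#' Hill-equation drug effect
#'
#' Sigmoidal dose-response
#' `max_drug_effect * c^h / (ec50^h + c^h)`, monotone nondecreasing in the
#' concentration and bounded by `max_drug_effect`.
#'
#' @param concentration Drug concentration, `>= 0` (scalar or vector).
#' @param params A `fotsim_params` object supplying `ec50`, `hill_coef`
#'   and `max_drug_effect`.
#' @return Effect in `[0, max_drug_effect]`.
#' @export
#' @examples
#' p <- default_parameters()
#' hill_effect(p$ec50, p)  # half-maximal
hill_effect <- function(concentration, params) {
  if (params$ec50 <= 0) stop("ec50 must be > 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  ch <- concentration^params$hill_coef
  params$max_drug_effect * ch / (params$ec50^params$hill_coef + ch)
}

#' Hyperthermia session constructor
#'
#' Periodic thermal-therapy sessions: `temperature` for `duration_days`
#' every `period_days`, starting at `start_day`.
#'
#' @param temperature Session temperature (degrees C, `>= 37`).
#' @param duration_days Session length (days), at most `period_days`.
#' @param period_days Days between session starts.
#' @param start_day First session start.
#' @return Object of class `fotsim_hyperthermia`.
#' @export
hyperthermia_session <- function(temperature = 38.5, duration_days = 2,
                                 period_days = 21, start_day = 0) {
  if (temperature < 37) stop("session temperature must be >= 37 degrees C")
  if (duration_days > period_days) {
    stop("duration_days must be <= period_days")
  }
  structure(list(temperature = temperature, duration_days = duration_days,
                 period_days = period_days, start_day = start_day),
            class = "fotsim_hyperthermia")
}

#' Temperature at a time point
#'
#' @param t Time (days).
#' @param session A `fotsim_hyperthermia` object, or `NULL` for no
#'   thermal therapy.
#' @return Temperature in degrees C (37.0 outside sessions).
#' @export
temperature_at <- function(t, session = NULL) {
  if (is.null(session)) return(rep(37.0, length(t)))
  phase <- (t - session$start_day) %% session$period_days
  active <- t >= session$start_day & phase < session$duration_days
  out <- ifelse(active, session$temperature, 37.0)
  out
}

#' Thermal enhancement of therapy effect
#'
#' `1 + coef * max(0, temperature - 37)`; multiplies the therapy-effect
#' combination during hyperthermia sessions. `coef = 0` disables the
#' thermal effect.
#'
#' @param temperature Degrees C, `>= 36`.
#' @param coef Enhancement per degree above 37 C (default 0.1).
#' @return Multiplier `>= 1`.
#' @export
#' @examples
#' hyperthermia_modifier(38.5)  # 1.15
hyperthermia_modifier <- function(temperature, coef = 0.1) {
  1 + coef * pmax(0, temperature - 37.0)
}

#' Control inputs from the current drug state
#'
#' Maps the drug state to the four therapy controls: the raw scheduled
#' dose (`control_mode = "raw_dose"`, default) or the per-drug
#' concentration passed through the Hill dose-response (`"hill"`);
#' reads the temperature from any active
#' hyperthermia session, and sets
#' `immuno_boost = 1 + immuno_resist_boost * uI`.
#'
#' @param t Time (days).
#' @param drug_state Named numeric vector of per-drug concentrations
#'   (names among hormone/her2/chemo/immuno).
#' @param protocol A `fotsim_protocol` (for its schedules and
#'   hyperthermia session).
#' @param params A `fotsim_params` object.
#' @param options A `fotsim_options` object.
#' @param current_doses Named active adaptive doses, as in [pk_input()].
#' @return A `fotsim_controls` object.
#' @export
controls_at <- function(t, drug_state, protocol, params,
                        options = model_options(), current_doses = NULL) {
  u <- c(hormone = 0, her2 = 0, chemo = 0, immuno = 0)
  if (options$control_mode == "hill") {
    present <- intersect(names(drug_state), names(u))
    u[present] <- hill_effect(pmax(drug_state[present], 0), params)
  } else {
    for (s in protocol$schedules) {
      d <- if (!is.null(current_doses) && s$drug_type %in% names(current_doses))
        dose_at(t, s, current_doses[[s$drug_type]]) else dose_at(t, s)
      u[s$drug_type] <- u[s$drug_type] + d
    }
  }
  uI <- u[["immuno"]]
  control_inputs(
    uE = u[["hormone"]], uH = u[["her2"]], uC = u[["chemo"]], uI = uI,
    temperature = temperature_at(t, protocol$hyperthermia),
    immuno_boost = 1 + params$immuno_resist_boost * uI
  )
}
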