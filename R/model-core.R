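#' Model options
#'
#' Collects the switchable resolutions of formulation ambiguities and the
#' optional exploration hooks, with defaults matching the reference
#' formulation:
#'
#' * `metastasis_hypoxia_mode`: whether the metastatic seeding term divides
#'   (`"divide"`, default) or multiplies (`"multiply"`) by
#'   `1 + 0.5 * hypoxia_factor`.
#' * `control_mode`: `"raw_dose"` (default) feeds the scheduled dose
#'   directly into the therapy-effect sum; `"hill"` first maps the
#'   evolving drug concentration through the Hill dose-response. The raw
#'   dose is the default because it is the only reading under which the
#'   five protocols separate: scheduled doses (0.6-0.9) sit well below
#'   the EC50-relative concentrations reached by the slow pharmacokinetic
#'   compartment, so Hill-transformed controls collapse all protocols
#'   onto near-identical trajectories, while raw-dose controls reproduce
#'   the reported protocol ordering and efficacy spread.
#' * `immuno_boost_mode`: `"linear"` (default) sets
#'   `immuno_boost = 1 + immuno_resist_boost * uI`.
#' * `hyperthermia_coef`: thermal enhancement of therapy effect per degree
#'   above 37 C (1/degree C, default 0.1; 0 disables the thermal effect).
#' * `use_hypoxia_effect`: if `TRUE`, growth terms are additionally
#'   multiplied by the angiogenesis-buffered hypoxia effect
#'   `1 + hypoxia_factor * A / (1 + A)`; by default this quantity is
#'   computed and reported but not wired into any flux.
#'
#' @return Named list of class `fotsim_options`.
#' @export
model_options <- function(metastasis_hypoxia_mode = c("divide", "multiply"),
                          control_mode = c("raw_dose", "hill"),
                          immuno_boost_mode = "linear",
                          hyperthermia_coef = 0.1,
                          use_hypoxia_effect = FALSE) {
  structure(list(
    metastasis_hypoxia_mode = match.arg(metastasis_hypoxia_mode),
    control_mode = match.arg(control_mode),
    immuno_boost_mode = immuno_boost_mode,
    hyperthermia_coef = hyperthermia_coef,
    use_hypoxia_effect = use_hypoxia_effect
  ), class = "fotsim_options")
}

#' Circadian modulation factor
#'
#' `1 + amplitude * sin(2 * pi * (t / period - phase))`. When circadian
#' modulation is enabled the factor multiplies the tumor growth rates
#' (`lambda1`, `lambda2`), the immune death rate (`delta_I`) and the
#' cytotoxic killing rate (`beta1`); no other parameter is modulated.
#' When disabled the factor is exactly 1.
#'
#' @param t Time (days).
#' @param params A `fotsim_params` object.
#' @return Positive scalar in `[1 - amplitude, 1 + amplitude]`.
#' @export
#' @examples
#' circadian_factor(0, default_parameters())     # 1
#' circadian_factor(0.25, default_parameters())  # 1.2 (peak, 6 h into the day)
circadian_factor <- function(t, params) {
  if (!isTRUE(params$circadian_enabled)) return(1.0)
  if (params$circadian_period <= 0) stop("circadian_period must be > 0")
  if (params$circadian_amplitude >= 1) stop("circadian_amplitude must be < 1")
  1.0 + params$circadian_amplitude *
    sin(2 * pi * (t / params$circadian_period - params$circadian_phase))
}

#' Fractional-order memory scaling factor
#'
#' The fractional-order character of the model enters as a time-dependent
#' factor that multiplies the entire derivative vector:
#' `0.01 * (1 + (1 - alpha) * min(t^(-alpha), 100))` for `t > 0`, and 1
#' at `t <= 0`. `alpha = 1` is the memoryless classical case (constant
#' factor 0.01 for `t > 0`); smaller `alpha` adds a power-law decaying
#' memory boost, capped at 100 to avoid numerical overflow near `t = 0`.
#'
#' @param t Time (days), scalar or vector, `>= 0`.
#' @param alpha Fractional order in `(0, 1]`.
#' @return Positive scalar (or vector along `t`).
#' @export
#' @examples
#' fractional_factor(0, 0.8)     # 1 (t = 0 branch)
#' fractional_factor(5, 1.0)     # 0.01
#' fractional_factor(1, 0.75)    # 0.0125
fractional_factor <- function(t, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]")
  }
  if (any(t < 0)) stop("t must be >= 0")
  out <- rep(1.0, length(t))
  pos <- t > 0
  out[pos] <- 0.01 * (1 + (1 - alpha) * pmin(t[pos]^(-alpha), 100))
  if (length(t) == 1) out <- out[[1]]
  out
}

#' Intermediate quantities of the model right-hand side
#'
#' Computes the shared intermediate quantities that the fluxes are built
#' from: total tumor burden, logistic carrying-capacity factor,
#' metabolism-boosted growth factor, acidosis penalty, hypoxia factor and
#' its (reported, unwired) angiogenesis-buffered effect, hypoxia-impaired
#' immune kill factor, hypoxia-driven quiescence factor, the linear
#' therapy-effect combination, the instability-driven resistance
#' development factor, the genetic damage rate, and the metabolic shift.
#'
#' @param t Time (days).
#' @param state Named 15-component state vector (floored internally).
#' @param params A `fotsim_params` object.
#' @param controls A `fotsim_controls` object.
#' @param options A `fotsim_options` object.
#' @return Named list of class `fotsim_intermediates`.
#' @export
compute_intermediates <- function(t, state, params,
                                  controls = control_inputs(),
                                  options = model_options()) {
  if (params$K <= 0) stop("K must be > 0")
  y <- floor_state(state[state_names()])
  total <- y[["N1"]] + y[["N2"]] + y[["Q"]] + y[["R1"]] + y[["R2"]] + y[["S"]]
  ccf <- max(0, 1 - total / params$K)
  M <- y[["M"]]
  growth_factor <- ccf * (1 + 0.2 * M)
  acidosis_effect <- 1.0 + params$acidosis_factor * M * (total / params$K)
  thr <- params$hypoxia_threshold
  hf <- min(1, max(0, total / params$K - thr) / (1 - thr))
  hypoxia_effect <- 1.0 + hf * y[["A"]] / (1 + y[["A"]])
  immune_kill_factor <- 1.0 / (1 + 0.5 * hf)
  quiescence_factor <- 1.0 + 0.5 * hf
  therapy_effect <- (params$eta_E * controls$uE + params$eta_H * controls$uH +
                     params$eta_C * controls$uC) *
    hyperthermia_modifier(controls$temperature, options$hyperthermia_coef)
  G <- y[["G"]]
  resistance_dev_factor <- 1 + (1 - G)
  genetic_damage_rate <- params$mutation_rate * params$genetic_instability *
    (1 + therapy_effect + 0.5 * hf)
  metabolic_shift <- M * hf * params$metabolic_switch_rate
  structure(list(
    total_tumor = total,
    carrying_capacity_factor = ccf,
    growth_factor = growth_factor,
    acidosis_effect = acidosis_effect,
    hypoxia_factor = hf,
    hypoxia_effect = hypoxia_effect,
    immune_kill_factor = immune_kill_factor,
    quiescence_factor = quiescence_factor,
    therapy_effect = therapy_effect,
    resistance_dev_factor = resistance_dev_factor,
    genetic_damage_rate = genetic_damage_rate,
    metabolic_shift = metabolic_shift
  ), class = "fotsim_intermediates")
}

# Core right-hand side over the 15 compartments (unnamed numeric access on
# fixed index order; the hot path for the integrator). Returns the raw flux
# vector already multiplied by the fractional factor. `pk_flux` is the total
# drug absorption input (concentration units/day); `adj_elim` the
# liver/kidney-adjusted elimination rate.
rhs_core <- function(t, y, p, uE, uH, uC, uI, temperature, immuno_boost,
                     resistance_multiplier, alpha, pk_flux, adj_elim, opts,
                     want_intermediates = FALSE) {
  y <- pmax(y, STATE_FLOOR)
  if (y[13] > 1) y[13] <- 1
  N1 <- y[1]; N2 <- y[2]; I1 <- y[3]; I2 <- y[4]; P <- y[5]; A <- y[6]
  Q <- y[7]; R1 <- y[8]; R2 <- y[9]; S <- y[10]; D <- y[11]
  G <- y[13]; M <- y[14]; H <- y[15]

  cf <- if (isTRUE(p$circadian_enabled)) {
    1.0 + p$circadian_amplitude *
      sin(2 * pi * (t / p$circadian_period - p$circadian_phase))
  } else 1.0
  lambda1 <- p$lambda1 * cf
  lambda2 <- p$lambda2 * cf
  delta_I <- p$delta_I * cf
  beta1 <- p$beta1 * cf

  total <- N1 + N2 + Q + R1 + R2 + S
  K <- p$K
  ccf <- 1 - total / K
  if (ccf < 0) ccf <- 0
  growth_factor <- ccf * (1 + 0.2 * M)
  acidosis <- 1.0 + p$acidosis_factor * M * (total / K)
  thr <- p$hypoxia_threshold
  hf <- (total / K - thr) / (1 - thr)
  if (hf < 0) hf <- 0 else if (hf > 1) hf <- 1
  ikf <- 1.0 / (1 + 0.5 * hf)
  qf <- 1.0 + 0.5 * hf
  hyp_eff <- 1.0 + hf * A / (1 + A)

  therapy <- p$eta_E * uE + p$eta_H * uH + p$eta_C * uC
  if (temperature > 37) {
    therapy <- therapy * (1 + opts$hyperthermia_coef * (temperature - 37))
  }

  gmul <- growth_factor / acidosis
  if (isTRUE(opts$use_hypoxia_effect)) gmul <- gmul * hyp_eff
  growth_N1 <- lambda1 * N1 * gmul
  growth_N2 <- lambda2 * N2 * gmul
  growth_R1 <- p$lambda_R1 * R1 * gmul
  growth_R2 <- p$lambda_R2 * R2 * gmul

  sat <- 1 + 0.01 * total
  kill_base <- beta1 * I1 * ikf / sat
  ik_N1 <- kill_base * N1
  ik_N2 <- kill_base * N2 * 0.5
  ik_R1 <- kill_base * R1 * p$immune_resist_factor1
  ik_R2 <- kill_base * R2 * p$immune_resist_factor2

  prod_I1 <- p$phi1 + p$phi2 * total / sat
  supp_I1 <- p$beta2 * I1 * I2 / (1 + I1)
  prod_I2 <- p$phi3 * total / sat

  rdf <- 1 + (1 - G)
  rd_R1 <- p$omega_R1 * resistance_multiplier * therapy * N1 * rdf
  if (rd_R1 < 0) rd_R1 <- 0
  rd_R2 <- p$omega_R2 * resistance_multiplier * therapy * N1 * rdf
  if (rd_R2 < 0) rd_R2 <- 0

  qi_N1 <- p$kappa_Q * N1 * qf
  qi_N2 <- p$kappa_Q * N2 * qf
  q_react <- p$lambda_Q * Q / qf
  senesce <- p$kappa_S * therapy * N1 * (1 + 0.3 * (1 - G))

  met_flux <- p$gamma_met * total
  met_flux <- if (opts$metastasis_hypoxia_mode == "multiply") {
    met_flux * (1 + 0.5 * hf)
  } else {
    met_flux / (1 + 0.5 * hf)
  }

  damage <- p$mutation_rate * p$genetic_instability *
    (1 + therapy + 0.5 * hf)
  shift <- M * hf * p$metabolic_switch_rate

  dy <- c(
    growth_N1 - ik_N1 * immuno_boost - therapy * N1 - qi_N1 -
      rd_R1 - rd_R2 - senesce,                                   # N1
    growth_N2 - ik_N2 * immuno_boost - 0.5 * therapy * N2 - qi_N2, # N2
    prod_I1 - supp_I1 - delta_I * I1 + 0.1 * uI * I1,            # I1
    prod_I2 - delta_I * I2 - 0.1 * uI * I2,                      # I2
    met_flux - p$delta_P * P,                                    # P
    p$alpha_A * total / sat - p$delta_A * A,                     # A
    qi_N1 + qi_N2 - q_react,                                     # Q
    rd_R1 + growth_R1 - ik_R1 * immuno_boost,                    # R1
    rd_R2 + growth_R2 - ik_R2 * immuno_boost,                    # R2
    senesce - p$delta_S * S,                                     # S
    pk_flux - adj_elim * D,                                      # D
    adj_elim * D,                                                # Dm
    -damage * G + 0.001 * (1 - G),                               # G
    shift - 0.05 * M,                                            # M
    0.1 * hf - 0.1 * A * H                                       # H
  )
  ff <- if (t > 0) 0.01 * (1 + (1 - alpha) * min(t^(-alpha), 100)) else 1.0
  dy <- dy * ff
  if (any(!is.finite(dy))) {
    bad <- state_names()[!is.finite(dy)]
    stop("non-finite derivative in compartment(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (want_intermediates) {
    attr(dy, "intermediates") <- list(
      total_tumor = total, carrying_capacity_factor = ccf,
      growth_factor = growth_factor, acidosis_effect = acidosis,
      hypoxia_factor = hf, hypoxia_effect = hyp_eff,
      immune_kill_factor = ikf, quiescence_factor = qf,
      therapy_effect = therapy, resistance_dev_factor = rdf,
      genetic_damage_rate = damage, metabolic_shift = shift,
      fractional_factor = ff, circadian_factor = cf
    )
  }
  dy
}

#' Model derivatives
#'
#' Evaluates the complete 15-equation right-hand side at time `t`,
#' including circadian modulation of `lambda1`, `lambda2`, `delta_I`
#' and `beta1`, and multiplies the result by the fractional-order memory
#' factor. The incoming state is floored at 1e-6 before any term is
#' computed.
#'
#' @param t Time (days).
#' @param state Named 15-component state vector.
#' @param params A `fotsim_params` object.
#' @param controls A `fotsim_controls` object (drug effects, temperature,
#'   immune boost).
#' @param resistance_multiplier Protocol-specific multiplier on the
#'   resistance induction rates `omega_R1`/`omega_R2` (1 for standard
#'   protocols).
#' @param alpha Fractional order in `(0, 1]`.
#' @param pk_flux Total drug absorption input into the `D` compartment
#'   (concentration units per day, default 0 = no dosing).
#' @param options A `fotsim_options` object.
#' @return Named numeric vector of the 15 time derivatives, with the
#'   evaluated intermediate quantities attached as attribute
#'   `"intermediates"`.
#' @export
#' @examples
#' dy <- derivatives(0, initial_state(), default_parameters())
#' attr(dy, "intermediates")$total_tumor  # 202.2
derivatives <- function(t, state, params, controls = control_inputs(),
                        resistance_multiplier = 1.0, alpha = 1.0,
                        pk_flux = 0, options = model_options()) {
  y <- unname(state[state_names()])
  if (any(is.na(y))) stop("state must contain all 15 named compartments")
  adj_elim <- params$elimination_rate * params$liver_function *
    params$kidney_function
  immuno_boost <- controls$immuno_boost
  dy <- rhs_core(t, y, params, controls$uE, controls$uH, controls$uC,
                 controls$uI, controls$temperature, immuno_boost,
                 resistance_multiplier, alpha, pk_flux, adj_elim, options,
                 want_intermediates = TRUE)
  inter <- attr(dy, "intermediates")
  dy <- as.numeric(dy)
  names(dy) <- state_names()
  attr(dy, "intermediates") <- inter
  dy
}
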