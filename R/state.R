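#' Model state vector
#'
#' The model tracks 15 compartments: sensitive (`N1`) and partially
#' resistant (`N2`) tumor cells, cytotoxic (`I1`) and regulatory (`I2`)
#' immune cells, metastatic potential (`P`), angiogenesis factor (`A`),
#' quiescent cells (`Q`), two resistant subpopulations (`R1`, `R2`),
#' senescent cells (`S`), drug concentration (`D`), metabolized drug
#' (`Dm`), genetic stability (`G`, a 0-1 index), metabolic status (`M`)
#' and hypoxia level (`H`).
#'
#' @return Character vector of the 15 state names, in model order.
#' @export
state_names <- function() {
  c("N1", "N2", "I1", "I2", "P", "A", "Q", "R1", "R2", "S",
    "D", "Dm", "G", "M", "H")
}

# numeric floor applied to every compartment before derivative evaluation
STATE_FLOOR <- 1e-6

#' Construct a state vector
#'
#' Builds a named 15-component state vector. With no arguments this is the
#' reference initial condition of the simulation study: a 202.2-unit tumor
#' (190 sensitive, 10 partially resistant, small quiescent/resistant/
#' senescent seeds), 40 cytotoxic and 10 regulatory immune cells, no drug
#' on board, full genetic stability, unit metabolic status and no hypoxia.
#' The two resistant seeds are clamped from below at
#' `params$resistance_floor` (pre-existing resistant subclones).
#'
#' @param N1,N2,I1,I2,P,A,Q,R1,R2,S,D,Dm,G,M,H Compartment values.
#' @param params Parameter set supplying `resistance_floor`; `NULL` skips
#'   the resistance clamp.
#' @return Named numeric vector of length 15.
#' @export
#' @examples
#' y0 <- initial_state()
#' total_tumor_burden(y0)  # 202.2
initial_state <- function(N1 = 190, N2 = 10, I1 = 40, I2 = 10, P = 0.1,
                          A = 1, Q = 0.1, R1 = 1.0, R2 = 1.0, S = 0.1,
                          D = 0.0, Dm = 0.0, G = 1.0, M = 1.0, H = 0.0,
                          params = NULL) {
  y <- c(N1 = N1, N2 = N2, I1 = I1, I2 = I2, P = P, A = A, Q = Q,
         R1 = R1, R2 = R2, S = S, D = D, Dm = Dm, G = G, M = M, H = H)
  if (!is.null(params)) {
    floor_r <- params$resistance_floor
    y["R1"] <- max(y["R1"], floor_r)
    y["R2"] <- max(y["R2"], floor_r)
  }
  y
}

#' Apply the nonnegativity floor
#'
#' Clamps every compartment at 1e-6 (and `G` additionally into
#' `[1e-6, 1]`, since genetic stability is a 0-1 index whose recovery term
#' targets 1). The floor is applied to the incoming state copy at every
#' derivative evaluation so populations and concentrations stay physically
#' meaningful.
#'
#' @param y Numeric state vector (15 components, or longer when per-drug
#'   concentration slots are appended during integration).
#' @return Floored copy of `y`.
#' @export
floor_state <- function(y) {
  y <- pmax(y, STATE_FLOOR)
  y[13] <- min(y[13], 1.0)  # G
  y
}

#' Total tumor burden
#'
#' Sums the six tumor compartments `N1 + N2 + Q + R1 + R2 + S`; immune
#' cells, drug, microenvironment and genetic compartments are excluded.
#'
#' @param state Named state vector (or matrix with state columns).
#' @return Nonnegative scalar (or vector for a trajectory matrix).
#' @export
#' @examples
#' total_tumor_burden(initial_state())  # 202.2
total_tumor_burden <- function(state) {
  comp <- c("N1", "N2", "Q", "R1", "R2", "S")
  if (is.matrix(state)) {
    if (!all(comp %in% colnames(state))) stop("missing tumor compartments")
    vals <- state[, comp, drop = FALSE]
    if (any(!is.finite(vals))) stop("non-finite state in tumor compartments")
    return(rowSums(vals))
  }
  vals <- state[comp]
  if (any(is.na(vals))) stop("missing tumor compartments in state")
  if (any(!is.finite(vals))) stop("non-finite state in tumor compartments")
  sum(vals)
}

#' Control inputs acting on the model
#'
#' Bundles the instantaneous therapy controls: the four drug effects
#' (`uE` hormone/endocrine, `uH` HER2, `uC` chemotherapy, `uI`
#' immunotherapy), body/tumor `temperature` (degrees C) and the
#' `immuno_boost` multiplier on immune kill terms. With no active drugs
#' and no hyperthermia all effects are 0, temperature is 37.0 and
#' `immuno_boost` is 1.
#'
#' @param uE,uH,uC,uI Nonnegative drug effects (dimensionless).
#' @param temperature Body/tumor temperature, >= 36.
#' @param immuno_boost Nonnegative multiplier on immune kill terms.
#' @return An object of class `fotsim_controls` (named list).
#' @export
control_inputs <- function(uE = 0, uH = 0, uC = 0, uI = 0,
                           temperature = 37.0, immuno_boost = 1.0) {
  if (any(c(uE, uH, uC, uI) < 0)) stop("drug effects must be >= 0")
  if (temperature < 36) stop("temperature must be >= 36 degrees C")
  if (immuno_boost < 0) stop("immuno_boost must be >= 0")
  structure(list(uE = uE, uH = uH, uC = uC, uI = uI,
                 temperature = temperature, immuno_boost = immuno_boost),
            class = "fotsim_controls")
}
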