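# Independent monolithic transcription of the printed 15-equation system,
# written term by term as one flat expression block (no shared intermediate
# helpers from the package). Used to cross-check the package's modular RHS.
oracle_rhs <- function(t, y, p, uE = 0, uH = 0, uC = 0, uI = 0,
                       temperature = 37, immuno_boost = 1,
                       resistance_multiplier = 1, alpha = 1, pk_flux = 0,
                       hyper_coef = 0.1) {
  y <- pmax(y, 1e-6)
  y[13] <- min(y[13], 1)
  N1 <- y[1]; N2 <- y[2]; I1 <- y[3]; I2 <- y[4]; P <- y[5]; A <- y[6]
  Q <- y[7]; R1 <- y[8]; R2 <- y[9]; S <- y[10]; D <- y[11]; Dm <- y[12]
  G <- y[13]; M <- y[14]; H <- y[15]

  circ <- if (isTRUE(p$circadian_enabled)) {
    1.0 + p$circadian_amplitude *
      sin(2 * pi * (t / p$circadian_period - p$circadian_phase))
  } else 1.0

  total <- N1 + N2 + Q + R1 + R2 + S
  ccf <- max(0, 1 - total / p$K)
  hf <- min(1, max(0, total / p$K - p$hypoxia_threshold) /
              (1 - p$hypoxia_threshold))
  therapy <- (p$eta_E * uE + p$eta_H * uH + p$eta_C * uC) *
    (1 + hyper_coef * max(0, temperature - 37))
  elim <- p$elimination_rate * p$liver_function * p$kidney_function

  dN1 <- (p$lambda1 * circ) * N1 * (ccf * (1 + 0.2 * M)) /
           (1 + p$acidosis_factor * M * total / p$K) -
         ((p$beta1 * circ) * N1 * I1 * (1 / (1 + 0.5 * hf)) /
            (1 + 0.01 * total)) * immuno_boost -
         therapy * N1 -
         p$kappa_Q * N1 * (1 + 0.5 * hf) -
         max(p$omega_R1 * resistance_multiplier * therapy * N1 *
               (1 + (1 - G)), 0) -
         max(p$omega_R2 * resistance_multiplier * therapy * N1 *
               (1 + (1 - G)), 0) -
         p$kappa_S * therapy * N1 * (1 + 0.3 * (1 - G))
  dN2 <- (p$lambda2 * circ) * N2 * (ccf * (1 + 0.2 * M)) /
           (1 + p$acidosis_factor * M * total / p$K) -
         ((p$beta1 * circ) * N2 * I1 * 0.5 * (1 / (1 + 0.5 * hf)) /
            (1 + 0.01 * total)) * immuno_boost -
         0.5 * therapy * N2 -
         p$kappa_Q * N2 * (1 + 0.5 * hf)
  dI1 <- (p$phi1 + p$phi2 * total / (1 + 0.01 * total)) -
         p$beta2 * I1 * I2 / (1 + I1) -
         (p$delta_I * circ) * I1 + 0.1 * uI * I1
  dI2 <- p$phi3 * total / (1 + 0.01 * total) -
         (p$delta_I * circ) * I2 - 0.1 * uI * I2
  dP <- p$gamma_met * total / (1 + 0.5 * hf) - p$delta_P * P
  dA <- p$alpha_A * total / (1 + 0.01 * total) - p$delta_A * A
  dQ <- p$kappa_Q * N1 * (1 + 0.5 * hf) + p$kappa_Q * N2 * (1 + 0.5 * hf) -
        p$lambda_Q * Q / (1 + 0.5 * hf)
  dR1 <- max(p$omega_R1 * resistance_multiplier * therapy * N1 *
               (1 + (1 - G)), 0) +
         p$lambda_R1 * R1 * (ccf * (1 + 0.2 * M)) /
           (1 + p$acidosis_factor * M * total / p$K) -
         ((p$beta1 * circ) * R1 * I1 * p$immune_resist_factor1 *
            (1 / (1 + 0.5 * hf)) / (1 + 0.01 * total)) * immuno_boost
  dR2 <- max(p$omega_R2 * resistance_multiplier * therapy * N1 *
               (1 + (1 - G)), 0) +
         p$lambda_R2 * R2 * (ccf * (1 + 0.2 * M)) /
           (1 + p$acidosis_factor * M * total / p$K) -
         ((p$beta1 * circ) * R2 * I1 * p$immune_resist_factor2 *
            (1 / (1 + 0.5 * hf)) / (1 + 0.01 * total)) * immuno_boost
  dS <- p$kappa_S * therapy * N1 * (1 + 0.3 * (1 - G)) - p$delta_S * S
  dD <- pk_flux - elim * D
  dDm <- elim * D
  dG <- -(p$mutation_rate * p$genetic_instability *
            (1 + therapy + 0.5 * hf)) * G + 0.001 * (1 - G)
  dM <- M * hf * p$metabolic_switch_rate - 0.05 * M
  dH <- 0.1 * hf - 0.1 * A * H

  ff <- if (t > 0) 0.01 * (1 + (1 - alpha) * min(t^(-alpha), 100)) else 1.0
  c(dN1, dN2, dI1, dI2, dP, dA, dQ, dR1, dR2, dS, dD, dDm, dG, dM, dH) * ff
}

# random finite state for property tests (positive, spanning magnitudes)
random_state <- function() {
  y <- stats::runif(15, 0, 1) * 10^stats::runif(15, -3, 2.5)
  names(y) <- state_names()
  y["G"] <- stats::runif(1, 0, 1)
  y
}

quick_config <- function(...) simulation_config(...)
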