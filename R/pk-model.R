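#' Convert an mg/kg infusion regimen to molar amount and rate
#'
#' Doses are prescribed in mg of ascorbate per kg body weight while plasma
#' concentrations are measured in mM, so model amounts are kept in mmol
#' (molar mass of ascorbic acid: 176.12 g/mol).
#'
#' @param regimen An [infusion_regimen()].
#' @return A list with `amount` (mmol) and `rate` (mmol/h).
#' @export
#' @examples
#' dose_to_amount(infusion_regimen(2200, 9, 6)) # ~112.4 mmol at ~18.7 mmol/h
dose_to_amount <- function(regimen) {
  if (!inherits(regimen, "infusion_regimen")) {
    abort("`regimen` must be an `infusion_regimen` object.")
  }
  amount <- regimen$dose_per_kg * regimen$body_weight / ASCORBATE_MOLAR_MASS
  list(amount = amount, rate = amount / regimen$t_inf)
}

#' Micro rate constants and disposition exponents
#'
#' Derive the first-order micro constants of the two-compartment mammillary
#' model (`k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`) and the disposition
#' exponents `alpha >= beta`, the roots of
#' `lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0`. The macro-coefficient
#' weights satisfy `A_coef + B_coef = 1`; the unit-bolus central concentration
#' is `(A_coef exp(-alpha t) + B_coef exp(-beta t)) / V1`.
#' With `Q = 0` the compartments decouple: `alpha = k10`, `beta = 0`.
#'
#' @param params A [pop_params()] object or named list with `CL`, `V1`, `Q`,
#'   `V2` (individual values are accepted under `CL_i` etc.).
#' @return A list of class `micro_constants` with fields `k10`, `k12`, `k21`,
#'   `alpha`, `beta`, `A_coef`, `B_coef` (all rates in 1/h).
#' @export
#' @examples
#' micro_constants(ascorbate_pop_params())
micro_constants <- function(params) {
  p <- .structural(params)
  CL <- p[1]; V1 <- p[2]; Q <- p[3]; V2 <- p[4]
  k10 <- CL / V1
  if (Q <= 0 || V2 <= 0) {
    out <- list(k10 = k10, k12 = 0, k21 = 0, alpha = k10, beta = 0,
                A_coef = 1, B_coef = 0)
    return(structure(out, class = "micro_constants"))
  }
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21    # always >= 0 for a mammillary model
  root <- sqrt(max(disc, 0))
  alpha <- (s + root) / 2
  beta <- k10 * k21 / alpha      # Vieta; numerically stable slow root
  if ((alpha - beta) / alpha < 1e-9) {
    # confluent (repeated-root) limit; weights taken at the common exponent
    lam <- s / 2
    out <- list(k10 = k10, k12 = k12, k21 = k21, alpha = lam, beta = lam,
                A_coef = 0.5, B_coef = 0.5)
  } else {
    out <- list(
      k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta,
      A_coef = (alpha - k21) / (alpha - beta),
      B_coef = (k21 - beta) / (alpha - beta)
    )
  }
  structure(out, class = "micro_constants")
}

#' @export
print.micro_constants <- function(x, ...) {
  cat(sprintf("k10 = %.5g  k12 = %.5g  k21 = %.5g  (1/h)\n", x$k10, x$k12, x$k21))
  cat(sprintf("alpha = %.5g  beta = %.5g  A = %.5g  B = %.5g\n",
              x$alpha, x$beta, x$A_coef, x$B_coef))
  invisible(x)
}

# Cumulative response F(u): central concentration at time u under an infusion
# (rate mmol/h) that started at u = 0 and never stops. The finite infusion is
# the superposition F(u) - F(u - t_inf) of two step inputs, which is exact for
# this linear time-invariant system and continuous at u = t_inf.
.conc_step <- function(u, rate, CL, V1, Q, V2) {
  if (Q <= 0 || V2 <= 0) {
    k <- CL / V1
    return((rate / CL) * (1 - exp(-k * u)))
  }
  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  root <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + root) / 2
  beta <- k10 * k21 / alpha   # Vieta; avoids cancellation in (s - root)/2
  if ((alpha - beta) / alpha < 1e-9) {
    # repeated-root limit of the two-exponential form
    lam <- s / 2
    (rate / V1) * ((1 - exp(-lam * u)) / lam -
      (lam - k21) * (1 - (1 + lam * u) * exp(-lam * u)) / lam^2)
  } else {
    A <- (alpha - k21) / (alpha - beta)
    B <- (k21 - beta) / (alpha - beta)
    (rate / V1) * (A * (1 - exp(-alpha * u)) / alpha +
                   B * (1 - exp(-beta * u)) / beta)
  }
}

# Hot path used by the simulator and the SAEM estimator: no argument checks.
.conc2 <- function(t, rate, t_inf, CL, V1, Q = 0, V2 = 0, start_time = 0) {
  u <- pmax(t - start_time, 0)
  .conc_step(u, rate, CL, V1, Q, V2) -
    .conc_step(pmax(u - t_inf, 0), rate, CL, V1, Q, V2)
}

#' Closed-form concentration-time profile under a zero-order infusion
#'
#' Central-compartment concentration of the two-compartment model during and
#' after a constant-rate IV infusion, evaluated in closed form (the finite
#' infusion is the exact superposition of two step inputs, so the profile is
#' continuous at the end of infusion). The drug-free initial condition gives
#' `conc = 0` at the infusion start, and the profile is exactly linear in
#' dose.
#'
#' @param t Times, h (non-negative).
#' @param regimen An [infusion_regimen()].
#' @param params Structural parameters (see [micro_constants()]).
#' @return Concentrations in mM, same length as `t`.
#' @export
#' @examples
#' tt <- c(0, 0.5, 1, 3, 5, 6, 6.5, 7, 8, 10, 12, 16)
#' conc_profile(tt, infusion_regimen(2200, 9, 6), ascorbate_pop_params())
conc_profile <- function(t, regimen, params) {
  if (!is.numeric(t)) abort("`t` must be numeric (hours).")
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be finite and non-negative.")
  }
  if (!inherits(regimen, "infusion_regimen")) {
    abort("`regimen` must be an `infusion_regimen` object.")
  }
  p <- .structural(params)
  rate <- dose_to_amount(regimen)$rate
  .conc2(t, rate, regimen$t_inf, p[1], p[2], p[3], p[4], regimen$start_time)
}

#' Steady-state plateau concentration of an infinite-duration infusion
#'
#' The concentration an infusion at this rate would approach if continued
#' indefinitely: `rate / CL`. The 6-h infusions of the canine study were
#' chosen to approach this plateau, so end-of-infusion concentrations sit
#' just below it.
#'
#' @inheritParams conc_profile
#' @return Plateau concentration, mM.
#' @export
plateau_concentration <- function(regimen, params) {
  if (!inherits(regimen, "infusion_regimen")) {
    abort("`regimen` must be an `infusion_regimen` object.")
  }
  p <- .structural(params)
  dose_to_amount(regimen)$rate / p[1]
}

#' Derived pharmacology: half-life, steady-state volume, extraction ratio
#'
#' Terminal (beta-phase) half-life `ln(2)/beta`, model-based steady-state
#' volume `V1 + V2`, allometric cardiac output
#' `Q_cardiac = 180 * BW^-0.19` (mL/kg/min), and whole-body extraction ratio
#' `E = CL / Q_cardiac` with clearance normalised to mL/kg/min. A low `E`
#' (for canine ascorbate, about 0.03) marks a drug whose clearance is far
#' below perfusion-limited.
#'
#' @param params Structural parameters (see [micro_constants()]).
#' @param body_weight Body weight, kg (default: the 9 kg representative dog).
#' @return A list of class `derived_pk`: `t_half_beta` (h), `Vss_model` (L),
#'   `Q_cardiac` (mL/kg/min), `extraction_ratio`.
#' @export
#' @examples
#' derived_pk(ascorbate_pop_params(), body_weight = 9)
derived_pk <- function(params, body_weight = 9) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L || body_weight <= 0) {
    abort("`body_weight` must be a single positive number (kg).")
  }
  p <- .structural(params)
  mc <- micro_constants(params)
  k_term <- if (mc$beta > 0) mc$beta else mc$k10
  q_card <- 180 * body_weight^-0.19
  cl_norm <- p[1] * 1000 / 60 / body_weight  # L/h -> mL/kg/min
  structure(
    list(
      t_half_beta = log(2) / k_term,
      Vss_model = p[2] + p[4],
      Q_cardiac = q_card,
      extraction_ratio = cl_norm / q_card
    ),
    class = "derived_pk"
  )
}

#' @export
print.derived_pk <- function(x, ...) {
  cat(sprintf("Terminal half-life: %.3g h\n", x$t_half_beta))
  cat(sprintf("Model Vss (V1 + V2): %.3g L\n", x$Vss_model))
  cat(sprintf("Cardiac output: %.4g mL/kg/min; extraction ratio E = %.3g\n",
              x$Q_cardiac, x$extraction_ratio))
  invisible(x)
}
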