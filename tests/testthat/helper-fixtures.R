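# Shared fixtures: the published canine estimates, the nominal sampling grid,
# and memoised batches of SAEM fits reused by several expensive tests.

canine_params <- function(...) ascorbate_pop_params(...)

nominal_times <- c(0, 0.5, 1, 3, 5, 6, 6.5, 7, 8, 10, 12, 16)

high_dose_regimen <- function() infusion_regimen(2200, body_weight = 9, t_inf = 6)
low_dose_regimen <- function() infusion_regimen(550, body_weight = 9, t_inf = 6)

# Independent ODE oracle for the two-compartment infusion model, with an
# elimination bucket so mass balance can be checked.
ode_oracle <- function(t, regimen, params, rtol = 1e-11, atol = 1e-14) {
  skip_if_not_installed("deSolve")
  p <- list(CL = params$CL, V1 = params$V1, Q = params$Q, V2 = params$V2)
  k10 <- p$CL / p$V1
  k12 <- if (p$V1 > 0) p$Q / p$V1 else 0
  k21 <- if (p$V2 > 0) p$Q / p$V2 else 0
  rate <- dose_to_amount(regimen)$rate
  rhs <- function(tt, y, parms) {
    inp <- if (tt >= regimen$start_time &&
               tt <= regimen$start_time + regimen$t_inf) rate else 0
    list(c(inp - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2],
           k10 * y[1]))
  }
  times <- sort(unique(c(0, regimen$start_time,
                         regimen$start_time + regimen$t_inf, t)))
  out <- deSolve::ode(c(0, 0, 0), times, rhs, NULL, rtol = rtol, atol = atol)
  idx <- match(t, out[, 1])
  list(conc = out[idx, 2] / p$V1, central = out[idx, 2],
       peripheral = out[idx, 3], eliminated = out[idx, 4])
}

# Reduced SAEM schedule used throughout the suite: long enough for the
# parameter search to settle on these small studies, short enough to keep
# the whole suite fast.
test_settings <- function(seed, ...) {
  saem_settings(n_exploratory = 150, n_smoothing = 80, seed = seed,
                n_loglik_samples = 100, n_posthoc = 100, ...)
}

.fit_cache <- new.env(parent = emptyenv())

# 20 replicate studies at the published design, fitted once; reused by the recovery and
# model-selection tests.
recovery_batch <- function() {
  if (!is.null(.fit_cache$recovery)) return(.fit_cache$recovery)
  fits <- lapply(1:20, function(s) {
    d <- generate_study(seed = s)
    f2 <- suppressWarnings(saem(d, init = NULL,
                                settings = test_settings(1000 + s), se = FALSE))
    f1 <- suppressWarnings(saem(d, init = NULL, model = "one_cpt",
                                settings = test_settings(1000 + s), se = FALSE))
    list(two = f2, one = f1)
  })
  .fit_cache$recovery <- fits
  fits
}
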