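# Closed-form two-compartment infusion model and derived pharmacology.

test_that("dose conversion bridges mg/kg dosing and molar amounts", {
  da <- dose_to_amount(high_dose_regimen())
  expect_equal(da$amount, 2200 * 9 / 176.12)
  expect_equal(da$amount, 112.42, tolerance = 1e-4)
  expect_equal(da$rate, da$amount / 6)
  expect_equal(dose_to_amount(low_dose_regimen())$amount, 28.10, tolerance = 1e-3)
  expect_error(infusion_regimen(2200, 9, t_inf = 0), "t_inf")
  expect_error(infusion_regimen(-1, 9), "dose_per_kg")
  expect_error(infusion_regimen(2200, 0), "body_weight")
})

test_that("micro constants match the eigenvalues of the rate matrix", {
  p <- canine_params()
  mc <- micro_constants(p)
  expect_equal(mc$k10, p$CL / p$V1)
  expect_equal(mc$k12, p$Q / p$V1)
  expect_equal(mc$k21, p$Q / p$V2)
  # independent oracle: eigenvalues of the 2x2 rate matrix
  M <- matrix(c(-(mc$k10 + mc$k12), mc$k21, mc$k12, -mc$k21), 2, 2, byrow = TRUE)
  ev <- sort(-eigen(M)$values)
  expect_equal(mc$beta, ev[1], tolerance = 1e-12)
  expect_equal(mc$alpha, ev[2], tolerance = 1e-12)
  expect_equal(mc$k10, 1.041, tolerance = 1e-3)
  expect_equal(mc$beta, 0.192, tolerance = 1e-2)
  expect_equal(mc$A_coef + mc$B_coef, 1, tolerance = 1e-12)
})

test_that("micro constants satisfy the Vieta identities for random parameters", {
  withr::with_seed(41, {
    for (i in 1:25) {
      p <- list(CL = runif(1, 0.1, 10), V1 = runif(1, 0.1, 10),
                Q = runif(1, 0.01, 5), V2 = runif(1, 0.05, 10))
      mc <- micro_constants(p)
      expect_equal(mc$alpha * mc$beta, mc$k10 * mc$k21, tolerance = 1e-12)
      expect_equal(mc$alpha + mc$beta, mc$k10 + mc$k12 + mc$k21, tolerance = 1e-12)
      expect_true(mc$alpha >= mc$beta && mc$beta > 0)
    }
  })
})

test_that("the one-compartment limit decouples the peripheral compartment", {
  mc <- micro_constants(list(CL = 2, V1 = 2, Q = 0, V2 = 0))
  expect_equal(mc$alpha, 1)
  expect_equal(mc$beta, 0)
  expect_equal(mc$A_coef, 1)
  expect_error(pop_params(CL = 2, V1 = 2, Q = 0.1, V2 = 0), "V2")
})

test_that("closed-form profile agrees with the ODE oracle", {
  skip_if_not_installed("deSolve")
  tt <- sort(c(nominal_times, seq(0.1, 15.9, by = 0.37)))
  withr::with_seed(7, {
    for (i in 1:8) {
      p <- pop_params(CL = runif(1, 0.5, 5), V1 = runif(1, 0.5, 5),
                      Q = runif(1, 0.02, 2), V2 = runif(1, 0.1, 4))
      reg <- infusion_regimen(runif(1, 300, 2500), runif(1, 8, 10), 6)
      cf <- conc_profile(tt, reg, p)
      ode <- ode_oracle(tt, reg, p)
      # relative error where the curve is appreciable (> 1e-6 mM); below
      # that the integrator's own absolute tolerance dominates
      expect_lt(max(abs(cf - ode$conc) / pmax(ode$conc, 1e-6)), 1e-6)
    }
  })
})

test_that("mass is conserved in the ODE oracle at all times", {
  skip_if_not_installed("deSolve")
  reg <- high_dose_regimen()
  tt <- seq(0, 16, by = 0.25)
  ode <- ode_oracle(tt, reg, canine_params())
  infused <- dose_to_amount(reg)$rate * pmin(tt, reg$t_inf)
  total <- ode$central + ode$peripheral + ode$eliminated
  expect_lt(max(abs(total[-1] - infused[-1]) / infused[-1]), 1e-8)
})

test_that("the profile is continuous at end of infusion and linear in dose", {
  p <- canine_params()
  reg <- high_dose_regimen()
  eps <- 1e-9
  expect_equal(conc_profile(6 - eps, reg, p), conc_profile(6 + eps, reg, p),
               tolerance = 1e-6)
  expect_equal(conc_profile(0, reg, p), 0)
  tt <- c(0.5, 3, 6, 8, 12, 16)
  for (k in c(0.25, 2, 7)) {
    reg_k <- infusion_regimen(2200 * k, 9, 6)
    expect_equal(conc_profile(tt, reg_k, p), k * conc_profile(tt, reg, p),
                 tolerance = 1e-12)
  }
  expect_error(conc_profile(c(-1, 2), reg, p), "non-negative")
})

test_that("end-of-infusion concentration reproduces the observed peak", {
  # typical 9-kg dog, Table-2-style estimates: peak just below the plateau
  cc <- conc_profile(6, high_dose_regimen(), canine_params())
  expect_equal(cc, 8.8701, tolerance = 1e-4)   # frozen ODE-oracle value
  expect_equal(cc, 8.6, tolerance = 0.05)      # observed mean peak, ~5%
})

test_that("plateau concentration is rate/CL and is the infinite-time limit", {
  p <- canine_params()
  reg <- high_dose_regimen()
  plateau <- plateau_concentration(reg, p)
  expect_equal(plateau, 18.7372 / 2.04, tolerance = 1e-4)
  expect_equal(plateau, 9.19, tolerance = 1e-3)
  # infusion lasting 50 terminal half-lives sits within 0.1% of the plateau
  t_half <- derived_pk(p)$t_half_beta
  long <- infusion_regimen(2200 * 50, 9, t_inf = 50 * t_half)
  expect_equal(conc_profile(50 * t_half, long, p) / plateau_concentration(long, p),
               1, tolerance = 1e-3)
  big_cl <- pop_params(CL = 1e6, V1 = 1.96, Q = 0.16, V2 = 0.76)
  expect_lt(plateau_concentration(reg, big_cl), 1e-4)
})

test_that("derived pharmacology matches the published summary quantities", {
  d <- derived_pk(canine_params(), body_weight = 9)
  expect_equal(d$t_half_beta, 3.6091, tolerance = 1e-4)  # ~3.5 h reported
  expect_equal(d$t_half_beta, 3.5, tolerance = 0.05)
  expect_equal(d$Vss_model, 2.72)
  expect_equal(d$Q_cardiac, 180 * 9^-0.19)
  # extraction ratio from the weight-normalised clearance 0.24 L/kg/h
  e <- derived_pk(pop_params(CL = 0.24 * 9, V1 = 1.96), body_weight = 9)
  expect_equal(round(e$extraction_ratio, 2), 0.03)
  # one-compartment closed form for the half-life
  d1 <- derived_pk(pop_params(CL = 2, V1 = 3), body_weight = 9)
  expect_equal(d1$t_half_beta, log(2) * 3 / 2)
})

test_that("analytic AUC to infinity equals infused amount over clearance", {
  p <- canine_params()
  reg <- high_dose_regimen()
  # high-resolution quadrature of the noise-free curve far into the tail
  tt <- seq(0, 250, by = 0.01)
  cc <- conc_profile(tt, reg, p)
  auc <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  expect_equal(auc, dose_to_amount(reg)$amount / p$CL, tolerance = 1e-3)
})
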