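# Stochastic approximation EM for the nonlinear mixed-effects infusion model.
#
# Random effects are additive on the log scale (log-normal individual
# parameters). Parameters carrying a random effect are updated through the
# sufficient statistics of the linear-in-eta exponent model; parameters
# without a random effect (the inter-compartmental clearance by default) and
# the residual-error coefficients are updated by conditional-likelihood
# optimisation with stochastic-approximation smoothing.

#' SAEM algorithm settings
#'
#' @param n_exploratory Iterations of the exploratory phase (constant step
#'   size 1). The canine analysis used 1,000; parameter-recovery runs in the
#'   tests and examples use reduced schedules.
#' @param n_smoothing Iterations of the smoothing phase (step size
#'   `1/k^step_power`).
#' @param n_mcmc Metropolis-Hastings kernels applied per subject per
#'   iteration.
#' @param n_chains Independent MCMC chains per subject (sufficient statistics
#'   are averaged over chains).
#' @param step_power Exponent of the decreasing step-size schedule.
#' @param seed Optional integer seed; a fixed seed makes the whole fit
#'   bit-reproducible.
#' @param n_loglik_samples Importance-sampling draws per subject for the
#'   marginal log-likelihood.
#' @param n_posthoc,n_posthoc_burn Retained/burn-in MCMC kernels for the
#'   post-hoc individual parameters (posterior means at the final estimates).
#' @param accept_target Target Metropolis acceptance rate for the adaptive
#'   proposal scaling (adapted during exploration only, then frozen).
#' @param convergence_window,convergence_tol Convergence is declared when
#'   the relative SD of every parameter trace over the final
#'   `convergence_window` smoothing iterations is below `convergence_tol`.
#' @param log_floor Lower clamp for censored log-likelihood terms.
#' @return A list of class `saem_settings`.
#' @export
saem_settings <- function(n_exploratory = 1000, n_smoothing = 300,
                          n_mcmc = 2, n_chains = 1, step_power = 0.7,
                          seed = NULL, n_loglik_samples = 1000,
                          n_posthoc = 200, n_posthoc_burn = 50,
                          accept_target = 0.35,
                          convergence_window = 100, convergence_tol = 0.01,
                          log_floor = -700) {
  if (n_exploratory < 1 || n_smoothing < 1) {
    abort("Iteration counts must be >= 1.")
  }
  if (n_mcmc < 1 || n_chains < 1) abort("`n_mcmc` and `n_chains` must be >= 1.")
  if (step_power <= 0.5 || step_power > 1) {
    abort("`step_power` must lie in (0.5, 1] for a valid SA schedule.")
  }
  structure(
    list(n_exploratory = as.integer(n_exploratory),
         n_smoothing = as.integer(n_smoothing),
         n_mcmc = as.integer(n_mcmc), n_chains = as.integer(n_chains),
         step_power = step_power, seed = seed,
         n_loglik_samples = as.integer(n_loglik_samples),
         n_posthoc = as.integer(n_posthoc),
         n_posthoc_burn = as.integer(n_posthoc_burn),
         accept_target = accept_target,
         convergence_window = as.integer(convergence_window),
         convergence_tol = convergence_tol,
         log_floor = log_floor),
    class = "saem_settings"
  )
}

# ---- internal data layout ---------------------------------------------------

# Split a schema-conformant dataset into per-subject blocks. Subjects are
# taken in order of first appearance and observations sorted by time within
# occasion, so the fit is invariant to subject relabeling and to row
# reordering within a subject.
.saem_prep <- function(data) {
  data <- .validate_dataset(data)
  ids <- unique(data$ID)
  subjects <- lapply(ids, function(id) {
    sub <- data[data$ID == id, ]
    occs <- unique(sub$OCC)
    occ_rate <- occ_tinf <- numeric(length(occs))
    time <- dv <- lloq <- numeric(0)
    cens <- logical(0)
    occ_idx <- integer(0)
    for (j in seq_along(occs)) {
      blk <- sub[sub$OCC == occs[j], ]
      dose <- blk[blk$EVID == 1L, ]
      if (nrow(dose) == 0L) {
        abort(sprintf("Subject %s occasion %s has no dose event.", id, occs[j]))
      }
      occ_rate[j] <- dose$RATE[1] / ASCORBATE_MOLAR_MASS  # mg/h -> mmol/h
      occ_tinf[j] <- dose$AMT[1] / dose$RATE[1]
      obs <- blk[blk$EVID == 0L, ]
      obs <- obs[order(obs$TIME), ]
      time <- c(time, obs$TIME)
      dv <- c(dv, obs$DV)
      cens <- c(cens, obs$CENS == 1L)
      lloq <- c(lloq, obs$LLOQ)
      occ_idx <- c(occ_idx, rep(j, nrow(obs)))
    }
    list(id = id, time = time, dv = dv, cens = cens, lloq = lloq,
         occ_idx = occ_idx, occ_label = occs,
         occ_rate = occ_rate, occ_tinf = occ_tinf)
  })
  list(subjects = subjects,
       n_obs = sum(vapply(subjects, function(s) length(s$time), integer(1))))
}

.subject_pred <- function(sub, psi) {
  out <- numeric(length(sub$time))
  Q <- if (length(psi) > 2) psi[3] else 0
  V2 <- if (length(psi) > 3) psi[4] else 0
  for (j in seq_along(sub$occ_rate)) {
    sel <- sub$occ_idx == j
    out[sel] <- .conc2(sub$time[sel], sub$occ_rate[j], sub$occ_tinf[j],
                       psi[1], psi[2], Q, V2)
  }
  out
}

.subject_ll <- function(sub, pred, a, b, floor) {
  sum(.obs_loglik(sub$dv, pred, sub$cens, sub$lloq, a, b, floor))
}

# ---- exported MCMC building block ------------------------------------------

#' One-subject Metropolis-Hastings update of random effects
#'
#' Component-wise Gaussian random-walk kernel targeting the conditional
#' posterior of a subject's random effects: the acceptance ratio combines the
#' observation log-likelihood (supplied as a function of `eta`) with the
#' `N(0, omega^2)` prior. This is the simulation step inside SAEM, exposed so
#' its stationary distribution can be verified directly.
#'
#' @param eta Current random-effect vector.
#' @param loglik_fun Function `eta -> scalar` giving the observation
#'   log-likelihood of the subject (use `function(eta) 0` for a data-free
#'   subject, whose posterior is the prior).
#' @param omega Prior SDs, recycled to `length(eta)`; must be > 0.
#' @param proposal_sd Random-walk proposal SDs, recycled; 0 freezes a
#'   component.
#' @param n_steps Number of full component sweeps.
#' @param seed Optional integer seed.
#' @param keep_draws Return the chain (`n_steps` rows) as `draws`.
#' @return A list with `eta` (final state), `accept_rate`, and optionally
#'   `draws`.
#' @export
mcmc_individual_step <- function(eta, loglik_fun, omega, proposal_sd,
                                 n_steps = 1, seed = NULL, keep_draws = FALSE) {
  d <- length(eta)
  omega <- rep_len(omega, d)
  proposal_sd <- rep_len(proposal_sd, d)
  if (any(omega <= 0)) abort("`omega` must be > 0.")
  if (any(proposal_sd < 0)) abort("`proposal_sd` must be >= 0.")
  .with_seed(seed, {
    ll <- loglik_fun(eta)
    draws <- if (keep_draws) matrix(NA_real_, n_steps, d) else NULL
    n_acc <- 0L
    n_prop <- 0L
    for (s in seq_len(n_steps)) {
      for (j in seq_len(d)) {
        if (proposal_sd[j] == 0) next
        etap <- eta
        etap[j] <- eta[j] + proposal_sd[j] * rnorm(1)
        llp <- loglik_fun(etap)
        logr <- llp - ll +
          dnorm(etap[j], 0, omega[j], log = TRUE) -
          dnorm(eta[j], 0, omega[j], log = TRUE)
        n_prop <- n_prop + 1L
        if (log(runif(1)) < logr) {
          eta <- etap
          ll <- llp
          n_acc <- n_acc + 1L
        }
      }
      if (keep_draws) draws[s, ] <- eta
    }
    out <- list(eta = eta, accept_rate = if (n_prop) n_acc / n_prop else NA_real_)
    if (keep_draws) out$draws <- draws
    out
  })
}

# ---- marginal likelihood by importance sampling ----------------------------

# Per-subject marginal log-likelihood over the random effects, Gaussian
# proposal centred on the conditional posterior. `prop` is a list with
# matrices m (N x d) and v (N x d) of proposal means/variances.
.marginal_loglik <- function(prep, mu, omega2, iiv_idx, a, b, floor,
                             n_samples, prop, z = NULL) {
  subs <- prep$subjects
  d <- length(iiv_idx)
  if (d == 0L) {
    psi <- exp(mu)
    ll <- sum(vapply(subs, function(s) {
      .subject_ll(s, .subject_pred(s, psi), a, b, floor)
    }, numeric(1)))
    return(list(loglik = ll, se = 0))
  }
  sw <- sqrt(omega2[iiv_idx])
  total <- 0
  var_tot <- 0
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    m <- prop$m[i, ]
    pv <- sqrt(prop$v[i, ])
    zi <- if (is.null(z)) matrix(rnorm(n_samples * d), n_samples, d) else z[[i]]
    etas <- sweep(sweep(zi, 2, pv, `*`), 2, m, `+`)
    logw <- numeric(n_samples)
    for (k in seq_len(n_samples)) {
      eta_full <- numeric(length(mu))
      eta_full[iiv_idx] <- etas[k, ]
      psi <- exp(mu + eta_full)
      logw[k] <- .subject_ll(s, .subject_pred(s, psi), a, b, floor) +
        sum(dnorm(etas[k, ], 0, sw, log = TRUE)) -
        sum(dnorm(etas[k, ], m, pv, log = TRUE))
    }
    mx <- max(logw)
    w <- exp(logw - mx)
    total <- total + mx + log(mean(w))
    var_tot <- var_tot + var(w) / (n_samples * mean(w)^2)
  }
  list(loglik = total, se = sqrt(var_tot))
}

#' Marginal log-likelihood by importance sampling
#'
#' Monte Carlo estimate of the marginal likelihood of a dataset under given
#' population estimates, integrating the log-normal random effects out with
#' a Gaussian importance proposal centred on each subject's conditional
#' posterior (located by a short MCMC run). With all IIV terms equal to zero
#' the integral is degenerate and the plug-in likelihood is returned exactly
#' (`se = 0`).
#'
#' @param data Dataset tibble (schema of [read_pkdataset()]).
#' @param estimates A [pop_params()] with the population estimates.
#' @param n_samples Importance-sampling draws per subject.
#' @param seed Optional integer seed.
#' @param model `"two_cpt"` or `"one_cpt"`.
#' @param proposal_inflation Variance inflation of the Gaussian proposal.
#' @return A list with `loglik`, `se` (Monte Carlo standard error) and
#'   `n_samples`.
#' @export
loglik_importance <- function(data, estimates, n_samples = 1000, seed = NULL,
                              model = c("two_cpt", "one_cpt"),
                              proposal_inflation = 1.5) {
  model <- match.arg(model)
  if (!inherits(estimates, "pop_params")) {
    abort("`estimates` must be a `pop_params` object.")
  }
  if (n_samples < 2) abort("`n_samples` must be >= 2.")
  if (proposal_inflation <= 0) abort("`proposal_inflation` must be > 0.")
  prep <- .saem_prep(data)
  if (model == "two_cpt") {
    mu <- log(c(estimates$CL, estimates$V1, estimates$Q, estimates$V2))
    omega2 <- c(estimates$omega_CL, estimates$omega_V1, 0, estimates$omega_V2)^2
  } else {
    mu <- log(c(estimates$CL, estimates$V1))
    omega2 <- c(estimates$omega_CL, estimates$omega_V1)^2
  }
  iiv_idx <- which(omega2 > 0)
  a <- estimates$err_add
  b <- estimates$err_prop
  .with_seed(seed, {
    prop <- .posthoc_proposal(prep, mu, omega2, iiv_idx, a, b, -700,
                              n_burn = 100, n_keep = 150,
                              inflation = proposal_inflation)
    out <- .marginal_loglik(prep, mu, omega2, iiv_idx, a, b, -700,
                            n_samples, prop)
    out$n_samples <- n_samples
    out
  })
}

# Short MCMC at fixed parameters; returns proposal moments and posterior
# means of the individual parameters.
.posthoc_proposal <- function(prep, mu, omega2, iiv_idx, a, b, floor,
                              n_burn, n_keep, inflation = 1.5) {
  subs <- prep$subjects
  N <- length(subs)
  p <- length(mu)
  d <- length(iiv_idx)
  psi_mean <- matrix(rep(exp(mu), each = N), N, p)
  if (d == 0L) {
    return(list(m = matrix(0, N, 0), v = matrix(0, N, 0), psi_mean = psi_mean))
  }
  sw <- sqrt(omega2[iiv_idx])
  m <- v <- matrix(0, N, d)
  prop_sd <- pmax(sw, 0.05)
  for (i in seq_len(N)) {
    s <- subs[[i]]
    eta <- numeric(p)
    psi <- exp(mu + eta)
    ll <- .subject_ll(s, .subject_pred(s, psi), a, b, floor)
    keep_eta <- matrix(0, n_keep, d)
    keep_psi <- matrix(0, n_keep, p)
    for (k in seq_len(n_burn + n_keep)) {
      for (jj in seq_len(d)) {
        j <- iiv_idx[jj]
        etap <- eta
        etap[j] <- eta[j] + prop_sd[jj] * rnorm(1)
        psip <- exp(mu + etap)
        llp <- .subject_ll(s, .subject_pred(s, psip), a, b, floor)
        logr <- llp - ll +
          dnorm(etap[j], 0, sw[jj], log = TRUE) -
          dnorm(eta[j], 0, sw[jj], log = TRUE)
        if (log(runif(1)) < logr) {
          eta <- etap
          ll <- llp
        }
      }
      if (k > n_burn) {
        keep_eta[k - n_burn, ] <- eta[iiv_idx]
        keep_psi[k - n_burn, ] <- exp(mu + eta)
      }
    }
    m[i, ] <- colMeans(keep_eta)
    v[i, ] <- pmax(apply(keep_eta, 2, var) * inflation, 1e-6)
    psi_mean[i, ] <- colMeans(keep_psi)
  }
  list(m = m, v = v, psi_mean = psi_mean)
}

# ---- the estimator ----------------------------------------------------------

#' Fit the population model by stochastic approximation EM
#'
#' Two-phase SAEM for the nonlinear mixed-effects infusion model with
#' censored (BLQ) likelihood: an exploratory phase with constant step size 1
#' followed by a smoothing phase with step `1/k^step_power`. Each iteration
#' draws subject random effects from their conditional posteriors by
#' adaptive Metropolis-Hastings, then updates (i) parameters with IIV via the
#' stochastically averaged sufficient statistics of the log-normal model,
#' (ii) parameters without IIV and the residual-error coefficients via
#' conditional-likelihood optimisation with the same stochastic averaging.
#' Random effects are placed on the parameters whose initial `omega` is
#' positive (defaults: CL, V1, V2; the inter-compartmental clearance carries
#' none). After the parameter search the fit computes post-hoc individual
#' parameters (posterior means from retained MCMC draws at the final
#' estimates), the marginal log-likelihood by importance sampling, BIC, and
#' optionally relative standard errors from a Monte Carlo Fisher-information
#' estimate.
#'
#' @param data Dataset tibble (schema of [read_pkdataset()]); needs at least
#'   2 subjects with 4 observations each. Occasions of one subject share the
#'   subject's random effects.
#' @param init Initial [pop_params()]; `NULL` derives crude starting values
#'   from the data. Parameters with `omega = 0` in `init` are fitted without
#'   a random effect.
#' @param settings A [saem_settings()].
#' @param model `"two_cpt"` (default) or `"one_cpt"` for the nested
#'   one-compartment alternative used in BIC-based model selection.
#' @param estimate_error Estimate the residual-error coefficients (those with
#'   positive initial values) jointly; `FALSE` keeps them fixed at `init`.
#' @param se Compute relative standard errors (adds a modest Monte Carlo
#'   cost).
#' @return An object of class `saem_fit`: list with `estimates`
#'   ([pop_params()]), `individual` (post-hoc tibble), `loglik`, `loglik_se`,
#'   `bic`, `rse`, `trace` (tibble of per-iteration estimates), `converged`,
#'   `convergence` (per-parameter table), `settings`, `model`, `n_obs`,
#'   `n_subjects`, `n_par`. Non-convergence is reported with a warning, never
#'   silently.
#' @export
#' @examples
#' \donttest{
#' d <- generate_study(seed = 42)
#' fit <- saem(d, init = ascorbate_pop_params(),
#'             settings = saem_settings(n_exploratory = 100, n_smoothing = 50,
#'                                      seed = 1))
#' tidy(fit)
#' glance(fit)
#' }
saem <- function(data, init = NULL, settings = saem_settings(),
                 model = c("two_cpt", "one_cpt"),
                 estimate_error = TRUE, se = TRUE) {
  model <- match.arg(model)
  if (!inherits(settings, "saem_settings")) {
    abort("`settings` must come from `saem_settings()`.")
  }
  prep <- .saem_prep(data)
  subs <- prep$subjects
  N <- length(subs)
  if (N < 2) abort("SAEM needs at least 2 subjects.")
  if (any(vapply(subs, function(s) length(s$time), integer(1)) < 4)) {
    abort("Every subject needs at least 4 observations.")
  }
  if (is.null(init)) init <- .saem_init(prep)
  if (!inherits(init, "pop_params")) abort("`init` must be a `pop_params` object.")

  if (model == "two_cpt") {
    pnames <- c("CL", "V1", "Q", "V2")
    mu <- log(c(init$CL, init$V1, max(init$Q, 1e-3), max(init$V2, 1e-3)))
    omega0 <- c(init$omega_CL, init$omega_V1, 0, init$omega_V2)
  } else {
    pnames <- c("CL", "V1")
    mu <- log(c(init$CL, init$V1))
    omega0 <- c(init$omega_CL, init$omega_V1)
  }
  p <- length(mu)
  iiv_idx <- which(omega0 > 0)
  fix_idx <- setdiff(seq_len(p), iiv_idx)
  omega2 <- omega0^2
  a <- init$err_add
  b <- init$err_prop
  if (a <= 0 && b <= 0) abort("At least one residual-error coefficient must be > 0.")
  est_a <- estimate_error && a > 0
  est_b <- estimate_error && b > 0
  floor <- settings$log_floor
  K1 <- settings$n_exploratory
  K2 <- settings$n_smoothing
  n_chains <- settings$n_chains

  t0 <- proc.time()[["elapsed"]]
  res <- .with_seed(settings$seed, {
    eta <- array(0, dim = c(N, p, n_chains))
    prop_sd <- pmax(sqrt(omega2[iiv_idx]), 0.1)
    S1 <- S2 <- numeric(p)
    trace_cols <- c(pnames,
                    if (length(iiv_idx)) paste0("omega_", pnames[iiv_idx]),
                    if (est_a) "err_add", if (est_b) "err_prop")
    trace <- matrix(NA_real_, K1 + K2, length(trace_cols),
                    dimnames = list(NULL, trace_cols))

    pooled_dv <- unlist(lapply(subs, `[[`, "dv"))
    pooled_cens <- unlist(lapply(subs, `[[`, "cens"))
    pooled_lloq <- unlist(lapply(subs, `[[`, "lloq"))

    for (k in seq_len(K1 + K2)) {
      gamma <- if (k <= K1) 1 else 1 / ((k - K1)^settings$step_power)
      sw <- sqrt(omega2[iiv_idx])
      acc <- n_prop <- numeric(length(iiv_idx))

      # -- simulation step: MH on each subject's random effects
      for (ch in seq_len(n_chains)) {
        for (i in seq_len(N)) {
          s <- subs[[i]]
          eta_i <- eta[i, , ch]
          psi <- exp(mu + eta_i)
          pred <- .subject_pred(s, psi)
          ll <- .subject_ll(s, pred, a, b, floor)
          for (m_k in seq_len(settings$n_mcmc)) {
            for (jj in seq_along(iiv_idx)) {
              j <- iiv_idx[jj]
              etap <- eta_i
              etap[j] <- eta_i[j] + prop_sd[jj] * rnorm(1)
              psip <- exp(mu + etap)
              predp <- .subject_pred(s, psip)
              llp <- .subject_ll(s, predp, a, b, floor)
              logr <- llp - ll +
                dnorm(etap[j], 0, sw[jj], log = TRUE) -
                dnorm(eta_i[j], 0, sw[jj], log = TRUE)
              n_prop[jj] <- n_prop[jj] + 1
              # a non-finite ratio (overflowed proposal) counts as rejection
              if (isTRUE(log(runif(1)) < logr)) {
                eta_i <- etap
                ll <- llp
                acc[jj] <- acc[jj] + 1
              }
            }
          }
          eta[i, , ch] <- eta_i
        }
      }
      if (k <= K1 && length(iiv_idx)) {
        rate <- acc / pmax(n_prop, 1)
        prop_sd <- pmin(pmax(prop_sd * exp(0.4 * (rate - settings$accept_target)),
                             1e-3), 5)
      }

      # -- stochastic approximation of the sufficient statistics
      if (length(iiv_idx)) {
        phi1 <- phi2 <- numeric(p)
        for (ch in seq_len(n_chains)) {
          phi <- sweep(eta[, , ch, drop = FALSE][, , 1], 2, mu, `+`)
          phi1 <- phi1 + colSums(phi)
          phi2 <- phi2 + colSums(phi^2)
        }
        phi1 <- phi1 / n_chains
        phi2 <- phi2 / n_chains
        S1 <- S1 + gamma * (phi1 - S1)
        S2 <- S2 + gamma * (phi2 - S2)
        mu_old <- mu
        mu[iiv_idx] <- S1[iiv_idx] / N
        om_emp <- pmax(S2[iiv_idx] / N - (S1[iiv_idx] / N)^2, 1e-8)
        # simulated annealing: during exploration the variance components may
        # shrink at most 5% per iteration, preventing premature collapse of
        # the random-effect distribution before the chains have dispersed
        omega2[iiv_idx] <- if (k <= K1) {
          pmax(om_emp, 0.95 * omega2[iiv_idx])
        } else {
          om_emp
        }
        # keep the search numerically sane on degenerate (unidentifiable)
        # data: log-parameters within exp(+-50), log-SD of IIV at most 5
        mu[iiv_idx] <- pmin(pmax(mu[iiv_idx], -50), 50)
        omega2[iiv_idx] <- pmin(omega2[iiv_idx], 25)
        # the MCMC state is the individual log-parameter phi = mu + eta:
        # shift eta so phi is unchanged by the population-mean update
        for (ch in seq_len(n_chains)) {
          eta[, iiv_idx, ch] <- eta[, iiv_idx, ch] +
            matrix(mu_old[iiv_idx] - mu[iiv_idx], N, length(iiv_idx), byrow = TRUE)
        }
      }

      # -- conditional update of parameters without random effects
      if (length(fix_idx)) {
        tot_ll <- function(mu_fix) {
          mu2 <- mu
          mu2[fix_idx] <- mu_fix
          tot <- 0
          for (ch in seq_len(n_chains)) {
            for (i in seq_len(N)) {
              psi <- exp(mu2 + eta[i, , ch])
              tot <- tot + .subject_ll(subs[[i]], .subject_pred(subs[[i]], psi),
                                       a, b, floor)
            }
          }
          tot
        }
        if (length(fix_idx) == 1L) {
          opt <- optimize(function(v) -tot_ll(v),
                          interval = mu[fix_idx] + c(-1.5, 1.5), tol = 1e-3)$minimum
        } else {
          opt <- optim(mu[fix_idx], function(v) -tot_ll(v),
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-9))$par
        }
        mu[fix_idx] <- mu[fix_idx] + gamma * (opt - mu[fix_idx])
      }

      # -- conditional update of residual-error coefficients
      if (est_a || est_b) {
        pooled_pred <- unlist(lapply(seq_len(N), function(i) {
          acc_pred <- 0
          for (ch in seq_len(n_chains)) {
            acc_pred <- acc_pred +
              .subject_pred(subs[[i]], exp(mu + eta[i, , ch]))
          }
          acc_pred / n_chains
        }))
        err_obj <- function(la, lb) {
          -sum(.obs_loglik(pooled_dv, pooled_pred, pooled_cens, pooled_lloq,
                           exp(la), exp(lb), floor))
        }
        # the same annealing guard applies to the residual-error scale
        anneal <- function(old, new) {
          if (k <= K1) max(new, sqrt(0.95) * old) else new
        }
        if (est_a && est_b) {
          o <- optim(c(log(a), log(b)), function(v) err_obj(v[1], v[2]),
                     method = "Nelder-Mead",
                     control = list(maxit = 40, reltol = 1e-7))$par
          a <- anneal(a, exp(log(a) + gamma * (o[1] - log(a))))
          b <- anneal(b, exp(log(b) + gamma * (o[2] - log(b))))
        } else if (est_a) {
          o <- optimize(function(v) err_obj(v, log(max(b, 1e-300))),
                        interval = log(a) + c(-2, 2), tol = 1e-4)$minimum
          a <- anneal(a, exp(log(a) + gamma * (o - log(a))))
        } else {
          o <- optimize(function(v) err_obj(log(max(a, 1e-300)), v),
                        interval = log(b) + c(-2, 2), tol = 1e-4)$minimum
          b <- anneal(b, exp(log(b) + gamma * (o - log(b))))
        }
      }

      trace[k, ] <- c(exp(mu),
                      if (length(iiv_idx)) sqrt(omega2[iiv_idx]),
                      if (est_a) a, if (est_b) b)
    }

    # -- convergence assessment on the final smoothing window
    win <- min(settings$convergence_window, K2)
    tail_tr <- trace[(K1 + K2 - win + 1):(K1 + K2), , drop = FALSE]
    rel_sd <- apply(tail_tr, 2, function(x) {
      m <- mean(x)
      if (abs(m) < 1e-12) 0 else sd(x) / abs(m)
    })
    converged <- all(rel_sd < settings$convergence_tol)

    # -- post-hoc individual parameters and marginal likelihood
    prop <- .posthoc_proposal(prep, mu, omega2, iiv_idx, a, b, floor,
                              settings$n_posthoc_burn, settings$n_posthoc)
    ml <- .marginal_loglik(prep, mu, omega2, iiv_idx, a, b, floor,
                           settings$n_loglik_samples, prop)

    rse <- NULL
    if (se) {
      rse <- .saem_rse(prep, mu, omega2, iiv_idx, a, b, est_a, est_b,
                       floor, prop, pnames)
    }
    list(mu = mu, omega2 = omega2, a = a, b = b, eta = eta,
         trace = trace, rel_sd = rel_sd, converged = converged,
         prop = prop, ml = ml, rse = rse, prop_sd = prop_sd)
  })
  elapsed <- proc.time()[["elapsed"]] - t0

  n_par <- p + length(iiv_idx) + est_a + est_b
  bic <- -2 * res$ml$loglik + n_par * log(prep$n_obs)
  est_nat <- exp(res$mu)
  om <- sqrt(res$omega2)
  estimates <- if (model == "two_cpt") {
    pop_params(CL = est_nat[1], V1 = est_nat[2], Q = est_nat[3], V2 = est_nat[4],
               omega_CL = om[1], omega_V1 = om[2], omega_V2 = om[4],
               err_add = res$a, err_prop = res$b)
  } else {
    pop_params(CL = est_nat[1], V1 = est_nat[2],
               omega_CL = om[1], omega_V1 = om[2],
               err_add = res$a, err_prop = res$b)
  }
  individual <- as_tibble(as.data.frame(res$prop$psi_mean))
  names(individual) <- paste0(pnames, "_i")
  individual <- dplyr::bind_cols(
    tibble(ID = vapply(subs, `[[`, numeric(1), "id")), individual
  )
  trace_tb <- as_tibble(as.data.frame(res$trace))
  trace_tb <- dplyr::mutate(
    trace_tb,
    iteration = dplyr::row_number(),
    phase = ifelse(.data$iteration <= K1, "exploratory", "smoothing"),
    .before = 1
  )
  fit <- structure(
    list(estimates = estimates, model = model, individual = individual,
         loglik = res$ml$loglik, loglik_se = res$ml$se, bic = bic,
         rse = res$rse, trace = trace_tb,
         converged = res$converged,
         convergence = tibble(parameter = names(res$rel_sd),
                              rel_sd_final_window = unname(res$rel_sd)),
         settings = settings, n_obs = prep$n_obs, n_subjects = N,
         n_par = n_par, elapsed = elapsed),
    class = "saem_fit"
  )
  if (!fit$converged) {
    bad <- fit$convergence$parameter[
      fit$convergence$rel_sd_final_window >= settings$convergence_tol]
    warn(sprintf(
      "SAEM parameter search not settled for: %s (relative SD over the final window >= %g). Consider more iterations.",
      paste(bad, collapse = ", "), settings$convergence_tol),
      class = "ascorbpk_nonconvergence")
  }
  fit
}

# Crude data-driven starting values: clearance from dose/AUC of each profile,
# unit elimination rate for the central volume, small peripheral compartment.
.saem_init <- function(prep) {
  cls <- unlist(lapply(prep$subjects, function(s) {
    vapply(seq_along(s$occ_rate), function(j) {
      sel <- s$occ_idx == j & !s$cens
      if (sum(sel) < 3) return(NA_real_)
      tt <- s$time[sel]
      cc <- s$dv[sel]
      o <- order(tt)
      auc <- auc_trapezoid(tt[o], pmax(cc[o], 0))
      amt <- s$occ_rate[j] * s$occ_tinf[j]
      if (auc > 0) amt / auc else NA_real_
    }, numeric(1))
  }))
  cl0 <- median(cls, na.rm = TRUE)
  if (!is.finite(cl0) || cl0 <= 0) cl0 <- 1
  pop_params(CL = cl0, V1 = cl0, Q = 0.1 * cl0, V2 = 0.5 * cl0,
             omega_CL = 0.3, omega_V1 = 0.3, omega_V2 = 0.3,
             err_add = 0.05, err_prop = 0.15)
}

# Relative standard errors from a Monte Carlo Fisher-information estimate:
# per-subject scores of the importance-sampled marginal log-likelihood by
# central finite differences with common random numbers; FIM as the sum of
# score outer products. All coordinates are logs of positive quantities, so
# sqrt(diag(FIM^-1)) is directly a relative SE.
.saem_rse <- function(prep, mu, omega2, iiv_idx, a, b, est_a, est_b,
                      floor, prop, pnames, n_samples = 300, h = 1e-3) {
  d <- length(iiv_idx)
  N <- length(prep$subjects)
  z <- lapply(seq_len(N), function(i) matrix(rnorm(n_samples * d), n_samples, d))
  theta <- c(mu, if (d) log(sqrt(omega2[iiv_idx])),
             if (est_a) log(a), if (est_b) log(b))
  nm <- c(pnames, if (d) paste0("omega_", pnames[iiv_idx]),
          if (est_a) "err_add", if (est_b) "err_prop")
  p <- length(mu)
  subj_ll <- function(th) {
    mu2 <- th[seq_len(p)]
    om2 <- omega2
    if (d) om2[iiv_idx] <- exp(th[p + seq_len(d)])^2
    pos <- p + d
    a2 <- if (est_a) exp(th[pos + 1]) else a
    b2 <- if (est_b) exp(th[pos + est_a + 1]) else b
    sw <- sqrt(om2[iiv_idx])
    vapply(seq_len(N), function(i) {
      s <- prep$subjects[[i]]
      if (d == 0L) {
        return(.subject_ll(s, .subject_pred(s, exp(mu2)), a2, b2, floor))
      }
      m <- prop$m[i, ]
      pv <- sqrt(prop$v[i, ])
      etas <- sweep(sweep(z[[i]], 2, pv, `*`), 2, m, `+`)
      logw <- vapply(seq_len(n_samples), function(k) {
        ef <- numeric(p)
        ef[iiv_idx] <- etas[k, ]
        .subject_ll(s, .subject_pred(s, exp(mu2 + ef)), a2, b2, floor) +
          sum(dnorm(etas[k, ], 0, sw, log = TRUE)) -
          sum(dnorm(etas[k, ], m, pv, log = TRUE))
      }, numeric(1))
      mx <- max(logw)
      mx + log(mean(exp(logw - mx)))
    }, numeric(1))
  }
  q <- length(theta)
  scores <- matrix(0, N, q)
  for (j in seq_len(q)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    scores[, j] <- (subj_ll(tp) - subj_ll(tm)) / (2 * h)
  }
  fim <- crossprod(scores)
  rse <- rep(NA_real_, q)
  ok <- tryCatch({
    cv <- solve(fim)
    rse <- 100 * sqrt(pmax(diag(cv), 0))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    warn("Fisher information matrix is singular; RSEs unavailable.",
         class = "ascorbpk_singular_fim")
  }
  setNames(rse, nm)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.saem_fit <- function(x, ...) {
  cat(sprintf("SAEM fit (%s model): %d subjects, %d observations\n",
              x$model, x$n_subjects, x$n_obs))
  print(x$estimates)
  cat(sprintf("logLik %.2f (MC se %.3f)   BIC %.2f   %s\n",
              x$loglik, x$loglik_se, x$bic,
              if (x$converged) "converged" else "NOT settled"))
  invisible(x)
}

#' @method tidy saem_fit
#' @export
tidy.saem_fit <- function(x, ...) {
  e <- x$estimates
  if (x$model == "two_cpt") {
    terms <- c("CL", "V1", "Q", "V2")
    est <- c(e$CL, e$V1, e$Q, e$V2)
    units <- c("L/h", "L", "L/h", "L")
    iiv <- c(e$omega_CL, e$omega_V1, NA, e$omega_V2) * 100
  } else {
    terms <- c("CL", "V1")
    est <- c(e$CL, e$V1)
    units <- c("L/h", "L")
    iiv <- c(e$omega_CL, e$omega_V1) * 100
  }
  rse <- if (!is.null(x$rse)) unname(x$rse[terms]) else rep(NA_real_, length(terms))
  tibble(term = terms, estimate = est, unit = units,
         rse_pct = rse, iiv_pct = iiv)
}

#' @method glance saem_fit
#' @export
glance.saem_fit <- function(x, ...) {
  tibble(
    model = x$model, n_subjects = x$n_subjects, n_obs = x$n_obs,
    n_par = x$n_par, logLik = x$loglik, logLik_se = x$loglik_se,
    BIC = x$bic, converged = x$converged,
    err_add = x$estimates$err_add, err_prop = x$estimates$err_prop
  )
}
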