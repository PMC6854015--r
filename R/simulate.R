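# Synthetic study generator emulating the two-dose canine crossover design.

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Study design of the two-dose canine infusion experiment
#'
#' Defaults reproduce the published design: 8 Beagles of 8--10 kg, two
#' occasions per dog (550 and 2,200 mg/kg ascorbate as a 6-h constant-rate
#' IV infusion), plasma sampled at 12 nominal times from infusion start to
#' 16 h, endogenous baseline ascorbate about 0.02 mM, and a quantification
#' limit of 0.005 mM (the assay limit was not published; the default sits
#' well below the quantified 0.02 mM baseline).
#'
#' @param n_subjects Number of dogs.
#' @param body_weight_range Uniform sampling interval for body weight, kg.
#' @param dose_levels Doses, mg/kg; one occasion per dose.
#' @param t_inf Infusion duration, h.
#' @param sampling_times Nominal sampling times, h (sorted, non-negative).
#' @param lloq Lower limit of quantification, mM.
#' @param baseline_conc Endogenous baseline ascorbate, mM; added to simulated
#'   observations but deliberately left out of the structural model (it is
#'   under 0.3% of pharmacological peak concentrations).
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_subjects = 8,
                         body_weight_range = c(8, 10),
                         dose_levels = c(550, 2200),
                         t_inf = 6,
                         sampling_times = c(0, 0.5, 1, 3, 5, 6, 6.5, 7, 8, 10, 12, 16),
                         lloq = 0.005,
                         baseline_conc = 0.02) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    abort("`n_subjects` must be a positive count.")
  }
  if (length(body_weight_range) != 2L || any(body_weight_range <= 0) ||
      body_weight_range[1] > body_weight_range[2]) {
    abort("`body_weight_range` must be a positive interval c(lo, hi).")
  }
  if (!length(dose_levels) || any(dose_levels <= 0)) {
    abort("`dose_levels` must be positive doses in mg/kg.")
  }
  if (t_inf <= 0) abort("`t_inf` must be > 0.")
  if (!length(sampling_times)) abort("`sampling_times` must be non-empty.")
  if (is.unsorted(sampling_times, strictly = TRUE) || any(sampling_times < 0)) {
    abort("`sampling_times` must be strictly increasing and non-negative.")
  }
  if (lloq < 0) abort("`lloq` must be >= 0.")
  if (baseline_conc < 0) abort("`baseline_conc` must be >= 0.")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      body_weight_range = as.numeric(body_weight_range),
      dose_levels = as.numeric(dose_levels),
      t_inf = as.numeric(t_inf),
      sampling_times = as.numeric(sampling_times),
      lloq = as.numeric(lloq),
      baseline_conc = as.numeric(baseline_conc)
    ),
    class = "study_design"
  )
}

#' Draw individual parameters from the population distribution
#'
#' Individual parameters are log-normal around the typical values:
#' `p_i = p_typ * exp(eta)`, `eta ~ N(0, omega^2)`, the standard assumption
#' for strictly positive PK parameters. The inter-compartmental clearance
#' carries no random effect.
#'
#' @param params A [pop_params()] object.
#' @param n Number of individuals.
#' @param seed Optional integer seed (draws are reproducible given the seed
#'   and leave the global RNG state untouched).
#' @return A tibble with columns `ID`, `CL_i`, `V1_i`, `Q_i`, `V2_i`.
#' @export
sample_individuals <- function(params, n, seed = NULL) {
  if (!inherits(params, "pop_params")) abort("`params` must be a `pop_params` object.")
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  .with_seed(seed, {
    tibble(
      ID = seq_len(n),
      CL_i = params$CL * exp(rnorm(n, 0, params$omega_CL)),
      V1_i = params$V1 * exp(rnorm(n, 0, params$omega_V1)),
      Q_i = rep(params$Q, n),
      V2_i = params$V2 * exp(rnorm(n, 0, params$omega_V2))
    )
  })
}

#' Add combined residual error to model predictions
#'
#' `obs = pred + (err_add + err_prop * pred) * eps`, `eps ~ N(0, 1)`.
#' Negative draws are floored at zero; the number of floored values is
#' reported as attribute `n_floored` and via a message of class
#' `ascorbpk_floor` (suppressable with `suppressMessages()`).
#'
#' @param pred Non-negative model predictions, mM.
#' @param params A [pop_params()] (only the error coefficients are used).
#' @param seed Optional integer seed.
#' @return Observed concentrations, mM.
#' @export
add_residual_error <- function(pred, params, seed = NULL) {
  if (!inherits(params, "pop_params")) abort("`params` must be a `pop_params` object.")
  if (any(pred < 0)) abort("`pred` must be non-negative.")
  .with_seed(seed, {
    obs <- pred + (params$err_add + params$err_prop * pred) * rnorm(length(pred))
    n_floored <- sum(obs < 0)
    if (n_floored > 0) {
      inform(sprintf("Floored %d negative simulated concentration(s) at 0.", n_floored),
             class = "ascorbpk_floor")
    }
    obs <- pmax(obs, 0)
    attr(obs, "n_floored") <- n_floored
    obs
  })
}

#' Censor observations below the limit of quantification
#'
#' Observations below `lloq` are flagged BLQ and their reported value set to
#' the LLOQ itself; the flag plus the LLOQ bound is what the censored
#' likelihood needs (the true value is only known to lie in `[0, lloq)`).
#'
#' @param obs Observed concentrations, mM.
#' @param lloq Lower limit of quantification, mM (0 disables censoring).
#' @return A tibble with columns `conc` and `is_blq`.
#' @export
censor_bloq <- function(obs, lloq) {
  if (!is.numeric(lloq) || length(lloq) != 1L || lloq < 0) {
    abort("`lloq` must be a single non-negative number.")
  }
  is_blq <- obs < lloq
  tibble(conc = ifelse(is_blq, lloq, obs), is_blq = is_blq)
}

#' Simulate a complete synthetic study
#'
#' Generates a NONMEM-style long-format dataset for the crossover design:
#' per dog, a body weight drawn uniformly from the design range (one draw,
#' reused on both occasions) and one concentration profile per dose level,
#' built as structural model + endogenous baseline + combined residual error,
#' then BLQ-censored. By default one set of random effects is shared by both
#' occasions of a dog (the two dose time-courses were analysed
#' simultaneously); `occasion_effects = TRUE` instead draws fresh random
#' effects per dog-occasion.
#'
#' @param design A [study_design()].
#' @param params A [pop_params()]; the simulation truth.
#' @param seed Optional integer seed; fixed seed implies an identical dataset.
#' @param occasion_effects Treat each dog-occasion as its own statistical
#'   individual when drawing random effects.
#' @return A tibble with the dataset schema of [read_pkdataset()]: columns
#'   `ID`, `OCC`, `TIME` (h), `DV` (mM), `AMT` (mg), `RATE` (mg/h), `EVID`,
#'   `MDV`, `CENS`, `LLOQ` (mM), `BW` (kg), `DOSEGRP` (mg/kg). Each
#'   dog-occasion has one dose row (`EVID = 1`) followed by the observation
#'   rows.
#' @export
#' @examples
#' d <- generate_study(seed = 1)
#' dplyr::count(d, EVID)
generate_study <- function(design = study_design(),
                           params = ascorbate_pop_params(),
                           seed = NULL,
                           occasion_effects = FALSE) {
  if (!inherits(design, "study_design")) abort("`design` must be a `study_design` object.")
  if (!inherits(params, "pop_params")) abort("`params` must be a `pop_params` object.")
  .with_seed(seed, {
    n <- design$n_subjects
    bw <- runif(n, design$body_weight_range[1], design$body_weight_range[2])
    indiv <- sample_individuals(params, if (occasion_effects) n * length(design$dose_levels) else n)
    rows <- vector("list", n * length(design$dose_levels))
    k <- 0L
    for (i in seq_len(n)) {
      for (occ in seq_along(design$dose_levels)) {
        k <- k + 1L
        dose <- design$dose_levels[occ]
        reg <- infusion_regimen(dose, bw[i], design$t_inf)
        ii <- if (occasion_effects) (i - 1L) * length(design$dose_levels) + occ else i
        psi <- list(CL = indiv$CL_i[ii], V1 = indiv$V1_i[ii],
                    Q = indiv$Q_i[ii], V2 = indiv$V2_i[ii])
        pred <- conc_profile(design$sampling_times, reg, psi) + design$baseline_conc
        obs <- suppressMessages(add_residual_error(pred, params))
        cen <- censor_bloq(as.numeric(obs), design$lloq)
        amt_mg <- dose * bw[i]
        dose_row <- tibble(
          ID = i, OCC = occ, TIME = 0, DV = NA_real_,
          AMT = amt_mg, RATE = amt_mg / design$t_inf,
          EVID = 1L, MDV = 1L, CENS = 0L,
          LLOQ = design$lloq, BW = bw[i], DOSEGRP = dose
        )
        obs_rows <- tibble(
          ID = i, OCC = occ, TIME = design$sampling_times, DV = cen$conc,
          AMT = 0, RATE = 0, EVID = 0L, MDV = 0L,
          CENS = as.integer(cen$is_blq),
          LLOQ = design$lloq, BW = bw[i], DOSEGRP = dose
        )
        rows[[k]] <- dplyr::bind_rows(dose_row, obs_rows)
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "design") <- design
    out
  })
}
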