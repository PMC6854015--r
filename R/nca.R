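# Non-compartmental analysis of individual concentration-time profiles.

#' Linear trapezoidal area under the curve
#'
#' @param times Strictly increasing times, h.
#' @param concs Non-negative concentrations, mM.
#' @return AUC over the observed interval, mM*h.
#' @export
#' @examples
#' auc_trapezoid(c(0, 3), c(2, 2)) # 6
auc_trapezoid <- function(times, concs) {
  if (length(times) < 2L) abort("Need at least two points for a trapezoidal AUC.")
  if (length(times) != length(concs)) abort("`times` and `concs` lengths differ.")
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing (no duplicates).")
  }
  if (any(concs < 0)) abort("`concs` must be non-negative.")
  sum(0.5 * (concs[-1] + concs[-length(concs)]) * diff(times))
}

# AUMC (first moment) by the linear trapezoid on t*c.
.aumc_trapezoid <- function(times, concs) {
  tc <- times * concs
  sum(0.5 * (tc[-1] + tc[-length(tc)]) * diff(times))
}

#' Terminal slope by log-linear regression
#'
#' Ordinary least squares of `log(conc)` on time over a terminal window of
#' post-Tmax points. The window is the suffix of at least 3 points (the Cmax
#' point itself excluded) that maximises the adjusted R-squared — the usual
#' automatic best-fit rule. Returns `lambda_z = -slope`; a non-positive slope
#' or fewer than 3 usable points leaves `lambda_z` undefined (`NA`).
#'
#' @param times Times, h.
#' @param concs Concentrations, mM; non-positive values are dropped from the
#'   regression (log scale).
#' @return A list with `lambda_z` (1/h), `intercept` (log mM), `r2adj`,
#'   `n_points`.
#' @export
lambda_z_fit <- function(times, concs) {
  if (length(times) != length(concs)) abort("`times` and `concs` lengths differ.")
  keep <- is.finite(concs) & concs > 0
  times <- times[keep]; concs <- concs[keep]
  undefined <- list(lambda_z = NA_real_, intercept = NA_real_,
                    r2adj = NA_real_, n_points = 0L)
  if (length(times) < 3L) return(undefined)
  i_max <- which.max(concs)[1]          # ties resolved to the earliest time
  cand <- seq_along(times)[seq_along(times) > i_max]
  if (length(cand) < 3L) return(undefined)
  best <- NULL
  y <- log(concs)
  for (s in cand) {
    w <- s:length(times)
    if (length(w) < 3L) break
    n <- length(w)
    tx <- times[w]; ty <- y[w]
    sxx <- sum((tx - mean(tx))^2)
    if (sxx == 0) next
    slope <- sum((tx - mean(tx)) * (ty - mean(ty))) / sxx
    resid <- ty - mean(ty) - slope * (tx - mean(tx))
    sst <- sum((ty - mean(ty))^2)
    r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
    r2adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.null(best) || r2adj > best$r2adj + 1e-12) {
      best <- list(lambda_z = -slope,
                   intercept = mean(ty) - slope * mean(tx),
                   r2adj = r2adj, n_points = n)
    }
  }
  if (is.null(best) || !is.finite(best$lambda_z) || best$lambda_z <= 0) {
    return(undefined)
  }
  best
}

#' Non-compartmental analysis of a single profile
#'
#' Computes the standard NCA parameter set for one subject-occasion profile
#' under a constant-rate infusion: linear-trapezoid AUC to the last point,
#' extrapolation to infinity via `c_last / lambda_z`, observed Cmax/Tmax
#' (first occurrence on ties), steady-state concentration as the mean of
#' observations in the plateau window (by default the second half of the
#' infusion), clearance as `amount / AUC_inf`, and steady-state volume by
#' moment analysis with the infusion correction
#' `Vss = CL * (AUMC/AUC - t_inf/2)`.
#'
#' @param times Sampling times, h.
#' @param concs Concentrations, mM.
#' @param amount Infused amount, mmol.
#' @param t_inf Infusion duration, h.
#' @param css_window Plateau window `c(lo, hi)` in h for the Css mean;
#'   default `c(t_inf/2, t_inf)`.
#' @param baseline Pre-dose concentration to subtract before analysis
#'   (default 0: no baseline subtraction).
#' @return One-row tibble with `auc_last`, `auc_inf` (mM*h), `cmax` (mM),
#'   `tmax` (h), `css` (mM), `lambda_z` (1/h), `t_half` (h), `cl_nca` (L/h),
#'   `vss_nca` (L), `lambda_z_n_points`, `lambda_z_r2adj`. Quantities that
#'   rely on an undefined terminal slope are `NA`.
#' @export
#' @examples
#' reg <- infusion_regimen(2200, 9, 6)
#' tt <- c(0, 0.5, 1, 3, 5, 6, 6.5, 7, 8, 10, 12, 16)
#' cc <- conc_profile(tt, reg, ascorbate_pop_params())
#' nca_profile(tt, cc, amount = dose_to_amount(reg)$amount, t_inf = 6)
nca_profile <- function(times, concs, amount, t_inf,
                        css_window = NULL, baseline = 0) {
  if (length(times) != length(concs)) abort("`times` and `concs` lengths differ.")
  if (!is.numeric(amount) || length(amount) != 1L || amount <= 0) {
    abort("`amount` must be a single positive amount (mmol).")
  }
  if (!is.numeric(t_inf) || length(t_inf) != 1L || t_inf <= 0) {
    abort("`t_inf` must be a single positive duration (h).")
  }
  ord <- order(times)
  times <- times[ord]; concs <- pmax(concs[ord] - baseline, 0)
  if (is.null(css_window)) css_window <- c(t_inf / 2, t_inf)

  empty <- tibble(
    auc_last = NA_real_, auc_inf = NA_real_, cmax = NA_real_, tmax = NA_real_,
    css = NA_real_, lambda_z = NA_real_, t_half = NA_real_,
    cl_nca = NA_real_, vss_nca = NA_real_,
    lambda_z_n_points = 0L, lambda_z_r2adj = NA_real_
  )
  if (length(times) < 2L || all(concs <= 0)) return(empty)

  auc_last <- auc_trapezoid(times, concs)
  i_max <- which.max(concs)[1]
  cmax <- concs[i_max]
  tmax <- times[i_max]
  in_win <- times >= css_window[1] & times <= css_window[2]
  css <- if (any(in_win)) mean(concs[in_win]) else NA_real_
  lz <- lambda_z_fit(times, concs)

  if (is.na(lz$lambda_z)) {
    out <- empty
    out$auc_last <- auc_last; out$cmax <- cmax; out$tmax <- tmax; out$css <- css
    return(out)
  }
  c_last <- concs[length(concs)]
  t_last <- times[length(times)]
  auc_inf <- auc_last + c_last / lz$lambda_z
  aumc_inf <- .aumc_trapezoid(times, concs) +
    c_last * t_last / lz$lambda_z + c_last / lz$lambda_z^2
  cl_nca <- amount / auc_inf
  mrt <- aumc_inf / auc_inf - t_inf / 2
  tibble(
    auc_last = auc_last, auc_inf = auc_inf, cmax = cmax, tmax = tmax,
    css = css, lambda_z = lz$lambda_z, t_half = log(2) / lz$lambda_z,
    cl_nca = cl_nca, vss_nca = cl_nca * mrt,
    lambda_z_n_points = lz$n_points, lambda_z_r2adj = lz$r2adj
  )
}

#' Non-compartmental analysis of every profile in a dataset
#'
#' Runs [nca_profile()] on each subject-occasion of a NONMEM-style dataset
#' (see [read_pkdataset()]). BLQ records are excluded from the curves (their
#' count is reported); the infused amount is taken from the dose row and
#' converted from mg to mmol.
#'
#' @param data Dataset tibble (schema of [read_pkdataset()]).
#' @param css_window,baseline_subtract Passed through to [nca_profile()];
#'   `baseline_subtract = TRUE` subtracts each profile's pre-dose (t = 0)
#'   concentration.
#' @return A tibble with one row per subject-occasion: `ID`, `OCC`,
#'   `DOSEGRP`, `BW`, `n_blq_excluded`, and the [nca_profile()] columns.
#' @export
nca <- function(data, css_window = NULL, baseline_subtract = FALSE) {
  data <- .validate_dataset(data)
  keys <- dplyr::distinct(data, .data$ID, .data$OCC)
  res <- purrr::pmap(keys, function(ID, OCC) {
    sub <- data[data$ID == ID & data$OCC == OCC, ]
    dose_rows <- sub[sub$EVID == 1L, ]
    if (nrow(dose_rows) == 0L) {
      abort(sprintf("Subject %s occasion %s has no dose event.", ID, OCC))
    }
    amt_mmol <- dose_rows$AMT[1] / ASCORBATE_MOLAR_MASS
    t_inf <- dose_rows$AMT[1] / dose_rows$RATE[1]
    obs <- sub[sub$EVID == 0L, ]
    n_blq <- sum(obs$CENS == 1L)
    obs <- obs[obs$CENS == 0L, ]
    base <- 0
    if (baseline_subtract && any(obs$TIME == 0)) base <- obs$DV[obs$TIME == 0][1]
    out <- nca_profile(obs$TIME, obs$DV, amount = amt_mmol, t_inf = t_inf,
                       css_window = css_window, baseline = base)
    dplyr::bind_cols(
      tibble(ID = ID, OCC = OCC, DOSEGRP = sub$DOSEGRP[1], BW = sub$BW[1],
             n_blq_excluded = n_blq),
      out
    )
  })
  dplyr::bind_rows(res)
}

#' Summary table of NCA parameters by dose group
#'
#' Mean +/- SD for AUC_inf, Cmax, Css, Vss, CL and lambda_z; median +/- SD
#' for Tmax and the terminal half-life — the usual reporting convention for
#' time-like parameters. Groups are `all` plus each dose level.
#'
#' @param results Output of [nca()].
#' @return A tibble with columns `group`, `parameter`, `center` (mean or
#'   median as per convention), `center_type`, `sd`, `n`.
#' @export
nca_summary <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    abort("`results` must be a non-empty data frame from `nca()`.")
  }
  mean_pars <- c(auc_inf = "AUC_INF", cmax = "CMAX", css = "CSS",
                 vss_nca = "VSS", cl_nca = "CL", lambda_z = "LAMBDA_Z")
  med_pars <- c(tmax = "TMAX", t_half = "T_HALF")
  one_group <- function(df, label) {
    rows <- lapply(names(mean_pars), function(col) {
      x <- df[[col]][is.finite(df[[col]])]
      if (!length(x)) abort(sprintf("No finite values of `%s` in group %s.", col, label))
      tibble(group = label, parameter = mean_pars[[col]],
             center = mean(x), center_type = "mean",
             sd = if (length(x) > 1) sd(x) else 0, n = length(x))
    })
    rows2 <- lapply(names(med_pars), function(col) {
      x <- df[[col]][is.finite(df[[col]])]
      if (!length(x)) abort(sprintf("No finite values of `%s` in group %s.", col, label))
      tibble(group = label, parameter = med_pars[[col]],
             center = median(x), center_type = "median",
             sd = if (length(x) > 1) sd(x) else 0, n = length(x))
    })
    dplyr::bind_rows(c(rows, rows2))
  }
  out <- list(one_group(results, "all"))
  for (g in sort(unique(results$DOSEGRP))) {
    out <- c(out, list(one_group(results[results$DOSEGRP == g, ],
                                 sprintf("%g mg/kg", g))))
  }
  dplyr::bind_rows(out)
}
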