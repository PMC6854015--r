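# Observation-level likelihood with M3-style handling of censored records.

#' Log-likelihood of observations under the combined error model
#'
#' For an uncensored record the contribution is the Gaussian log-density of
#' `dv` around the model prediction with SD `err_add + err_prop * pred`. For
#' a BLQ record the contribution is the log-probability that the true
#' concentration lies between 0 and the LLOQ,
#' `log(Phi((lloq - pred)/sd) - Phi((0 - pred)/sd))` — the censored-data
#' ("M3") term added to the likelihood in place of a point density. Log
#' contributions are clamped below at `log_floor` to guard against underflow
#' when a BLQ record sits far in the tail of the predictive distribution.
#'
#' @param dv Observed concentrations, mM (ignored for BLQ records).
#' @param pred Model predictions, mM (non-negative).
#' @param params A [pop_params()] or list with `err_add`, `err_prop`.
#' @param is_blq Logical (or 0/1) censoring flags.
#' @param lloq LLOQ, mM; scalar or per-record.
#' @param log_floor Lower clamp for each log contribution.
#' @return Vector of per-record log-likelihood contributions.
#' @export
#' @examples
#' p <- pop_params(CL = 2, V1 = 2, err_add = 0.05, err_prop = 0.08)
#' observation_loglik(dv = 5, pred = 5, params = p)
observation_loglik <- function(dv, pred, params, is_blq = FALSE, lloq = 0,
                               log_floor = -700) {
  if (any(pred < 0)) abort("`pred` must be non-negative.")
  a <- if (is.list(params)) params$err_add else params["err_add"]
  b <- if (is.list(params)) params$err_prop else params["err_prop"]
  .obs_loglik(dv, pred, as.logical(is_blq), lloq, a, b, log_floor)
}

# Hot path: no validation. All arguments recycled to length of `pred`.
.obs_loglik <- function(dv, pred, is_blq, lloq, err_add, err_prop,
                        log_floor = -700) {
  sdv <- err_add + err_prop * pred
  if (any(sdv <= 0)) abort("Residual SD must be > 0 for every record.")
  n <- length(pred)
  is_blq <- rep_len(is_blq, n)
  lloq <- rep_len(lloq, n)
  ll <- numeric(n)
  if (any(!is_blq)) {
    i <- !is_blq
    ll[i] <- dnorm(dv[i], pred[i], sdv[i], log = TRUE)
  }
  if (any(is_blq)) {
    i <- is_blq
    p_hi <- pnorm((lloq[i] - pred[i]) / sdv[i])
    p_lo <- pnorm((0 - pred[i]) / sdv[i])
    ll[i] <- log(pmax(p_hi - p_lo, 0))
  }
  pmax(ll, log_floor)
}
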