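#' Noncompartmental analysis of a concentration-time profile
#'
#' Linear-up/log-down trapezoidal AUC. The terminal slope `lambda_z` is
#' estimated by log-linear regression on the last `3..k` post-peak points,
#' choosing the point set with the best adjusted R-squared (this explicit rule
#' differs from some vendor defaults and is documented here). `auc_inf` adds
#' the extrapolated tail `C_last / lambda_z`.
#'
#' @param profile Tibble/data frame with columns `time` (h, strictly
#'   increasing) and `conc` (ng/mL). Time is taken relative to the dose; pass
#'   a profile already shifted so the dose is at `time = 0`.
#' @param dose Dose, mg (for dose-normalized quantities; optional).
#' @param tau Dosing interval, h. If given, `auc_tau` over `[0, tau]` is
#'   computed.
#' @param max_points Maximal number of terminal points considered for
#'   `lambda_z` (default 12).
#' @return One-row tibble: `cmax`, `tmax`, `auc_last`, `auc_inf`, `auc_tau`,
#'   `lambda_z`, `half_life`, `n_lambda`, `adj_r2`, `dn_auc_inf`
#'   (ng·h/mL per mg, if `dose` given). `auc_inf`/`lambda_z` are `NA` with no
#'   terminal decline.
#' @export
nca <- function(profile, dose = NA_real_, tau = NULL, max_points = 12) {
  t <- profile$time
  cc <- profile$conc
  if (any(diff(t) <= 0))
    abort("time must be strictly increasing", class = "pbpkddi_argument_error")
  if (length(t) < 3) abort("need at least 3 points", class = "pbpkddi_argument_error")

  auc_seg <- function(t1, t2, c1, c2) {
    if (c2 < c1 && c1 > 0 && c2 > 0)      # log-down
      (c1 - c2) * (t2 - t1) / log(c1 / c2)
    else (c1 + c2) / 2 * (t2 - t1)        # linear-up (or flat/zero)
  }
  segs <- vapply(seq_len(length(t) - 1), function(i)
    auc_seg(t[i], t[i + 1], cc[i], cc[i + 1]), 0)
  auc_last <- sum(segs)

  imax <- which.max(cc)
  cmax <- cc[imax]; tmax <- t[imax]

  # lambda_z: best adjusted R^2 over the last 3..k points strictly after tmax
  cand <- which(seq_along(t) > imax & cc > 0)
  lam <- NA_real_; r2 <- NA_real_; nlam <- NA_integer_
  if (length(cand) >= 3) {
    ks <- 3:min(length(cand), max_points)
    best <- -Inf
    for (k in ks) {
      idx <- tail(cand, k)
      fit <- lm(log(cc[idx]) ~ t[idx])
      sl <- unname(coef(fit)[2])
      ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
      if (is.finite(ar2) && sl < 0 && ar2 > best + 1e-10) {
        best <- ar2; lam <- -sl; nlam <- k; r2 <- ar2
      }
    }
  }
  auc_inf <- if (is.finite(lam)) auc_last + cc[length(cc)] / lam else NA_real_

  auc_tau <- NA_real_
  if (!is.null(tau)) {
    if (tau > max(t) + 1e-9)
      abort("tau exceeds the sampled range", class = "pbpkddi_argument_error")
    tt <- sort(unique(c(t[t <= tau + 1e-12], tau)))
    ci <- approx(t, cc, tt)$y
    auc_tau <- sum(vapply(seq_len(length(tt) - 1), function(i)
      auc_seg(tt[i], tt[i + 1], ci[i], ci[i + 1]), 0))
  }
  tibble(cmax = cmax, tmax = tmax, auc_last = auc_last, auc_inf = auc_inf,
         auc_tau = auc_tau, lambda_z = lam,
         half_life = if (is.finite(lam)) log(2) / lam else NA_real_,
         n_lambda = nlam, adj_r2 = r2,
         dn_auc_inf = auc_inf / dose)
}

#' Accumulation ratio
#'
#' `Racc = metric(steady state) / metric(first dose)`, conventionally on
#' `AUC_tau` (or Cmax) over one dosing interval.
#'
#' @param ss,first Steady-state and first-dose values of the metric.
#' @return Dimensionless ratio.
#' @export
accumulation_ratio <- function(ss, first) {
  if (first <= 0) abort("first-dose metric must be > 0",
                        class = "pbpkddi_argument_error")
  ss / first
}

# analytic oral two-compartment (central + peripheral) plasma concentration;
# parameters are apparent (per bioavailable dose): cl, vc, vsac, q in /F terms
.conc_2cpt_oral <- function(t, dose, ka, cl, vc, vsac, q) {
  if (vsac <= 0 || q <= 0) {            # one-compartment limit
    ke <- cl / vc
    if (abs(ka - ke) < 1e-10) ka <- ka * (1 + 1e-8)
    return(dose * ka / (vc * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)))
  }
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vsac
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  a <- (s + disc) / 2; b <- (s - disc) / 2
  A <- (k21 - a) / ((ka - a) * (b - a))
  B <- (k21 - b) / ((ka - b) * (a - b))
  C <- (k21 - ka) / ((a - ka) * (b - ka))
  dose * ka / vc * (A * exp(-a * t) + B * exp(-b * t) + C * exp(-ka * t))
}

#' Fit oral PK parameters to a single-dose profile
#'
#' Weighted least squares on log concentrations of the analytic oral
#' two-compartment disposition model (absorption `ka`, apparent clearance
#' `CL/F`, central volume `V/F`, peripheral volume `v_sac/F`,
#' inter-compartment flow `q_sac/F`). Positivity is enforced by fitting on
#' the log-parameter scale with `minpack.lm`. Starting values come from a
#' noncompartmental pass.
#'
#' @param profile Tibble with `time` (h) and `conc` (ng/mL); single oral dose
#'   at time 0.
#' @param dose Dose, mg.
#' @param one_compartment Force `v_sac = q_sac = 0`.
#' @return One-row tibble with estimates and standard errors
#'   (`ka, cl_f, v_f, v_sac, q_sac, *_se`), convergence info and the final
#'   objective; attribute `"fitted"` holds the fitted profile.
#' @export
fit_oral_pk <- function(profile, dose, one_compartment = FALSE) {
  keep <- profile$conc > 0
  t <- profile$time[keep]; y <- log(profile$conc[keep] / 1000)  # mg/L
  if (length(t) < 6 || diff(range(profile$conc)) <= 0 ||
      sd(y) < 1e-8)
    abort("profile is degenerate (flat or too short); cannot fit",
          class = "pbpkddi_fit_error")
  base <- nca(profile[keep, ], dose = dose)
  lam <- base$lambda_z
  if (!is.finite(lam))
    abort("no terminal decline; cannot fit", class = "pbpkddi_fit_error")
  cl0 <- dose / (base$auc_inf / 1000)           # L/h (AUC ng.h/mL -> mg.h/L)
  vz <- cl0 / lam
  start <- if (one_compartment)
    c(ka = log(2 / max(base$tmax, 0.25)), cl = log(cl0), vc = log(vz))
  else c(ka = log(2 / max(base$tmax, 0.25)), cl = log(cl0), vc = log(0.35 * vz),
         vsac = log(0.45 * vz), q = log(cl0))
  model <- function(p, t) {
    p <- exp(p)
    if (one_compartment) .conc_2cpt_oral(t, dose, p[1], p[2], p[3], 0, 0)
    else .conc_2cpt_oral(t, dose, p[1], p[2], p[3], p[4], p[5])
  }
  resid_fn <- function(p) {
    m <- model(p, t)
    if (any(!is.finite(m)) || any(m <= 0)) return(rep(1e3, length(t)))
    log(m) - y
  }
  fit <- minpack.lm::nls.lm(start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    abort(sprintf("fit did not converge (info %d, objective %.4g)",
                  fit$info, fit$deviance), class = "pbpkddi_fit_error")
  est <- exp(fit$par)
  vcov <- tryCatch(solve(fit$hessian) * 2 * fit$deviance /
                     max(length(t) - length(fit$par), 1),
                   error = function(e) matrix(NA, length(fit$par), length(fit$par)))
  se_log <- sqrt(pmax(diag(vcov), 0))
  se <- est * se_log                     # delta method from log scale
  out <- tibble(ka = est[["ka"]], cl_f = est[["cl"]], v_f = est[["vc"]],
                v_sac = if (one_compartment) 0 else est[["vsac"]],
                q_sac = if (one_compartment) 0 else est[["q"]],
                ka_se = se[[1]], cl_f_se = se[[2]], v_f_se = se[[3]],
                v_sac_se = if (one_compartment) 0 else se[[4]],
                q_sac_se = if (one_compartment) 0 else se[[5]],
                objective = fit$deviance, iterations = fit$niter)
  attr(out, "fitted") <- tibble(time = profile$time,
                                conc = model(fit$par, profile$time) * 1000)
  out
}

#' Signed percent prediction error
#'
#' `PE = (GM_prediction - GM_observation) / GM_observation * 100`.
#'
#' @param gm_pred,gm_obs Predicted and observed geometric means.
#' @return Percent (signed).
#' @export
#' @examples
#' prediction_error(3.17, 3.06)  # +3.6%
prediction_error <- function(gm_pred, gm_obs) {
  if (any(gm_obs <= 0)) abort("observation must be > 0",
                              class = "pbpkddi_argument_error")
  (gm_pred - gm_obs) / gm_obs * 100
}
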