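#' Virtual DDI trial design
#'
#' Describes a paired two-arm virtual study: the victim is simulated alone and
#' co-administered with the perpetrator in the *same* virtual subjects (the
#' crossover-style design implied by within-subject geometric-mean ratios).
#' Exposure is read per subject by noncompartmental analysis of the victim
#' profile: `metric = "auc_inf"` uses `AUC_inf`/`Cmax` of a single victim dose
#' at `obs_dose_time`; `metric = "auc_tau"` uses `AUC_tau`/`Cmax` over
#' `[obs_dose_time, obs_dose_time + tau]` for a repeated-dose victim at
#' steady state.
#'
#' @param victim Victim compound name.
#' @param victim_regimen [regimen()] for the victim.
#' @param perpetrator Perpetrator compound name, or `NULL` for a single-arm
#'   (control) design.
#' @param perp_regimen [regimen()] for the perpetrator.
#' @param population A [population_spec()].
#' @param n_trials,n_subjects Virtual trial replication structure.
#' @param metric `"auc_inf"` or `"auc_tau"`.
#' @param obs_dose_time Time (h) of the victim dose that is sampled.
#' @param tau Dosing interval for `auc_tau`, h.
#' @param t_end Simulation end, h.
#' @param seed Base seed; trial `i` uses `seed + i`.
#' @param on_failure `"fail"` (stop) or `"drop"` (flag and drop the subject).
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(victim, victim_regimen, perpetrator = NULL,
                         perp_regimen = NULL,
                         population = population_spec("healthy"),
                         n_trials = 10, n_subjects = 10,
                         metric = c("auc_inf", "auc_tau"),
                         obs_dose_time = 0, tau = 24, t_end = NULL,
                         seed = 1L, on_failure = c("fail", "drop")) {
  metric <- match.arg(metric)
  on_failure <- match.arg(on_failure)
  if (n_trials < 1 || n_subjects < 1)
    abort("n_trials and n_subjects must be >= 1", class = "pbpkddi_argument_error")
  if (is.null(t_end))
    t_end <- max(victim_regimen$stop, perp_regimen$stop %||% 0,
                 obs_dose_time + 14 * 24)
  structure(list(victim = victim, victim_regimen = victim_regimen,
                 perpetrator = perpetrator, perp_regimen = perp_regimen,
                 population = population, n_trials = n_trials,
                 n_subjects = n_subjects, metric = metric,
                 obs_dose_time = obs_dose_time, tau = tau, t_end = t_end,
                 seed = as.integer(seed), on_failure = on_failure),
            class = "trial_design")
}

.victim_metrics <- function(sim, design) {
  pr <- pk_profile(sim, design$victim)
  pr <- pr[pr$time >= design$obs_dose_time - 1e-9, ]
  pr$time <- pr$time - design$obs_dose_time
  if (design$metric == "auc_inf") {
    r <- nca(pr)
    tibble(cmax = r$cmax, auc = r$auc_inf)
  } else {
    r <- nca(pr[pr$time <= design$tau + 1e-9, ], tau = design$tau)
    tibble(cmax = r$cmax, auc = r$auc_tau)
  }
}

#' Run a paired virtual DDI study
#'
#' For each trial, a fresh subject sample is drawn (`seed + trial`); each
#' subject is simulated in the alone arm and, if a perpetrator is specified,
#' in the co-administration arm with identical physiology, so ratios are
#' within-subject. Geometric means are `exp(mean(log x))`; the 90% CI of the
#' GM ratio uses the t-distribution on the paired log-ratios pooled across
#' all subjects (the pooling choice is documented in the methods vignette).
#'
#' @param design A [trial_design()].
#' @param compounds Named list of `compound_model`s covering victim and
#'   perpetrator (e.g. from [compound_library()]).
#' @return Object of class `ddi_result`: `$subjects` (per-subject NCA
#'   metrics), `$arms` (per-arm mean/SD/GM), `$ratios` (GM ratio with 90% CI
#'   per metric), `$design`.
#' @export
run_trials <- function(design, compounds) {
  stopifnot(inherits(design, "trial_design"))
  need <- c(design$victim, design$perpetrator)
  if (!all(need %in% names(compounds)))
    abort(paste0("compounds must include: ", paste(need, collapse = ", ")),
          class = "pbpkddi_argument_error")
  paired <- !is.null(design$perpetrator) &&
    any(design$perp_regimen$dose > 0)
  rows <- vector("list", design$n_trials)
  for (tr in seq_len(design$n_trials)) {
    subs <- sample_population(design$population, design$n_subjects,
                              seed = design$seed + tr)
    res <- purrr::map_dfr(seq_len(nrow(subs)), function(i) {
      subject <- subs[i, ]
      one <- function(arm) {
        cps <- if (arm == "alone") compounds[design$victim]
               else compounds[c(design$victim, design$perpetrator)]
        reg <- if (arm == "alone") design$victim_regimen
               else regimens(design$victim_regimen, design$perp_regimen)
        sim <- simulate_pk(subject, cps, reg, t_end = design$t_end)
        dplyr::mutate(.victim_metrics(sim, design), arm = arm)
      }
      out <- tryCatch(
        dplyr::bind_rows(one("alone"), if (paired) one("combo")),
        error = function(e) {
          if (design$on_failure == "fail") stop(e)
          warn(sprintf("subject %d in trial %d dropped: %s", i, tr,
                       conditionMessage(e)))
          NULL
        })
      if (!is.null(out)) dplyr::mutate(out, trial = tr, subject = i)
    })
    rows[[tr]] <- res
  }
  subjects <- dplyr::bind_rows(rows)

  arms <- subjects |>
    tidyr::pivot_longer(c("cmax", "auc"), names_to = "metric") |>
    dplyr::group_by(.data$arm, .data$metric) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), gm = .geo_mean(.data$value),
                     .groups = "drop")

  ratios <- NULL
  if (paired) {
    wide <- subjects |>
      tidyr::pivot_longer(c("cmax", "auc"), names_to = "metric") |>
      tidyr::pivot_wider(names_from = "arm", values_from = "value")
    ratios <- wide |>
      dplyr::mutate(logr = log(.data$combo / .data$alone)) |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(n = dplyr::n(), gm_ratio = exp(mean(.data$logr)),
                       sd_logr = sd(.data$logr), .groups = "drop") |>
      dplyr::mutate(
        half = ifelse(.data$n > 1,
                      qt(0.95, pmax(.data$n - 1, 1)) * .data$sd_logr /
                        sqrt(.data$n), 0),
        ci_lo = .data$gm_ratio * exp(-.data$half),
        ci_hi = .data$gm_ratio * exp(.data$half)) |>
      dplyr::select(-"half", -"sd_logr")
    ratios$ci_lo[is.na(ratios$ci_lo)] <- ratios$gm_ratio[is.na(ratios$ci_lo)]
    ratios$ci_hi[is.na(ratios$ci_hi)] <- ratios$gm_ratio[is.na(ratios$ci_hi)]
  }
  structure(list(subjects = subjects, arms = arms, ratios = ratios,
                 design = design), class = "ddi_result")
}

#' @export
print.ddi_result <- function(x, ...) {
  cat(sprintf("<ddi_result> victim %s%s, %d trials x %d subjects, metric %s\n",
              x$design$victim,
              if (!is.null(x$design$perpetrator))
                paste0(" + ", x$design$perpetrator) else "",
              x$design$n_trials, x$design$n_subjects, x$design$metric))
  if (!is.null(x$ratios))
    for (i in seq_len(nrow(x$ratios)))
      cat(sprintf("  GM %s ratio %.3f (90%% CI %.3f-%.3f)\n",
                  x$ratios$metric[i], x$ratios$gm_ratio[i], x$ratios$ci_lo[i],
                  x$ratios$ci_hi[i]))
  invisible(x)
}

#' Prediction errors of a DDI result against observations
#'
#' @param x A `ddi_result`.
#' @param observed Named vector, e.g. `c(auc = 3.06, cmax = 1.93)` of observed
#'   GM ratios.
#' @return Tibble with predicted/observed ratio and percent error per metric.
#' @export
ddi_prediction_errors <- function(x, observed) {
  stopifnot(inherits(x, "ddi_result"), !is.null(x$ratios))
  r <- x$ratios
  tibble(metric = r$metric, predicted = r$gm_ratio,
         observed = observed[r$metric],
         pe_percent = prediction_error(r$gm_ratio, observed[r$metric]))
}

# address a nested numeric field in a compound by a /-separated path
.pluck_path <- function(cm, path) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  purrr::pluck(cm, !!!keys)
}
.poke_path <- function(cm, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  purrr::pluck(cm, !!!keys) <- value
  validate_compound(cm)
}

#' Parameter sensitivity analysis
#'
#' Re-runs the full trial set (same seeds) once per candidate value of a
#' numeric compound parameter addressed by a `/`-separated path (e.g.
#' `"interactions/CYP3A4_liver/ki_reversible"` or
#' `"enzyme_clearances/CYP3A4_liver/value"`), and reports the GM ratio
#' trajectory.
#'
#' @param design A [trial_design()].
#' @param compounds Compound list; `compound` names which one to perturb.
#' @param compound Name of the perturbed compound.
#' @param parameter_path Path into the compound object.
#' @param values Numeric values to scan.
#' @return Tibble: value, metric, gm_ratio, ci.
#' @export
psa <- function(design, compounds, compound, parameter_path, values) {
  base <- .pluck_path(compounds[[compound]], parameter_path)
  if (is.null(base) || !is.numeric(base))
    abort(sprintf("'%s' does not address a numeric parameter", parameter_path),
          class = "pbpkddi_argument_error")
  purrr::map_dfr(values, function(v) {
    cps <- compounds
    cps[[compound]] <- .poke_path(cps[[compound]], parameter_path, v)
    r <- run_trials(design, cps)
    dplyr::mutate(r$ratios, value = v, .before = 1)
  })
}

#' Dose re-escalation scenario after inhibitor discontinuation
#'
#' Simulates the phased schedule used to support stepwise victim dose
#' re-escalation once a strong CYP3A4 inhibitor is stopped: reduced victim
#' dose with the inhibitor, an intermediate dose for the enzyme-recovery
#' window (set by CYP3A4 kdeg), then the full dose. Phases must not overlap.
#'
#' @param compounds Named compound list (victim first).
#' @param subject A subject row (default: central healthy).
#' @param victim,perpetrator Compound names.
#' @param phases Tibble with columns `dose` (mg victim QD) and `days`;
#'   default 200 mg + inhibitor (14 d), 300 mg (14 d), 400 mg (14 d).
#' @param perp_dose,perp_schedule Perpetrator dosing while co-administered.
#' @param kdeg Enzyme degradation rates passed to [simulate_pk()] (the
#'   recovery timescale; a very large value decouples the phases).
#' @return List of class `reescalation_result`: `$sim`, `$phases` (per-phase
#'   steady-state `AUC_tau`/`Cmax` from the last interval of each phase),
#'   `$enzyme` (CYP3A4 recovery trajectory).
#' @export
dose_reescalation_scenario <- function(compounds,
                                       subject = central_subject(),
                                       victim = names(compounds)[1],
                                       perpetrator = names(compounds)[2],
                                       phases = tibble(dose = c(200, 300, 400),
                                                       days = c(14, 14, 14)),
                                       perp_dose = 200,
                                       perp_schedule = "bid",
                                       kdeg = enzyme_kdeg()) {
  if (any(phases$days <= 0)) abort("phase durations must be positive",
                                   class = "pbpkddi_schedule_error")
  starts <- cumsum(c(0, head(phases$days, -1))) * 24
  stops <- cumsum(phases$days) * 24
  if (any(head(stops, -1) > tail(starts, -1) + 1e-9))
    abort("phases overlap", class = "pbpkddi_schedule_error")
  vreg <- purrr::pmap(list(phases$dose, starts, stops),
                      function(d, s0, s1) regimen(victim, d, "qd", s0, s1))
  vreg <- do.call(regimens, vreg)
  preg <- regimen(perpetrator, perp_dose, perp_schedule, 0, stops[1])
  t_end <- max(stops) + 24
  sim <- simulate_pk(subject, compounds[c(victim, perpetrator)],
                     regimens(vreg, preg), t_end = t_end, kdeg = kdeg)
  pr <- pk_profile(sim, victim)
  phase_stats <- purrr::map_dfr(seq_len(nrow(phases)), function(i) {
    t0 <- stops[i] - 24
    seg <- pr[pr$time >= t0 - 1e-9 & pr$time <= stops[i] + 1e-9, ]
    seg$time <- seg$time - t0
    r <- nca(seg, tau = 24)
    tibble(phase = i, dose = phases$dose[i],
           with_inhibitor = i == 1, auc_tau = r$auc_tau, cmax = r$cmax)
  })
  enz <- tibble(time = sim$times,
                cyp3a4_liver = sim$enzymes[, "CYP3A4_liver"],
                cyp3a4_gut = sim$enzymes[, "CYP3A4_gut"])
  structure(list(sim = sim, phases = phase_stats, enzyme = enz),
            class = "reescalation_result")
}
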