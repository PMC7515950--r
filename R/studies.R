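#' Canonical DDI study designs
#'
#' Pre-specified paired virtual-trial designs for the interaction studies the
#' calibrated fedratinib model is verified and applied against:
#'
#' * `"ketoconazole_single"`: fedratinib 300 mg single dose (48 h into
#'   ketoconazole 200 mg BID, continued through sampling), healthy subjects,
#'   `AUC_inf`/Cmax of fedratinib.
#' * `"ketoconazole_ss"`: fedratinib 400 mg QD to steady state; ketoconazole
#'   200 mg BID added from day 21; `AUC_tau` of fedratinib over day 34-35.
#' * `"midazolam_cocktail"`: midazolam 2 mg single dose at fedratinib 500 mg
#'   QD steady state (day 15); `AUC_inf`/Cmax of midazolam.
#' * `"repaglinide"`: repaglinide 0.25 mg single dose at fedratinib 400 mg QD
#'   steady state.
#' * `"warfarin"`: warfarin 15 mg single dose at fedratinib 400 mg QD steady
#'   state (long sampling for the slow substrate).
#'
#' @param name Study name (see above).
#' @param n_trials,n_subjects Replication structure (default 10 x 10).
#' @param population A [population_spec()].
#' @param seed Base seed.
#' @return A [trial_design()].
#' @export
ddi_study <- function(name = c("ketoconazole_single", "ketoconazole_ss",
                               "midazolam_cocktail", "repaglinide",
                               "warfarin"),
                      n_trials = 10, n_subjects = 10,
                      population = population_spec("healthy"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    ketoconazole_single = trial_design(
      victim = "fedratinib",
      victim_regimen = regimen("fedratinib", 300, "single", 48),
      perpetrator = "ketoconazole",
      perp_regimen = regimen("ketoconazole", 200, "bid", 0, 360),
      population = population, n_trials = n_trials, n_subjects = n_subjects,
      metric = "auc_inf", obs_dose_time = 48, t_end = 360, seed = seed),
    ketoconazole_ss = trial_design(
      victim = "fedratinib",
      victim_regimen = regimen("fedratinib", 400, "qd", 0, 840),
      perpetrator = "ketoconazole",
      perp_regimen = regimen("ketoconazole", 200, "bid", 504, 840),
      population = population, n_trials = n_trials, n_subjects = n_subjects,
      metric = "auc_tau", obs_dose_time = 816, tau = 24, t_end = 840,
      seed = seed),
    midazolam_cocktail = trial_design(
      victim = "midazolam",
      victim_regimen = regimen("midazolam", 2, "single", 360),
      perpetrator = "fedratinib",
      perp_regimen = regimen("fedratinib", 500, "qd", 0, 432),
      population = population, n_trials = n_trials, n_subjects = n_subjects,
      metric = "auc_inf", obs_dose_time = 360, t_end = 432, seed = seed),
    repaglinide = trial_design(
      victim = "repaglinide",
      victim_regimen = regimen("repaglinide", 0.25, "single", 360),
      perpetrator = "fedratinib",
      perp_regimen = regimen("fedratinib", 400, "qd", 0, 408),
      population = population, n_trials = n_trials, n_subjects = n_subjects,
      metric = "auc_inf", obs_dose_time = 360, t_end = 408, seed = seed),
    warfarin = trial_design(
      victim = "warfarin",
      victim_regimen = regimen("warfarin", 15, "single", 360),
      perpetrator = "fedratinib",
      perp_regimen = regimen("fedratinib", 400, "qd", 0, 840),
      population = population, n_trials = n_trials, n_subjects = n_subjects,
      metric = "auc_inf", obs_dose_time = 360, t_end = 840, seed = seed))
}

#' Accumulation-ratio virtual study
#'
#' Simulates repeated QD dosing in a virtual population and computes each
#' subject's AUC accumulation ratio `AUC_tau(steady state) / AUC_tau(first
#' dose)` (and the Cmax analogue), with the geometric mean across subjects.
#'
#' @param compound A `compound_model` (e.g. calibrated fedratinib).
#' @param dose Dose, mg.
#' @param n_trials,n_subjects Replication structure.
#' @param population A [population_spec()].
#' @param days Treatment duration (steady state read from the last interval).
#' @param seed Base seed.
#' @return List: `$subjects` tibble (per-subject first/ss AUC-tau, Racc),
#'   `$gm_racc_auc`, `$gm_racc_cmax`.
#' @export
accumulation_trials <- function(compound, dose = 400, n_trials = 10,
                                n_subjects = 10,
                                population = population_spec("healthy"),
                                days = 28, seed = 1L) {
  reg <- regimen(compound$name, dose, "qd", 0, days * 24)
  last0 <- max(dose_times(reg)$time)
  rows <- purrr::map_dfr(seq_len(n_trials), function(tr) {
    subs <- sample_population(population, n_subjects, seed = seed + tr)
    purrr::map_dfr(seq_len(nrow(subs)), function(i) {
      sim <- simulate_pk(subs[i, ], compound, reg, t_end = days * 24)
      pr <- pk_profile(sim, compound$name)
      n1 <- nca(pr[pr$time <= 24 + 1e-9, ], tau = 24)
      prs <- pr[pr$time >= last0 - 1e-9, ]
      prs$time <- prs$time - last0
      nss <- nca(prs, tau = 24)
      tibble(trial = tr, subject = i, auc_tau_first = n1$auc_tau,
             auc_tau_ss = nss$auc_tau, cmax_first = n1$cmax,
             cmax_ss = nss$cmax,
             racc_auc = nss$auc_tau / n1$auc_tau,
             racc_cmax = nss$cmax / n1$cmax)
    })
  })
  list(subjects = rows, gm_racc_auc = .geo_mean(rows$racc_auc),
       gm_racc_cmax = .geo_mean(rows$racc_cmax))
}

#' Calibration target and shell for the built-in fedratinib model
#'
#' Convenience constructors for re-running the middle-out calibration of the
#' shipped fedratinib fixture: `fedratinib_target()` returns the
#' [fm_target()] (day-1 fm/fe split 64/16/2/11/7 over
#' CYP3A4/CYP2C19/CYP2D6/renal/biliary and dose-normalized `AUC_inf`
#' 28.5 ng·h/mL per mg for a 300 mg single dose), and `fedratinib_shell()`
#' returns the library fixture with its clearance entries reset so
#' [retrograde_clint()] must reproduce them.
#'
#' @return An `fm_target` / `compound_model`.
#' @export
fedratinib_target <- function() {
  fm_target(
    fractions = c(CYP3A4_liver = 0.64, CYP2C19 = 0.16, CYP2D6 = 0.02,
                  renal = 0.11, biliary = 0.07),
    dn_auc_inf = 8550 / 300,
    auc_regimen = regimen("fedratinib", 300, "single", 0),
    fm_regimen = regimen("fedratinib", 400, "qd", 0, 48),
    fm_window = c(0, 24))
}

#' @rdname fedratinib_target
#' @export
fedratinib_shell <- function() {
  cm <- compound_library("fedratinib")[[1]]
  for (e in names(cm$enzyme_clearances))
    cm$enzyme_clearances[[e]]$value <-
      if (e == "HLM_additional") 0 else 1
  cm$cl_renal <- 2
  cm$cl_biliary <- 1.5
  cm
}
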