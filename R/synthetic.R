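#' Synthetic "observed" concentration-time study
#'
#' Defines a simulated clinical PK dataset: the engine-predicted profile of a
#' known ("true") compound under a regimen, sampled at given times, with
#' multiplicative log-normal residual error per subject and sample. The
#' generating truth is retained so recovery of parameters can be scored.
#'
#' @param compound A `compound_model` (the truth).
#' @param reg A [regimen()].
#' @param times Sampling times, h.
#' @param cv_percent Residual log-normal CV, %.
#' @param n_subjects Number of sampled subjects.
#' @param seed RNG seed.
#' @param subject Subject used for the mean model (default central healthy).
#' @return Object of class `synthetic_study`.
#' @export
synthetic_study <- function(compound, reg, times, cv_percent = 20,
                            n_subjects = 12, seed = 1L,
                            subject = central_subject()) {
  if (cv_percent < 0) .stop_validation("cv_percent must be >= 0")
  structure(list(compound = compound, regimen = reg, times = times,
                 cv_percent = cv_percent, n_subjects = n_subjects,
                 seed = as.integer(seed), subject = subject),
            class = "synthetic_study")
}

#' Generate observed data from a synthetic study
#'
#' Per-subject profiles are the engine simulation multiplied by
#' `exp(eps)`, `eps ~ Normal(0, sigma^2)` on the log scale with
#' `sigma = sqrt(log(1 + cv^2))`; `cv = 0` reproduces the simulation exactly.
#'
#' @param study A [synthetic_study()].
#' @return Tibble (subject_id, time_h, conc_ng_per_mL) of class
#'   `synthetic_data`; attributes: `truth` (the generating compound and
#'   settings), `mean_profile`, `summary` (NCA of the mean profile).
#' @export
generate_observed <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  t_end <- max(study$times) + 1
  sim <- simulate_pk(study$subject, study$compound, study$regimen, t_end)
  mp <- pk_profile(sim, study$compound$name)
  conc <- approx(mp$time, mp$conc, study$times)$y
  sig <- sqrt(log(1 + (study$cv_percent / 100)^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(study$seed, kind = "Mersenne-Twister")
  out <- purrr::map_dfr(seq_len(study$n_subjects), function(s) {
    eps <- if (sig > 0) rnorm(length(conc), 0, sig) else 0
    tibble(subject_id = s, time_h = study$times,
           conc_ng_per_mL = conc * exp(eps))
  })
  class(out) <- c("synthetic_data", class(out))
  attr(out, "truth") <- list(compound = study$compound,
                             regimen = study$regimen,
                             cv_percent = study$cv_percent, seed = study$seed)
  attr(out, "mean_profile") <- tibble(time = study$times, conc = conc)
  attr(out, "summary") <- nca(tibble(time = study$times, conc = conc),
                              dose = study$regimen$dose[1])
  out
}

#' Write a suite of synthetic study fixtures
#'
#' Writes single-dose 300/500 mg and repeated-dose 300/400/500 mg QD studies
#' of the calibrated fedratinib model, mimicking 28-day cycles with full PK
#' sampling after the first dose and after the cycle-2 day-1 dose. Each CSV
#' gets a JSON truth sidecar; regeneration is byte-identical for a fixed
#' seed.
#'
#' @param seed Base seed.
#' @param dir Output directory (created if needed).
#' @param compound The generating compound (default: library fedratinib).
#' @param cv_percent Residual CV, %.
#' @param n_subjects Subjects per study.
#' @return Tibble of the files written (study, csv, json), invisibly.
#' @export
make_fixture_suite <- function(seed, dir, compound = NULL, cv_percent = 20,
                               n_subjects = 12) {
  if (is.null(compound)) compound <- compound_library("fedratinib")[[1]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rich <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48, 72, 96)
  specs <- list(
    sd_300 = list(reg = regimen(compound$name, 300, "single", 0), t = rich),
    sd_500 = list(reg = regimen(compound$name, 500, "single", 0), t = rich),
    qd_300 = NULL, qd_400 = NULL, qd_500 = NULL)
  for (d in c(300, 400, 500)) {
    # 28-day cycle: sampling on cycle 1 day 1 and cycle 2 day 1 (t = 672 h)
    specs[[paste0("qd_", d)]] <- list(
      reg = regimen(compound$name, d, "qd", 0, 29 * 24),
      t = sort(unique(c(rich[rich <= 24], 672 + rich[rich <= 24]))))
  }
  files <- purrr::imap_dfr(specs, function(sp, nm) {
    st <- synthetic_study(compound, sp$reg, sp$t, cv_percent, n_subjects,
                          seed = seed + which(names(specs) == nm))
    obs <- generate_observed(st)
    csv <- file.path(dir, paste0(nm, ".csv"))
    con <- file(csv, open = "wb")  # byte-stable line endings
    writeLines("subject_id,time_h,conc_ng_per_mL", con)
    writeLines(sprintf("%d,%.10g,%.10g", obs$subject_id, obs$time_h,
                       obs$conc_ng_per_mL), con)
    close(con)
    js <- file.path(dir, paste0(nm, "_truth.json"))
    tr <- attr(obs, "truth")
    jsonlite::write_json(
      list(compound = unclass(tr$compound), regimen = as.list(tr$regimen),
           cv_percent = tr$cv_percent, seed = tr$seed),
      js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tibble(study = nm, csv = csv, json = js)
  })
  invisible(files)
}
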