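# quick two-compound design used across trial tests (short horizon)
quick_design <- function(perp_dose = 200, n_trials = 2, n_subjects = 3,
                         population = population_spec("healthy"), seed = 1) {
  trial_design(
    victim = "midazolam",
    victim_regimen = regimen("midazolam", 2, "single", 24),
    perpetrator = "ketoconazole",
    perp_regimen = regimen("ketoconazole", perp_dose, "bid", 0, 60),
    population = population, n_trials = n_trials, n_subjects = n_subjects,
    metric = "auc_inf", obs_dose_time = 24, t_end = 60, seed = seed)
}

test_that("zero perpetrator dose gives ratios of exactly 1", {
  lib <- compound_library(c("midazolam", "ketoconazole"))
  r <- run_trials(quick_design(perp_dose = 0), lib)
  expect_null(r$ratios)           # unpaired: no interaction arm simulated
  # with a tiny but non-zero dose the paired machinery runs; ratios ~ 1
  r2 <- run_trials(quick_design(perp_dose = 1e-9), lib)
  expect_true(all(abs(r2$ratios$gm_ratio - 1) < 1e-6))
})

test_that("CV = 0 population gives identical subjects and zero-width CIs", {
  lib <- compound_library(c("midazolam", "ketoconazole"))
  r <- run_trials(quick_design(population = healthy_cv0(), n_trials = 2,
                               n_subjects = 3), lib)
  expect_lt(max(r$ratios$ci_hi - r$ratios$ci_lo), 1e-9)
  auc <- r$subjects$auc[r$subjects$arm == "alone"]
  expect_lt(diff(range(auc)), 1e-9 * mean(auc))
})

test_that("trials are seed-deterministic and pairing-invariant", {
  lib <- compound_library(c("midazolam", "ketoconazole"))
  r1 <- run_trials(quick_design(seed = 5), lib)
  r2 <- run_trials(quick_design(seed = 5), lib)
  expect_identical(r1$ratios, r2$ratios)
  r3 <- run_trials(quick_design(seed = 6), lib)
  expect_false(identical(r1$ratios$gm_ratio, r3$ratios$gm_ratio))
  # arm GM ratio equals GM of within-subject ratios by construction
  wide <- tidyr::pivot_wider(r1$subjects[, c("trial", "subject", "arm", "auc")],
                             names_from = "arm", values_from = "auc")
  expect_equal(r1$ratios$gm_ratio[r1$ratios$metric == "auc"],
               exp(mean(log(wide$combo / wide$alone))), tolerance = 1e-12)
  ga <- r1$arms$gm[r1$arms$arm == "combo" & r1$arms$metric == "auc"] /
    r1$arms$gm[r1$arms$arm == "alone" & r1$arms$metric == "auc"]
  expect_equal(ga, r1$ratios$gm_ratio[r1$ratios$metric == "auc"],
               tolerance = 1e-12)
})

test_that("tidy/glance/autoplot surfaces behave", {
  lib <- compound_library(c("midazolam", "ketoconazole"))
  r <- run_trials(quick_design(), lib)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$metric, c("auc", "cmax"))
  g <- glance(r)
  expect_equal(g$victim, "midazolam")
  expect_true(is.numeric(g$auc_ratio))
  expect_s3_class(autoplot(r), "ggplot")
  sub <- central_subject()
  sim <- simulate_pk(sub, lib$midazolam, regimen("midazolam", 2, "single", 0), 24)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_enzymes(sim), "ggplot")
  expect_true(all(c("time", "compound", "conc") %in% names(tidy(sim))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_sim_csv(sim, f)
  expect_gt(nrow(utils::read.csv(f)), 10)
})

test_that("psa scans a parameter path and a single baseline value is idempotent", {
  lib <- compound_library(c("midazolam", "ketoconazole"))
  des <- quick_design(n_trials = 1, n_subjects = 2)
  base_ki <- lib$ketoconazole$interactions$CYP3A4_liver$ki_reversible
  tab <- psa(des, lib, "ketoconazole",
             "interactions/CYP3A4_liver/ki_reversible",
             c(base_ki, base_ki * 10))
  auc <- tab$gm_ratio[tab$metric == "auc"]
  expect_gt(auc[1], auc[2])       # weaker Ki -> smaller interaction
  ref <- run_trials(des, lib)
  expect_equal(auc[1], ref$ratios$gm_ratio[ref$ratios$metric == "auc"],
               tolerance = 1e-12)
  expect_error(psa(des, lib, "ketoconazole", "name", 1),
               class = "pbpkddi_argument_error")
})

test_that("run manifest hashes configurations reproducibly", {
  lib <- compound_library("midazolam")
  f <- withr::local_tempfile(fileext = ".json")
  m1 <- run_manifest(3L, list(cm = lib[[1]]), f)
  m2 <- run_manifest(3L, list(cm = lib[[1]]))
  expect_identical(m1$config_hashes, m2$config_hashes)
  expect_true(file.exists(f))
  j <- jsonlite::read_json(f)
  expect_equal(j$seed, 3)
})

test_that("dose recommendation thresholds, tie rule, and classes", {
  expect_equal(recommend_dose(2.5)$recommended_dose_mg, 200)
  expect_equal(recommend_dose(2.0)$recommended_dose_mg, 200)   # tie -> reduce
  expect_equal(recommend_dose(1.5)$recommended_dose_mg, 300)
  expect_equal(recommend_dose(1.2)$recommended_dose_mg, 300)   # tie -> reduce
  expect_equal(recommend_dose(1.15)$recommended_dose_mg, 400)
  expect_true(all(recommend_dose(1.7)$recommended_dose_mg %in%
                    c(200, 300, 400)))
  # configurable thresholds
  expect_equal(recommend_dose(1.5, strong_threshold = 1.4)$recommended_dose_mg,
               200)
  expect_error(recommend_dose("x"), class = "pbpkddi_argument_error")

  expect_equal(as.character(perpetrator_class(6)), "strong")
  expect_equal(as.character(perpetrator_class(3)), "moderate")
  expect_equal(as.character(perpetrator_class(1.3)), "weak")
  expect_equal(as.character(perpetrator_class(1.1)), "none")
  expect_equal(attr(perpetrator_class(0.15), "direction"), "inducer")
  expect_equal(as.character(perpetrator_class(0.15)), "strong")
})
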