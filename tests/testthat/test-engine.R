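sub0 <- central_subject()

test_that("one-compartment reduction matches the analytic oral solution", {
  cm <- onecpt_drug(cl = 10, v = 100, ka = 1)
  sim <- simulate_pk(sub0, cm, regimen("onecpt", 100, "single", 0), 120)
  r <- nca(pk_profile(sim), dose = 100)
  # AUCinf = F*D/CL = 10 mg.h/L
  expect_lt(abs(r$auc_inf / 1000 - 10), 10 * 0.001)
  # Bateman peak
  ka <- 1; ke <- 0.1
  tmax <- log(ka / ke) / (ka - ke)
  cmax <- ka / (ka - ke) * (exp(-ke * tmax) - exp(-ka * tmax)) # F*D/V = 1 mg/L
  expect_lt(abs(r$cmax / 1000 - cmax), cmax * 0.001)
  expect_lt(abs(r$tmax - tmax), 0.11)
  # terminal slope equals ke
  expect_lt(abs(r$lambda_z - ke), ke * 0.001)
})

test_that("mass balance holds and enzymes stay at baseline without interactions", {
  cm <- twopath_victim()
  sim <- simulate_pk(sub0, cm, regimen("twopath", 200, "qd", 0, 96), 144)
  expect_lt(max(sim$mass_balance_drift), 1e-3)
  expect_equal(range(sim$enzymes), c(1, 1), tolerance = 1e-8)
  expect_true(all(sim$conc >= 0))
  expect_true(all(diff(sim$times) > 0))
})

test_that("output grid is dense enough: AUC stable under half-step refinement", {
  cm <- twopath_victim()
  reg <- regimen("twopath", 200, "single", 0)
  a1 <- nca(pk_profile(simulate_pk(sub0, cm, reg, 96)), dose = 200)$auc_last
  a2 <- nca(pk_profile(simulate_pk(sub0, cm, reg, 96,
                                   solver = solver_opts(dt = 0.05))),
            dose = 200)$auc_last
  expect_lt(abs(a1 / a2 - 1), 0.005)
})

test_that("no-perpetrator equivalence: interaction fields alone change nothing", {
  victim <- pure3a4_victim()
  victim_ik <- victim
  victim_ik$interactions <- list()  # absent vs empty map
  reg <- regimen("victim3a4", 50, "single", 0)
  s1 <- simulate_pk(sub0, victim, reg, 72)
  s2 <- simulate_pk(sub0, victim_ik, reg, 72)
  expect_equal(s1$conc, s2$conc, tolerance = 1e-12)
})

test_that("competitive inhibition identity: constant Iu = Ki doubles exposure of an fm=1 victim", {
  ki <- 2
  inh <- const_inhibitor(ki)
  victim <- pure3a4_victim()
  reg_v <- regimen("victim3a4", 50, "single", 24)
  dose_i <- const_inhibitor_dose(ki)            # unbound conc = Ki
  alone <- simulate_pk(sub0, victim, reg_v, 360)
  both <- simulate_pk(sub0, list(victim3a4 = victim, inhib = inh),
                      regimens(reg_v, regimen("inhib", dose_i, "single", 0)),
                      360)
  met <- function(s) {
    p <- pk_profile(s, "victim3a4"); p <- p[p$time >= 24, ]
    p$time <- p$time - 24; nca(p)$auc_inf
  }
  expect_lt(abs(met(both) / met(alone) - 2), 2 * 0.02)
})

test_that("static-model limit reproduces the competitive-inhibition AUC ratio for fm < 1", {
  # victim with hepatic CYP3A4 + renal pathway, fg = 1, constant inhibitor
  victim <- compound_model("vmix", mol_weight = 450, fu_plasma = 0.1,
                           ka = 1, vss = 1.2, v_sac = 0, q_sac = 0,
                           enzyme_clearances = list(
                             CYP3A4_liver = list(value = 0.3,
                                                 units = "uL/min/pmol")),
                           cl_renal = 2)
  reg_v <- regimen("vmix", 50, "single", 24)
  alone <- simulate_pk(sub0, victim, reg_v, 480)
  fm <- fm_fe_partition(alone, c(24, 480))[["CYP3A4_liver"]]
  ki <- 1.5; iu_over_ki <- 3
  inh <- const_inhibitor(ki)
  both <- simulate_pk(sub0, list(vmix = victim, inhib = inh),
                      regimens(reg_v, regimen("inhib",
                                              const_inhibitor_dose(ki * iu_over_ki),
                                              "single", 0)), 480)
  met <- function(s) {
    p <- pk_profile(s, "vmix"); p <- p[p$time >= 24, ]
    p$time <- p$time - 24; nca(p)$auc_inf
  }
  aucr <- met(both) / met(alone)
  expected <- 1 / (fm / (1 + iu_over_ki) + (1 - fm))
  expect_lt(abs(aucr / expected - 1), 0.02)
})

test_that("enzyme pools recover exponentially with rate kdeg after washout", {
  # TDI perpetrator with fast elimination: one dose, then clean washout
  perp <- compound_model("tdi", mol_weight = 400, fu_plasma = 0.3, ka = 2,
                         vss = 0.7, v_sac = 0, q_sac = 0, cl_additional = 40,
                         interactions = list(
                           CYP3A4_liver = interaction_kinetics(
                             kinact = 2, ki_app = 0.5, provenance = "test")))
  sim <- simulate_pk(sub0, perp, regimen("tdi", 200, "single", 0), 400)
  e <- sim$enzymes[, "CYP3A4_liver"]
  t <- sim$times
  # washout window: drug gone (t1/2 ~ 1 h), recovery under way
  i1 <- which.min(abs(t - 100)); i2 <- which.min(abs(t - 200))
  expect_lt(e[i1], 0.9)                     # pool was inactivated
  kdeg <- enzyme_kdeg()[["CYP3A4_liver"]]
  ratio <- (1 - e[i2]) / (1 - e[i1])
  expect_lt(abs(ratio / exp(-kdeg * (t[i2] - t[i1])) - 1), 0.01)
})

test_that("victim AUC ratio is monotone in inhibitor and inducer exposure", {
  victim <- pure3a4_victim()
  reg_v <- regimen("victim3a4", 50, "single", 24)
  met <- function(s) {
    p <- pk_profile(s, "victim3a4"); p <- p[p$time >= 24, ]
    p$time <- p$time - 24; nca(p)$auc_inf
  }
  base <- met(simulate_pk(sub0, victim, reg_v, 360))
  ki <- 1
  inh <- const_inhibitor(ki)
  aucr_inh <- vapply(c(0.5, 2, 8), function(mult) {
    both <- simulate_pk(sub0, list(victim3a4 = victim, inhib = inh),
                        regimens(reg_v, regimen("inhib",
                                                const_inhibitor_dose(ki * mult),
                                                "single", 0)), 360)
    met(both) / base
  }, 0)
  expect_true(all(diff(aucr_inh) > 0))
  expect_true(all(aucr_inh > 1))

  indr <- compound_model("ind", mol_weight = 400, fu_plasma = 0.5, ka = 50,
                         vss = 50 / 75, v_sac = 0, q_sac = 0, cl_renal = 1e-6,
                         interactions = list(
                           CYP3A4_liver = interaction_kinetics(
                             ind_max = 5, ind_c50 = 1, provenance = "test")))
  aucr_ind <- vapply(c(10, 100), function(d) {
    both <- simulate_pk(sub0, list(victim3a4 = victim, ind = indr),
                        regimens(reg_v, regimen("ind", d, "single", 0)), 360)
    met(both) / base
  }, 0)
  expect_true(all(diff(aucr_ind) < 0))
  expect_true(all(aucr_ind < 1))
})

test_that("compiled right-hand side agrees with the R reference implementation", {
  lib <- compound_library(c("midazolam", "ketoconazole"))
  compounds <- lib
  parms <- pbpkddi:::.engine_parms(compounds, sub0)
  nst <- pbpkddi:::.NSTC * 2 + pbpkddi:::.NENZ
  y0 <- numeric(nst); y0[pbpkddi:::.NSTC * 2 + seq_len(pbpkddi:::.NENZ)] <- 1
  names(y0) <- pbpkddi:::.state_names(compounds)
  ev <- data.frame(var = c("midazolam.gut", "ketoconazole.gut"),
                   time = c(1, 2), value = c(2, 200), method = "add")
  times <- seq(0, 48, 0.5)
  oc <- deSolve::lsoda(y0, times, func = "pbpk_derivs", parms = parms,
                       dllname = "pbpkddi", initfunc = "pbpk_initmod",
                       events = list(data = ev), rtol = 1e-10, atol = 1e-12)
  orr <- deSolve::lsoda(y0, times, func = pbpkddi:::.pbpk_rhs_r, parms = parms,
                        events = list(data = ev), rtol = 1e-10, atol = 1e-12)
  expect_equal(unclass(oc)[, -1], unclass(orr)[, -1], tolerance = 1e-6)
})

test_that("fm_fe_partition: single pathway gives 1, empty window errors", {
  cm <- onecpt_drug()
  sim <- simulate_pk(sub0, cm, regimen("onecpt", 100, "single", 0), 72)
  fr <- fm_fe_partition(sim, c(0, 72))
  expect_equal(unname(fr[["additional"]]), 1, tolerance = 1e-9)
  expect_equal(sum(fr), 1, tolerance = 1e-6)
  expect_error(fm_fe_partition(sim, c(60, 80)),
               class = "pbpkddi_argument_error")
  # zero elimination window (before any dose reaches the body)
  sim2 <- simulate_pk(sub0, cm, regimen("onecpt", 100, "single", 10), 72)
  expect_error(fm_fe_partition(sim2, c(0, 5)),
               class = "pbpkddi_undefined_fraction_error")
})

test_that("simulation guards: t_end before last dose, unknown compound", {
  cm <- onecpt_drug()
  expect_error(simulate_pk(sub0, cm, regimen("onecpt", 10, "qd", 0, 96), 48),
               class = "pbpkddi_argument_error")
  expect_error(simulate_pk(sub0, cm, regimen("other", 10, "single", 0), 48),
               class = "pbpkddi_argument_error")
})
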