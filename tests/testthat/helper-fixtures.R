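# shared fixtures for the test suite; everything is built in code

# one-compartment test drug: dose into a linear systemic clearance, no liver
# extraction limit (elimination via cl_additional), V = 100 L at 75 kg
onecpt_drug <- function(cl = 10, v = 100, ka = 1) {
  compound_model("onecpt", mol_weight = 400, fu_plasma = 0.1, ka = ka,
                 vss = v / 75, v_sac = 0, q_sac = 0, cl_additional = cl)
}

# pure hepatic CYP3A4 victim (fm = 1) for static-limit checks
pure3a4_victim <- function(fm3a4_clint = 0.3) {
  compound_model("victim3a4", mol_weight = 450, fu_plasma = 0.1,
                 ka = 1, vss = 1.2, v_sac = 0, q_sac = 0,
                 enzyme_clearances = list(
                   CYP3A4_liver = list(value = fm3a4_clint,
                                       units = "uL/min/pmol")))
}

# split-pathway victim with known fm for retrograde round trips
twopath_victim <- function(cl3a4 = 0.4, cl2c19 = 1.2, clr = 1.5, clb = 0.8) {
  compound_model("twopath", mol_weight = 500, fu_plasma = 0.06,
                 ka = 0.9, vss = 2.5, v_sac = 4, q_sac = 5,
                 enzyme_clearances = list(
                   CYP3A4_liver = list(value = cl3a4, units = "uL/min/pmol"),
                   CYP2C19 = list(value = cl2c19, units = "uL/min/pmol")),
                 cl_renal = clr, cl_biliary = clb)
}

# constant-concentration perpetrator: near-instant absorption, negligible
# elimination, so unbound concentration is ~ dose * fu / V for the whole run
const_inhibitor <- function(ki_um, dose_um_target = NULL, fu = 0.5, v = 50) {
  compound_model("inhib", mol_weight = 400, fu_plasma = fu, ka = 50,
                 vss = v / 75, v_sac = 0, q_sac = 0, cl_renal = 1e-6,
                 interactions = list(
                   CYP3A4_liver = interaction_kinetics(
                     ki_reversible = ki_um, provenance = "test")))
}

# dose (mg) of const_inhibitor giving unbound concentration iu_um (uM)
const_inhibitor_dose <- function(iu_um, fu = 0.5, v = 50, mw = 400) {
  iu_um * mw / 1000 / fu * v
}

healthy_cv0 <- function() {
  f <- population_spec("healthy")
  f$fields$cv[] <- 0
  f
}

# calibrated fedratinib, memoised across test files (takes ~1 s)
fed_calibrated <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- retrograde_clint(fedratinib_target(), central_subject(),
                                 fedratinib_shell())
    cache
  }
})

library_cal <- function() {
  lib <- compound_library()
  lib$fedratinib <- fed_calibrated()
  lib
}
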