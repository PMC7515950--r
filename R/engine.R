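#' Dosing regimen
#'
#' One row per compound treatment course. `schedule` is `"single"` (one dose
#' at `start`), `"qd"` (every 24 h) or `"bid"` (every 12 h); repeated doses
#' are given at the start of each interval from `start` up to (excluding)
#' `stop`. All dosing is oral, fasted.
#'
#' @param compound Compound name (must match a supplied `compound_model`).
#' @param dose Dose, mg (>= 0).
#' @param schedule `"single"`, `"qd"` or `"bid"`.
#' @param start First dose time, h.
#' @param stop End of the course, h (`single` ignores it); must be > start.
#' @return Tibble of class `regimen`.
#' @export
#' @examples
#' regimen("midazolam", 2, "single", start = 0)
regimen <- function(compound, dose, schedule = c("single", "qd", "bid"),
                    start = 0, stop = start + 24) {
  schedule <- match.arg(schedule)
  if (dose < 0) .stop_validation("dose must be >= 0", "dose")
  if (schedule != "single" && stop <= start)
    .stop_validation("stop must be > start", "stop")
  out <- tibble(compound = compound, dose = dose, schedule = schedule,
                start = start, stop = stop)
  class(out) <- c("regimen", class(out))
  out
}

#' Combine regimen rows
#' @param ... `regimen` objects.
#' @return A `regimen` tibble.
#' @export
regimens <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- unique(c("regimen", class(out)))
  out
}

#' Dose event times of a regimen row
#' @param reg A `regimen` tibble.
#' @return Tibble (compound, time, dose).
#' @export
dose_times <- function(reg) {
  purrr::pmap_dfr(reg, function(compound, dose, schedule, start, stop, ...) {
    times <- switch(schedule,
      single = start,
      qd = seq(start, stop - 1e-6, by = 24),
      bid = seq(start, stop - 1e-6, by = 12))
    tibble(compound = compound, time = times, dose = dose)
  })
}

#' Solver options
#'
#' @param rtol,atol Relative/absolute integration tolerances (stiff-capable
#'   `lsoda`).
#' @param dt Output grid spacing, h.
#' @param maxsteps Maximal internal steps between outputs.
#' @return List of options for [simulate_pk()].
#' @export
solver_opts <- function(rtol = 1e-8, atol = 1e-10, dt = 0.1, maxsteps = 50000) {
  list(rtol = rtol, atol = atol, dt = dt, maxsteps = maxsteps)
}

# pack engine parameters for one subject + compound list (mirrors src/pbpk.c)
.engine_parms <- function(compounds, subject, kdeg = .default_kdeg) {
  nc <- length(compounds)
  if (nc < 1 || nc > .NCMAX)
    abort(sprintf("between 1 and %d compounds supported", .NCMAX),
          class = "pbpkddi_argument_error")
  ab <- .subject_abundance(subject)
  p <- numeric(.NPAR)
  p[1] <- nc
  p[2] <- subject$hepatic_blood_flow
  p[3] <- subject$villous_blood_flow
  p[4:10] <- kdeg[enzyme_ids()]
  eid <- enzyme_ids()
  for (c in seq_len(nc)) {
    cm <- compounds[[c]]
    base <- 10 + .CBLK * (c - 1)
    fu <- .scaled_fu(cm$fu_plasma, subject$plasma_protein_scalar)
    fgm <- cm$fg_model
    dyn <- fgm$type == "gut_extraction"
    clg <- if (dyn) fgm$clint_gut$value * ab[["CYP3A4_gut"]] * 6e-5 else 0
    clh <- numeric(.NENZ)
    for (e in seq_along(eid)) {
      ec <- cm$enzyme_clearances[[eid[e]]]
      if (is.null(ec) || eid[e] == "CYP3A4_gut") next
      scale <- subject$mppgl * subject$liver_weight * 6e-5
      clh[e] <- if (ec$units == "uL/min/pmol") ec$value * ab[[eid[e]]] * scale
                else ec$value * scale
    }
    ik <- matrix(0, .NENZ, 5)
    for (e in seq_along(eid)) {
      k <- cm$interactions[[eid[e]]]
      if (is.null(k)) next
      ik[e, ] <- c(k$ki_reversible %||% 0, k$kinact %||% 0, k$ki_app %||% 0,
                   k$ind_max %||% 0, k$ind_c50 %||% 0)
    }
    p[base + 1:.CBLK] <- c(
      cm$ka, cm$vss * subject$body_weight, cm$v_sac * subject$body_weight,
      cm$q_sac, fu, cm$blood_plasma_ratio, cm$mol_weight,
      as.numeric(dyn), if (dyn) 1 else fgm$fg, clg,
      if (dyn) fgm$fu_gut %||% 1 else 1,
      cm$cl_renal * subject$gfr_scalar, cm$cl_biliary, cm$cl_additional,
      clh, as.vector(t(ik)))
  }
  p
}

.state_names <- function(compounds) {
  nms <- unlist(lapply(names(compounds), function(nm)
    paste0(nm, ".", c("gut", "cen", "sac", paste0("cum.", pathway_ids()[1:7]),
                      "cum.renal", "cum.biliary", "cum.additional"))))
  c(nms, paste0("E.", enzyme_ids()))
}

#' Simulate one subject under a multi-compound regimen
#'
#' Integrates the coupled drug/enzyme ODE system: per compound a gut lumen,
#' central and single-adjusting peripheral compartment with a well-stirred
#' liver (unbound liver-inlet concentration drives metabolism and all
#' interaction terms) and optionally a dynamic enterocyte CYP3A4 extraction;
#' per enzyme pool a turnover state with synthesis induction and
#' mechanism-based inactivation. Dosing is event-based (no impulse
#' smoothing); the stiff `lsoda` solver is used at rtol 1e-8 / atol 1e-10.
#'
#' Mass balance (dose absorbed = amount in body + cumulative eliminated) is
#' checked at every output time and must hold to 0.1%; a violation or a
#' substantially negative state is a hard error.
#'
#' @param subject One row of a `subject_table`.
#' @param compounds A `compound_model` or list of them (victim first by
#'   convention).
#' @param reg A [regimen()] covering the supplied compounds.
#' @param t_end End of simulation, h (beyond the last dose).
#' @param solver [solver_opts()].
#' @param kdeg Named enzyme degradation rates (1/h), defaulting to
#'   [enzyme_kdeg()]; exposed so turnover-timescale limits can be studied.
#' @return Object of class `pbpk_sim` with elements `times`, `conc` (ng/mL
#'   matrix, one column per compound), `enzymes`, `cum` (cumulative eliminated
#'   mg per pathway per compound), `states`, plus inputs.
#' @export
simulate_pk <- function(subject, compounds, reg, t_end,
                        solver = solver_opts(), kdeg = enzyme_kdeg()) {
  if (inherits(compounds, "compound_model")) compounds <- list(compounds)
  if (is.null(names(compounds)) || any(!nzchar(names(compounds))))
    names(compounds) <- vapply(compounds, function(x) x$name, "")
  dt <- dose_times(reg)
  if (!all(dt$compound %in% names(compounds)))
    abort("regimen references compounds not supplied",
          class = "pbpkddi_argument_error")
  if (t_end <= max(dt$time))
    abort("t_end must lie beyond the last dose", class = "pbpkddi_argument_error")

  parms <- .engine_parms(compounds, subject, kdeg)
  nstate <- .NSTC * length(compounds) + .NENZ
  y0 <- numeric(nstate)
  y0[.NSTC * length(compounds) + seq_len(.NENZ)] <- 1
  names(y0) <- .state_names(compounds)

  ci <- match(dt$compound, names(compounds))
  ev <- data.frame(var = names(y0)[.NSTC * (ci - 1) + 1],
                   time = dt$time + vapply(compounds[ci], `[[`, 0, "lag_time"),
                   value = dt$dose * vapply(compounds[ci], `[[`, 0, "fa"),
                   method = "add")
  ev$time <- round(ev$time, 6)   # snap to avoid near-duplicate output times
  ev <- ev[order(ev$time), ]
  times <- sort(unique(round(c(seq(0, t_end, by = solver$dt), ev$time, t_end), 6)))
  times <- times[times <= t_end + 1e-9]

  out <- deSolve::lsoda(y0, times, func = "pbpk_derivs", parms = parms,
                        dllname = "pbpkddi", initfunc = "pbpk_initmod",
                        events = list(data = ev), rtol = solver$rtol,
                        atol = solver$atol, maxsteps = solver$maxsteps)
  if (attr(out, "istate")[1] < 0)
    abort(paste0("ODE solver failure; last state:\n",
                 paste(capture_state(out), collapse = "\n")),
          class = "pbpkddi_solver_error")
  tt <- out[, 1]
  st <- out[, -1, drop = FALSE]
  amax <- max(abs(st))
  if (min(st) < -1e-6 * max(amax, 1))
    abort("negative state encountered in simulation",
          class = "pbpkddi_solver_error")
  st[st < 0] <- 0

  nc <- length(compounds)
  conc <- sapply(seq_len(nc), function(c) {
    vc <- compounds[[c]]$vss * subject$body_weight
    st[, .NSTC * (c - 1) + 2] / vc * 1000  # mg/L -> ng/mL
  })
  conc <- matrix(conc, ncol = nc, dimnames = list(NULL, names(compounds)))
  cum <- lapply(seq_len(nc), function(c)
    st[, .NSTC * (c - 1) + 3 + seq_len(10), drop = FALSE])
  names(cum) <- names(compounds)
  for (c in seq_len(nc)) colnames(cum[[c]]) <- pathway_ids()

  # mass balance: per compound, dosed-in vs in-body + eliminated
  # states reported exactly at an event time are pre-event; skip those points
  at_event <- vapply(tt, function(t) any(abs(ev$time - t) < 1e-6), TRUE)
  drift <- vapply(seq_len(nc), function(c) {
    evc <- ev[ev$var == names(y0)[.NSTC * (c - 1) + 1], , drop = FALSE]
    dosed <- vapply(tt, function(t) sum(evc$value[evc$time <= t + 1e-9]), 0)
    body <- rowSums(st[, .NSTC * (c - 1) + 1:3, drop = FALSE])
    elim <- rowSums(cum[[c]])
    d <- abs(dosed - body - elim)[!at_event]
    max(d / pmax(dosed[!at_event], max(dosed) * 1e-3, 1e-12))
  }, 0)
  if (any(drift > 1e-3))
    abort(sprintf("mass-balance drift %.3g exceeds 0.1%%", max(drift)),
          class = "pbpkddi_mass_balance_error")

  structure(list(times = tt, conc = conc,
                 enzymes = st[, .NSTC * nc + seq_len(.NENZ), drop = FALSE] |>
                   `colnames<-`(enzyme_ids()),
                 cum = cum, states = st, compounds = compounds,
                 regimen = reg, subject = subject, mass_balance_drift = drift),
            class = "pbpk_sim")
}

capture_state <- function(out) {
  n <- nrow(out)
  sprintf("%s = %.6g", colnames(out), out[n, ])
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %d compounds, t in [0, %.5g] h, %d output times\n",
              ncol(x$conc), max(x$times), length(x$times)))
  for (nm in colnames(x$conc))
    cat(sprintf("  %s: Cmax %.4g ng/mL\n", nm, max(x$conc[, nm])))
  invisible(x)
}

#' Concentration profile of one compound
#'
#' @param sim A `pbpk_sim`.
#' @param compound Compound name (default: first).
#' @return Tibble (time, conc) in h and ng/mL.
#' @export
pk_profile <- function(sim, compound = colnames(sim$conc)[1]) {
  tibble(time = sim$times, conc = sim$conc[, compound])
}

#' Fraction of elimination per pathway over a time window
#'
#' Computes each pathway's eliminated mass within `[t0, t1]` divided by the
#' total mass eliminated in the window, from the cumulative elimination
#' fluxes of the simulation. Fractions sum to 1 (to 1e-6). With repeated
#' dosing, evaluating the first dosing interval gives the day-1 fm/fe split;
#' a late interval gives the steady-state split.
#'
#' @param sim A [simulate_pk()] result.
#' @param window Numeric `c(t0, t1)` within the simulated range.
#' @param compound Compound name (default: first).
#' @param scope `"systemic"` (default) partitions systemic elimination only,
#'   excluding pre-systemic gut-wall metabolism — the convention under which
#'   fm/fe are reported relative to systemic clearance. `"all"` includes the
#'   gut CYP3A4 pathway in the denominator.
#' @return Named numeric vector of fractions over pathways with non-zero
#'   clearance.
#' @export
fm_fe_partition <- function(sim, window, compound = colnames(sim$conc)[1],
                            scope = c("systemic", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(sim, "pbpk_sim"), length(window) == 2)
  if (window[1] < min(sim$times) - 1e-9 || window[2] > max(sim$times) + 1e-9 ||
      window[2] <= window[1])
    abort("window must lie within the simulated range",
          class = "pbpkddi_argument_error")
  cum <- sim$cum[[compound]]
  if (scope == "systemic")
    cum <- cum[, setdiff(colnames(cum), "CYP3A4_gut"), drop = FALSE]
  at <- function(t) apply(cum, 2, function(col) approx(sim$times, col, t)$y)
  d <- at(window[2]) - at(window[1])
  d[d < 0 & d > -1e-12] <- 0
  tot <- sum(d)
  if (tot <= 0)
    abort("no elimination in window: fractions undefined",
          class = "pbpkddi_undefined_fraction_error")
  frac <- d / tot
  frac[frac > 0 | colSums(cum) > 0]
}

#' Export a simulation as tidy CSV
#'
#' Long format: time, compound, concentration, active enzyme fractions and
#' cumulative pathway masses.
#'
#' @param sim A `pbpk_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  td <- tidy(sim)
  write.csv(as.data.frame(td), path, row.names = FALSE)
  invisible(path)
}

# R reference implementation of the compiled right-hand side (used to
# cross-check the C route in tests; not used in production runs)
.pbpk_rhs_r <- function(t, y, p) {
  nc <- as.integer(p[1]); Qh <- p[2]; Qent <- p[3]; kdeg <- p[4:10]
  eoff <- .NSTC * nc
  q <- function(c, i) p[10 + .CBLK * (c - 1) + i]
  Ient <- vapply(seq_len(nc), function(c)
    q(c, 11) * (q(c, 1) * max(y[.NSTC * (c - 1) + 1], 0) / Qent) * 1000 / q(c, 7), 0)
  fg <- portal <- gutmet <- numeric(nc)
  for (c in seq_len(nc)) {
    absr <- q(c, 1) * max(y[.NSTC * (c - 1) + 1], 0)
    if (q(c, 8) < 0.5) fg[c] <- q(c, 9)
    else {
      inh <- 1 + sum(vapply(seq_len(nc), function(k) {
        ki <- q(k, 21 + 5 * 1 + 1); if (ki > 0) Ient[k] / ki else 0 }, 0))
      clg <- q(c, 10) * y[eoff + 2] / inh
      fg[c] <- Qent / (Qent + q(c, 11) * clg)
    }
    portal[c] <- absr * fg[c]; gutmet[c] <- absr * (1 - fg[c])
  }
  Iliv <- vapply(seq_len(nc), function(c) {
    Ccen <- max(y[.NSTC * (c - 1) + 2], 0) / q(c, 2)
    CinB <- Ccen * q(c, 6) + portal[c] / Qh
    q(c, 5) * (CinB / q(c, 6)) * 1000 / q(c, 7)
  }, 0)
  dy <- numeric(length(y))
  for (c in seq_len(nc)) {
    s <- .NSTC * (c - 1)
    Ccen <- y[s + 2] / q(c, 2)
    Csac <- if (q(c, 3) > 0) y[s + 3] / q(c, 3) else 0
    CinB <- Ccen * q(c, 6) + portal[c] / Qh
    fuB <- q(c, 5) / q(c, 6)
    cl_eff <- vapply(seq_len(.NENZ), function(e) {
      cl <- q(c, 14 + e)
      if (e == 2 || cl <= 0) return(0)
      inh <- 1 + sum(vapply(seq_len(nc), function(k) {
        ki <- q(k, 21 + 5 * (e - 1) + 1); if (ki > 0) Iliv[k] / ki else 0 }, 0))
      cl * y[eoff + e] / inh
    }, 0)
    S <- fuB * sum(cl_eff); Eh <- S / (Qh + S)
    hep <- Eh * Qh * CinB
    other <- (q(c, 12) + q(c, 13) + q(c, 14)) * Ccen
    dy[s + 1] <- -q(c, 1) * max(y[s + 1], 0)
    dy[s + 2] <- (1 - Eh) * Qh * CinB - Qh * Ccen * q(c, 6) - other -
      q(c, 4) * (Ccen - Csac)
    dy[s + 3] <- q(c, 4) * (Ccen - Csac)
    sh <- if (sum(cl_eff) > 0) cl_eff / sum(cl_eff) else rep(0, .NENZ)
    dy[s + 3 + seq_len(.NENZ)] <- hep * sh
    dy[s + 5] <- gutmet[c]
    dy[s + 11] <- q(c, 12) * Ccen
    dy[s + 12] <- q(c, 13) * Ccen
    dy[s + 13] <- q(c, 14) * Ccen
  }
  for (e in seq_len(.NENZ)) {
    inact <- ind <- 0
    for (c in seq_len(nc)) {
      r <- vapply(1:5, function(i) q(c, 21 + 5 * (e - 1) + i), 0)
      I <- if (e == 2) Ient[c] else Iliv[c]
      if (r[2] > 0 && r[3] > 0) inact <- inact + r[2] * I / (r[3] + I)
      if (r[4] > 0 && r[5] > 0) ind <- ind + r[4] * I / (r[5] + I)
    }
    dy[eoff + e] <- kdeg[e] * (1 + ind) - y[eoff + e] * (kdeg[e] + inact)
  }
  list(dy)
}
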