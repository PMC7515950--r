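#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into long format
#'
#' @param x A `pbpk_sim`.
#' @param ... Unused.
#' @return Tibble: time, compound, conc (ng/mL), per-pathway cumulative
#'   eliminated mass (mg, `cum_*` columns), and enzyme fractions (`E_*`).
#' @export
tidy.pbpk_sim <- function(x, ...) {
  purrr::map_dfr(colnames(x$conc), function(nm) {
    cum <- as_tibble(x$cum[[nm]])
    names(cum) <- paste0("cum_", names(cum))
    dplyr::bind_cols(
      tibble(time = x$times, compound = nm, conc = x$conc[, nm]),
      cum,
      as_tibble(x$enzymes) |> setNames(paste0("E_", colnames(x$enzymes))))
  })
}

#' One-line summary of a simulation
#' @param x A `pbpk_sim`.
#' @param ... Unused.
#' @return One row per compound: Cmax, tmax, final enzyme fractions.
#' @export
glance.pbpk_sim <- function(x, ...) {
  purrr::map_dfr(colnames(x$conc), function(nm) {
    i <- which.max(x$conc[, nm])
    tibble(compound = nm, cmax = x$conc[i, nm], tmax = x$times[i],
           t_end = max(x$times),
           e_cyp3a4_liver_end = tail(x$enzymes[, "CYP3A4_liver"], 1),
           mass_balance_drift = max(x$mass_balance_drift))
  })
}

#' @export
tidy.ddi_result <- function(x, ...) {
  if (is.null(x$ratios)) return(x$arms)
  x$ratios
}

#' @export
glance.ddi_result <- function(x, ...) {
  out <- tibble(victim = x$design$victim,
                perpetrator = x$design$perpetrator %||% NA_character_,
                n_trials = x$design$n_trials,
                n_subjects = x$design$n_subjects,
                metric = x$design$metric)
  if (!is.null(x$ratios)) {
    out$auc_ratio <- x$ratios$gm_ratio[x$ratios$metric == "auc"]
    out$cmax_ratio <- x$ratios$gm_ratio[x$ratios$metric == "cmax"]
  }
  out
}

#' Plot simulated concentration-time profiles
#'
#' @param object A `pbpk_sim`.
#' @param log_y Log concentration axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbpk_sim <- function(object, log_y = TRUE, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df[df$conc > 0, ],
                       ggplot2::aes(x = .data$time, y = .data$conc,
                                    colour = .data$compound)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "plasma concentration (ng/mL)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Forest-style plot of DDI GM ratios
#'
#' @param object A `ddi_result` (or row-bound tidy ratios from several).
#' @param ... Unused.
#' @return A ggplot with GM ratios and 90% CIs on a log axis.
#' @export
autoplot.ddi_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gm_ratio, y = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.15) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "GM ratio (90% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot enzyme-pool trajectories
#'
#' @param sim A `pbpk_sim`.
#' @param pools Enzyme pools to show.
#' @return A ggplot of active enzyme fraction vs time.
#' @export
plot_enzymes <- function(sim, pools = c("CYP3A4_liver", "CYP3A4_gut")) {
  df <- purrr::map_dfr(pools, function(p)
    tibble(time = sim$times, pool = p, fraction = sim$enzymes[, p]))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$fraction,
                                   colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "time (h)", y = "active enzyme (fraction of baseline)") +
    ggplot2::theme_minimal()
}
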