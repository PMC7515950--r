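#' Dose recommendation from a steady-state DDI ratio
#'
#' Implements the label logic for a victim whose approved dose is 400 mg QD:
#' if the steady-state AUC ratio with the co-administered modulator is at or
#' above `strong_threshold` (default 2, the predicted magnitude with strong
#' CYP3A4 inhibitors), reduce to 200 mg QD; below `maintain_threshold`
#' (default 1.2, mild/moderate inhibitors at steady state, where the
#' predicted increase is under 20%), maintain 400 mg QD; between the two,
#' use the intermediate 300 mg QD step. A ratio exactly at a threshold takes
#' the more conservative (lower-dose) branch.
#'
#' @param ddi A `ddi_result` with an `auc` ratio, or a single numeric
#'   steady-state AUC ratio.
#' @param strong_threshold,maintain_threshold Configurable class thresholds.
#' @return Tibble of class `label_recommendation`: scenario ratio,
#'   recommended dose (mg QD) and rationale.
#' @export
#' @examples
#' recommend_dose(2.0)   # strong inhibition -> 200 mg
#' recommend_dose(1.15)  # < 20% increase -> maintain 400 mg
recommend_dose <- function(ddi, strong_threshold = 2, maintain_threshold = 1.2) {
  ratio <- if (inherits(ddi, "ddi_result")) {
    if (is.null(ddi$ratios)) abort("ddi_result carries no ratio",
                                   class = "pbpkddi_argument_error")
    ddi$ratios$gm_ratio[ddi$ratios$metric == "auc"]
  } else if (is.numeric(ddi) && length(ddi) == 1 && is.finite(ddi)) ddi
  else abort("supply a ddi_result or a single steady-state AUC ratio",
             class = "pbpkddi_argument_error")
  dose <- if (ratio >= strong_threshold) 200
          else if (ratio >= maintain_threshold) 300
          else 400
  rationale <- sprintf(
    "steady-state AUC ratio %.3g %s", ratio,
    if (dose == 200) sprintf(">= %.3g (strong-inhibitor magnitude): reduce to 200 mg QD",
                             strong_threshold)
    else if (dose == 300) sprintf("in [%.3g, %.3g): intermediate 300 mg QD step",
                                  maintain_threshold, strong_threshold)
    else sprintf("< %.3g (exposure increase under %d%%): maintain 400 mg QD",
                 maintain_threshold, round(100 * (maintain_threshold - 1))))
  out <- tibble(auc_ratio = ratio, recommended_dose_mg = dose,
                rationale = rationale)
  class(out) <- c("label_recommendation", class(out))
  out
}

#' Regulatory perpetrator class from an index-substrate AUC ratio
#'
#' Strong >= 5x, moderate 2-5x, weak 1.25-2x AUC increase of a sensitive
#' index substrate; inducers classified on the reciprocal scale.
#'
#' @param auc_ratio GM AUC ratio of the index substrate with/without the
#'   perpetrator.
#' @return One of `"strong"`, `"moderate"`, `"weak"`, `"none"` with attribute
#'   `direction` (`"inhibitor"`/`"inducer"`).
#' @export
perpetrator_class <- function(auc_ratio) {
  stopifnot(is.numeric(auc_ratio), auc_ratio > 0)
  if (auc_ratio >= 1) {
    cls <- if (auc_ratio >= 5) "strong" else if (auc_ratio >= 2) "moderate"
           else if (auc_ratio >= 1.25) "weak" else "none"
    structure(cls, direction = "inhibitor")
  } else {
    inv <- 1 / auc_ratio
    cls <- if (inv >= 5) "strong" else if (inv >= 2) "moderate"
           else if (inv >= 1.25) "weak" else "none"
    structure(cls, direction = "inducer")
  }
}

#' Run manifest
#'
#' Records seed, config hashes and package version so a run can be
#' reproduced bit-identically.
#'
#' @param seed Integer seed of the run.
#' @param configs Named list of objects (hashed via their serialization).
#' @param path Optional JSON output path.
#' @return Manifest list (invisibly written to `path` when given).
#' @export
run_manifest <- function(seed, configs = list(), path = NULL) {
  hashes <- vapply(configs, function(x) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    writeBin(serialize(x, NULL, version = 2), f)
    unname(tools::md5sum(f))
  }, "")
  m <- list(seed = seed, package = "pbpkddi",
            version = as.character(utils::packageVersion("pbpkddi")),
            config_hashes = as.list(hashes))
  if (!is.null(path))
    jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(m)
}
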