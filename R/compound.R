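#' Define a compound parameterization
#'
#' A `compound_model` collects everything the simulation engine needs to know
#' about one drug: physicochemical constants, oral absorption, the minimal
#' distribution model (central volume `vss`, single adjusting compartment
#' `v_sac`, inter-compartment flow `q_sac`), per-enzyme intrinsic clearances,
#' non-metabolic clearances, and interaction kinetics (reversible inhibition,
#' mechanism-based inactivation, induction) per enzyme pool.
#'
#' Intrinsic clearance entries are declared with explicit units:
#' `"uL/min/pmol"` (scaled by enzyme abundance, microsomal protein per gram
#' liver and liver weight) or `"uL/min/mg"` (microsomal-protein based, for the
#' lumped `HLM_additional` pool). The gut pathway uses the total enterocyte
#' CYP3A4 amount (pmol) of the subject.
#'
#' @param name Compound identifier.
#' @param mol_weight Molar mass, g/mol.
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @param blood_plasma_ratio Blood-to-plasma concentration ratio (> 0).
#' @param ka First-order absorption rate constant, 1/h.
#' @param fa Fraction of the dose absorbed from the lumen, in (0, 1].
#' @param lag_time Absorption lag, h.
#' @param fg_model Either `list(type = "fixed_fg", fg = <value>)` or
#'   `list(type = "gut_extraction", clint_gut = list(value =, units =
#'   "uL/min/pmol"), fu_gut = 1)` for a dynamic enterocyte CYP3A4 pathway.
#' @param vss Central (systemic) volume, L/kg.
#' @param v_sac Peripheral single-adjusting-compartment volume, L/kg (0 for a
#'   one-compartment drug).
#' @param q_sac Inter-compartmental flow, L/h.
#' @param enzyme_clearances Named list, enzyme id -> `list(value, units)`.
#' @param cl_renal,cl_biliary,cl_additional First-order plasma clearances, L/h.
#' @param interactions Named list, enzyme id -> [interaction_kinetics()].
#' @param transporters Optional list of transporter parameters; parsed for
#'   forward compatibility but ignored by the engine (a note is emitted).
#' @param provenance Free-text source note for the parameter values.
#'
#' @return A validated object of class `compound_model`.
#' @seealso [load_compound()], [write_compound()], [compound_library()]
#' @export
compound_model <- function(name, mol_weight, fu_plasma, blood_plasma_ratio = 1,
                           ka, fa = 1, lag_time = 0,
                           fg_model = list(type = "fixed_fg", fg = 1),
                           vss, v_sac = 0, q_sac = 0,
                           enzyme_clearances = list(),
                           cl_renal = 0, cl_biliary = 0, cl_additional = 0,
                           interactions = list(),
                           transporters = NULL,
                           provenance = "unspecified") {
  obj <- list(
    name = name, mol_weight = mol_weight, fu_plasma = fu_plasma,
    blood_plasma_ratio = blood_plasma_ratio, ka = ka, fa = fa,
    lag_time = lag_time, fg_model = fg_model, vss = vss, v_sac = v_sac,
    q_sac = q_sac, enzyme_clearances = enzyme_clearances,
    cl_renal = cl_renal, cl_biliary = cl_biliary,
    cl_additional = cl_additional, interactions = interactions,
    transporters = transporters, provenance = provenance
  )
  class(obj) <- "compound_model"
  validate_compound(obj)
}

#' Interaction kinetics for one enzyme pool
#'
#' All constants are on unbound concentrations (liver-inlet plasma for hepatic
#' pools, enterocyte concentration for gut CYP3A4). Absent values switch the
#' corresponding mechanism off.
#'
#' @param ki_reversible Competitive inhibition constant, uM.
#' @param kinact Maximal inactivation rate for time-dependent inhibition, 1/h.
#' @param ki_app Inactivator concentration at half-maximal rate, uM.
#' @param ind_max Maximal fold-increase of enzyme synthesis minus one is not
#'   used; `ind_max` is the maximal multiple added to baseline synthesis
#'   (synthesis rate scales as `1 + ind_max * I / (ind_c50 + I)`). Must be
#'   >= 0.
#' @param ind_c50 Inducer concentration at half-maximal induction, uM.
#' @param provenance Mandatory source note for the constants.
#' @return List of class `interaction_kinetics`.
#' @export
interaction_kinetics <- function(ki_reversible = NULL, kinact = NULL,
                                 ki_app = NULL, ind_max = NULL,
                                 ind_c50 = NULL, provenance = "unspecified") {
  out <- list(ki_reversible = ki_reversible, kinact = kinact,
              ki_app = ki_app, ind_max = ind_max, ind_c50 = ind_c50,
              provenance = provenance)
  class(out) <- "interaction_kinetics"
  out
}

.check_num <- function(x, field, min = 0, strict = FALSE, max = Inf,
                       max_strict = FALSE) {
  if (is.null(x) || length(x) != 1 || !is.numeric(x) || is.na(x))
    .stop_schema(sprintf("field '%s' must be a single number", field), field)
  if ((strict && x <= min) || (!strict && x < min))
    .stop_validation(sprintf("field '%s' = %g violates lower bound %s%g",
                             field, x, if (strict) "> " else ">= ", min), field)
  if ((max_strict && x >= max) || (!max_strict && x > max))
    .stop_validation(sprintf("field '%s' = %g violates upper bound %g",
                             field, x, max), field)
  invisible(x)
}

#' Validate a compound model
#'
#' Enforces the type invariants: positivity of rates/volumes/clearances,
#' fractions in (0, 1], known enzyme identifiers, at least one strictly
#' positive elimination pathway, and well-formed interaction entries.
#'
#' @param x A `compound_model` (or plain list with the same fields).
#' @return The validated `compound_model`, invisibly classed.
#' @export
validate_compound <- function(x) {
  for (f in c("name", "mol_weight", "fu_plasma", "blood_plasma_ratio", "ka",
              "fa", "lag_time", "fg_model", "vss", "v_sac", "q_sac"))
    if (is.null(x[[f]])) .stop_schema(sprintf("missing mandatory field '%s'", f), f)
  if (!is.character(x$name) || !nzchar(x$name))
    .stop_schema("field 'name' must be a non-empty string", "name")
  .check_num(x$mol_weight, "mol_weight", strict = TRUE)
  .check_num(x$fu_plasma, "fu_plasma", strict = TRUE, max = 1)
  .check_num(x$blood_plasma_ratio, "blood_plasma_ratio", strict = TRUE)
  .check_num(x$ka, "ka", strict = TRUE)
  .check_num(x$fa, "fa", strict = TRUE, max = 1)
  .check_num(x$lag_time, "lag_time")
  .check_num(x$vss, "vss", strict = TRUE)
  .check_num(x$v_sac, "v_sac")
  .check_num(x$q_sac, "q_sac")
  for (f in c("cl_renal", "cl_biliary", "cl_additional"))
    .check_num(x[[f]], f)

  fg <- x$fg_model
  if (!is.list(fg) || is.null(fg$type) ||
      !fg$type %in% c("fixed_fg", "gut_extraction"))
    .stop_schema("fg_model$type must be 'fixed_fg' or 'gut_extraction'",
                 "fg_model")
  if (fg$type == "fixed_fg") {
    .check_num(fg$fg, "fg_model$fg", strict = TRUE, max = 1)
  } else {
    if (is.null(fg$clint_gut))
      .stop_schema("gut_extraction fg_model requires 'clint_gut'", "fg_model")
    .check_num(fg$clint_gut$value, "fg_model$clint_gut$value")
    if (!identical(fg$clint_gut$units, "uL/min/pmol"))
      .stop_schema("clint_gut units must be 'uL/min/pmol'", "fg_model")
    .check_num(fg$fu_gut %||% 1, "fg_model$fu_gut", strict = TRUE, max = 1)
  }

  if (length(x$enzyme_clearances)) {
    bad <- setdiff(names(x$enzyme_clearances), enzyme_ids())
    if (length(bad))
      .stop_schema(paste0("unknown enzyme id(s): ", paste(bad, collapse = ", ")),
                   "enzyme_clearances")
    for (e in names(x$enzyme_clearances)) {
      ec <- x$enzyme_clearances[[e]]
      .check_num(ec$value, paste0("enzyme_clearances$", e, "$value"))
      if (is.null(ec$units) || !ec$units %in% c("uL/min/pmol", "uL/min/mg"))
        .stop_schema(sprintf("enzyme_clearances$%s$units must be declared", e),
                     paste0("enzyme_clearances$", e))
    }
  }

  if (length(x$interactions)) {
    bad <- setdiff(names(x$interactions), enzyme_ids())
    if (length(bad))
      .stop_schema(paste0("unknown enzyme id(s) in interactions: ",
                          paste(bad, collapse = ", ")), "interactions")
    for (e in names(x$interactions)) {
      ik <- x$interactions[[e]]
      for (f in c("ki_reversible", "kinact", "ki_app", "ind_c50"))
        if (!is.null(ik[[f]]))
          .check_num(ik[[f]], paste0("interactions$", e, "$", f), strict = TRUE)
      if (!is.null(ik$ind_max))
        .check_num(ik$ind_max, paste0("interactions$", e, "$ind_max"))
      if (!is.null(ik$kinact) != !is.null(ik$ki_app))
        .stop_schema(sprintf("interactions$%s: kinact and ki_app must be given together", e))
      if (!is.null(ik$ind_max) && ik$ind_max > 0 && is.null(ik$ind_c50))
        .stop_schema(sprintf("interactions$%s: ind_max > 0 requires ind_c50", e))
    }
  }

  met <- sum(vapply(x$enzyme_clearances, function(e) e$value, 0))
  gut <- if (x$fg_model$type == "gut_extraction") x$fg_model$clint_gut$value else 0
  if (met + gut + x$cl_renal + x$cl_biliary + x$cl_additional <= 0)
    .stop_validation("no elimination pathway: at least one clearance must be > 0")

  if (!is.null(x$transporters) && length(x$transporters))
    inform(sprintf("compound '%s': transporter parameters parsed but inactive (not modeled)",
                   x$name), class = "pbpkddi_transporters_inactive")
  class(x) <- "compound_model"
  x
}

#' @export
print.compound_model <- function(x, ...) {
  cat(sprintf("<compound_model> %s (MW %.1f g/mol)\n", x$name, x$mol_weight))
  cat(sprintf("  fu %.4g, B/P %.3g, ka %.3g/h, fa %.3g, lag %.2g h\n",
              x$fu_plasma, x$blood_plasma_ratio, x$ka, x$fa, x$lag_time))
  cat(sprintf("  vss %.3g L/kg, v_sac %.3g L/kg, q_sac %.3g L/h; fg_model %s\n",
              x$vss, x$v_sac, x$q_sac, x$fg_model$type))
  if (length(x$enzyme_clearances))
    cat("  enzymes:", paste(names(x$enzyme_clearances), collapse = ", "), "\n")
  cat(sprintf("  CL renal %.3g, biliary %.3g, additional %.3g L/h\n",
              x$cl_renal, x$cl_biliary, x$cl_additional))
  if (length(x$interactions))
    cat("  interactions on:", paste(names(x$interactions), collapse = ", "), "\n")
  invisible(x)
}

.num_fmt <- function(x) {
  # full-precision scalar formatting so config round-trips are value-identical
  if (is.numeric(x)) structure(sprintf("%.17g", x), class = "verbatim") else x
}

#' Read a compound configuration file
#'
#' Accepts YAML (`.yaml`/`.yml`) or JSON (`.json`), one compound per file.
#' All invariants are enforced on load; unknown enzyme names and missing
#' mandatory fields raise classed errors naming the offending field.
#'
#' @param path Path to the configuration file.
#' @return A validated [compound_model()].
#' @export
load_compound <- function(path) {
  if (!file.exists(path)) .stop_schema(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    .stop_schema("compound config must be .yaml, .yml or .json"))
  compound_from_list(raw)
}

#' @rdname load_compound
#' @param x A plain list with `compound_model` fields (e.g. parsed config).
#' @export
compound_from_list <- function(x) {
  # normalize parser artifacts: zero-length values (e.g. JSON null) -> absent
  if (length(x$interactions))
    x$interactions <- lapply(x$interactions, function(ik)
      ik[vapply(ik, length, 0L) > 0])
  obj <- structure(x, class = "compound_model")
  validate_compound(obj)
}

#' Write a compound configuration file
#'
#' Numeric values are serialized at full precision (17 significant digits) so
#' that `load_compound(write_compound(x))` is value-identical to `x`.
#'
#' @param x A `compound_model`.
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_compound <- function(x, path) {
  stopifnot(inherits(x, "compound_model"))
  lst <- unclass(x)
  lst <- lst[!vapply(lst, is.null, TRUE)]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    txt <- yaml::as.yaml(rapply(lst, .num_fmt, how = "replace"))
    writeLines(txt, path)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else .stop_schema("output path must be .yaml, .yml or .json")
  invisible(path)
}

#' Built-in compound library
#'
#' Returns the compound fixtures shipped with the package: the calibrated
#' fedratinib model plus literature-informed perpetrator and probe-substrate
#' models (ketoconazole, itraconazole, erythromycin, diltiazem, fluconazole,
#' efavirenz, rifampin, midazolam, omeprazole, metoprolol, repaglinide,
#' warfarin). Each fixture documents its sources in a free-text `provenance`
#' field; perpetrators are calibrated so their effect on a sensitive CYP3A4
#' index substrate falls in the intended regulatory class.
#'
#' @param names Optional character vector to subset the library.
#' @return Named list of [compound_model()] objects.
#' @export
compound_library <- function(names = NULL) {
  dir <- system.file("extdata", "compounds", package = "pbpkddi")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  lib <- lapply(files, function(f) suppressMessages(load_compound(f)))
  names(lib) <- vapply(lib, function(x) x$name, "")
  if (!is.null(names)) {
    missing <- setdiff(names, names(lib))
    if (length(missing))
      .stop_schema(paste0("not in library: ", paste(missing, collapse = ", ")))
    lib <- lib[names]
  }
  lib
}
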