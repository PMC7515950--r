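#' Virtual population specification
#'
#' Central (median) values and log-normal geometric CVs for the sampled
#' physiological fields of a virtual subject. Central values for the healthy
#' population are widely published human defaults (liver weight, hepatic blood
#' flow, microsomal protein per gram liver, CYP abundances); they are listed in
#' the methods vignette. Sampling is log-normal with the central value as the
#' median, so geometric means are preserved and no sampled value can be zero
#' or negative.
#'
#' @param name `"healthy"` or `"cancer"`.
#' @param overrides Named list of `list(central =, cv =)` entries (cv in %)
#'   replacing defaults field-by-field.
#' @param age_range Requested `c(min, max)` age in years; clipped into the
#'   allowed range 18-65 (healthy) / 18-85 (cancer) with a message, mirroring
#'   the convention of replacing out-of-range bounds by the nearest allowed
#'   value.
#' @param seed Default seed carried by the spec (can be overridden at
#'   sampling time).
#' @return Object of class `population_spec` with a `fields` tibble.
#' @export
population_spec <- function(name = c("healthy", "cancer"), overrides = list(),
                            age_range = c(20, 50), seed = 1L) {
  name <- match.arg(name)
  f <- tibble::tribble(
    ~field,                   ~central, ~cv,
    "body_weight",                 75,   20,   # kg
    "liver_weight",              1650,   20,   # g
    "hepatic_blood_flow",          87,   15,   # L/h
    "villous_blood_flow",          18,   20,   # L/h (enterocyte supply)
    "mppgl",                       40,   30,   # mg microsomal protein / g liver
    "gfr_scalar",                   1,   15,
    "plasma_protein_scalar",        1,   10,
    "hematocrit",                0.45,    8,
    "abund_CYP3A4_liver",         137,   40,   # pmol/mg protein
    "abund_CYP3A4_gut",         66300,   40,   # pmol total enterocyte
    "abund_CYP2C19",               14,   45,
    "abund_CYP2D6",                 8,   60,
    "abund_CYP2C8",                24,   45,
    "abund_CYP2C9",                73,   45,
    "abund_HLM_additional",         1,   30,   # scalar on the lumped pool
    "age",                         35,   20
  )
  allowed <- if (name == "cancer") c(18, 85) else c(18, 65)
  clipped <- c(max(age_range[1], allowed[1]), min(age_range[2], allowed[2]))
  if (!isTRUE(all.equal(clipped, age_range)))
    inform(sprintf("age range [%g, %g] clipped to allowed [%g, %g]",
                   age_range[1], age_range[2], clipped[1], clipped[2]))
  for (nm in names(overrides)) {
    if (!nm %in% f$field) .stop_schema(paste0("unknown population field: ", nm))
    ov <- overrides[[nm]]
    if (!is.null(ov$central)) f$central[f$field == nm] <- ov$central
    if (!is.null(ov$cv)) f$cv[f$field == nm] <- ov$cv
  }
  if (any(f$cv < 0)) .stop_validation("CV% must be >= 0")
  structure(list(name = name, fields = f, age_range = clipped, seed = seed),
            class = "population_spec")
}

#' Cancer population derived from a healthy spec
#'
#' Applies the documented modifier set for the cancer population: increased
#' plasma protein binding (alpha-1-acid glycoprotein; `plasma_protein_scalar`
#' 1.25, lowering the unbound fraction of basic drugs), reduced hepatic and
#' enterocyte CYP3A4 abundance, lower body weight and hematocrit, and an older
#' demographic. The field-by-field difference table is emitted as a message
#' and attached as attribute `"modifier_table"`.
#'
#' @param spec_healthy A healthy [population_spec()].
#' @return A `population_spec` named `"cancer"`.
#' @export
cancer_modifiers <- function(spec_healthy) {
  stopifnot(inherits(spec_healthy, "population_spec"))
  mods <- c(plasma_protein_scalar = 1.25, abund_CYP3A4_liver = 0.75,
            abund_CYP3A4_gut = 0.85, body_weight = 72 / 75,
            hematocrit = 0.38 / 0.45, age = 60 / 35)
  f <- spec_healthy$fields
  for (nm in names(mods)) f$central[f$field == nm] <- f$central[f$field == nm] * mods[[nm]]
  out <- spec_healthy
  out$name <- "cancer"
  out$fields <- f
  out$age_range <- c(40, 75)
  tab <- tibble(field = names(mods),
                healthy = spec_healthy$fields$central[match(names(mods), spec_healthy$fields$field)],
                cancer = f$central[match(names(mods), f$field)])
  inform(paste0("cancer population modifiers:\n",
                paste(sprintf("  %-22s %8.3g -> %8.3g", tab$field, tab$healthy,
                              tab$cancer), collapse = "\n")))
  attr(out, "modifier_table") <- tab
  out
}

#' Sample virtual subjects
#'
#' Log-normal sampling per field with the spec's central value as the median
#' and `sdlog = sqrt(log(1 + cv^2))`. Uses the Mersenne-Twister generator via
#' `set.seed()` in a local RNG scope, so the draw is reproducible across
#' platforms for a fixed seed. Hematocrit is additionally required to fall in
#' (0.2, 0.6); draws outside are redrawn deterministically from the same
#' stream.
#'
#' @param spec A [population_spec()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; defaults to the spec's seed.
#' @return A tibble of class `subject_table`, one row per subject.
#' @export
sample_population <- function(spec, n_subjects, seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.numeric(n_subjects) || n_subjects < 1)
    abort("n_subjects must be >= 1", class = "pbpkddi_argument_error")
  n_subjects <- as.integer(n_subjects)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  f <- spec$fields
  draws <- lapply(seq_len(nrow(f)), function(i) {
    cv <- f$cv[i] / 100
    if (cv <= 0) return(rep(f$central[i], n_subjects))
    sdl <- sqrt(log(1 + cv^2))
    x <- rlnorm(n_subjects, meanlog = log(f$central[i]), sdlog = sdl)
    if (f$field[i] == "hematocrit") {
      for (k in seq_len(50)) {
        bad <- x <= 0.2 | x >= 0.6
        if (!any(bad)) break
        x[bad] <- rlnorm(sum(bad), log(f$central[i]), sdl)
      }
      x <- pmin(pmax(x, 0.201), 0.599)
    }
    if (f$field[i] == "age")
      x <- pmin(pmax(x, spec$age_range[1]), spec$age_range[2])
    x
  })
  names(draws) <- f$field
  out <- as_tibble(draws)
  out <- dplyr::mutate(out, subject_id = dplyr::row_number(),
                       population = spec$name, .before = 1)
  class(out) <- c("subject_table", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "spec") <- spec
  out
}

#' Central (median) subject of a population
#'
#' All fields at their central values (equivalent to sampling with every
#' CV = 0); used for deterministic calibration runs.
#'
#' @param spec A [population_spec()].
#' @return One-row `subject_table`.
#' @export
central_subject <- function(spec = population_spec("healthy")) {
  f <- spec$fields
  out <- as_tibble(setNames(as.list(f$central), f$field))
  out <- dplyr::mutate(out, subject_id = 1L, population = spec$name, .before = 1)
  class(out) <- c("subject_table", class(out))
  attr(out, "spec") <- spec
  out
}

#' Export sampled subjects for audit
#'
#' @param subjects A `subject_table`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  write.csv(as.data.frame(subjects), path, row.names = FALSE)
  invisible(path)
}

# named abundance vector for one subject row
.subject_abundance <- function(subject) {
  ab <- c(CYP3A4_liver = subject$abund_CYP3A4_liver,
          CYP3A4_gut = subject$abund_CYP3A4_gut,
          CYP2C19 = subject$abund_CYP2C19,
          CYP2D6 = subject$abund_CYP2D6,
          CYP2C8 = subject$abund_CYP2C8,
          CYP2C9 = subject$abund_CYP2C9,
          HLM_additional = subject$abund_HLM_additional)
  ab
}

# effective unbound fraction after scaling binding-protein concentration
.scaled_fu <- function(fu, protein_scalar) {
  fu / (protein_scalar * (1 - fu) + fu)
}
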