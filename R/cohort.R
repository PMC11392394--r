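# Encounter cohorts: reading, validation, exclusion filtering, and a
# calibrated synthetic generator.
#
# A cohort is a plain data.frame with one row per ventilated admission
# (an *encounter*, not a unique patient) and the canonical columns below.

VENT_RACES <- c("white_nh", "black_nh", "hispanic", "aapi_nh", "aian_nh",
                "multi_nh", "unknown")
VENT_SEXES <- c("male", "female")

COHORT_COLUMNS <- c("encounter_id", "age", "sex", "race_ethnicity",
                    "covid_positive", "sofa", "elixhauser",
                    "charlson_points", "survived")

#' Validate an encounter cohort
#'
#' Checks the canonical column set and the encounter invariants: integer age
#' >= 18, SOFA in 0--24, sex and race levels, logical COVID status and
#' outcome, non-negative Charlson points.
#'
#' @param cohort data.frame of encounters.
#' @param require_life_expectancy if TRUE, also require a filled (non-missing,
#'   non-negative) `life_expectancy` column, as needed by life-years metrics.
#' @return the cohort, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cohort <- function(cohort, require_life_expectancy = FALSE) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) == 0L) {
    return(invisible(cohort))
  }
  bad <- function(what, which_rows) {
    stop("invalid cohort: ", what, " (rows ",
         paste(utils::head(which_rows, 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.numeric(cohort$age) || anyNA(cohort$age)) {
    bad("age must be numeric and non-missing", which(is.na(cohort$age)))
  }
  if (any(cohort$age < 18)) bad("age must be >= 18", which(cohort$age < 18))
  if (!is.numeric(cohort$sofa) || anyNA(cohort$sofa)) {
    bad("sofa must be numeric and non-missing", which(is.na(cohort$sofa)))
  }
  if (any(cohort$sofa < 0 | cohort$sofa > 24)) {
    bad("sofa must lie in 0..24", which(cohort$sofa < 0 | cohort$sofa > 24))
  }
  if (!all(cohort$sex %in% VENT_SEXES)) {
    bad("sex must be 'male' or 'female'", which(!cohort$sex %in% VENT_SEXES))
  }
  if (!all(cohort$race_ethnicity %in% VENT_RACES)) {
    bad("unknown race_ethnicity level",
        which(!cohort$race_ethnicity %in% VENT_RACES))
  }
  if (!is.logical(cohort$covid_positive) || anyNA(cohort$covid_positive)) {
    bad("covid_positive must be logical and non-missing",
        which(is.na(cohort$covid_positive)))
  }
  if (!is.logical(cohort$survived) || anyNA(cohort$survived)) {
    bad("survived must be logical and non-missing",
        which(is.na(cohort$survived)))
  }
  if (anyNA(cohort$elixhauser)) {
    bad("elixhauser must be non-missing", which(is.na(cohort$elixhauser)))
  }
  if (anyNA(cohort$charlson_points) || any(cohort$charlson_points < 0)) {
    bad("charlson_points must be non-missing and >= 0",
        which(is.na(cohort$charlson_points) | cohort$charlson_points < 0))
  }
  if (require_life_expectancy) {
    if (is.null(cohort$life_expectancy) || anyNA(cohort$life_expectancy) ||
        any(cohort$life_expectancy < 0)) {
      stop("cohort must carry a filled non-negative life_expectancy column; ",
           "run annotate_cohort() first", call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Read an encounter cohort from CSV
#'
#' Reads a cohort CSV with the canonical columns (`encounter_id`, `age`,
#' `sex`, `race_ethnicity`, `covid_positive`, `sofa`, `elixhauser`,
#' `charlson_points`, `survived`).  A `dialect` map renames external column
#' names onto the canonical ones, so arbitrary extracts can be consumed
#' without editing the file.
#'
#' Unparseable race/ethnicity values map to `"unknown"`; unparseable sex or
#' outcome values are row-level errors (these fields drive the protocols and
#' metrics and cannot be imputed).
#'
#' @param path CSV file path.  Header required; missing values are empty
#'   strings or `NA`.
#' @param dialect named character vector mapping canonical name ->
#'   column name in the file, e.g. `c(age = "AgeYears")`.  Unmapped canonical
#'   columns are looked up by their own name.
#' @return data.frame cohort, validated.
#' @export
read_cohort <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (canon in names(dialect)) {
    ext <- dialect[[canon]]
    if (!ext %in% names(raw)) {
      stop("dialect maps '", canon, "' to missing column '", ext, "'",
           call. = FALSE)
    }
    names(raw)[names(raw) == ext] <- canon
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  n <- nrow(raw)
  parse_num <- function(x, what, integer = TRUE) {
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0L) {
      stop("non-numeric ", what, " in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    miss <- which(is.na(out))
    if (length(miss) > 0L) {
      stop("missing ", what, " in row(s) ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    }
    if (integer) out <- as.integer(round(out))
    out
  }
  parse_logical <- function(x, what) {
    key <- tolower(trimws(x))
    out <- rep(NA, n)
    out[key %in% c("true", "t", "1", "yes", "y")] <- TRUE
    out[key %in% c("false", "f", "0", "no", "n")] <- FALSE
    bad <- which(is.na(out))
    if (length(bad) > 0L) {
      stop("unparseable ", what, " in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    out
  }
  sex <- tolower(trimws(raw$sex))
  sex[sex %in% c("m")] <- "male"
  sex[sex %in% c("f")] <- "female"
  bad_sex <- which(!sex %in% VENT_SEXES)
  if (length(bad_sex) > 0L) {
    stop("unparseable sex in row(s) ",
         paste(utils::head(bad_sex, 5L), collapse = ", "), call. = FALSE)
  }
  race <- tolower(trimws(raw$race_ethnicity))
  race[!race %in% VENT_RACES] <- "unknown"

  cohort <- data.frame(
    encounter_id = as.character(raw$encounter_id),
    age = parse_num(raw$age, "age"),
    sex = sex,
    race_ethnicity = race,
    covid_positive = parse_logical(raw$covid_positive, "covid_positive"),
    sofa = parse_num(raw$sofa, "sofa"),
    elixhauser = parse_num(raw$elixhauser, "elixhauser"),
    charlson_points = parse_num(raw$charlson_points, "charlson_points"),
    survived = parse_logical(raw$survived, "survived"),
    stringsAsFactors = FALSE
  )
  if ("life_expectancy" %in% names(raw)) {
    le <- raw$life_expectancy
    le[le == ""] <- NA
    cohort$life_expectancy <- suppressWarnings(as.numeric(le))
  }
  validate_cohort(cohort)
  cohort
}

#' Apply the study exclusion filters to raw admission records
#'
#' Removes records that cannot enter the simulation, in this fixed reason
#' order (a record matching several reasons is counted once, under the first):
#' \describe{
#'   \item{no_sofa}{no SOFA score recorded at initial intubation
#'     (`sofa` missing).}
#'   \item{no_outcome_data}{no discharge disposition, no ICD-10 codes and no
#'     COVID test data (all three absent).}
#'   \item{ambiguous_intubation}{multiple intubations within the admission
#'     with no way to tie a SOFA score to the initial one.}
#' }
#'
#' @param raw data.frame of admission records.  Recognised auxiliary columns
#'   (all optional): `discharge_disposition` (character; `NA`/`""` = missing),
#'   `has_icd10`, `has_covid_test` (logical), `ambiguous_intubation`
#'   (logical).  Absent auxiliary columns are treated as "data present /
#'   unambiguous", so their reason never fires.
#' @return list with `retained` (records passing all filters, unmodified) and
#'   `report` (named integer vector of per-reason exclusion counts plus
#'   `retained` and `total`).
#' @export
apply_exclusions <- function(raw) {
  stopifnot(is.data.frame(raw))
  n <- nrow(raw)
  col_or <- function(name, default) {
    if (name %in% names(raw)) raw[[name]] else rep(default, n)
  }
  sofa <- if ("sofa" %in% names(raw)) {
    suppressWarnings(as.numeric(ifelse(raw$sofa == "", NA, raw$sofa)))
  } else {
    rep(NA_real_, n)
  }
  disp <- col_or("discharge_disposition", "present")
  disp_missing <- is.na(disp) | trimws(as.character(disp)) == ""
  has_icd10 <- col_or("has_icd10", TRUE)
  has_covid <- col_or("has_covid_test", TRUE)
  ambiguous <- col_or("ambiguous_intubation", FALSE)
  has_icd10[is.na(has_icd10)] <- FALSE
  has_covid[is.na(has_covid)] <- FALSE
  ambiguous[is.na(ambiguous)] <- FALSE

  reason <- rep(NA_character_, n)
  reason[is.na(sofa)] <- "no_sofa"
  r2 <- is.na(reason) & disp_missing & !has_icd10 & !has_covid
  reason[r2] <- "no_outcome_data"
  r3 <- is.na(reason) & ambiguous
  reason[r3] <- "ambiguous_intubation"

  keep <- is.na(reason)
  report <- c(
    no_sofa = sum(reason == "no_sofa", na.rm = TRUE),
    no_outcome_data = sum(reason == "no_outcome_data", na.rm = TRUE),
    ambiguous_intubation = sum(reason == "ambiguous_intubation", na.rm = TRUE),
    retained = sum(keep),
    total = n
  )
  retained <- raw[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, report = report)
}

# ---------------------------------------------------------------------------
# Synthetic cohort generation
# ---------------------------------------------------------------------------

#' Specification for a synthetic encounter cohort
#'
#' The defaults reproduce the marginal structure of the modelling cohort the
#' simulator was developed against: 3707 ventilated adults in a single US
#' hospital system during the first pandemic year.  Concretely:
#' age-band masses and sex/race margins from that cohort's descriptive table;
#' race-conditional age (Black and Hispanic encounters younger: mean 56 and 53
#' years vs 64 for White non-Hispanic), COVID positivity (0.45 / 0.39 / 0.33)
#' and mean SOFA at intubation (3.46 / 3.14 / 3.69); and survival to
#' discharge drawn from a logistic model in SOFA, age and Elixhauser score
#' with odds ratios 0.896, 0.964 and 1.054 per unit.  The logistic intercept
#' is left free and calibrated at generation time so that expected overall
#' survival matches `survival_target` (default 0.72).
#'
#' SOFA is drawn as a negative binomial (dispersion `sofa_size`, clamped to
#' 0--24) whose dispersion was fixed once so the 1--7 / 8--11 / 12--24 band
#' masses are close to the observed 86/10/4\%.  The Elixhauser (van Walraven)
#' summary is a discretised, shifted gamma whose scale is solved so that
#' `P(elixhauser >= 12) = elixhauser_tail` (that threshold defines "severe
#' comorbidity" for the Maryland protocol).  Charlson condition points are a
#' small geometric-like integer.
#'
#' @param n number of encounters.
#' @param seed integer seed; generation is deterministic given the spec.
#' @param age_band_probs probability over the 8 reporting age bands
#'   (18--24, 25--34, ..., 75--84, 85+).
#' @param sex_probs named probabilities for male/female.
#' @param race_probs named probabilities over the race/ethnicity levels.
#' @param covid_rate_by_race named COVID-positivity rate per race level.
#' @param age_normal_by_race named list race -> c(mean, sd); races listed here
#'   draw age from a truncated normal (>= 18, capped at 100) instead of the
#'   band distribution.
#' @param sofa_mean_by_race named mean SOFA per race level.
#' @param sofa_size negative-binomial dispersion for SOFA.
#' @param elixhauser_shape,elixhauser_shift gamma shape and integer downshift
#'   for the Elixhauser distribution.
#' @param elixhauser_tail target `P(elixhauser >= 12)`.
#' @param charlson_prob geometric success probability for Charlson points.
#' @param charlson_max cap on Charlson condition points.
#' @param survival_model list with `intercept` (NA = calibrate) and odds
#'   ratios `or_sofa`, `or_age`, `or_elixhauser`.
#' @param survival_target overall survival the intercept is calibrated to.
#' @param covid_fraction_override optional overall COVID+ fraction in [0,1];
#'   when set, COVID status ignores race and uses this rate (patient-mix
#'   sensitivity analyses).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 2000,
                        seed = 1L,
                        age_band_probs = NULL,
                        sex_probs = NULL,
                        race_probs = NULL,
                        covid_rate_by_race = NULL,
                        age_normal_by_race = NULL,
                        sofa_mean_by_race = NULL,
                        sofa_size = 1.2,
                        elixhauser_shape = 1.2,
                        elixhauser_shift = 2L,
                        elixhauser_tail = 0.1,
                        charlson_prob = 0.6,
                        charlson_max = 8L,
                        survival_model = NULL,
                        survival_target = 0.72,
                        covid_fraction_override = NULL) {
  age_bands <- data.frame(
    lower = c(18, 25, 35, 45, 55, 65, 75, 85),
    upper = c(24, 34, 44, 54, 64, 74, 84, 100)
  )
  if (is.null(age_band_probs)) {
    age_band_probs <- c(104, 235, 247, 456, 868, 980, 629, 188) / 3707
  }
  if (is.null(sex_probs)) {
    sex_probs <- c(male = 2197, female = 1510) / 3707
  }
  if (is.null(race_probs)) {
    race_probs <- c(white_nh = 2752, black_nh = 577, hispanic = 152,
                    aapi_nh = 50, aian_nh = 3, multi_nh = 16,
                    unknown = 157) / 3707
  }
  if (is.null(covid_rate_by_race)) {
    covid_rate_by_race <- c(white_nh = 0.33, black_nh = 0.45,
                            hispanic = 0.39, aapi_nh = 0.34, aian_nh = 0.34,
                            multi_nh = 0.34, unknown = 0.34)
  }
  if (is.null(age_normal_by_race)) {
    age_normal_by_race <- list(black_nh = c(mean = 56, sd = 17),
                               hispanic = c(mean = 53, sd = 18))
  }
  if (is.null(sofa_mean_by_race)) {
    sofa_mean_by_race <- c(white_nh = 3.69, black_nh = 3.46,
                           hispanic = 3.14, aapi_nh = 3.6, aian_nh = 3.6,
                           multi_nh = 3.6, unknown = 3.6)
  }
  if (is.null(survival_model)) {
    survival_model <- list(intercept = NA_real_, or_sofa = 0.896,
                           or_age = 0.964, or_elixhauser = 1.054)
  }
  spec <- structure(list(
    n = as.integer(n), seed = as.integer(seed),
    age_bands = age_bands, age_band_probs = age_band_probs,
    sex_probs = sex_probs, race_probs = race_probs,
    covid_rate_by_race = covid_rate_by_race,
    age_normal_by_race = age_normal_by_race,
    sofa_mean_by_race = sofa_mean_by_race, sofa_size = sofa_size,
    elixhauser_shape = elixhauser_shape,
    elixhauser_shift = as.integer(elixhauser_shift),
    elixhauser_tail = elixhauser_tail,
    charlson_prob = charlson_prob, charlson_max = as.integer(charlson_max),
    survival_model = survival_model, survival_target = survival_target,
    covid_fraction_override = covid_fraction_override
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.na(spec$n) || spec$n < 0) stop("n must be >= 0", call. = FALSE)
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  check_probs(spec$age_band_probs, "age_band_probs")
  check_probs(spec$sex_probs, "sex_probs")
  check_probs(spec$race_probs, "race_probs")
  if (length(spec$age_band_probs) != nrow(spec$age_bands)) {
    stop("age_band_probs must have one entry per age band", call. = FALSE)
  }
  stopifnot(all(names(spec$race_probs) %in% VENT_RACES),
            all(names(spec$covid_rate_by_race) %in% VENT_RACES))
  rates <- spec$covid_rate_by_race
  if (any(rates < 0 | rates > 1)) {
    stop("covid_rate_by_race entries must lie in [0,1]", call. = FALSE)
  }
  if (!is.null(spec$covid_fraction_override)) {
    f <- spec$covid_fraction_override
    if (!is.numeric(f) || f < 0 || f > 1) {
      stop("covid_fraction_override must lie in [0,1]", call. = FALSE)
    }
  }
  m <- spec$survival_model
  if (!all(c("intercept", "or_sofa", "or_age", "or_elixhauser") %in% names(m))) {
    stop("survival_model must name intercept, or_sofa, or_age, or_elixhauser",
         call. = FALSE)
  }
  if (any(unlist(m[c("or_sofa", "or_age", "or_elixhauser")]) <= 0)) {
    stop("survival_model odds ratios must be positive", call. = FALSE)
  }
  if (spec$survival_target <= 0 || spec$survival_target >= 1) {
    stop("survival_target must lie in (0,1)", call. = FALSE)
  }
  invisible(spec)
}

# Gamma scale such that P(round(Gamma(shape, scale)) - shift >= 12) = tail.
elixhauser_scale <- function(shape, shift, tail) {
  cut <- 12 + shift - 0.5
  uniroot(function(s) pgamma(cut, shape = shape, scale = s,
                             lower.tail = FALSE) - tail,
          interval = c(1e-3, 1e3), tol = 1e-10)$root
}

#' Generate a synthetic encounter cohort
#'
#' Samples encounters from a [cohort_spec()]: race, then age (band-uniform,
#' or truncated normal for races with stated age shifts), sex, race-conditional
#' COVID status, race-conditional SOFA, Elixhauser and Charlson scores, and
#' finally survival to discharge from the logistic model.  When the model
#' intercept is `NA` it is calibrated by one-dimensional root finding on the
#' sampled covariates so the cohort's expected survival equals
#' `spec$survival_target`.
#'
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame cohort with the canonical columns plus
#'   `life_expectancy` initialised to `NA` (fill with [annotate_cohort()]).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n
  empty <- data.frame(
    encounter_id = character(0), age = integer(0), sex = character(0),
    race_ethnicity = character(0), covid_positive = logical(0),
    sofa = integer(0), elixhauser = integer(0), charlson_points = integer(0),
    survived = logical(0), life_expectancy = numeric(0),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)

  with_rng(spec$seed, {
    race <- sample(names(spec$race_probs), n, replace = TRUE,
                   prob = spec$race_probs)
    sex <- sample(names(spec$sex_probs), n, replace = TRUE,
                  prob = spec$sex_probs)

    # Age: band-uniform by default, truncated normal for races with a
    # stated age shift.
    band <- sample.int(nrow(spec$age_bands), n, replace = TRUE,
                       prob = spec$age_band_probs)
    lo <- spec$age_bands$lower[band]
    hi <- spec$age_bands$upper[band]
    age <- lo + floor(runif(n) * (hi - lo + 1))
    for (r in names(spec$age_normal_by_race)) {
      idx <- which(race == r)
      if (length(idx) == 0L) next
      pars <- spec$age_normal_by_race[[r]]
      draw <- round(rnorm(length(idx), pars[["mean"]], pars[["sd"]]))
      # redraw below the adult floor rather than piling mass at 18
      bad <- which(draw < 18 | draw > 100)
      while (length(bad) > 0L) {
        draw[bad] <- round(rnorm(length(bad), pars[["mean"]], pars[["sd"]]))
        bad <- bad[draw[bad] < 18 | draw[bad] > 100]
      }
      age[idx] <- draw
    }

    covid_rate <- if (!is.null(spec$covid_fraction_override)) {
      rep(spec$covid_fraction_override, n)
    } else {
      unname(spec$covid_rate_by_race[race])
    }
    covid <- runif(n) < covid_rate

    sofa_mu <- unname(spec$sofa_mean_by_race[race])
    sofa <- rnbinom(n, size = spec$sofa_size, mu = sofa_mu)
    sofa <- pmin(sofa, 24L)

    scale <- elixhauser_scale(spec$elixhauser_shape, spec$elixhauser_shift,
                              spec$elixhauser_tail)
    elix <- as.integer(round(rgamma(n, shape = spec$elixhauser_shape,
                                    scale = scale))) - spec$elixhauser_shift
    charlson <- pmin(rgeom(n, spec$charlson_prob), spec$charlson_max)

    m <- spec$survival_model
    lp <- log(m$or_sofa) * sofa + log(m$or_age) * age +
      log(m$or_elixhauser) * elix
    intercept <- m$intercept
    if (is.na(intercept)) {
      intercept <- calibrate_intercept(lp, spec$survival_target)
    }
    survived <- runif(n) < plogis(intercept + lp)

    data.frame(
      encounter_id = sprintf("synth-%06d", seq_len(n)),
      age = as.integer(age), sex = sex, race_ethnicity = race,
      covid_positive = covid, sofa = as.integer(sofa),
      elixhauser = elix, charlson_points = as.integer(charlson),
      survived = survived, life_expectancy = NA_real_,
      stringsAsFactors = FALSE
    )
  })
}

# Solve for b0 with mean(plogis(b0 + lp)) = target.
calibrate_intercept <- function(lp, target) {
  f <- function(b0) mean(plogis(b0 + lp)) - target
  uniroot(f, interval = c(-50, 50), tol = 1e-10)$root
}

#' Write a cohort to CSV in the canonical dialect
#'
#' @param cohort validated cohort data.frame.
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
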