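# Comorbidity-adjusted remaining life expectancy.
#
# Raw remaining life expectancy is looked up in a period life table by
# (age, sex, race).  Comorbidity burden then *shifts the lookup age* (the
# effective-age method): encounters are banded into none / low_medium / high
# comorbidity, each band adds a fixed number of years to the age at which the
# table is re-entered.  Encounters younger than 65 receive the 65-year-old's
# adjustment (offsets here do not otherwise vary with age, so this holds by
# construction).

LE_BANDS <- c("none", "low_medium", "high")

#' Comorbidity adjustment configuration
#'
#' Thresholds band a comorbidity weight (by default the Elixhauser / van
#' Walraven summary already on the encounter) into none / low_medium / high;
#' each band maps to a non-negative age offset in years added to the
#' chronological age before the life-table lookup.  The default offsets
#' (0 / 3 / 7 years) are placeholders chosen to be of realistic magnitude --
#' the claims-based adjustments they stand in for are not published in a
#' reusable form -- and should be overridden when calibrated values are
#' available.
#'
#' @param none_max weights <= this are band "none".
#' @param high_min weights >= this are band "high" (default 12, matching the
#'   severe-comorbidity threshold used by the Maryland protocol).
#' @param offsets named numeric: years added per band.
#' @return object of class `comorbidity_adjustment`.
#' @export
comorbidity_adjustment <- function(none_max = 0, high_min = 12,
                                   offsets = c(none = 0, low_medium = 3,
                                               high = 7)) {
  stopifnot(none_max < high_min, all(LE_BANDS %in% names(offsets)))
  offsets <- offsets[LE_BANDS]
  if (offsets[["none"]] != 0) {
    stop("offset for band 'none' must be 0", call. = FALSE)
  }
  if (is.unsorted(offsets)) {
    stop("offsets must be non-decreasing across none/low_medium/high",
         call. = FALSE)
  }
  structure(list(none_max = none_max, high_min = high_min, offsets = offsets),
            class = "comorbidity_adjustment")
}

#' Band a comorbidity weight
#'
#' @param weight integer comorbidity weight(s) (may be negative).
#' @param adj a [comorbidity_adjustment()].
#' @return character band: "none", "low_medium" or "high".
#' @export
comorbidity_band <- function(weight, adj = comorbidity_adjustment()) {
  ifelse(weight <= adj$none_max, "none",
         ifelse(weight >= adj$high_min, "high", "low_medium"))
}

#' Read a life table from CSV
#'
#' Columns: `age` (integer years), `sex` (`male`/`female`/`all`), `race`
#' (race levels or `all`), `ex` (remaining life expectancy in years).
#' Strata absent from the table fall back to the `all` stratum at lookup
#' time.  `ex` should be non-increasing in age within each stratum; a
#' violation beyond age 18 is reported as a warning, not an error.
#'
#' @param path CSV file path.
#' @return data.frame of class `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path, call. = FALSE)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_life_table(lt)
}

#' Validate a life-table data.frame
#'
#' @param lt data.frame with columns age, sex, race, ex.
#' @return the table with class `life_table`.
#' @export
as_life_table <- function(lt) {
  need <- c("age", "sex", "race", "ex")
  if (!all(need %in% names(lt))) {
    stop("life table needs columns age, sex, race, ex", call. = FALSE)
  }
  if (any(lt$ex < 0)) stop("life expectancy ex must be >= 0", call. = FALSE)
  for (s in unique(lt$sex)) {
    for (r in unique(lt$race)) {
      rows <- lt[lt$sex == s & lt$race == r & lt$age >= 18, ]
      rows <- rows[order(rows$age), ]
      if (nrow(rows) > 1L && is.unsorted(-rows$ex)) {
        warning("life expectancy not non-increasing in age for stratum (",
                s, ", ", r, ")", call. = FALSE)
      }
    }
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Bundled synthetic life table
#'
#' A self-contained, monotone life table covering ages 18--110 for both
#' sexes and every race level (plus an `all` stratum).  It is SYNTHETIC:
#' remaining life expectancy follows a smooth schedule anchored at
#' plausible US magnitudes (about 62 years remaining at 18, 19 at 65, 6.5 at
#' 85), with multiplicative sex and race scalings.  It is NOT a national
#' vital-statistics table and carries no such authority; use
#' [read_life_table()] to supply a real one.
#'
#' @return a `life_table` data.frame.
#' @export
synthetic_life_table <- function() {
  ages <- 18:110
  # monotone interpolation through plausible anchors, flat floor at old age
  anchor_age <- c(18, 30, 40, 50, 65, 75, 85, 95, 110)
  anchor_ex <- c(62.0, 50.5, 41.2, 32.3, 19.2, 12.3, 6.5, 3.3, 1.5)
  base <- approx(anchor_age, anchor_ex, xout = ages, method = "linear")$y
  sex_mult <- c(male = 0.94, female = 1.06, all = 1.0)
  race_mult <- c(white_nh = 1.00, black_nh = 0.95, hispanic = 1.04,
                 aapi_nh = 1.09, aian_nh = 0.92, multi_nh = 1.00,
                 unknown = 1.00, all = 1.00)
  grid <- expand.grid(age = ages, sex = names(sex_mult),
                      race = names(race_mult), stringsAsFactors = FALSE)
  grid$ex <- round(base[grid$age - 17L] * sex_mult[grid$sex] *
                     race_mult[grid$race], 2)
  as_life_table(grid)
}

#' Look up remaining life expectancy
#'
#' Vectorised lookup by (age, sex, race); ages beyond the table maximum are
#' clamped to the oldest available age in the stratum, and races (or sexes)
#' absent from the table fall back to the `all` stratum if present.
#'
#' @param age integer ages.
#' @param sex,race character vectors, recycled to the length of `age`.
#' @param lt a `life_table`.
#' @return numeric years remaining.
#' @export
lookup_life_expectancy <- function(age, sex, race, lt) {
  n <- length(age)
  sex <- rep_len(sex, n)
  race <- rep_len(race, n)
  race_avail <- unique(lt$race)
  sex_avail <- unique(lt$sex)
  race_use <- ifelse(race %in% race_avail, race, "all")
  sex_use <- ifelse(sex %in% sex_avail, sex, "all")
  key <- paste(sex_use, race_use, sep = "\r")
  table_key <- paste(lt$sex, lt$race, sep = "\r")
  out <- numeric(n)
  for (k in unique(key)) {
    idx <- which(key == k)
    rows <- lt[table_key == k, ]
    if (nrow(rows) == 0L) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      stop("life table has no stratum for (age=", age[idx[1L]],
           ", sex=", parts[1L], ", race=", parts[2L], ")", call. = FALSE)
    }
    rows <- rows[order(rows$age), ]
    a <- pmin(pmax(age[idx], min(rows$age)), max(rows$age))
    pos <- match(a, rows$age)
    if (anyNA(pos)) {
      stop("life table stratum (", gsub("\r", ", ", k),
           ") does not cover age ", a[which(is.na(pos))[1L]], call. = FALSE)
    }
    out[idx] <- rows$ex[pos]
  }
  out
}

#' Comorbidity-adjusted remaining life expectancy
#'
#' Effective-age method: look up `ex` at chronological age plus the age
#' offset of the encounter's comorbidity band.  Offsets do not vary with age,
#' so the rule that under-65s receive the 65-year-old's adjustment is
#' satisfied automatically.  Lookup ages past the table maximum clamp to the
#' oldest age.
#'
#' @param age,sex,race encounter demographics (vectors).
#' @param weight comorbidity weight (default source: Elixhauser summary).
#' @param lt a `life_table`.
#' @param adj a [comorbidity_adjustment()].
#' @return numeric adjusted years remaining.
#' @export
adjusted_life_expectancy <- function(age, sex, race, weight, lt,
                                     adj = comorbidity_adjustment()) {
  band <- comorbidity_band(weight, adj)
  eff_age <- age + unname(adj$offsets[band])
  lookup_life_expectancy(eff_age, sex, race, lt)
}

#' Fill the life_expectancy column of a cohort
#'
#' Every encounter gets a comorbidity-adjusted remaining life expectancy,
#' survivors and non-survivors alike (downstream life-years metrics only
#' count it for encounters that are allocated a bed and survive).
#'
#' @param cohort validated cohort data.frame.
#' @param lt a `life_table` (default: the bundled synthetic table).
#' @param adj a [comorbidity_adjustment()].
#' @return the cohort with `life_expectancy` filled.
#' @export
annotate_cohort <- function(cohort, lt = synthetic_life_table(),
                            adj = comorbidity_adjustment()) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0L) {
    cohort$life_expectancy <- numeric(0)
    return(cohort)
  }
  cohort$life_expectancy <- adjusted_life_expectancy(
    cohort$age, cohort$sex, cohort$race_ethnicity, cohort$elixhauser, lt, adj
  )
  cohort
}
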