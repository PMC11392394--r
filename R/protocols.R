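# Triage protocols: each maps an encounter to an ordinal priority band
# (lower band = higher priority).  Ties within a band are broken by lottery:
# a fresh uniform tiebreak per decision, compared lexicographically after the
# band.  All scoring is deterministic given the encounter; randomness lives
# only in the tiebreak.

PROTOCOLS <- c("lottery", "age", "pure_sofa", "new_york_15", "maryland_21",
               "colorado_20")

#' Default age bands for the age-based protocol
#'
#' Eight roughly 10-year reporting bands: 18--24, 25--34, ..., 75--84, 85+.
#' @return data.frame with `lower` and `upper` (inclusive) columns.
#' @export
default_age_bands <- function() {
  data.frame(lower = c(18, 25, 35, 45, 55, 65, 75, 85),
             upper = c(24, 34, 44, 54, 64, 74, 84, Inf))
}

#' Priority band under the age-based protocol
#'
#' Priority by age band, youngest first: band 0 is the youngest decade.
#' Monotone non-decreasing in age.
#'
#' @param age integer vector of ages (>= 18).
#' @param bands age-band table as from [default_age_bands()].
#' @return integer band, 0-based.
#' @export
score_age <- function(age, bands = default_age_bands()) {
  if (any(age < 18)) stop("age must be >= 18", call. = FALSE)
  findInterval(age, bands$lower) - 1L
}

#' Priority band under the pure-SOFA protocol
#'
#' Band equals the SOFA score itself (lower SOFA = higher priority), giving
#' the finest clinically-driven banding of the six protocols.
#'
#' @param sofa integer vector, 0--24.
#' @return integer band.
#' @export
score_pure_sofa <- function(sofa) {
  check_sofa(sofa)
  as.integer(sofa)
}

#' Priority tier under the New York 2015 protocol
#'
#' SOFA <= 7 is Tier 1, SOFA 8--11 Tier 2, SOFA >= 12 Tier 3.
#'
#' @param sofa integer vector, 0--24.
#' @return integer tier in 1..3.
#' @export
score_new_york <- function(sofa) {
  check_sofa(sofa)
  ifelse(sofa <= 7, 1L, ifelse(sofa <= 11, 2L, 3L))
}

#' Priority points under the Maryland 2021 protocol
#'
#' SOFA points (<=8 -> 1, 9--11 -> 2, 12--14 -> 3, >14 -> 4) plus 3 points
#' for severe comorbidity, operationalised as an Elixhauser (van Walraven)
#' summary score >= 12 (the weight of metastatic cancer, used as the
#' "death likely within 1 year" proxy).  Range 1--7.
#'
#' @param sofa integer vector, 0--24.
#' @param elixhauser integer vector (may be negative).
#' @param severe_threshold Elixhauser cutoff for the +3 bonus.
#' @return integer points.
#' @export
score_maryland <- function(sofa, elixhauser, severe_threshold = 12) {
  check_sofa(sofa)
  if (anyNA(elixhauser)) stop("elixhauser must be non-missing", call. = FALSE)
  pts <- ifelse(sofa <= 8, 1L, ifelse(sofa <= 11, 2L,
                ifelse(sofa <= 14, 3L, 4L)))
  pts + ifelse(elixhauser >= severe_threshold, 3L, 0L)
}

#' Default Colorado 2020 scoring table
#'
#' SOFA points (<=5 -> 1, 6--9 -> 2, 10--12 -> 3, >12 -> 4) and modified
#' age-adjusted Charlson points by age band.  The age points default to the
#' conventional age-adjusted Charlson increments (0 below 50, then +1 per
#' decade, capped at 3 from 70 up); the published supplement table was not
#' available, so these defaults are an assumption and the whole table is
#' overridable (see [read_colorado_table()]).
#'
#' @return list with `sofa_upper` / `sofa_points` (band upper bounds,
#'   inclusive, covering 0--24) and `age_lower` / `age_points`.
#' @export
default_colorado_table <- function() {
  list(sofa_upper = c(5, 9, 12, 24),
       sofa_points = c(1L, 2L, 3L, 4L),
       age_lower = c(18, 50, 60, 70),
       age_points = c(0L, 1L, 2L, 3L))
}

#' Read a Colorado scoring table from CSV
#'
#' Expects rows with columns `kind` (`"sofa"` or `"age"`), `bound` (the
#' inclusive SOFA upper bound, or the age lower bound) and `points`.
#'
#' @param path CSV file path.
#' @return scoring table as in [default_colorado_table()].
#' @export
read_colorado_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "bound", "points")
  if (!all(need %in% names(tab))) {
    stop("Colorado table needs columns kind, bound, points", call. = FALSE)
  }
  sofa <- tab[tab$kind == "sofa", ]
  age <- tab[tab$kind == "age", ]
  sofa <- sofa[order(sofa$bound), ]
  age <- age[order(age$bound), ]
  out <- list(sofa_upper = sofa$bound, sofa_points = as.integer(sofa$points),
              age_lower = age$bound, age_points = as.integer(age$points))
  check_colorado_table(out)
  out
}

check_colorado_table <- function(table) {
  if (is.unsorted(table$sofa_upper, strictly = TRUE) ||
      utils::tail(table$sofa_upper, 1L) < 24) {
    stop("Colorado SOFA bands must be strictly increasing and cover 0..24",
         call. = FALSE)
  }
  if (length(table$sofa_upper) != length(table$sofa_points) ||
      length(table$age_lower) != length(table$age_points)) {
    stop("Colorado table bounds and points must align", call. = FALSE)
  }
  invisible(table)
}

#' Priority points under the Colorado 2020 protocol
#'
#' SOFA band points plus age points plus pre-computed Charlson condition
#' points (the age contribution of the modified Charlson index comes from the
#' table, so `charlson_points` must exclude it).
#'
#' @param sofa integer vector, 0--24.
#' @param charlson_points non-negative integer condition points.
#' @param age integer ages (>= 18).
#' @param table scoring table, see [default_colorado_table()].
#' @return integer points.
#' @export
score_colorado <- function(sofa, charlson_points, age,
                           table = default_colorado_table()) {
  check_sofa(sofa)
  check_colorado_table(table)
  if (anyNA(charlson_points) || any(charlson_points < 0)) {
    stop("charlson_points must be non-missing and >= 0", call. = FALSE)
  }
  if (any(age < table$age_lower[1L])) {
    stop("age below Colorado table coverage (", table$age_lower[1L], ")",
         call. = FALSE)
  }
  sofa_pts <- table$sofa_points[findInterval(sofa, c(-Inf, table$sofa_upper),
                                             left.open = TRUE)]
  age_pts <- table$age_points[findInterval(age, table$age_lower)]
  as.integer(sofa_pts + age_pts + charlson_points)
}

check_sofa <- function(sofa) {
  if (anyNA(sofa) || any(sofa < 0 | sofa > 24)) {
    stop("sofa must be non-missing and lie in 0..24", call. = FALSE)
  }
  invisible(sofa)
}

#' Priority bands for a whole cohort under a protocol
#'
#' Vectorised scoring: returns the deterministic band for each encounter.
#' Lottery assigns the constant band 0 (ordering is by tiebreak alone).
#'
#' @param cohort validated cohort data.frame.
#' @param protocol one of `"lottery"`, `"age"`, `"pure_sofa"`,
#'   `"new_york_15"`, `"maryland_21"`, `"colorado_20"`.
#' @param colorado_table Colorado scoring table.
#' @param age_bands age bands for the age protocol.
#' @return integer vector of bands, lower = higher priority.
#' @export
protocol_bands <- function(cohort, protocol,
                           colorado_table = default_colorado_table(),
                           age_bands = default_age_bands()) {
  protocol <- match.arg(protocol, PROTOCOLS)
  switch(protocol,
    lottery = rep(0L, nrow(cohort)),
    age = score_age(cohort$age, age_bands),
    pure_sofa = score_pure_sofa(cohort$sofa),
    new_york_15 = score_new_york(cohort$sofa),
    maryland_21 = score_maryland(cohort$sofa, cohort$elixhauser),
    colorado_20 = score_colorado(cohort$sofa, cohort$charlson_points,
                                 cohort$age, colorado_table)
  )
}

#' Rank a pair of encounters under a protocol
#'
#' Returns the index (1 or 2) of the higher-priority encounter: the one with
#' the lexicographically smaller (band, tiebreak).  Tiebreak draws are fresh
#' uniforms from the current RNG on every call, so repeated calls on a tied
#' pair are independent lotteries.
#'
#' @param a,b single-row encounter data.frames (or a 2-row cohort via
#'   `rank_pair(cohort[1, ], cohort[2, ], ...)`).
#' @param protocol protocol name.
#' @param colorado_table,age_bands scoring tables.
#' @return 1L if `a` wins the bed, 2L if `b` does.
#' @export
rank_pair <- function(a, b, protocol,
                      colorado_table = default_colorado_table(),
                      age_bands = default_age_bands()) {
  pair <- rbind(a, b)
  bands <- protocol_bands(pair, protocol, colorado_table, age_bands)
  tie <- runif(2)
  if (bands[1L] < bands[2L] ||
      (bands[1L] == bands[2L] && tie[1L] < tie[2L])) 1L else 2L
}
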