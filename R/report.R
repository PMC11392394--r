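# Tidy metric tables over one or more simulation runs, mirroring the shape
# of the headline outputs: survival/allocation by race, lives saved,
# life-years saved, and the capacity sweep.

RACE_REPORT_GROUPS <- c(black_nh = "black_nh", hispanic = "hispanic",
                        white_nh = "white_nh")

result_list_flat <- function(results) {
  # Accepts protocol -> vent_result, or protocol -> (capacity -> vent_result);
  # returns a flat list of vent_result objects.
  flat <- list()
  for (p in names(results)) {
    el <- results[[p]]
    if (inherits(el, "vent_result")) {
      flat[[length(flat) + 1L]] <- el
    } else {
      for (r in el) flat[[length(flat) + 1L]] <- r
    }
  }
  flat
}

#' Build tidy metric tables from simulation results
#'
#' Produces four tidy data.frames across protocols and capacities:
#' \describe{
#'   \item{survival_allocation}{overall survival, allocation rate and
#'     age-adjusted survival, overall and for the Black non-Hispanic,
#'     Hispanic and White non-Hispanic subgroups (percent).}
#'   \item{lives_saved}{lives saved per 1000 patients, overall and by the
#'     same subgroups.}
#'   \item{life_years_saved}{life-years saved per 1000 patients, likewise.}
#'   \item{capacity_sweep}{one row per protocol and capacity with overall
#'     survival, allocation, lives saved and life-years saved.}
#' }
#' All CIs are 95\% Monte Carlo intervals over replicates.  When
#' `output_dir` is given the tables are also written as CSV
#' (`table2_survival_allocation.csv`, `table3_lives_saved.csv`,
#' `table4_life_years_saved.csv`, `capacity_sweep.csv`).
#'
#' @param results named list: protocol -> `vent_result`, or protocol ->
#'   named list of `vent_result` per capacity (as from [capacity_sweep()]).
#' @param cohort the annotated cohort the results were computed on.
#' @param output_dir optional directory for CSV output.
#' @param age_bands age-band table used for age adjustment.
#' @return invisible list of the four data.frames.
#' @export
build_report <- function(results, cohort, output_dir = NULL,
                         age_bands = default_age_bands()) {
  validate_cohort(cohort)
  flat <- result_list_flat(results)
  if (length(flat) == 0L) stop("no simulation results supplied", call. = FALSE)
  standard <- standard_age_distribution(cohort, age_bands)
  groups <- c(list(overall = NULL),
              lapply(RACE_REPORT_GROUPS,
                     function(r) cohort$race_ethnicity == r))

  fmt_row <- function(res) {
    base <- data.frame(protocol = res$protocol, capacity = res$capacity,
                       replicates = res$replicates)
    rows <- lapply(names(groups), function(g) {
      sub <- groups[[g]]
      bl <- baseline_rates(cohort, sub)
      sr <- survival_rate(res, sub)
      ar <- allocation_rate(res, sub)
      aa <- suppressWarnings(
        age_adjusted_survival(res, sub, standard, age_bands))
      ls <- lives_saved(res, sub, baseline = bl)
      lys <- life_years_saved(res, sub, baseline = bl)
      cbind(base, data.frame(
        subgroup = g, n = bl$n,
        survival_pct = 100 * sr$mean,
        survival_lo = 100 * sr$ci_lower, survival_hi = 100 * sr$ci_upper,
        allocation_pct = 100 * ar$mean,
        allocation_lo = 100 * ar$ci_lower, allocation_hi = 100 * ar$ci_upper,
        age_adj_survival_pct = 100 * aa$mean,
        age_adj_survival_lo = 100 * aa$ci_lower,
        age_adj_survival_hi = 100 * aa$ci_upper,
        lives_saved_per_1000 = ls$per_1000,
        lives_saved_lo = ls$per_1000_ci[1L],
        lives_saved_hi = ls$per_1000_ci[2L],
        life_years_saved_per_1000 = lys$per_1000,
        life_years_saved_lo = lys$per_1000_ci[1L],
        life_years_saved_hi = lys$per_1000_ci[2L]
      ))
    })
    do.call(rbind, rows)
  }
  long <- do.call(rbind, lapply(flat, fmt_row))

  pick <- function(cols) long[, c("protocol", "capacity", "replicates",
                                  "subgroup", "n", cols)]
  tables <- list(
    survival_allocation = pick(c("survival_pct", "survival_lo", "survival_hi",
                                 "allocation_pct", "allocation_lo",
                                 "allocation_hi", "age_adj_survival_pct",
                                 "age_adj_survival_lo",
                                 "age_adj_survival_hi")),
    lives_saved = pick(c("lives_saved_per_1000", "lives_saved_lo",
                         "lives_saved_hi")),
    life_years_saved = pick(c("life_years_saved_per_1000",
                              "life_years_saved_lo", "life_years_saved_hi")),
    capacity_sweep = long[long$subgroup == "overall",
                          c("protocol", "capacity", "replicates",
                            "survival_pct", "survival_lo", "survival_hi",
                            "lives_saved_per_1000", "lives_saved_lo",
                            "lives_saved_hi", "life_years_saved_per_1000",
                            "life_years_saved_lo", "life_years_saved_hi")]
  )
  tables <- lapply(tables, function(d) { rownames(d) <- NULL; d })

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(survival_allocation = "table2_survival_allocation.csv",
               lives_saved = "table3_lives_saved.csv",
               life_years_saved = "table4_life_years_saved.csv",
               capacity_sweep = "capacity_sweep.csv")
    for (k in names(files)) {
      utils::write.csv(tables[[k]], file.path(output_dir, files[[k]]),
                       row.names = FALSE)
    }
  }
  invisible(tables)
}
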