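# Outcome metrics over Monte Carlo allocation results.
#
# Replicate-level quantities (survival rate, allocation rate, life-years per
# patient, lives saved, life-years saved) are summarised as
# mean +/- 1.96 * SE over replicates -- these CIs describe Monte Carlo error,
# matching how the simulation's headline tables are reported.  Directly
# age-standardized rates instead use gamma confidence intervals (Fay-Feuer,
# with the Tiwari modification as default), the standard method for
# standardized rates from registry statistics.

# subgroup: NULL (overall), a logical vector over encounters, or an integer
# index vector.
subgroup_index <- function(result_or_cohort, subgroup) {
  n <- if (inherits(result_or_cohort, "vent_result")) {
    ncol(result_or_cohort$alloc)
  } else {
    nrow(result_or_cohort)
  }
  if (is.null(subgroup)) return(seq_len(n))
  if (is.logical(subgroup)) {
    stopifnot(length(subgroup) == n)
    return(which(subgroup))
  }
  as.integer(subgroup)
}

replicate_summary <- function(x, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  m <- mean(x)
  se <- if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  list(per_replicate = x, mean = m, se = se,
       ci_lower = if (is.na(se)) NA_real_ else m - z * se,
       ci_upper = if (is.na(se)) NA_real_ else m + z * se)
}

undefined_rate <- function() {
  list(per_replicate = numeric(0), mean = NA_real_, se = NA_real_,
       ci_lower = NA_real_, ci_upper = NA_real_, n = 0L, undefined = TRUE)
}

#' Simulated survival rate
#'
#' Fraction of the subgroup surviving to discharge per replicate:
#' allocated encounters keep their scarcity-free outcome, unallocated
#' encounters are counted as deaths.
#'
#' @param result a `vent_result` from [run_simulation()].
#' @param subgroup NULL (overall), logical mask, or index vector over
#'   encounters.
#' @param conf confidence level for the Monte Carlo CI.
#' @return list with `per_replicate`, `mean`, `se`, `ci_lower`, `ci_upper`,
#'   `n` (subgroup size); an undefined-rate marker (`undefined = TRUE`,
#'   `NA` values) for an empty subgroup.
#' @export
survival_rate <- function(result, subgroup = NULL, conf = 0.95) {
  stopifnot(inherits(result, "vent_result"))
  cols <- subgroup_index(result, subgroup)
  if (length(cols) == 0L) return(undefined_rate())
  surv_cols <- cols[result$cohort$survived[cols]]
  counts <- if (length(surv_cols) == 0L) {
    rep(0, nrow(result$alloc))
  } else {
    rowSums(result$alloc[, surv_cols, drop = FALSE])
  }
  out <- replicate_summary(counts / length(cols), conf)
  out$n <- length(cols)
  out
}

#' Simulated allocation rate
#'
#' Fraction of the subgroup allocated a bed, per replicate.
#'
#' @inheritParams survival_rate
#' @return as [survival_rate()].
#' @export
allocation_rate <- function(result, subgroup = NULL, conf = 0.95) {
  stopifnot(inherits(result, "vent_result"))
  cols <- subgroup_index(result, subgroup)
  if (length(cols) == 0L) return(undefined_rate())
  out <- replicate_summary(
    rowSums(result$alloc[, cols, drop = FALSE]) / length(cols), conf)
  out$n <- length(cols)
  out
}

# Mean realized life-years per patient, per replicate: life_expectancy for
# allocated survivors, 0 otherwise.
life_years_per_patient <- function(result, cols) {
  le <- result$cohort$life_expectancy[cols]
  if (anyNA(le)) {
    bad <- cols[which(is.na(le))[1L]]
    stop("missing life_expectancy for encounter ",
         result$cohort$encounter_id[bad],
         "; run annotate_cohort() first", call. = FALSE)
  }
  yrs <- le * result$cohort$survived[cols]
  as.numeric(result$alloc[, cols, drop = FALSE] %*% yrs) / length(cols)
}

#' Baseline (no-scarcity) survival rate and life-years per patient
#'
#' `S_B` is the scarcity-free survival fraction; `LY_B` the scarcity-free
#' expected post-discharge life-years per patient (non-survivors contribute
#' zero years).
#'
#' @param cohort validated, annotated cohort.
#' @param subgroup NULL, logical mask, or index vector.
#' @return list with `s_b`, `ly_b`, and subgroup size `n`.
#' @export
baseline_rates <- function(cohort, subgroup = NULL) {
  idx <- subgroup_index(cohort, subgroup)
  if (length(idx) == 0L) {
    return(list(s_b = NA_real_, ly_b = NA_real_, n = 0L))
  }
  le <- cohort$life_expectancy[idx]
  ly_b <- if (anyNA(le)) NA_real_ else mean(le * cohort$survived[idx])
  list(s_b = mean(cohort$survived[idx]), ly_b = ly_b, n = length(idx))
}

#' Lives saved per patient (and per 1000)
#'
#' `LS = S_sim - S_B * c` per replicate: the protocol's survival advantage
#' over proportional (expected) survival at capacity `c`.  Zero in
#' expectation for the lottery at any capacity.
#'
#' @inheritParams survival_rate
#' @param baseline optional precomputed [baseline_rates()] for the subgroup
#'   (computed from the result's cohort when omitted).
#' @return list with per-patient summary fields and `per_1000` /
#'   `per_1000_ci` scalings, plus `s_b` and `capacity`.
#' @export
lives_saved <- function(result, subgroup = NULL, baseline = NULL,
                        conf = 0.95) {
  rate <- survival_rate(result, subgroup, conf)
  if (isTRUE(rate$undefined)) return(rate)
  if (is.null(baseline)) baseline <- baseline_rates(result$cohort, subgroup)
  ls <- rate$per_replicate - baseline$s_b * result$capacity
  out <- replicate_summary(ls, conf)
  out$n <- rate$n
  out$s_b <- baseline$s_b
  out$capacity <- result$capacity
  out$per_1000 <- out$mean * 1000
  out$per_1000_ci <- c(out$ci_lower, out$ci_upper) * 1000
  out
}

#' Life-years saved per patient (and per 1000)
#'
#' `LYS = LY_sim - LY_B * c` per replicate, where `LY_sim` is the mean
#' realized post-discharge life-years per patient (life expectancy counted
#' only for allocated survivors).
#'
#' @inheritParams lives_saved
#' @return as [lives_saved()], with `ly_b` in place of `s_b`.
#' @export
life_years_saved <- function(result, subgroup = NULL, baseline = NULL,
                             conf = 0.95) {
  stopifnot(inherits(result, "vent_result"))
  cols <- subgroup_index(result, subgroup)
  if (length(cols) == 0L) return(undefined_rate())
  ly_sim <- life_years_per_patient(result, cols)  # errors name the encounter
  if (is.null(baseline)) baseline <- baseline_rates(result$cohort, subgroup)
  if (is.na(baseline$ly_b)) {
    stop("cohort lacks life_expectancy; run annotate_cohort() first",
         call. = FALSE)
  }
  lys <- ly_sim - baseline$ly_b * result$capacity
  out <- replicate_summary(lys, conf)
  out$n <- length(cols)
  out$ly_b <- baseline$ly_b
  out$capacity <- result$capacity
  out$per_1000 <- out$mean * 1000
  out$per_1000_ci <- c(out$ci_lower, out$ci_upper) * 1000
  out
}

# ---------------------------------------------------------------------------
# Direct age standardization with gamma confidence intervals
# ---------------------------------------------------------------------------

#' Directly standardized rate with gamma confidence interval
#'
#' Computes the directly standardized rate `sum(w_i * d_i / n_i)` and a
#' gamma-based confidence interval.  `method = "fay_feuer"` uses the maximum
#' standardizing ratio `max(w_i / n_i)` in the upper bound; the default
#' `"tiwari"` modification replaces it with the mean ratio, giving slightly
#' narrower but still conservative intervals.  Strata with a zero
#' denominator are dropped with a warning and the weights renormalized.
#'
#' @param events numeric vector of event counts per stratum.
#' @param totals numeric vector of denominators per stratum.
#' @param weights standard-population weights per stratum (normalized to sum
#'   to 1 internally).
#' @param conf confidence level.
#' @param method `"tiwari"` (default) or `"fay_feuer"`.
#' @param clamp_upper cap for the upper bound (1 for proportions; `Inf` to
#'   disable).
#' @return list with `rate`, `ci_lower`, `ci_upper`, `variance`.
#' @export
age_adjusted_rate <- function(events, totals, weights, conf = 0.95,
                              method = c("tiwari", "fay_feuer"),
                              clamp_upper = 1) {
  method <- match.arg(method)
  stopifnot(length(events) == length(totals),
            length(weights) == length(totals))
  keep <- totals > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep),
            " stratum/strata with zero denominator; weights renormalized",
            call. = FALSE)
    events <- events[keep]; totals <- totals[keep]; weights <- weights[keep]
  }
  if (length(events) == 0L || sum(weights) <= 0) {
    return(list(rate = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                variance = NA_real_))
  }
  w <- weights / sum(weights)
  ratio <- w / totals
  y <- sum(ratio * events)
  v <- sum(ratio^2 * events)
  wm <- if (method == "fay_feuer") max(ratio) else mean(ratio)
  alpha <- 1 - conf
  lower <- if (y <= 0 || v <= 0) 0 else {
    qgamma(alpha / 2, shape = y^2 / v, scale = v / y)
  }
  upper <- qgamma(1 - alpha / 2, shape = (y + wm)^2 / (v + wm^2),
                  scale = (v + wm^2) / (y + wm))
  list(rate = y, ci_lower = lower, ci_upper = min(upper, clamp_upper),
       variance = v)
}

# Age stratum factor for a cohort, from an age-band table.
age_strata <- function(age, bands = default_age_bands()) {
  labels <- paste(bands$lower, bands$upper, sep = "-")
  factor(labels[findInterval(age, bands$lower)], levels = labels)
}

#' Standard age distribution of a cohort
#'
#' The default standard population for age adjustment is the full modelling
#' cohort's own age distribution, which makes crude and age-adjusted overall
#' rates coincide at baseline.
#'
#' @param cohort validated cohort.
#' @param age_bands age-band table.
#' @return named weight vector over age bands, summing to 1.
#' @export
standard_age_distribution <- function(cohort, age_bands = default_age_bands()) {
  tab <- table(age_strata(cohort$age, age_bands))
  w <- as.numeric(tab) / sum(tab)
  names(w) <- names(tab)
  w
}

#' Baseline age-adjusted survival with gamma CI
#'
#' Directly standardizes the subgroup's scarcity-free survival over age
#' strata, using a standard age distribution (default: the full cohort's),
#' with a Tiwari modified-gamma confidence interval.
#'
#' @param cohort validated cohort.
#' @param subgroup NULL, logical mask or index vector.
#' @param standard named weight vector over age bands (default from the full
#'   cohort).
#' @param age_bands age-band table.
#' @param conf confidence level.
#' @return as [age_adjusted_rate()].
#' @export
baseline_age_adjusted_survival <- function(cohort, subgroup = NULL,
                                           standard = NULL,
                                           age_bands = default_age_bands(),
                                           conf = 0.95) {
  if (is.null(standard)) standard <- standard_age_distribution(cohort, age_bands)
  idx <- subgroup_index(cohort, subgroup)
  strata <- age_strata(cohort$age[idx], age_bands)
  events <- tapply(cohort$survived[idx], strata, sum, default = 0)
  totals <- tapply(rep(1L, length(idx)), strata, sum, default = 0)
  age_adjusted_rate(as.numeric(events), as.numeric(totals),
                    standard[levels(strata)], conf = conf)
}

#' Simulated age-adjusted survival rate
#'
#' Per replicate, directly standardizes the subgroup's simulated survival
#' rate over age strata with the standard weights, then summarises over
#' replicates (mean +/- 1.96 SE).  Subgroup strata that are empty are dropped
#' and the weights renormalized (with a warning).
#'
#' @inheritParams survival_rate
#' @param standard named weight vector over age bands (default: the result
#'   cohort's age distribution).
#' @param age_bands age-band table.
#' @return as [survival_rate()].
#' @export
age_adjusted_survival <- function(result, subgroup = NULL, standard = NULL,
                                  age_bands = default_age_bands(),
                                  conf = 0.95) {
  stopifnot(inherits(result, "vent_result"))
  cohort <- result$cohort
  if (is.null(standard)) standard <- standard_age_distribution(cohort, age_bands)
  cols <- subgroup_index(result, subgroup)
  if (length(cols) == 0L) return(undefined_rate())
  strata <- age_strata(cohort$age[cols], age_bands)
  present <- levels(strata)[table(strata) > 0]
  if (length(present) < length(levels(strata))) {
    warning("empty age stratum/strata in subgroup dropped; ",
            "weights renormalized", call. = FALSE)
  }
  w <- standard[present]
  w <- w / sum(w)
  R <- nrow(result$alloc)
  dsr <- numeric(R)
  for (s in present) {
    scols <- cols[strata == s]
    surv_cols <- scols[cohort$survived[scols]]
    r_s <- if (length(surv_cols) == 0L) {
      rep(0, R)
    } else {
      rowSums(result$alloc[, surv_cols, drop = FALSE]) / length(scols)
    }
    dsr <- dsr + w[[s]] * r_s
  }
  out <- replicate_summary(dsr, conf)
  out$n <- length(cols)
  out
}
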