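# Shared fixtures and independent oracles.

# Minimal hand-built cohort; defaults give valid encounters.
toy_cohort <- function(sofa, survived = rep(TRUE, length(sofa)),
                       age = rep(50L, length(sofa)),
                       elixhauser = rep(0L, length(sofa)),
                       charlson = rep(0L, length(sofa)),
                       race = rep("white_nh", length(sofa)),
                       life_expectancy = NULL) {
  n <- length(sofa)
  co <- data.frame(
    encounter_id = sprintf("toy-%03d", seq_len(n)),
    age = as.integer(age), sex = rep("male", n), race_ethnicity = race,
    covid_positive = rep(FALSE, n), sofa = as.integer(sofa),
    elixhauser = as.integer(elixhauser),
    charlson_points = as.integer(charlson), survived = survived,
    stringsAsFactors = FALSE
  )
  if (!is.null(life_expectancy)) co$life_expectancy <- life_expectancy
  co
}

# Hand-assembled simulation result (for hand-computable metric checks).
manual_result <- function(alloc, cohort, capacity = 0.5) {
  structure(list(alloc = alloc, cohort = cohort, capacity = capacity,
                 beds_per_20 = as.integer(round(capacity * 20)),
                 replicates = nrow(alloc), seed = NA_integer_),
            class = "vent_result")
}

# All permutations of 1..m as a matrix (rows), m <= 8.
all_perms <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(m - 1L)
  blocks <- lapply(seq_len(m), function(i) {
    rest <- seq_len(m)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  })
  do.call(rbind, blocks)
}

# Independent brute-force oracle: expected survival rate of a block of m
# encounters with all-distinct priority bands, averaging over every ordered
# arrangement (pairing AND pair order).  Plain loops, no shared code with
# the simulator.
oracle_expected_survival <- function(bands, survived, capacity) {
  m <- length(bands)
  beds <- round(capacity * m)
  perms <- all_perms(m)
  total <- 0
  for (r in seq_len(nrow(perms))) {
    o <- perms[r, ]
    n_full <- m %/% 2L
    has_single <- m %% 2L == 1L
    n_pairs <- n_full + as.integer(has_single)
    beds_of_pair <- integer(n_pairs)
    left <- beds
    for (j in seq_len(n_pairs)) {          # one bed each, front to back
      if (left == 0L) break
      beds_of_pair[j] <- 1L
      left <- left - 1L
    }
    for (j in seq_len(n_full)) {           # second beds to full pairs
      if (left == 0L) break
      beds_of_pair[j] <- 2L
      left <- left - 1L
    }
    surv <- 0L
    for (j in seq_len(n_full)) {
      a <- o[2L * j - 1L]; b <- o[2L * j]
      if (beds_of_pair[j] == 2L) {
        surv <- surv + survived[a] + survived[b]
      } else if (beds_of_pair[j] == 1L) {
        winner <- if (bands[a] < bands[b]) a else b
        surv <- surv + survived[winner]
      }
    }
    if (has_single && beds_of_pair[n_pairs] >= 1L) {
      surv <- surv + survived[o[m]]
    }
    total <- total + surv / m
  }
  total / nrow(perms)
}

# Default annotated synthetic cohort shared by heavier tests (memoised).
default_test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- annotate_cohort(generate_cohort(cohort_spec()))
    }
    cache
  }
})

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
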