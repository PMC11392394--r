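# Pair-based Monte Carlo scarcity engine.
#
# One replicate: randomly permute the cohort, cut it into blocks of 20,
# group each block into ten randomly-ordered pairs, and allocate n beds per
# block (capacity c = n/20): with n > 10 the first n-10 pairs get both beds
# and each remaining pair sends only its higher-priority member; with
# n < 10 only the first n pairs get a (contested) bed; with n = 10 every
# pair is contested.  Unallocated encounters are assumed not to survive.
#
# A final short block of size m (cohort size mod 20) forms floor(m/2) pairs
# plus a singleton when m is odd, and receives round(c*m) beds by the same
# first-pairs-double / last-pairs-zero scheme; the singleton competes as a
# pair of one (it can hold at most one bed).

#' Allocate beds within one block of 20 encounters
#'
#' Randomly pairs the 20 encounters (pair k = positions 2k-1, 2k of a random
#' permutation) and allocates `n` beds per the block scheme above, with
#' contested pairs resolved by protocol priority and lottery tiebreaks drawn
#' from the current RNG.
#'
#' @param block data.frame of exactly 20 encounters.
#' @param n integer beds, 1--19.
#' @param protocol protocol name.
#' @param colorado_table,age_bands scoring tables.
#' @return logical allocation vector in the block's row order.
#' @export
allocate_block <- function(block, n, protocol,
                           colorado_table = default_colorado_table(),
                           age_bands = default_age_bands()) {
  if (nrow(block) != 20L) {
    stop("allocate_block requires exactly 20 encounters", call. = FALSE)
  }
  if (n < 1L || n > 19L) stop("beds n must lie in 1..19", call. = FALSE)
  bands <- protocol_bands(block, protocol, colorado_table, age_bands)
  perm <- sample.int(20L)
  alloc_perm <- alloc_ordered_block(bands[perm], as.integer(n), runif(20L))
  alloc <- logical(20L)
  alloc[perm] <- alloc_perm
  alloc
}

# Core allocator for one block already in random (pair) order.
# bands: priority bands at positions 1..m (pairs are (1,2), (3,4), ...;
# position m is a singleton when m is odd); beds: total beds for the block;
# u: per-position uniform tiebreaks.  Returns logical allocation.
alloc_ordered_block <- function(bands, beds, u) {
  m <- length(bands)
  stopifnot(beds >= 0L, beds <= m)
  n_full <- m %/% 2L
  has_single <- m %% 2L == 1L
  n_pairs <- n_full + as.integer(has_single)
  bp <- integer(n_pairs)
  k <- min(beds, n_pairs)
  if (k > 0L) bp[seq_len(k)] <- 1L
  extra <- beds - k
  if (extra > 0L) bp[seq_len(extra)] <- 2L  # second beds go to full pairs first
  alloc <- logical(m)
  if (n_full > 0L) {
    i1 <- seq(1L, by = 2L, length.out = n_full)
    i2 <- i1 + 1L
    fb <- bp[seq_len(n_full)]
    alloc[i1[fb == 2L]] <- TRUE
    alloc[i2[fb == 2L]] <- TRUE
    contested <- which(fb == 1L)
    if (length(contested) > 0L) {
      a <- i1[contested]; b <- i2[contested]
      first_wins <- bands[a] < bands[b] |
        (bands[a] == bands[b] & u[a] < u[b])
      alloc[a[first_wins]] <- TRUE
      alloc[b[!first_wins]] <- TRUE
    }
  }
  if (has_single && bp[n_pairs] >= 1L) alloc[m] <- TRUE
  alloc
}

#' Simulate one replicate of the scarcity allocation
#'
#' Permutes the cohort, partitions it into blocks of 20 (plus a short
#' remainder block) and allocates beds per block.  Every encounter receives
#' exactly one allocation decision.  Uses the current RNG state.
#'
#' @param cohort validated cohort data.frame.
#' @param protocol protocol name.
#' @param capacity beds per patient on the n/20 grid (0 < c < 1).
#' @param bands optional precomputed priority bands (performance path).
#' @param colorado_table,age_bands scoring tables.
#' @return logical allocation vector in cohort row order.
#' @export
simulate_replicate <- function(cohort, protocol, capacity, bands = NULL,
                               colorado_table = default_colorado_table(),
                               age_bands = default_age_bands()) {
  n_beds <- capacity_to_beds(capacity)
  if (is.null(bands)) {
    bands <- protocol_bands(cohort, protocol, colorado_table, age_bands)
  }
  N <- length(bands)
  if (N == 0L) stop("cohort must be nonempty", call. = FALSE)
  perm <- sample.int(N)
  u <- runif(N)
  bperm <- bands[perm]
  alloc_perm <- logical(N)

  n_blocks <- N %/% 20L
  if (n_blocks > 0L) {
    n_pair_tot <- 10L * n_blocks
    i1 <- seq(1L, by = 2L, length.out = n_pair_tot)
    i2 <- i1 + 1L
    pk <- ((seq_len(n_pair_tot) - 1L) %% 10L) + 1L  # pair index within block
    if (n_beds > 10L) {
      both <- pk <= (n_beds - 10L)
      contested <- !both
    } else if (n_beds == 10L) {
      both <- rep(FALSE, n_pair_tot)
      contested <- rep(TRUE, n_pair_tot)
    } else {
      both <- rep(FALSE, n_pair_tot)
      contested <- pk <= n_beds
    }
    alloc_perm[i1[both]] <- TRUE
    alloc_perm[i2[both]] <- TRUE
    a <- i1[contested]; b <- i2[contested]
    first_wins <- bperm[a] < bperm[b] |
      (bperm[a] == bperm[b] & u[a] < u[b])
    alloc_perm[a[first_wins]] <- TRUE
    alloc_perm[b[!first_wins]] <- TRUE
  }
  m <- N - 20L * n_blocks
  if (m > 0L) {
    rest <- (20L * n_blocks + 1L):N
    beds_rem <- as.integer(round(capacity * m))
    alloc_perm[rest] <- alloc_ordered_block(bperm[rest], beds_rem, u[rest])
  }
  alloc <- logical(N)
  alloc[perm] <- alloc_perm
  alloc
}

# Validate capacity on the n/20 grid and return integer beds per 20.
capacity_to_beds <- function(capacity) {
  n <- capacity * 20
  if (length(capacity) != 1L || capacity <= 0 || capacity >= 1 ||
      abs(n - round(n)) > 1e-9) {
    stop("capacity must lie on the n/20 grid with n in 1..19", call. = FALSE)
  }
  as.integer(round(n))
}

# Default replicate counts: 1000 at c = 0.5, 250 elsewhere.
default_replicates <- function(capacity) {
  if (abs(capacity - 0.5) < 1e-9) 1000L else 250L
}

#' Run the scarcity simulation
#'
#' Repeats [simulate_replicate()] with an independent RNG substream per
#' replicate, derived from a single master seed, so results are reproducible
#' and replicate-order independent.
#'
#' @param cohort validated cohort data.frame.
#' @param protocol protocol name.
#' @param capacity beds per patient, on the n/20 grid.
#' @param replicates number of Monte Carlo replicates (default 1000 at
#'   c = 0.5, 250 otherwise).
#' @param seed integer master seed (ignored when `stream` is given).
#' @param stream optional L'Ecuyer-CMRG `.Random.seed` state to descend from
#'   (used by [capacity_sweep()]).
#' @param colorado_table,age_bands scoring tables.
#' @return object of class `vent_result`: list with the replicate-by-encounter
#'   logical allocation matrix `alloc`, the `cohort`, and run metadata.
#' @export
run_simulation <- function(cohort, protocol, capacity, replicates = NULL,
                           seed = 1L, stream = NULL,
                           colorado_table = default_colorado_table(),
                           age_bands = default_age_bands()) {
  validate_cohort(cohort)
  n_beds <- capacity_to_beds(capacity)
  if (is.null(replicates)) replicates <- default_replicates(capacity)
  stopifnot(replicates >= 1L)
  bands <- protocol_bands(cohort, protocol, colorado_table, age_bands)
  if (is.null(stream)) stream <- rng_root_stream(seed)
  subs <- rng_substreams(stream, replicates)
  N <- nrow(cohort)
  alloc <- matrix(FALSE, nrow = replicates, ncol = N)
  for (r in seq_len(replicates)) {
    alloc[r, ] <- with_rng(subs[[r]], {
      simulate_replicate(cohort, protocol, capacity, bands = bands)
    })
  }
  structure(list(alloc = alloc, cohort = cohort, protocol = protocol,
                 capacity = capacity, beds_per_20 = n_beds,
                 replicates = replicates, seed = seed),
            class = "vent_result")
}

#' @export
print.vent_result <- function(x, ...) {
  cat("<vent_result> protocol=", x$protocol,
      " capacity=", format(x$capacity),
      " replicates=", x$replicates,
      " encounters=", ncol(x$alloc), "\n", sep = "")
  invisible(x)
}

#' Sweep the capacity grid
#'
#' Runs [run_simulation()] at each capacity with a distinct RNG stream per
#' capacity, all descended from one master seed.
#'
#' @param cohort validated cohort data.frame.
#' @param protocol protocol name.
#' @param capacities capacities on the n/20 grid (default the full
#'   0.05..0.95 grid).
#' @param replicates_map optional function(capacity) -> replicate count, or a
#'   single count applied everywhere; default is the standard 1000/250 rule.
#' @param seed integer master seed.
#' @param colorado_table,age_bands scoring tables.
#' @return named list capacity -> `vent_result`.
#' @export
capacity_sweep <- function(cohort, protocol, capacities = (1:19) / 20,
                           replicates_map = NULL, seed = 1L,
                           colorado_table = default_colorado_table(),
                           age_bands = default_age_bands()) {
  reps_for <- if (is.null(replicates_map)) {
    default_replicates
  } else if (is.function(replicates_map)) {
    replicates_map
  } else {
    function(capacity) as.integer(replicates_map)
  }
  streams <- rng_streams(rng_root_stream(seed), length(capacities))
  out <- vector("list", length(capacities))
  names(out) <- format(capacities)
  for (i in seq_along(capacities)) {
    out[[i]] <- run_simulation(cohort, protocol, capacities[i],
                               replicates = reps_for(capacities[i]),
                               stream = streams[[i]],
                               colorado_table = colorado_table,
                               age_bands = age_bands)
  }
  out
}
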