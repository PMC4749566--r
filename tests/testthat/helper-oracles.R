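# Brute-force oracles, independent of the package internals: plain loops and
# set algebra only. These recompute what the implementation computes so the
# two routes can be compared on small instances.

# Per-probe occurrence count of `probe` across a list of probe sets.
oracle_count <- function(probe, sets) {
  n <- 0L
  for (s in sets) if (probe %in% s) n <- n + 1L
  n
}

# Support table by exhaustive counting.
oracle_supports <- function(universe, sets) {
  vapply(universe, oracle_count, integer(1), sets = sets)
}

# Fuzzy intersection by per-probe counting.
oracle_core <- function(universe, sets, k) {
  keep <- logical(length(universe))
  for (i in seq_along(universe)) {
    keep[i] <- oracle_count(universe[i], sets) >= k
  }
  universe[keep]
}

# KS running-sum enrichment score by explicit prefix evaluation (same
# positive-wins tie rule as the implementation, applied to independently
# accumulated prefix sums).
oracle_es <- function(set, ranked) {
  U <- length(ranked)
  nh <- sum(ranked %in% set)
  running <- 0
  mx <- -Inf
  mn <- Inf
  for (i in seq_len(U)) {
    running <- running +
      if (ranked[i] %in% set) 1 / nh else -1 / (U - nh)
    if (running > mx) mx <- running
    if (running < mn) mn <- running
  }
  if (mx >= -mn - 1e-12) mx else mn
}

# Upper-tail hypergeometric p by exhaustive enumeration of all query draws of
# size n from the universe (universe must be small).
oracle_hyper_p <- function(overlap, set, universe, n) {
  draws <- utils::combn(universe, n)
  hits <- 0L
  for (j in seq_len(ncol(draws))) {
    if (length(intersect(draws[, j], set)) >= overlap) hits <- hits + 1L
  }
  hits / ncol(draws)
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  q[order(o)]
}

# --- fixture builders ------------------------------------------------------

probe_ids <- function(U) sprintf("P%04d", seq_len(U))

# iid standard-normal score compendium (pure noise).
noise_compendium <- function(U, n, seed, prefix = "drug") {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(U * n), U, n,
                dimnames = list(probe_ids(U),
                                sprintf("%s_%03d", prefix, seq_len(n))))
    rank_from_expression(m)
  })
}

# A compendium whose profiles have prescribed up-tails: each element of
# `up_sets` is placed at the top of its profile (rest of the universe in a
# seeded random order below).
compendium_with_up_tails <- function(universe, up_sets, seed = 42) {
  withr::with_seed(seed, {
    profiles <- lapply(seq_along(up_sets), function(i) {
      rest <- sample(setdiff(universe, up_sets[[i]]))
      ranked_profile(paste0("drug", i), c(up_sets[[i]], rest))
    })
    compendium(profiles)
  })
}
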