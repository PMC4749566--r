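test_that("a degenerate background of identical profiles gives constant null cardinality", {
  p <- withr::with_seed(1, ranked_profile("d", sample(probe_ids(50))))
  bg <- compendium(lapply(1:6, function(i) ranked_profile(paste0("d", i), p$probes)))
  null <- resampling_null(bg, N = 4, k_min = 4, f = 0.2, B = 25, seed = 2)
  expect_true(all(null$up == 10L))   # tail size floor(0.2*50)
  expect_true(all(null$down == 10L))

  one <- resampling_null(bg, N = 4, k_min = 2, f = 0.2, B = 1, seed = 3)
  expect_length(one$up, 1L)
})

test_that("resampling null matches a brute-force re-run with the same seed", {
  bg <- noise_compendium(60, 20, seed = 8)
  B <- 15
  null <- resampling_null(bg, N = 5, k_min = 5, f = 0.2, B = B, seed = 99)
  # independent route: replay the draw sequence, then use plain set algebra
  draws <- withr::with_seed(99, {
    replicate(B, sample.int(20, 5), simplify = FALSE)
  })
  expected <- vapply(draws, function(cols) {
    sigs <- lapply(cols, function(j) {
      extract_signature(profile_of(bg, j), 0.2)
    })
    length(Reduce(intersect, lapply(sigs, `[[`, "up")))
  }, numeric(1))
  expect_equal(null$up, as.integer(expected))
})

test_that("both null models are bit-reproducible given a seed", {
  bg <- noise_compendium(60, 15, seed = 4)
  a <- resampling_null(bg, N = 6, k_min = 3, B = 20, seed = 7)
  b <- resampling_null(bg, N = 6, k_min = 3, B = 20, seed = 7)
  expect_identical(a$up, b$up)
  expect_identical(a$down, b$down)

  comp <- noise_compendium(60, 6, seed = 5)
  c1 <- probe_permutation_null(comp, k_min = 2, B = 20, seed = 11)
  c2 <- probe_permutation_null(comp, k_min = 2, B = 20, seed = 11)
  expect_identical(c1$down, c2$down)
  expect_length(probe_permutation_null(comp, k_min = 2, B = 1, seed = 1)$up, 1L)
})

test_that("probe-permutation null mean matches the independent-tails expectation", {
  comp <- noise_compendium(60, 5, seed = 6)
  null <- probe_permutation_null(comp, k_min = 2, f = 0.2, B = 500, seed = 13)
  # each permuted profile carries any probe in its up tail w.p. 12/60 exactly,
  # independently across profiles: E[card] = U * P(Binom(5, 0.2) >= 2)
  expected <- 60 * pbinom(1, 5, 12 / 60, lower.tail = FALSE)
  se <- sd(null$up) / sqrt(500)
  expect_lt(abs(mean(null$up) - expected), 4 * se + 0.05)
})

test_that("permuting destroys the agreement of identical profiles", {
  p <- withr::with_seed(2, sample(probe_ids(100)))
  comp <- compendium(lapply(1:6, function(i) ranked_profile(paste0("d", i), p)))
  sup <- support_counts(signatures(comp, 0.2))
  observed <- sum(sup$up >= 6L)          # = tail size, perfect agreement
  null <- probe_permutation_null(comp, k_min = 6, f = 0.2, B = 100, seed = 21)
  expect_equal(observed, 20L)
  expect_lt(mean(null$up), observed / 100)
})

test_that("empirical p follows the add-one counting rule", {
  expect_equal(empirical_p(999, 0:998), 1 / 1000)   # beats all 999 draws
  expect_equal(empirical_p(0, 1:9), 1)              # beaten by all
  draws <- rep(c(1, 3), 100)
  expect_equal(empirical_p(3, draws), (1 + 100) / 201)
  expect_equal(empirical_p(2, draws), (1 + 100) / 201) # median-ish ~ 0.5
})

test_that("fold ratio reproduces the printed signal-to-noise arithmetic", {
  expect_equal(fold_ratio(108, rep(32, 1000)), 3.375)
  expect_equal(fold_ratio(5, rep(5, 10)), 1.0)
  degenerate <- fold_ratio(10, rep(0, 10))
  expect_true(is.infinite(degenerate))
  expect_true(attr(degenerate, "degenerate_null"))
  # scale-free: duplicating every draw leaves the ratio unchanged
  draws <- c(2, 4, 6)
  expect_equal(fold_ratio(12, draws), fold_ratio(12, rep(draws, 2)))
})

test_that("cutoff_scan reports consistent observed counts and p-values", {
  panel <- noise_compendium(100, 5, seed = 31, prefix = "panel")
  bg <- noise_compendium(100, 30, seed = 32, prefix = "bg")
  scan <- cutoff_scan(panel, bg, f = 0.2, B = 100, seed = 41)
  expect_s3_class(scan, "fit_scan")
  expect_equal(nrow(scan), 10L) # 5 k x 2 directions
  sup <- support_counts(signatures(panel, 0.2))
  for (k in 1:5) {
    expect_equal(scan$observed[scan$k == k & scan$direction == "up"],
                 sum(sup$up >= k))
  }
  expect_true(all(scan$p > 0 & scan$p <= 1))
  # deterministic given seed
  scan2 <- cutoff_scan(panel, bg, f = 0.2, B = 100, seed = 41)
  expect_identical(as.data.frame(scan), as.data.frame(scan2))
})

make_scan <- function(k, fold, p, N = 11) {
  df <- rbind(
    data.frame(k = k, direction = "up", observed = 0, null_mean = 1,
               fold = 0, p = 1, degenerate_null = FALSE),
    data.frame(k = k, direction = "down", observed = 0, null_mean = 1,
               fold = fold, p = p, degenerate_null = FALSE))
  structure(df, N = N, class = c("fit_scan", "data.frame"))
}

test_that("cut-off selection applies the fold and p criteria per rule", {
  # k = 8..11 pass: minimal rule picks 8 (the fold-ratio crossing), the
  # stringent alternative picks 11
  scan <- make_scan(5:11, fold = c(1, 2, 2.9, 3.4, 5, 9, 20),
                    p = c(0.6, 0.2, 0.04, 0.001, 0.001, 0.001, 0.001))
  sel <- select_cutoff(scan)
  expect_equal(sel$k[sel$direction == "down"], 8L)
  expect_equal(sel$n_passing[sel$direction == "down"], 4L)
  expect_true(is.na(sel$k[sel$direction == "up"]))
  sel_max <- select_cutoff(scan, rule = "max")
  expect_equal(sel_max$k[sel_max$direction == "down"], 11L)

  none <- select_cutoff(make_scan(5:8, fold = c(1, 1, 2, 2.5),
                                  p = rep(0.001, 4)))
  expect_true(all(is.na(none$k)))

  one <- select_cutoff(make_scan(5:8, fold = c(1, 1, 3.2, 1),
                                 p = c(1, 1, 0.01, 0.2)))
  expect_equal(one$k[one$direction == "down"], 7L)
  expect_equal(one$n_passing[one$direction == "down"], 1L)
})

test_that("enrichment refinement picks the maximal enriched significant cut-off", {
  # synthetic supports: 30 probes at support 10, 30 more at 9, 40 more at 8
  universe <- probe_ids(200)
  sup <- structure(list(probe = universe,
                        up = integer(200),
                        down = c(rep(10L, 30), rep(9L, 30), rep(8L, 40),
                                 rep(0L, 100)),
                        N = 11L, n_tail = 40L, f = 0.2),
                   class = "fit_support")
  fits <- setNames(lapply(8:10, function(k) fuzzy_intersect(sup, k)),
                   8:10)
  map <- data.frame(probe = universe, gene = sub("P", "G", universe))
  # the set covers the k<=9 core but misses every k=10 core gene
  sets <- structure(list(S1 = sub("P", "G", universe[31:60])),
                    class = "gene_set_collection")
  scan <- make_scan(8:10, fold = c(4, 5, 6), p = rep(0.001, 3))
  ref <- refine_cutoff_by_enrichment(scan, fits, sets, map)
  expect_equal(ref$k[ref$direction == "down"], 9L)
  expect_true(ref$refined[ref$direction == "down"])

  # all significant cores enriched -> maximal k
  sets_all <- structure(list(S1 = sub("P", "G", universe[1:30])),
                        class = "gene_set_collection")
  ref_all <- refine_cutoff_by_enrichment(scan, fits, sets_all, map)
  expect_equal(ref_all$k[ref_all$direction == "down"], 10L)

  # nothing enriched -> fall back to the base selection, flagged
  sets_none <- structure(list(S1 = sub("P", "G", universe[150:180])),
                         class = "gene_set_collection")
  ref_none <- refine_cutoff_by_enrichment(scan, fits, sets_none, map)
  expect_false(ref_none$refined[ref_none$direction == "down"])
  expect_equal(ref_none$k[ref_none$direction == "down"], 8L)
})

test_that("the plateau rule finds the first sustained-stability point", {
  find <- fitcore:::.find_plateau
  expect_equal(find(c(30, 18, 12, 10, 10, 10), 0.02), 4L)  # N = 8 of 5..10
  expect_true(is.na(find(c(30, 20, 12, 8, 5), 0.02)))      # keeps falling
  expect_equal(find(rep(7, 5), 0.02), 1L)                  # constant curve
  expect_equal(find(c(5, 0, 0, 0), 0.02), 2L)              # zero tail
})

test_that("plateau_scan flattens once panels of identical profiles saturate", {
  p <- withr::with_seed(3, sample(probe_ids(60)))
  bg <- compendium(lapply(1:12, function(i) ranked_profile(paste0("d", i), p)))
  ps <- plateau_scan(bg, theta = 0.7, N_range = 2:8, B = 10, seed = 5)
  # identical profiles: cardinality is the tail size whatever N
  expect_true(all(ps$mean_cardinality == 12))
  expect_equal(unname(attr(ps, "plateau")["down"]), 2L)
  expect_true(all(ps$is_plateau))
})
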