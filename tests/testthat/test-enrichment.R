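test_that("hypergeometric enrichment reproduces exhaustive enumeration", {
  universe <- paste0("G", 1:20)
  sets <- list(S1 = universe[1:5])
  res <- hypergeom_enrich(universe[1:5], sets, universe)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p, 1 / choose(20, 5))               # 1/15504
  expect_equal(res$p, oracle_hyper_p(5, sets$S1, universe, 5))

  # zero overlap with a tiny set: upper tail includes 0, so p = 1
  res0 <- hypergeom_enrich(universe[10:12], list(S = universe[1:2]), universe)
  expect_equal(res0$p, 1)
})

test_that("hypergeometric p matches enumeration on random small instances", {
  for (seed in 1:12) {
    inst <- withr::with_seed(seed, {
      U <- sample(10:25, 1)
      universe <- paste0("G", seq_len(U))
      set <- sample(universe, sample(2:6, 1))
      query <- sample(universe, sample(3:7, 1))
      list(universe = universe, set = set, query = query)
    })
    res <- hypergeom_enrich(inst$query, list(S = inst$set), inst$universe)
    expect_equal(res$p,
                 oracle_hyper_p(res$overlap, inst$set, inst$universe,
                                length(inst$query)),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is the hand-computed step-up", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.04))
  universe <- paste0("G", 1:30)
  sets <- list(A = universe[1:5], B = universe[1:10], C = universe[25:28])
  res <- hypergeom_enrich(universe[1:6], sets, universe)
  expect_equal(res$q, oracle_bh(res$p)[order(order(res$p, res$set_id))],
               tolerance = 1e-12)
  expect_true(all(res$q >= res$p))
  expect_true(all(diff(res$q) >= -1e-12))  # ordered by p -> q non-decreasing
})

test_that("enrichment input contracts are enforced", {
  universe <- paste0("G", 1:10)
  expect_error(hypergeom_enrich(character(0), list(S = universe[1:2]),
                                universe), "non-empty")
  expect_error(hypergeom_enrich(c("G1", "ZZ"), list(S = universe[1:2]),
                                universe), "outside universe")
})

toy_net <- function() {
  # complete bipartite between A1..A5 and B1..B5 plus a decoy chain C1..C10,
  # so random node sets essentially never reproduce the full bipartite overlap
  edges <- expand.grid(a = paste0("A", 1:5), b = paste0("B", 1:5),
                       stringsAsFactors = FALSE)
  net <- rbind(data.frame(a = edges$a, b = edges$b, confidence = 0.95),
               data.frame(a = paste0("C", 1:9), b = paste0("C", 2:10),
                          confidence = 0.9))
  class(net) <- c("fit_network", "data.frame")
  net
}

test_that("maximal bipartite overlap is as significant as B permits", {
  res <- ppi_overlap_significance(paste0("A", 1:5), paste0("B", 1:5),
                                  toy_net(), B = 200, seed = 1)
  expect_equal(res$observed, 25L)
  expect_equal(res$p, 1 / 201)
})

test_that("confidence filtering is strictly greater-than", {
  net <- data.frame(a = c("A1", "A2"), b = c("B1", "B2"),
                    confidence = c(0.70, 0.71))
  class(net) <- c("fit_network", "data.frame")
  res <- ppi_overlap_significance(c("A1", "A2"), c("B1", "B2"), net,
                                  conf_min = 0.7, B = 50, seed = 2)
  expect_equal(res$observed, 1L)   # the 0.70 edge is excluded
  expect_equal(res$n_a, 1L)        # A1 is no longer in the network node space
})

test_that("overlap z-scores are centred on random sets", {
  net <- withr::with_seed(5, {
    nodes <- paste0("N", 1:40)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.15
    data.frame(a = pairs[keep, 1], b = pairs[keep, 2], confidence = 0.9)
  })
  class(net) <- c("fit_network", "data.frame")
  zs <- vapply(1:8, function(s) {
    sets <- withr::with_seed(100 + s, {
      list(a = sample(paste0("N", 1:40), 8), b = sample(paste0("N", 1:40), 8))
    })
    ppi_overlap_significance(sets$a, sets$b, net, B = 300, seed = 200 + s)$z
  }, numeric(1))
  expect_true(all(abs(zs) < 3))
})

test_that("core-frequency fold compares per-signature core fractions", {
  universe <- probe_ids(50)
  comp <- noise_compendium(50, 8, seed = 6)
  sigs <- signatures(comp, 0.2)
  expect_equal(as.numeric(core_frequency_fold(universe[1:5], sigs, sigs)), 1.0)

  # core occupying every foreground down-tail, absent from background
  core <- sigs[[1]]$down
  fg <- list(sigs[[1]])
  bg_prof <- ranked_profile("bg", c(core, setdiff(comp$ranks[, 2], core)))
  bg <- list(extract_signature(bg_prof, 0.2))
  fold <- core_frequency_fold(core, fg, bg)
  expect_true(is.infinite(fold))
  expect_true(attr(fold, "degenerate_background"))
})

test_that("running-sum enrichment scores match the prefix-walk oracle", {
  ranked <- paste0("g", 1:6)
  expect_equal(gsea_es("g1", ranked), 1)     # single top hit peaks at 1
  expect_equal(gsea_es(c("g2", "g5"), ranked),
               oracle_es(c("g2", "g5"), ranked))
  for (seed in 1:10) {
    case <- withr::with_seed(seed, {
      case_u <- sample(10:40, 1)
      case_ranked <- sample(paste0("g", seq_len(case_u)))
      list(ranked = case_ranked,
           set = sample(case_ranked, sample(2:5, 1)))
    })
    expect_equal(gsea_es(case$set, case$ranked),
                 oracle_es(case$set, case$ranked), tolerance = 1e-9)
  }
  expect_error(gsea_es(paste0("g", 1:6), ranked), "entire universe")
  expect_error(gsea_es("absent", ranked), "no members")
})

test_that("two-tailed scores are symmetric and bounded", {
  prof <- withr::with_seed(4, ranked_profile("d", sample(probe_ids(40))))
  up <- prof$probes[1:5]
  down <- prof$probes[36:40]
  sc <- gsea_two_tailed(up, down, prof)
  expect_equal(sc$tes, 1)   # the profile's own tails give the maximal score
  rev_prof <- ranked_profile("r", rev(prof$probes))
  expect_equal(gsea_two_tailed(up, down, rev_prof)$tes, -1)
  expect_error(gsea_two_tailed(up, up, prof), "disjoint")
})

test_that("drug ranking recognizes a profile's own signature", {
  comp <- noise_compendium(100, 20, seed = 12)
  sig <- extract_signature(profile_of(comp, 7), 0.2)
  rk <- gsea_rank_drugs(sig$up, sig$down, comp)
  expect_equal(rk$drug_id[1], colnames(comp$ranks)[7])
  expect_true(all(rk$tes >= -1 & rk$tes <= 1))
  expect_true(all(abs(rk$es_up) <= 1 & abs(rk$es_down) <= 1))
})
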