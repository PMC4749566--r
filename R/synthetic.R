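#' Specification for a synthetic perturbation compendium
#'
#' Describes a compendium in which a small panel of "corrector" drugs shares
#' a weakly penetrant planted signature (each planted probe responds in a
#' random ~70-90% subset of the panel) buried under strong, heterogeneous
#' per-cluster primary mechanism-of-action (MOA) signals and Gaussian noise,
#' while a large background of unrelated drugs carries only noise plus its
#' own idiosyncratic modules. Defaults emulate an 11-corrector panel against
#' a ~200-drug background on a 5000-probe array, with a 150-probe planted
#' down-core at moderate effect size and three MOA clusters whose footprint
#' is deliberately stronger than the shared signal.
#'
#' @param U Probe universe size.
#' @param n_correctors Panel size carrying the planted signal.
#' @param n_background Number of background drugs.
#' @param n_core_up,n_core_down Planted shared-signal sizes per direction.
#' @param support_prob Per-corrector probability that each planted probe
#'   responds (the penetrance of the shared signal).
#' @param core_strength Latent-score shift of a responding planted probe
#'   (in noise-SD units; noise is standard normal).
#' @param n_moa_clusters Number of disjoint primary-MOA modules shared by
#'   corrector subsets (round-robin assignment).
#' @param moa_size Probes per MOA module.
#' @param moa_strength Latent shift of MOA-module probes (stronger than
#'   `core_strength` by default, so the primary MOA dominates each profile).
#' @param background_module_size Probes in each background drug's own module.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(U = 5000L, n_correctors = 11L, n_background = 200L,
                           n_core_up = 0L, n_core_down = 150L,
                           support_prob = 0.85, core_strength = 2.5,
                           n_moa_clusters = 3L, moa_size = 150L,
                           moa_strength = 4, background_module_size = 150L,
                           seed = 1L) {
  spec <- list(U = as.integer(U), n_correctors = as.integer(n_correctors),
               n_background = as.integer(n_background),
               n_core_up = as.integer(n_core_up),
               n_core_down = as.integer(n_core_down),
               support_prob = support_prob, core_strength = core_strength,
               n_moa_clusters = as.integer(n_moa_clusters),
               moa_size = as.integer(moa_size), moa_strength = moa_strength,
               background_module_size = as.integer(background_module_size),
               seed = as.integer(seed))
  if (spec$support_prob <= 0 || spec$support_prob > 1) {
    stop("support_prob must lie in (0, 1]", call. = FALSE)
  }
  planted <- spec$n_core_up + spec$n_core_down +
    spec$n_moa_clusters * spec$moa_size
  if (planted > spec$U) {
    stop("planted core + MOA modules (", planted, ") exceed universe size ",
         spec$U, call. = FALSE)
  }
  if (spec$n_correctors < 1L || spec$U < 10L) {
    stop("need at least 1 corrector and 10 probes", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic compendium with planted ground truth
#'
#' Each drug's latent score vector is standard-normal noise; corrector `j`
#' additionally receives `+core_strength` on responding planted up-probes and
#' `-core_strength` on responding planted down-probes (each probe responds
#' independently with probability `support_prob`), plus `+/- moa_strength` on
#' its MOA cluster's module probes (module signs fixed per cluster, so
#' cluster members share their primary MOA footprint). Background drugs get
#' noise plus an idiosyncratic module of their own. Profiles are emitted via
#' [rank_from_expression()], so only rank order leaves the generator.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `compendium` (a `fit_compendium`; correctors named
#'   `corrector_*`, background `background_*`) and `truth` (class
#'   `synthetic_truth`): planted `core_up`/`core_down` probe ids, logical
#'   response matrices `response_up`/`response_down` (planted probe x
#'   corrector), `moa_cluster` assignment per corrector, and the module probe
#'   lists.
#' @export
generate_compendium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    probes <- sprintf("P%05d", seq_len(spec$U))
    planted_n <- spec$n_core_up + spec$n_core_down +
      spec$n_moa_clusters * spec$moa_size
    planted <- sample(probes, planted_n)
    take <- function(n, offset) {
      if (n == 0L) character(0) else planted[seq.int(offset + 1L, offset + n)]
    }
    core_up <- take(spec$n_core_up, 0L)
    core_down <- take(spec$n_core_down, spec$n_core_up)
    moa_modules <- lapply(seq_len(spec$n_moa_clusters), function(c) {
      ids <- take(spec$moa_size,
                  spec$n_core_up + spec$n_core_down + (c - 1L) * spec$moa_size)
      stats::setNames(sample(c(-1, 1), length(ids), replace = TRUE), ids)
    })
    free <- setdiff(probes, c(core_up, core_down))
    corr_ids <- sprintf("corrector_%02d", seq_len(spec$n_correctors))
    bg_ids <- sprintf("background_%03d", seq_len(spec$n_background))
    moa_cluster <- stats::setNames(
      rep_len(seq_len(spec$n_moa_clusters), spec$n_correctors), corr_ids)
    n_drugs <- spec$n_correctors + spec$n_background
    scores <- matrix(stats::rnorm(spec$U * n_drugs), spec$U, n_drugs,
                     dimnames = list(probes, c(corr_ids, bg_ids)))
    resp_mat <- function(core) {
      matrix(stats::runif(length(core) * spec$n_correctors) <=
               spec$support_prob,
             length(core), spec$n_correctors,
             dimnames = list(core, corr_ids))
    }
    response_up <- resp_mat(core_up)
    response_down <- resp_mat(core_down)
    for (j in seq_len(spec$n_correctors)) {
      if (length(core_up)) {
        r <- response_up[, j]
        scores[core_up[r], j] <- scores[core_up[r], j] + spec$core_strength
      }
      if (length(core_down)) {
        r <- response_down[, j]
        scores[core_down[r], j] <- scores[core_down[r], j] - spec$core_strength
      }
      mod <- moa_modules[[moa_cluster[[j]]]]
      if (length(mod)) {
        scores[names(mod), j] <- scores[names(mod), j] + spec$moa_strength * mod
      }
    }
    bg_modules <- lapply(bg_ids, function(id) {
      ids <- sample(free, spec$background_module_size)
      stats::setNames(sample(c(-1, 1), length(ids), replace = TRUE), ids)
    })
    names(bg_modules) <- bg_ids
    for (id in bg_ids) {
      mod <- bg_modules[[id]]
      if (length(mod)) {
        scores[names(mod), id] <- scores[names(mod), id] +
          spec$moa_strength * mod
      }
    }
    truth <- structure(list(core_up = core_up, core_down = core_down,
                            response_up = response_up,
                            response_down = response_down,
                            moa_cluster = moa_cluster,
                            moa_modules = moa_modules,
                            spec = spec),
                       class = "synthetic_truth")
    list(compendium = rank_from_expression(scores), truth = truth)
  })
}

#' Score recovery of the planted core by a fuzzy-intersection result
#'
#' Standard precision/recall/F1 of the recovered core against the planted
#' core, per direction, at probe level (or at gene level when a probe-to-gene
#' map is supplied). An empty recovered core yields precision 0 (flagged via
#' the `empty_core` column); an empty planted direction yields `NA` metrics.
#'
#' @param fit A `fit_result`.
#' @param truth A `synthetic_truth` from [generate_compendium()].
#' @param map Optional probe-to-gene data.frame; when given, both planted and
#'   recovered sets are collapsed to genes before scoring.
#' @return Data.frame with one row per direction: `direction`, `n_recovered`,
#'   `n_planted`, `tp`, `precision`, `recall`, `f1`, `empty_core`.
#' @export
score_recovery <- function(fit, truth, map = NULL) {
  stopifnot(inherits(fit, "fit_result"), inherits(truth, "synthetic_truth"))
  as_set <- function(x) {
    if (is.null(map)) unique(x) else collapse_probes_to_genes(x, map)$genes
  }
  rows <- lapply(c("up", "down"), function(dir) {
    recovered <- as_set(if (dir == "up") fit$up_core else fit$down_core)
    planted <- as_set(if (dir == "up") truth$core_up else truth$core_down)
    if (!length(planted)) {
      return(data.frame(direction = dir, n_recovered = length(recovered),
                        n_planted = 0L, tp = 0L, precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_,
                        empty_core = !length(recovered),
                        stringsAsFactors = FALSE))
    }
    tp <- length(intersect(recovered, planted))
    precision <- if (!length(recovered)) 0 else tp / length(recovered)
    recall <- tp / length(planted)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(direction = dir, n_recovered = length(recovered),
               n_planted = length(planted), tp = tp, precision = precision,
               recall = recall, f1 = f1, empty_core = !length(recovered),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
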