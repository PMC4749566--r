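#' Hypergeometric overrepresentation test across a gene-set collection
#'
#' One-sided upper-tail hypergeometric (Fisher's exact) p-value per set for
#' the overlap between a query gene set and each collection member, within a
#' stated gene universe, followed by Benjamini-Hochberg adjustment across all
#' tested sets. Sets are intersected with the universe before testing; exact
#' tail probabilities come from [stats::phyper()].
#'
#' @param query Character vector of query genes (must be within `universe`).
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param universe Character vector: the gene universe.
#' @return Data.frame ordered by `p`: `set_id`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `q`.
#' @examples
#' sets <- list(S1 = paste0("G", 1:5))
#' hypergeom_enrich(paste0("G", 1:5), sets, paste0("G", 1:20))
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(query) || !length(universe)) {
    stop("query and universe must be non-empty", call. = FALSE)
  }
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query gene(s) outside universe: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  if (!length(sets)) stop("empty gene-set collection", call. = FALSE)
  U <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    s <- intersect(unique(sets[[id]]), universe)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- if (K == 0L) 1 else stats::phyper(k - 1L, K, U - K, n,
                                           lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = K, query_size = n,
               universe_size = U, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_id), ]
  rownames(out) <- NULL
  out
}

#' Permutation test for interaction-network overlap between gene sets
#'
#' Counts interactions (edges above a strict confidence cut-off) connecting
#' two gene sets — either only edges bridging the two sets (`mode =
#' "between"`) or all edges within their union (`mode = "union"`) — and
#' compares the count with `B` node-label permutations drawing random sets of
#' matching sizes (and matching overlap) from the network's node space.
#' Significance uses the add-one empirical rule; a z-score against the
#' permutation mean/sd is also reported.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @param net A `fit_network` edge list (see [read_edges()]).
#' @param conf_min Confidence threshold; only edges with confidence strictly
#'   greater than this are used (default 0.7).
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @param mode `"between"` (edges with one endpoint in each set) or
#'   `"union"` (edges within the union of the sets).
#' @return An object of class `fit_overlap_test`: list with `observed`,
#'   `null_mean`, `null_sd`, `z`, `p`, `B`, `mode`, `conf_min`, `seed`, and
#'   the effective set sizes in the network node space.
#' @export
ppi_overlap_significance <- function(set_a, set_b, net, conf_min = 0.7,
                                     B = 1000L, seed,
                                     mode = c("between", "union")) {
  stopifnot(inherits(net, "fit_network"), B >= 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  mode <- match.arg(mode)
  keep <- net$confidence > conf_min
  if (!any(keep)) stop("no edges above confidence ", conf_min, call. = FALSE)
  ea <- net$a[keep]
  eb <- net$b[keep]
  nodes <- unique(c(ea, eb))
  a <- intersect(unique(set_a), nodes)
  b <- intersect(unique(set_b), nodes)
  if (!length(a)) stop("set_a has no genes in the network", call. = FALSE)
  if (!length(b)) stop("set_b has no genes in the network", call. = FALSE)
  count_edges <- function(sa, sb) {
    if (mode == "between") {
      sum((ea %in% sa & eb %in% sb) | (ea %in% sb & eb %in% sa))
    } else {
      u <- union(sa, sb)
      sum(ea %in% u & eb %in% u)
    }
  }
  observed <- count_edges(a, b)
  n_shared <- length(intersect(a, b))
  n_a <- length(a) - n_shared
  n_b <- length(b) - n_shared
  draws <- withr::with_seed(seed, {
    vapply(seq_len(B), function(i) {
      pick <- sample(nodes, n_a + n_b + n_shared)
      shared <- pick[seq_len(n_shared)]
      ra <- c(shared, pick[seq.int(n_shared + 1L, n_shared + n_a)])
      rb <- c(shared, pick[seq.int(n_shared + n_a + 1L, length(pick))])
      count_edges(ra, rb)
    }, numeric(1))
  })
  m <- mean(draws)
  s <- stats::sd(draws)
  structure(list(observed = observed,
                 null_mean = m,
                 null_sd = s,
                 z = if (isTRUE(s > 0)) (observed - m) / s else NA_real_,
                 p = (1 + sum(draws >= observed)) / (B + 1),
                 B = as.integer(B), mode = mode, conf_min = conf_min,
                 seed = seed, n_a = length(a), n_b = length(b),
                 n_shared = n_shared),
            class = "fit_overlap_test")
}

#' @export
print.fit_overlap_test <- function(x, ...) {
  cat("<fit_overlap_test> ", x$mode, ": observed ", x$observed,
      " edges vs null ", round(x$null_mean, 2), " +/- ",
      round(x$null_sd, 2), " (z = ", round(x$z, 2), ", p = ",
      signif(x$p, 3), ", B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Fold-enrichment of a core set across signature collections
#'
#' Mean fraction of the core probes present per signature in a foreground
#' collection (e.g. corrector drugs), divided by the same mean over a
#' background collection (e.g. random drugs). A background mean of zero gives
#' `Inf` flagged with attribute `degenerate_background = TRUE`.
#'
#' @param core Character vector of core probe ids.
#' @param drug_sigs List of `fit_signature` (foreground).
#' @param background_sigs List of `fit_signature` (background).
#' @param direction Which signature tail to interrogate: `"down"` (default)
#'   or `"up"`, matching the direction of the core.
#' @return Numeric fold-enrichment (possibly flagged `Inf`), with the two
#'   mean fractions in attributes `foreground_mean` and `background_mean`.
#' @export
core_frequency_fold <- function(core, drug_sigs, background_sigs,
                                direction = c("down", "up")) {
  direction <- match.arg(direction)
  core <- unique(as.character(core))
  if (!length(core)) stop("empty core set", call. = FALSE)
  frac <- function(sigs) {
    vapply(sigs, function(s) {
      length(intersect(core, s[[direction]])) / length(core)
    }, numeric(1))
  }
  mf <- mean(frac(drug_sigs))
  mb <- mean(frac(background_sigs))
  out <- if (mb == 0) structure(Inf, degenerate_background = TRUE) else mf / mb
  attr(out, "foreground_mean") <- mf
  attr(out, "background_mean") <- mb
  out
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Classic unweighted Kolmogorov-Smirnov enrichment score: walking down the
#' ranked list, the running sum gains `1/|S|` at each set member ("hit") and
#' loses `1/(U - |S|)` at each non-member; the score is the signed maximum
#' deviation from zero. Unweighted steps are the natural choice for prototype
#' ranked lists, which carry rank order but no expression magnitudes.
#'
#' @param set Character vector of probe/gene ids; must intersect the profile
#'   and must not cover the entire universe.
#' @param profile A [ranked_profile()] or a character vector in rank order.
#' @return The enrichment score in \[-1, 1\].
#' @export
gsea_es <- function(set, profile) {
  probes <- if (inherits(profile, "ranked_profile")) profile$probes
            else as.character(profile)
  hits <- probes %in% set
  nh <- sum(hits)
  if (nh == 0L) stop("set has no members in the profile universe", call. = FALSE)
  if (nh == length(probes)) {
    stop("set covers the entire universe", call. = FALSE)
  }
  steps <- ifelse(hits, 1 / nh, -1 / (length(probes) - nh))
  rs <- cumsum(steps)
  mx <- max(rs)
  mn <- min(rs)
  # signed maximum deviation; exact ties resolve to the positive excursion
  # (tolerance guards against accumulation-order rounding)
  if (mx >= -mn - 1e-12) mx else mn
}

#' Two-tailed enrichment score of a profile against an up/down query
#'
#' Scores how strongly a drug profile mimics a two-sided query signature:
#' the combined score is `(ES(up) - ES(down)) / 2`, so a drug placing the
#' query's up-set at its top and the down-set at its bottom scores near +1,
#' and a drug reversing the query scores near -1. This half-difference
#' combination is this package's stated convention for symmetric two-tailed
#' scoring.
#'
#' @param up,down Disjoint character vectors (the query's up- and down-sets).
#' @param profile A [ranked_profile()].
#' @return List with `es_up`, `es_down`, and combined `tes`.
#' @export
gsea_two_tailed <- function(up, down, profile) {
  if (length(intersect(up, down))) {
    stop("up and down query sets must be disjoint", call. = FALSE)
  }
  es_up <- gsea_es(up, profile)
  es_down <- gsea_es(down, profile)
  list(es_up = es_up, es_down = es_down, tes = (es_up - es_down) / 2)
}

#' Rank a compendium of drugs against a two-sided query signature
#'
#' Computes the two-tailed enrichment score of every profile in a compendium
#' against an up/down query (e.g. the CORE sets), then ranks drugs by
#' descending score. The top of the ranking holds query-mimicking drugs; the
#' bottom holds reversers — the candidate list for drugs that counteract the
#' query signature.
#'
#' One-sided queries are allowed (pass `NULL` or an empty vector for the
#' missing direction); the combined score is then the half-contribution of
#' the present side, keeping the ranking semantics unchanged.
#'
#' @param up,down Disjoint query sets (at most one may be empty/`NULL`).
#' @param x A `fit_compendium` to rank.
#' @return Data.frame ordered by descending `tes`: `drug_id`, `es_up`,
#'   `es_down`, `tes`, `rank`.
#' @export
gsea_rank_drugs <- function(up, down, x) {
  stopifnot(inherits(x, "fit_compendium"))
  has_up <- length(up) > 0L
  has_down <- length(down) > 0L
  if (!has_up && !has_down) stop("both query sets empty", call. = FALSE)
  if (has_up && has_down && length(intersect(up, down))) {
    stop("up and down query sets must be disjoint", call. = FALSE)
  }
  rows <- lapply(colnames(x$ranks), function(id) {
    prof <- profile_of(x, id)
    es_up <- if (has_up) gsea_es(up, prof) else NA_real_
    es_down <- if (has_down) gsea_es(down, prof) else NA_real_
    tes <- ((if (has_up) es_up else 0) - (if (has_down) es_down else 0)) / 2
    data.frame(drug_id = id, es_up = es_up, es_down = es_down,
               tes = tes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$tes, out$drug_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
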