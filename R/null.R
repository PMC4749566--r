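# Internal helpers shared by the two empirical null models and the scans.
# Tail membership is precomputed as logical matrices (probe x profile) so a
# null draw reduces to column sampling + rowSums.

.tail_membership <- function(x, f) {
  stopifnot(inherits(x, "fit_compendium"))
  u <- length(x$universe)
  m <- floor(f * u)
  if (m < 1L) stop("tail fraction too small: floor(f*U) = 0", call. = FALSE)
  n <- ncol(x$ranks)
  up <- matrix(FALSE, u, n, dimnames = list(x$universe, colnames(x$ranks)))
  down <- up
  for (j in seq_len(n)) {
    up[match(x$ranks[seq_len(m), j], x$universe), j] <- TRUE
    down[match(x$ranks[seq.int(u - m + 1L, u), j], x$universe), j] <- TRUE
  }
  list(up = up, down = down, n_tail = m)
}

# Cardinality of the fuzzy intersection at every k in 1..N, from a support
# vector, via tail-cumulated support histogram.
.cards_all_k <- function(support, N) {
  rev(cumsum(rev(tabulate(support, nbins = N))))
}

# B resampling draws of N profiles (without replacement) from a background
# membership matrix; returns a B x N cardinality matrix per direction.
.resample_cards <- function(mem, N, B) {
  M <- ncol(mem$up)
  up <- matrix(0L, B, N)
  down <- matrix(0L, B, N)
  for (b in seq_len(B)) {
    cols <- sample.int(M, N)
    up[b, ] <- .cards_all_k(rowSums(mem$up[, cols, drop = FALSE]), N)
    down[b, ] <- .cards_all_k(rowSums(mem$down[, cols, drop = FALSE]), N)
  }
  list(up = up, down = down)
}

# B probe-permutation draws: each iteration re-permutes every profile's rank
# order uniformly, so each profile contributes a random disjoint (up, down)
# tail pair of the original tail size.
.permute_cards <- function(U, n_tail, N, B) {
  up <- matrix(0L, B, N)
  down <- matrix(0L, B, N)
  lo <- seq_len(n_tail)
  hi <- seq.int(U - n_tail + 1L, U)
  for (b in seq_len(B)) {
    ui <- integer(0)
    di <- integer(0)
    for (i in seq_len(N)) {
      perm <- sample.int(U)
      ui <- c(ui, perm[lo])
      di <- c(di, perm[hi])
    }
    up[b, ] <- .cards_all_k(tabulate(ui, nbins = U), N)
    down[b, ] <- .cards_all_k(tabulate(di, nbins = U), N)
  }
  list(up = up, down = down)
}

.new_null <- function(cards, k_min, B, null_kind, N, f, seed) {
  structure(list(up = cards$up[, k_min], down = cards$down[, k_min],
                 B = B, null_kind = null_kind, N = N, k_min = k_min,
                 f = f, seed = seed),
            class = "fit_null")
}

#' Resampling null for the fuzzy-intersection cardinality
#'
#' Draws `B` pseudo-panels of `N` distinct profiles from a background
#' compendium (e.g. a large connectivity-map-style collection), extracts their
#' tail signatures, applies the fuzzy intersection at `k_min`, and records the
#' resulting cardinality per direction. This is the null of choice when a
#' large cross-platform background of ranked lists is available.
#'
#' @param background A `fit_compendium` of background profiles (>= `N`).
#' @param N Pseudo-panel size (number of profiles intersected per draw).
#' @param k_min Integer support threshold (see [min_support()]).
#' @param f Tail fraction.
#' @param B Number of iterations (default 1000).
#' @param seed Integer seed; the draw sequence is fully reproducible.
#' @return An object of class `fit_null` with integer vectors `up` and `down`
#'   of length `B`, plus provenance fields (`null_kind = "resampling"`).
#' @export
resampling_null <- function(background, N, k_min, f = 0.2, B = 1000L, seed) {
  stopifnot(inherits(background, "fit_compendium"))
  if (N > ncol(background$ranks)) {
    stop("N = ", N, " exceeds background size ", ncol(background$ranks),
         call. = FALSE)
  }
  stopifnot(B >= 1L, k_min >= 1L, k_min <= N)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  mem <- .tail_membership(background, f)
  cards <- withr::with_seed(seed, .resample_cards(mem, N, B))
  .new_null(cards, as.integer(k_min), as.integer(B), "resampling",
            as.integer(N), f, seed)
}

#' Probe-permutation null for the fuzzy-intersection cardinality
#'
#' For single-platform panels with no external background compendium, the
#' null randomly permutes each profile's probe order (independently, per
#' iteration), then extracts tails and intersects. Any shared structure among
#' the observed profiles is destroyed while tail sizes are preserved.
#'
#' @param x A `fit_compendium` (the observed panel; only its dimensions
#'   matter under this null).
#' @param k_min Integer support threshold.
#' @param f Tail fraction.
#' @param B Number of iterations.
#' @param seed Integer seed.
#' @return A `fit_null` with `null_kind = "probe_permutation"`.
#' @export
probe_permutation_null <- function(x, k_min, f = 0.2, B = 1000L, seed) {
  stopifnot(inherits(x, "fit_compendium"), B >= 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  N <- ncol(x$ranks)
  stopifnot(k_min >= 1L, k_min <= N)
  U <- length(x$universe)
  n_tail <- floor(f * U)
  if (n_tail < 1L) stop("tail fraction too small: floor(f*U) = 0", call. = FALSE)
  cards <- withr::with_seed(seed, .permute_cards(U, n_tail, N, B))
  .new_null(cards, as.integer(k_min), as.integer(B), "probe_permutation",
            as.integer(N), f, seed)
}

#' @export
print.fit_null <- function(x, ...) {
  cat("<fit_null> ", x$null_kind, ", B = ", x$B, ", N = ", x$N,
      ", k_min = ", x$k_min, ", f = ", x$f, "\n", sep = "")
  cat("  mean cardinality: up ", round(mean(x$up), 2), ", down ",
      round(mean(x$down), 2), "\n", sep = "")
  invisible(x)
}

.null_draws <- function(null, direction) {
  if (inherits(null, "fit_null")) {
    direction <- match.arg(direction, c("up", "down"))
    null[[direction]]
  } else {
    as.numeric(null)
  }
}

#' Empirical p-value against a null distribution
#'
#' Add-one empirical upper-tail p-value: `(1 + #\{null >= observed\}) / (B + 1)`,
#' which never returns 0 and is conservative (super-uniform) under the null.
#'
#' @param observed Observed intersection cardinality.
#' @param null A `fit_null` or a numeric vector of null draws.
#' @param direction `"up"` or `"down"` (used when `null` is a `fit_null`).
#' @return The empirical p-value in (0, 1].
#' @examples
#' empirical_p(999, 0:998) # greater than all 999 draws -> 1/1000
#' @export
empirical_p <- function(observed, null, direction = "up") {
  draws <- .null_draws(null, direction)
  (1 + sum(draws >= observed)) / (length(draws) + 1)
}

#' Signal-to-noise fold-ratio of an observed intersection
#'
#' Observed cardinality divided by the mean null cardinality (a
#' signal-to-noise ratio: 108 observed against an expected 32 gives 3.375).
#' A null with mean zero cannot calibrate a ratio; the result is then
#' `Inf` carrying attribute `degenerate_null = TRUE`.
#'
#' @inheritParams empirical_p
#' @return Numeric fold-ratio, possibly `Inf` (flagged).
#' @examples
#' fold_ratio(108, rep(32, 1000)) # 3.375
#' @export
fold_ratio <- function(observed, null, direction = "up") {
  draws <- .null_draws(null, direction)
  m <- mean(draws)
  if (m == 0) {
    return(structure(Inf, degenerate_null = TRUE))
  }
  observed / m
}

#' Scan candidate support thresholds against an empirical null
#'
#' For every `k` in `k_range` and both directions, computes the observed core
#' size, the mean null cardinality, the fold-ratio and the add-one empirical
#' p-value. One set of `B` null draws is shared across all `k` (each draw is
#' thresholded at every candidate cut-off), matching how the cut-off scan is
#' defined and keeping the per-`k` statistics mutually consistent.
#'
#' The fold-ratio denominator is floored at `eps` (default `1/B`, the
#' smallest nonzero mean estimable from `B` draws) so the scan table stays
#' finite; rows whose raw null mean is exactly zero are flagged in the
#' `degenerate_null` column.
#'
#' @param x A `fit_compendium`: the observed panel (e.g. the corrector drugs).
#' @param background Optional background `fit_compendium` for the resampling
#'   null; when absent, the probe-permutation null is used.
#' @param f Tail fraction.
#' @param k_range Integer vector of candidate thresholds (default `1:N`).
#' @param B Null iterations.
#' @param seed Integer seed.
#' @param null_kind `"auto"` (resampling if a background is supplied, else
#'   probe permutation), `"resampling"`, or `"probe_permutation"`.
#' @param eps Floor for the fold-ratio denominator (default `1/B`).
#' @return A data.frame of class `fit_scan` with columns `k`, `direction`,
#'   `observed`, `null_mean`, `fold`, `p`, `degenerate_null`; scan metadata in
#'   attributes (`N`, `f`, `B`, `null_kind`, `seed`, `eps`).
#' @export
cutoff_scan <- function(x, background = NULL, f = 0.2, k_range = NULL,
                        B = 1000L, seed,
                        null_kind = c("auto", "resampling", "probe_permutation"),
                        eps = NULL) {
  stopifnot(inherits(x, "fit_compendium"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  null_kind <- match.arg(null_kind)
  if (null_kind == "auto") {
    null_kind <- if (is.null(background)) "probe_permutation" else "resampling"
  }
  if (null_kind == "resampling" && is.null(background)) {
    stop("resampling null requires a background compendium", call. = FALSE)
  }
  N <- ncol(x$ranks)
  if (is.null(k_range)) k_range <- seq_len(N)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1L || max(k_range) > N) {
    stop("k_range must lie within [1, N = ", N, "]", call. = FALSE)
  }
  if (is.null(eps)) eps <- 1 / B
  sup <- support_counts(signatures(x, f))
  obs <- list(up = .cards_all_k(sup$up, N), down = .cards_all_k(sup$down, N))
  cards <- if (null_kind == "resampling") {
    if (N > ncol(background$ranks)) {
      stop("N = ", N, " exceeds background size ", ncol(background$ranks),
           call. = FALSE)
    }
    mem <- .tail_membership(background, f)
    withr::with_seed(seed, .resample_cards(mem, N, B))
  } else {
    U <- length(x$universe)
    withr::with_seed(seed, .permute_cards(U, floor(f * U), N, B))
  }
  rows <- lapply(c("up", "down"), function(dir) {
    nm <- colMeans(cards[[dir]][, k_range, drop = FALSE])
    p <- vapply(seq_along(k_range), function(i) {
      empirical_p(obs[[dir]][k_range[i]], cards[[dir]][, k_range[i]])
    }, numeric(1))
    data.frame(k = k_range, direction = dir,
               observed = obs[[dir]][k_range],
               null_mean = nm,
               fold = obs[[dir]][k_range] / pmax(nm, eps),
               p = p,
               degenerate_null = nm == 0,
               stringsAsFactors = FALSE)
  })
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  structure(scan, N = N, f = f, B = as.integer(B), null_kind = null_kind,
            seed = seed, eps = eps,
            class = c("fit_scan", "data.frame"))
}

#' Select the support threshold from a cut-off scan
#'
#' A threshold `k` passes when its fold-ratio is at least `fold_min` and its
#' empirical p-value is at most `alpha` (the "at least threefold above chance
#' and significant" rule). The default selection takes the *minimal* passing
#' `k` per direction — the significance screen establishes the lower edge of
#' the usable range, and at that edge the fold-ratio sits near `fold_min`,
#' mirroring how the optimum is reported for real corrector panels; the
#' maximal enriched threshold within the passing range is then the job of
#' [refine_cutoff_by_enrichment()]. Set `rule = "max"` for the most stringent
#' passing threshold instead. No passing `k` is a valid outcome (`NA`).
#'
#' @param scan A `fit_scan` from [cutoff_scan()].
#' @param fold_min Minimum fold-ratio (default 3).
#' @param alpha Maximum empirical p-value (default 0.05).
#' @param rule `"min"` (default) or `"max"` passing threshold.
#' @return A data.frame of class `fit_selection` with one row per direction:
#'   `direction`, `k` (NA if none passes), `theta` (`k/N`), `n_passing`; the
#'   scan and rule are kept as attributes.
#' @export
select_cutoff <- function(scan, fold_min = 3, alpha = 0.05,
                          rule = c("min", "max")) {
  stopifnot(inherits(scan, "fit_scan"))
  rule <- match.arg(rule)
  N <- attr(scan, "N")
  rows <- lapply(c("up", "down"), function(dir) {
    s <- scan[scan$direction == dir, ]
    pass <- s$k[s$fold >= fold_min & s$p <= alpha]
    k <- if (!length(pass)) NA_integer_
         else if (rule == "min") min(pass) else max(pass)
    data.frame(direction = dir, k = k,
               theta = if (is.na(k)) NA_real_ else k / N,
               n_passing = length(pass), stringsAsFactors = FALSE)
  })
  sel <- do.call(rbind, rows)
  structure(sel, scan = scan, fold_min = fold_min, alpha = alpha, rule = rule,
            class = c("fit_selection", "data.frame"))
}

#' Refine the selected cut-off by gene-set enrichment
#'
#' Among the thresholds passing the fold/p screen, returns per direction the
#' *maximal* `k` whose gene-collapsed core is enriched (BH-adjusted q <=
#' `alpha`) in at least one supplied gene set. When no passing threshold is
#' enriched, falls back to the [select_cutoff()] result with `refined =
#' FALSE`.
#'
#' @param scan A `fit_scan`.
#' @param fits_by_k Named list of `fit_result` objects, names = `k` values
#'   covering the scan's passing range.
#' @param sets A `gene_set_collection` (see [read_gmt()]).
#' @param map Probe-to-gene data.frame (see [read_probe_gene_map()]).
#' @param alpha BH-adjusted significance level for enrichment (default 0.05).
#' @param fold_min Fold-ratio screen passed through to the selection step.
#' @return Data.frame with one row per direction: `direction`, `k`,
#'   `refined` (logical: did enrichment confirm the threshold).
#' @export
refine_cutoff_by_enrichment <- function(scan, fits_by_k, sets, map,
                                        alpha = 0.05, fold_min = 3) {
  stopifnot(inherits(scan, "fit_scan"), is.list(fits_by_k))
  if (!length(sets)) stop("empty gene-set collection", call. = FALSE)
  base <- select_cutoff(scan, fold_min = fold_min, alpha = alpha, rule = "min")
  universe_genes <- collapse_probes_to_genes(
    fits_by_k[[1L]]$support$probe, map)$genes
  rows <- lapply(c("up", "down"), function(dir) {
    s <- scan[scan$direction == dir, ]
    pass <- sort(s$k[s$fold >= fold_min & s$p <= alpha], decreasing = TRUE)
    for (k in pass) {
      fit <- fits_by_k[[as.character(k)]]
      if (is.null(fit)) next
      core <- if (dir == "up") fit$up_core else fit$down_core
      genes <- collapse_probes_to_genes(core, map)$genes
      if (!length(genes)) next
      enr <- hypergeom_enrich(genes, sets, universe_genes)
      if (any(enr$q <= alpha)) {
        return(data.frame(direction = dir, k = as.integer(k), refined = TRUE,
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(direction = dir, k = base$k[base$direction == dir],
               refined = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Plateau rule: smallest scanned N from which every subsequent relative step
# |c(N+1)-c(N)| / c(N) stays below eps through the end of the range.
.find_plateau <- function(values, eps) {
  n <- length(values)
  if (n < 2L) return(NA_integer_)
  rel <- abs(diff(values)) / pmax(values[-n], .Machine$double.eps)
  ok <- rel < eps
  stable <- rev(cumprod(rev(ok))) == 1
  if (!any(stable)) return(NA_integer_)
  which(stable)[1L]
}

#' Scan panel size at a fixed fuzzy cut-off (plateau analysis)
#'
#' Holds the fuzzy cut-off `theta` constant, varies the number `N` of randomly
#' drawn background profiles, and records the mean null intersection
#' cardinality at `k = min_support(N, theta)` over `B` draws per `N`. The
#' curve's plateau locates the panel size beyond which additional profiles no
#' longer shrink the chance-level intersection — the scale at which the panel
#' size is adequate.
#'
#' @param background Background `fit_compendium`.
#' @param theta Fuzzy cut-off held constant across `N`.
#' @param N_range Integer vector of panel sizes to scan.
#' @param f Tail fraction.
#' @param B Draws per panel size.
#' @param seed Integer seed.
#' @param eps Relative-change tolerance defining the plateau (default 0.02,
#'   sustained through the end of the scanned range).
#' @return Data.frame of class `fit_plateau` with columns `N`, `direction`,
#'   `mean_cardinality`, `is_plateau`; plateau sizes per direction in the
#'   `plateau` attribute (`NA` when no plateau is reached in range).
#' @export
plateau_scan <- function(background, theta = 0.7, N_range, f = 0.2,
                         B = 1000L, seed, eps = 0.02) {
  stopifnot(inherits(background, "fit_compendium"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  N_range <- sort(unique(as.integer(N_range)))
  if (max(N_range) > ncol(background$ranks)) {
    stop("N_range exceeds background size ", ncol(background$ranks),
         call. = FALSE)
  }
  mem <- .tail_membership(background, f)
  means <- withr::with_seed(seed, {
    lapply(N_range, function(N) {
      k <- min_support(N, theta)
      cards <- .resample_cards(mem, N, B)
      c(up = mean(cards$up[, k]), down = mean(cards$down[, k]))
    })
  })
  up <- vapply(means, `[[`, numeric(1), "up")
  down <- vapply(means, `[[`, numeric(1), "down")
  plateau <- c(up = .find_plateau(up, eps), down = .find_plateau(down, eps))
  plateau_N <- ifelse(is.na(plateau), NA_integer_, N_range[plateau])
  names(plateau_N) <- names(plateau)
  flag <- function(idx) {
    f <- rep(FALSE, length(N_range))
    if (!is.na(idx)) f[seq.int(idx, length(N_range))] <- TRUE
    f
  }
  out <- rbind(
    data.frame(N = N_range, direction = "up", mean_cardinality = up,
               is_plateau = flag(plateau[["up"]]), stringsAsFactors = FALSE),
    data.frame(N = N_range, direction = "down", mean_cardinality = down,
               is_plateau = flag(plateau[["down"]]), stringsAsFactors = FALSE))
  structure(out, theta = theta, f = f, B = as.integer(B), seed = seed,
            eps = eps, plateau = plateau_N,
            class = c("fit_plateau", "data.frame"))
}
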