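#' Extract a tail signature from a ranked profile
#'
#' The signature of a profile is its two rank tails: the top fraction `f` of
#' probes as the upregulated set and the bottom fraction `f` as the
#' downregulated set (default 20% each, the tail width appropriate for
#' prototype ranked lists where fold-change or p-value thresholds are not
#' applicable). Tail size is `floor(f * U)`.
#'
#' @param profile A [ranked_profile()].
#' @param f Tail fraction in (0, 0.5]; beyond 0.5 the tails would overlap.
#' @return An object of class `fit_signature` with elements `drug_id`, `up`,
#'   `down`, `f`, and `universe` (sorted).
#' @examples
#' p <- ranked_profile("d", paste0("P", sprintf("%02d", 1:10)))
#' extract_signature(p, 0.2)
#' @export
extract_signature <- function(profile, f = 0.2) {
  stopifnot(inherits(profile, "ranked_profile"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 0.5) {
    stop("tail fraction f must lie in (0, 0.5]", call. = FALSE)
  }
  u <- length(profile$probes)
  m <- floor(f * u)
  if (m < 1L) stop("tail fraction too small: floor(f*U) = 0", call. = FALSE)
  structure(list(drug_id = profile$drug_id,
                 up = profile$probes[seq_len(m)],
                 down = profile$probes[seq.int(u - m + 1L, u)],
                 f = f,
                 universe = sort(profile$probes)),
            class = "fit_signature")
}

#' @export
print.fit_signature <- function(x, ...) {
  cat("<fit_signature> ", x$drug_id, ": |up| = ", length(x$up),
      ", |down| = ", length(x$down), " (f = ", x$f, ", U = ",
      length(x$universe), ")\n", sep = "")
  invisible(x)
}

#' Extract signatures for every profile in a compendium
#'
#' @param x A `fit_compendium`.
#' @param f Tail fraction passed to [extract_signature()].
#' @return List of `fit_signature` objects, one per profile.
#' @export
signatures <- function(x, f = 0.2) {
  stopifnot(inherits(x, "fit_compendium"))
  lapply(colnames(x$ranks), function(id) extract_signature(profile_of(x, id), f))
}

#' Integer support threshold for a fuzzy cut-off
#'
#' Converts the fuzzy cut-off theta — the fraction of profiles a probe must
#' respond in to count as consistently regulated — into the minimum integer
#' support `ceiling(theta * N)`, clamped to \[1, N\]. With 11 profiles and
#' theta 0.7 this gives 8 ("8 out of 11 drugs").
#'
#' @param N Number of profiles (>= 1).
#' @param theta Fuzzy cut-off in (0, 1].
#' @return Integer support threshold.
#' @examples
#' min_support(11, 0.7) # 8
#' @export
min_support <- function(N, theta) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1, N == as.integer(N))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1) {
    stop("theta must lie in (0, 1]", call. = FALSE)
  }
  as.integer(min(max(ceiling(theta * N), 1L), N))
}

#' Per-probe, per-direction support counts across signatures
#'
#' Counts, for every probe of the shared universe, how many signatures carry
#' it in their up-set and (independently) in their down-set. This table is the
#' raw material of the fuzzy intersection.
#'
#' @param sigs List of `fit_signature` objects over one shared universe.
#' @return An object of class `fit_support`: list with `probe` (sorted
#'   universe), integer vectors `up` and `down`, `N`, `n_tail`, and `f`.
#' @examples
#' comp <- rank_from_expression(matrix(rnorm(300), 100, 3,
#'   dimnames = list(sprintf("P%03d", 1:100), paste0("d", 1:3))))
#' s <- support_counts(signatures(comp, 0.2))
#' table(s$up)
#' @export
support_counts <- function(sigs) {
  stopifnot(is.list(sigs), length(sigs) >= 1L)
  ok <- vapply(sigs, inherits, logical(1), "fit_signature")
  if (!all(ok)) stop("all elements must be fit_signature objects", call. = FALSE)
  universe <- sigs[[1L]]$universe
  for (s in sigs[-1L]) {
    if (!identical(s$universe, universe)) {
      stop("signatures come from different probe universes ('",
           s$drug_id, "')", call. = FALSE)
    }
  }
  up <- integer(length(universe))
  down <- integer(length(universe))
  for (s in sigs) {
    up <- up + tabulate(match(s$up, universe), nbins = length(universe))
    down <- down + tabulate(match(s$down, universe), nbins = length(universe))
  }
  structure(list(probe = universe, up = up, down = down,
                 N = length(sigs),
                 n_tail = length(sigs[[1L]]$up),
                 f = sigs[[1L]]$f),
            class = "fit_support")
}

#' @export
print.fit_support <- function(x, ...) {
  cat("<fit_support> ", length(x$probe), " probes, N = ", x$N,
      " signatures, tail = ", x$n_tail, " probes\n", sep = "")
  invisible(x)
}

#' Threshold a support table into CORE probe sets (the fuzzy intersection)
#'
#' A probe enters the up-core when its up-support reaches `k_min`, and
#' likewise for the down-core; the two directions are computed and reported
#' separately and never merged. `k_min = 1` gives the union of the
#' signatures, `k_min = N` the classical intersection.
#'
#' @param support A `fit_support` table.
#' @param k_min Integer support threshold in \[1, N\] (see [min_support()]).
#' @return An object of class `fit_result`: list with `up_core`, `down_core`,
#'   `k_min`, `N`, and the `support` table.
#' @export
fuzzy_intersect <- function(support, k_min) {
  stopifnot(inherits(support, "fit_support"))
  if (!is.numeric(k_min) || length(k_min) != 1L || k_min != as.integer(k_min) ||
      k_min < 1L || k_min > support$N) {
    stop("k_min must be an integer in [1, N = ", support$N, "]", call. = FALSE)
  }
  k_min <- as.integer(k_min)
  up_core <- support$probe[support$up >= k_min]
  down_core <- support$probe[support$down >= k_min]
  both <- intersect(up_core, down_core)
  if (length(both)) {
    warning(length(both), " probe(s) pass both the up and down thresholds: ",
            paste(utils::head(both, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(up_core = up_core, down_core = down_core,
                 k_min = k_min, N = support$N, support = support),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> k_min = ", x$k_min, " / N = ", x$N, ": ",
      length(x$up_core), " up-core, ", length(x$down_core),
      " down-core probes\n", sep = "")
  invisible(x)
}

#' Serialize a fuzzy-intersection result as TSV
#'
#' One row per probe and direction with its support count and core-membership
#' flag, restricted by default to probes with nonzero support.
#'
#' @param x A `fit_result`.
#' @param path Output TSV path.
#' @param all_probes Include zero-support probes too?
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(x, path, all_probes = FALSE) {
  stopifnot(inherits(x, "fit_result"))
  s <- x$support
  tab <- rbind(
    data.frame(probe = s$probe, direction = "up", support = s$up,
               stringsAsFactors = FALSE),
    data.frame(probe = s$probe, direction = "down", support = s$down,
               stringsAsFactors = FALSE))
  if (!all_probes) tab <- tab[tab$support > 0L, ]
  tab$N <- x$N
  tab$k_min <- x$k_min
  tab$in_core <- tab$support >= x$k_min
  tab <- tab[order(tab$direction, -tab$support, tab$probe), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
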