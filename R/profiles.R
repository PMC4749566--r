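#' Construct a ranked expression profile
#'
#' A ranked profile is one perturbagen's full ordered probe-set list, from the
#' most upregulated probe (rank 1) to the most downregulated (rank U). Ranks
#' are stored 0-based internally nowhere; the probe order itself is the data.
#'
#' @param drug_id Single character label for the perturbagen/condition.
#' @param probes Character vector of unique probe-set identifiers in rank
#'   order, most upregulated first.
#' @return An object of class `ranked_profile`.
#' @examples
#' p <- ranked_profile("tunicamycin", paste0("P", 1:20))
#' head(p$probes)
#' @export
ranked_profile <- function(drug_id, probes) {
  stopifnot(is.character(drug_id), length(drug_id) == 1L, nzchar(drug_id))
  probes <- as.character(probes)
  if (length(probes) < 10L) {
    stop("profile '", drug_id, "' has fewer than 10 probes", call. = FALSE)
  }
  dup <- probes[duplicated(probes)]
  if (length(dup)) {
    stop("duplicate probe(s) in profile '", drug_id, "': ",
         paste(utils::head(unique(dup), 10L), collapse = ", "), call. = FALSE)
  }
  structure(list(drug_id = drug_id, probes = probes), class = "ranked_profile")
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat("<ranked_profile> ", x$drug_id, ": ", length(x$probes), " probes (",
      x$probes[1L], " ... ", x$probes[length(x$probes)], ")\n", sep = "")
  invisible(x)
}

#' Assemble ranked profiles into a compendium
#'
#' A compendium is a collection of ranked profiles over one shared probe
#' universe (every profile is a permutation of the same probe set), the form
#' in which connectivity-map-style prototype ranked lists are distributed.
#'
#' @param profiles List of [ranked_profile()] objects with distinct drug ids.
#' @return An object of class `fit_compendium` with elements `ranks` (a
#'   character matrix, one column per drug, rows in rank order) and `universe`
#'   (the sorted shared probe set).
#' @examples
#' ps <- lapply(1:3, function(i) {
#'   ranked_profile(paste0("drug", i), sample(paste0("P", 1:20)))
#' })
#' compendium(ps)
#' @export
compendium <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  ok <- vapply(profiles, inherits, logical(1), "ranked_profile")
  if (!all(ok)) stop("all elements must be ranked_profile objects", call. = FALSE)
  ids <- vapply(profiles, `[[`, character(1), "drug_id")
  if (anyDuplicated(ids)) {
    stop("duplicate drug ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  universe <- sort(profiles[[1L]]$probes)
  for (p in profiles) {
    if (length(p$probes) != length(universe) ||
        !identical(sort(p$probes), universe)) {
      diff <- c(setdiff(p$probes, universe), setdiff(universe, p$probes))
      stop("probe universe mismatch for profile '", p$drug_id,
           "'; symmetric difference (first 10): ",
           paste(utils::head(sort(diff), 10L), collapse = ", "), call. = FALSE)
    }
  }
  ranks <- vapply(profiles, `[[`, character(length(universe)), "probes")
  colnames(ranks) <- ids
  structure(list(ranks = ranks, universe = universe), class = "fit_compendium")
}

#' @export
print.fit_compendium <- function(x, ...) {
  cat("<fit_compendium> ", ncol(x$ranks), " profiles over ",
      length(x$universe), " probes\n", sep = "")
  cat("  drugs: ", paste(utils::head(colnames(x$ranks), 6L), collapse = ", "),
      if (ncol(x$ranks) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of profiles in a compendium
#' @param x A `fit_compendium`.
#' @return Integer count of profiles.
#' @export
n_profiles <- function(x) {
  stopifnot(inherits(x, "fit_compendium"))
  ncol(x$ranks)
}

#' Extract one profile from a compendium
#' @param x A `fit_compendium`.
#' @param drug_id Drug label or column index.
#' @return A [ranked_profile()].
#' @export
profile_of <- function(x, drug_id) {
  stopifnot(inherits(x, "fit_compendium"))
  if (is.character(drug_id) && !drug_id %in% colnames(x$ranks)) {
    stop("no profile named '", drug_id, "'", call. = FALSE)
  }
  id <- if (is.character(drug_id)) drug_id else colnames(x$ranks)[drug_id]
  ranked_profile(id, x$ranks[, drug_id])
}

#' Subset a compendium by drug id
#' @param x A `fit_compendium`.
#' @param drug_ids Character vector of drug labels (or column indices).
#' @return A `fit_compendium` restricted to the requested profiles.
#' @export
subset_compendium <- function(x, drug_ids) {
  stopifnot(inherits(x, "fit_compendium"))
  if (is.character(drug_ids)) {
    missing_ids <- setdiff(drug_ids, colnames(x$ranks))
    if (length(missing_ids)) {
      stop("no profile(s) named: ",
           paste(utils::head(missing_ids, 10L), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(ranks = x$ranks[, drug_ids, drop = FALSE],
                 universe = x$universe),
            class = "fit_compendium")
}

#' Rank an expression matrix into a compendium
#'
#' Orders each column of a signed score matrix (e.g. log fold-changes versus
#' control) from the highest to the lowest value, producing one ranked profile
#' per column. Ties are broken by ascending probe-id lexicographic order, a
#' documented deterministic rule.
#'
#' @param mat Numeric matrix, rows = probes (rownames required), columns =
#'   drugs (colnames required). Entries must be finite.
#' @return A `fit_compendium`.
#' @examples
#' m <- matrix(c(2, -1, 0), dimnames = list(c("P1", "P2", "P3"), "drugA"))
#' rank_from_expression(m)$ranks[, 1]
#' @export
rank_from_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("mat must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("mat must have probe rownames and drug colnames", call. = FALSE)
  }
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite score at (", rownames(mat)[bad[1L, 1L]], ", ",
         colnames(mat)[bad[1L, 2L]], ")", call. = FALSE)
  }
  probes <- rownames(mat)
  profiles <- lapply(seq_len(ncol(mat)), function(j) {
    # descending score; ties by ascending probe id (order() is stable and
    # probes enter pre-sorted as the secondary key)
    o <- order(-mat[, j], probes, method = "radix")
    ranked_profile(colnames(mat)[j], probes[o])
  })
  compendium(profiles)
}
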