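#' Read ranked profiles from disk
#'
#' Two layouts are accepted. A single wide TSV: one column per drug, header
#' row of drug ids, rows in rank order (most upregulated first), cells holding
#' probe ids. Or a directory of per-drug two-column TSVs (`rank<TAB>probe`),
#' the drug id taken from the file name minus its extension. Lines starting
#' with `#` are ignored in either layout.
#'
#' @param path Path to a wide TSV file or to a directory of per-drug files.
#' @return A [compendium()].
#' @seealso [write_ranked_profiles()] for the inverse.
#' @export
read_ranked_profiles <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    if (!length(files)) stop("no profile files in ", path, call. = FALSE)
    profiles <- lapply(files, function(f) {
      tab <- utils::read.delim(f, header = FALSE, comment.char = "#",
                               colClasses = "character")
      if (ncol(tab) != 2L) {
        stop("expected 2 columns (rank, probe) in ", f, call. = FALSE)
      }
      o <- order(as.integer(tab[[1L]]))
      ranked_profile(sub("\\.[^.]*$", "", basename(f)), tab[[2L]][o])
    })
    return(compendium(profiles))
  }
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  if (!nrow(tab) || !ncol(tab)) stop("empty profile table: ", path, call. = FALSE)
  compendium(lapply(names(tab), function(id) ranked_profile(id, tab[[id]])))
}

#' Write a compendium as a wide ranked-profile TSV
#'
#' @param x A `fit_compendium`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_profiles <- function(x, path) {
  stopifnot(inherits(x, "fit_compendium"))
  utils::write.table(x$ranks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV (`probe<TAB>gene_symbol`), `#` comments ignored. Many probes
#' may map to one gene; a probe mapping to two different genes is an error.
#' Probes absent from the table are simply unmapped.
#'
#' @param path Path to the mapping TSV.
#' @return A data.frame with columns `probe`, `gene`.
#' @export
read_probe_gene_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) != 2L) stop("expected 2 columns (probe, gene)", call. = FALSE)
  map <- unique(data.frame(probe = tab[[1L]], gene = tab[[2L]],
                           stringsAsFactors = FALSE))
  dup <- map$probe[duplicated(map$probe)]
  if (length(dup)) {
    stop("probe(s) mapped to more than one gene: ",
         paste(utils::head(unique(dup), 10L), collapse = ", "), call. = FALSE)
  }
  map
}

#' Collapse a probe set to its distinct gene symbols
#'
#' Unmapped probes are dropped (with a count returned, not an error): the
#' fuzzy intersection itself runs at probe level and gene identity only
#' matters for downstream enrichment and reporting.
#'
#' @param probes Character vector of probe ids.
#' @param map Probe-to-gene data.frame from [read_probe_gene_map()] (columns
#'   `probe`, `gene`).
#' @return List with `genes` (unique mapped symbols), `n_unmapped`, and
#'   `unmapped` (the unmapped probe ids).
#' @examples
#' map <- data.frame(probe = c("PA", "PB"), gene = c("G1", "G1"))
#' collapse_probes_to_genes(c("PA", "PB", "PX"), map)
#' @export
collapse_probes_to_genes <- function(probes, map) {
  stopifnot(is.data.frame(map), all(c("probe", "gene") %in% names(map)))
  probes <- unique(as.character(probes))
  idx <- match(probes, map$probe)
  unmapped <- probes[is.na(idx)]
  list(genes = unique(map$gene[idx[!is.na(idx)]]),
       n_unmapped = length(unmapped),
       unmapped = unmapped)
}

#' Read a gene-set collection in GMT format
#'
#' Broad-dialect GMT: tab-separated `set_id`, `description`, then one or more
#' member gene symbols. Members are deduplicated; empty sets are an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (class `gene_set_collection`);
#'   descriptions kept in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("malformed GMT line ", i, ": need set_id, description, >=1 member",
           call. = FALSE)
    }
    ids[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- ids
  structure(sets, descriptions = stats::setNames(desc, ids),
            class = "gene_set_collection")
}

#' Read a scored interaction network edge list
#'
#' Three-column TSV (`gene_a`, `gene_b`, `confidence`), `#` comments ignored.
#' Confidences must parse as numbers in \[0, 1\]; self-edges are dropped with
#' a warning; duplicate undirected edges keep their maximum confidence.
#'
#' @param path Path to the edge TSV.
#' @return A data.frame of class `fit_network` with columns `a`, `b`,
#'   `confidence` (undirected, `a` < `b` lexicographically).
#' @export
read_edges <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) != 3L) {
    stop("expected 3 columns (gene_a, gene_b, confidence)", call. = FALSE)
  }
  conf <- suppressWarnings(as.numeric(tab[[3L]]))
  bad <- which(is.na(conf) | conf < 0 | conf > 1)
  if (length(bad)) {
    stop("invalid confidence '", tab[[3L]][bad[1L]], "' at line ", bad[1L],
         call. = FALSE)
  }
  a <- tab[[1L]]; b <- tab[[2L]]
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped", call. = FALSE)
    a <- a[!self]; b <- b[!self]; conf <- conf[!self]
  }
  if (!length(a)) stop("no edges left after filtering", call. = FALSE)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  conf <- vapply(split(conf, key), max, numeric(1))
  pair <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
  net <- data.frame(a = pair[, 1L], b = pair[, 2L],
                    confidence = unname(conf), stringsAsFactors = FALSE)
  class(net) <- c("fit_network", "data.frame")
  net
}
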