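# End-to-end orchestration: config validation, the FIT stage (signatures ->
# scan -> selection -> cores), and the downstream stage (enrichment, PPI
# overlap, core-frequency fold, drug re-ranking), with TSV reports and a JSON
# manifest recording every seed and parameter so runs are reproducible
# byte-for-byte.

.default_config <- function() {
  list(f = 0.2, k_range = NULL, B = 1000L, seed = 1L,
       fold_min = 3, alpha = 0.05, null_kind = "auto",
       refine = FALSE, conf_min = 0.7, plateau_eps = 0.02,
       selection_rule = "min", out_dir = NULL)
}

.resolve <- function(x, reader) {
  if (is.null(x) || !is.character(x)) x else reader(x)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_fit()]/[run_downstream()]; file-path
#' values (`profiles`, `background`, `gene_sets`, `probe_gene_map`,
#' `network`) are kept as paths and loaded at validation time. Missing keys
#' take package defaults.
#'
#' @param path Path to a YAML config file.
#' @return A config list (class `fit_config`).
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  cfg <- yaml::yaml.load_file(path)
  validate_config(cfg)
}

#' Validate and complete a run configuration
#'
#' Fills defaults, loads any referenced files (erroring before compute if a
#' path is missing), and checks parameter ranges against the module
#' contracts.
#'
#' @param config Named list; see [run_fit()] for recognized fields.
#' @return A completed config list of class `fit_config`.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.default_config(), config)
  for (key in c("profiles", "background", "gene_sets", "probe_gene_map",
                "network")) {
    val <- cfg[[key]]
    if (is.character(val) && !file.exists(val)) {
      stop("config field '", key, "': file not found: ", val, call. = FALSE)
    }
  }
  cfg$profiles <- .resolve(cfg$profiles, read_ranked_profiles)
  cfg$background <- .resolve(cfg$background, read_ranked_profiles)
  cfg$gene_sets <- .resolve(cfg$gene_sets, read_gmt)
  cfg$probe_gene_map <- .resolve(cfg$probe_gene_map, read_probe_gene_map)
  cfg$network <- .resolve(cfg$network, read_edges)
  if (is.null(cfg$profiles)) stop("config needs 'profiles'", call. = FALSE)
  if (!inherits(cfg$profiles, "fit_compendium")) {
    stop("'profiles' must be a compendium or a path to one", call. = FALSE)
  }
  if (cfg$f <= 0 || cfg$f > 0.5) stop("f must lie in (0, 0.5]", call. = FALSE)
  if (cfg$B < 1L) stop("B must be >= 1", call. = FALSE)
  if (isTRUE(cfg$refine) &&
      (is.null(cfg$gene_sets) || is.null(cfg$probe_gene_map))) {
    stop("refine = TRUE requires 'gene_sets' and 'probe_gene_map'",
         call. = FALSE)
  }
  structure(cfg, class = c("fit_config", "list"))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.manifest <- function(cfg, stage, extra = list()) {
  keep <- c("f", "B", "seed", "fold_min", "alpha", "null_kind", "refine",
            "conf_min", "plateau_eps", "selection_rule")
  c(list(package = "fitcore",
         version = as.character(utils::packageVersion("fitcore")),
         stage = stage),
    cfg[keep], extra)
}

#' Run the FIT stage end-to-end
#'
#' Signatures -> support counts -> cut-off scan against the configured null
#' -> threshold selection (optionally refined by gene-set enrichment) ->
#' direction-specific CORE probe sets, gene-collapsed when a probe-to-gene
#' map is configured. When `out_dir` is set, writes `scan.tsv`,
#' `selection.tsv`, `fit_up.tsv`/`fit_down.tsv`, `core_genes.tsv` and
#' `manifest.json`; reruns with the same config are byte-identical.
#'
#' @param config Named list or `fit_config`. Recognized fields: `profiles`
#'   (compendium or path; required), `background` (compendium or path, for
#'   the resampling null), `f`, `k_range`, `B`, `seed`, `fold_min`, `alpha`,
#'   `null_kind`, `refine`, `gene_sets`, `probe_gene_map`,
#'   `selection_rule` (`"min"`/`"max"`), `out_dir`.
#' @return List with `scan`, `selection`, `refined` (or NULL), `fits`
#'   (per-direction `fit_result` at the selected `k`, NULL where nothing was
#'   selected), `cores` (per-direction probe and gene lists), `config`, and
#'   `manifest`.
#' @export
run_fit <- function(config) {
  cfg <- if (inherits(config, "fit_config")) config else validate_config(config)
  scan <- cutoff_scan(cfg$profiles, background = cfg$background, f = cfg$f,
                      k_range = cfg$k_range, B = cfg$B, seed = cfg$seed,
                      null_kind = cfg$null_kind)
  selection <- select_cutoff(scan, fold_min = cfg$fold_min, alpha = cfg$alpha,
                             rule = cfg$selection_rule)
  sup <- support_counts(signatures(cfg$profiles, cfg$f))
  passing <- unique(scan$k[scan$fold >= cfg$fold_min & scan$p <= cfg$alpha])
  fits_by_k <- stats::setNames(
    lapply(passing, function(k) suppressWarnings(fuzzy_intersect(sup, k))),
    passing)
  refined <- NULL
  chosen <- stats::setNames(selection$k, selection$direction)
  if (isTRUE(cfg$refine) && length(fits_by_k)) {
    refined <- refine_cutoff_by_enrichment(scan, fits_by_k, cfg$gene_sets,
                                           cfg$probe_gene_map,
                                           alpha = cfg$alpha,
                                           fold_min = cfg$fold_min)
    chosen <- stats::setNames(refined$k, refined$direction)
  }
  fits <- lapply(c(up = "up", down = "down"), function(dir) {
    k <- chosen[[dir]]
    if (is.na(k)) NULL else suppressWarnings(fuzzy_intersect(sup, k))
  })
  cores <- lapply(c(up = "up", down = "down"), function(dir) {
    fit <- fits[[dir]]
    probes <- if (is.null(fit)) character(0)
              else if (dir == "up") fit$up_core else fit$down_core
    genes <- if (is.null(cfg$probe_gene_map)) NULL
             else collapse_probes_to_genes(probes, cfg$probe_gene_map)
    list(probes = probes, genes = genes)
  })
  manifest <- .manifest(cfg, "fit", list(
    n_profiles = ncol(cfg$profiles$ranks),
    universe_size = length(cfg$profiles$universe),
    k_selected = as.list(chosen),
    n_core = list(up = length(cores$up$probes),
                  down = length(cores$down$probes))))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(as.data.frame(scan), file.path(cfg$out_dir, "scan.tsv"))
    .write_tsv(as.data.frame(selection),
               file.path(cfg$out_dir, "selection.tsv"))
    for (dir in c("up", "down")) {
      if (!is.null(fits[[dir]])) {
        write_fit_result(fits[[dir]],
                         file.path(cfg$out_dir, paste0("fit_", dir, ".tsv")))
      }
    }
    core_tab <- do.call(rbind, lapply(c("up", "down"), function(dir) {
      p <- cores[[dir]]$probes
      if (!length(p)) return(NULL)
      g <- cores[[dir]]$genes
      data.frame(direction = dir, probe = p,
                 gene = if (is.null(g)) NA_character_ else {
                   idx <- match(p, cfg$probe_gene_map$probe)
                   cfg$probe_gene_map$gene[idx]
                 }, stringsAsFactors = FALSE)
    }))
    if (!is.null(core_tab)) {
      .write_tsv(core_tab, file.path(cfg$out_dir, "core.tsv"))
    }
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(scan = scan, selection = selection, refined = refined, fits = fits,
       cores = cores, config = cfg, manifest = manifest)
}

#' Run the downstream stage on a FIT result
#'
#' Computes, as configured: gene-set overrepresentation of the gene-collapsed
#' cores, the interaction-network overlap test between the core genes and a
#' reference gene list (e.g. proteostasis genes), the core-frequency
#' fold-enrichment of the core in the panel's signatures versus background
#' signatures, and the two-tailed re-ranking of the background compendium
#' against the core sets (reversers of the core signature rank last — the
#' candidate search). Writes `enrichment.tsv`, `overlap.tsv`, `ranking.tsv`,
#' `frequency_fold.tsv` and `manifest.json` when `out_dir` is set.
#'
#' @param config As for [run_fit()]; additionally uses `network`,
#'   `reference_genes` (character vector for the overlap test), `conf_min`,
#'   `background` (compendium to re-rank), `out_dir`.
#' @param fit The list returned by [run_fit()].
#' @return List with `enrichment`, `overlap`, `frequency_fold`, `ranking`
#'   (NULL where inputs were not configured), and `manifest`.
#' @export
run_downstream <- function(config, fit) {
  cfg <- if (inherits(config, "fit_config")) config else validate_config(config)
  stopifnot(is.list(fit), !is.null(fit$cores))
  up <- fit$cores$up$probes
  down <- fit$cores$down$probes
  map <- cfg$probe_gene_map
  enrichment <- NULL
  if (!is.null(cfg$gene_sets) && !is.null(map)) {
    universe_genes <- collapse_probes_to_genes(cfg$profiles$universe, map)$genes
    enr <- lapply(c("up", "down"), function(dir) {
      genes <- collapse_probes_to_genes(
        if (dir == "up") up else down, map)$genes
      if (!length(genes)) return(NULL)
      cbind(direction = dir,
            hypergeom_enrich(genes, cfg$gene_sets, universe_genes))
    })
    enrichment <- do.call(rbind, enr)
  }
  overlap <- NULL
  if (!is.null(cfg$network) && length(cfg$reference_genes) && !is.null(map)) {
    core_genes <- collapse_probes_to_genes(c(up, down), map)$genes
    overlap <- ppi_overlap_significance(core_genes, cfg$reference_genes,
                                        cfg$network, conf_min = cfg$conf_min,
                                        B = cfg$B, seed = cfg$seed)
  }
  frequency_fold <- NULL
  ranking <- NULL
  if (!is.null(cfg$background)) {
    bg_sigs <- signatures(cfg$background, cfg$f)
    fg_sigs <- signatures(cfg$profiles, cfg$f)
    if (length(down)) {
      frequency_fold <- core_frequency_fold(down, fg_sigs, bg_sigs,
                                            direction = "down")
    } else if (length(up)) {
      frequency_fold <- core_frequency_fold(up, fg_sigs, bg_sigs,
                                            direction = "up")
    }
    if (length(up) || length(down)) {
      ranking <- gsea_rank_drugs(up, down, cfg$background)
    }
  }
  manifest <- .manifest(cfg, "downstream", list(
    n_core = list(up = length(up), down = length(down)),
    overlap_p = if (is.null(overlap)) NULL else overlap$p,
    frequency_fold = if (is.null(frequency_fold)) NULL
                     else as.numeric(frequency_fold)))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(enrichment)) {
      .write_tsv(enrichment, file.path(cfg$out_dir, "enrichment.tsv"))
    }
    if (!is.null(overlap)) {
      .write_tsv(data.frame(observed = overlap$observed,
                            null_mean = overlap$null_mean,
                            null_sd = overlap$null_sd, z = overlap$z,
                            p = overlap$p, B = overlap$B, mode = overlap$mode),
                 file.path(cfg$out_dir, "overlap.tsv"))
    }
    if (!is.null(frequency_fold)) {
      .write_tsv(data.frame(
        fold = as.numeric(frequency_fold),
        foreground_mean = attr(frequency_fold, "foreground_mean"),
        background_mean = attr(frequency_fold, "background_mean")),
        file.path(cfg$out_dir, "frequency_fold.tsv"))
    }
    if (!is.null(ranking)) {
      .write_tsv(ranking, file.path(cfg$out_dir, "ranking.tsv"))
    }
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest_downstream.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(enrichment = enrichment, overlap = overlap,
       frequency_fold = frequency_fold, ranking = ranking,
       manifest = manifest)
}
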