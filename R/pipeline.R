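#' Pipeline run configuration
#'
#' Bundles the input locations (or in-memory objects) and the tunable
#' parameters of both pipeline arms. Defaults are the analysis
#' constants used throughout: minimum row total 10 reads per gene,
#' top-100 extreme gene sets, pathway-bias enrichment at q < 0.005,
#' category thresholds of [default_category_thresholds()], factor-level
#' enrichment at q < 0.05, and a 2-cell floor per screen factor. A
#' resolved copy of the configuration is written with every run.
#'
#' @param counts,condition count-matrix TSV and condition-map TSV paths,
#'   or a [count_matrix()] in `counts`.
#' @param de_table optional external DE table (path or `de_result`);
#'   when supplied the DE estimation step is skipped.
#' @param pathways optional pathway collections for the expression arm:
#'   a GMT path, a [gene_set_collection()], or a named list of either
#'   (each collection is FDR-corrected separately).
#' @param screen screen directory (see [read_screen()]), dense TSV path,
#'   or a [perturbation_screen()].
#' @param ba_sets optional GMT path or list of two [gene_set()]s for the
#'   activation arm; defaults to the sets produced by the expression arm
#'   in `out_dir`.
#' @param factor_pathways optional factor-level pathway collection (GMT
#'   path or [gene_set_collection()]) for category enrichment.
#' @param out_dir output directory.
#' @param min_total,top_k,pathway_q,enrichment_q,thresholds,min_cells,min_overlap,min_set_genes,pseudocount
#'   stage parameters (see the stage functions).
#' @param seed integer seed recorded with the run.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(counts = NULL, condition = NULL, de_table = NULL,
                       pathways = NULL, screen = NULL, ba_sets = NULL,
                       factor_pathways = NULL, out_dir = "pipeline_out",
                       min_total = 10, top_k = 100, pathway_q = 0.005,
                       enrichment_q = 0.05,
                       thresholds = default_category_thresholds(),
                       min_cells = 2, min_overlap = 5, min_set_genes = 3,
                       pseudocount = 0.5, seed = 1) {
  structure(list(
    counts = counts, condition = condition, de_table = de_table,
    pathways = pathways, screen = screen, ba_sets = ba_sets,
    factor_pathways = factor_pathways, out_dir = out_dir,
    min_total = min_total, top_k = top_k, pathway_q = pathway_q,
    enrichment_q = enrichment_q, thresholds = thresholds,
    min_cells = min_cells, min_overlap = min_overlap,
    min_set_genes = min_set_genes, pseudocount = pseudocount,
    seed = seed
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields map 1:1 onto [run_config()] arguments; `thresholds` may
#' be given as a four-key mapping.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) y$thresholds <- unlist(y$thresholds)
  do.call(run_config, y)
}

# -- internal helpers ---------------------------------------------------

.log_open <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$lines <- character(0)
  env$path <- file.path(out_dir, "run.log")
  env
}

.log <- function(logger, ...) {
  line <- paste0(...)
  logger$lines <- c(logger$lines, line)
  message(line)
}

.log_close <- function(logger) {
  writeLines(logger$lines, logger$path)
}

.require_paths <- function(paths) {
  paths <- unlist(Filter(function(p) is.character(p), paths))
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("missing input path(s): ", paste(absent, collapse = ", "))
  }
}

.input_hashes <- function(cfg) {
  paths <- Filter(function(p) is.character(p) && length(p) == 1L &&
                    file.exists(p) && !dir.exists(p),
                  cfg[c("counts", "condition", "de_table", "screen",
                        "ba_sets", "factor_pathways")])
  if (length(paths) == 0L) return(list())
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

.write_provenance <- function(cfg, stage, extra = list()) {
  prov <- c(list(
    stage = stage,
    package = "bilactivr",
    package_version = as.character(utils::packageVersion("bilactivr")),
    parameters = list(
      min_total = cfg$min_total, top_k = cfg$top_k,
      pathway_q = cfg$pathway_q, enrichment_q = cfg$enrichment_q,
      thresholds = as.list(cfg$thresholds), min_cells = cfg$min_cells,
      min_overlap = cfg$min_overlap, min_set_genes = cfg$min_set_genes,
      pseudocount = cfg$pseudocount, seed = cfg$seed
    ),
    input_md5 = .input_hashes(cfg)
  ), extra)
  jsonlite::write_json(prov,
                       file.path(cfg$out_dir,
                                 paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

.write_resolved_config <- function(cfg) {
  scalar <- Filter(function(x) is.atomic(x) && length(x) >= 1L,
                   unclass(cfg))
  scalar$thresholds <- as.list(cfg$thresholds)
  yaml::write_yaml(scalar, file.path(cfg$out_dir, "resolved_config.yaml"))
}

.resolve_collections <- function(x) {
  if (is.null(x)) return(NULL)
  as_coll <- function(v, nm) {
    if (inherits(v, "gene_set_collection")) v
    else read_gmt(v, collection_name = nm)
  }
  if (inherits(x, "gene_set_collection") || is.character(x)) {
    x <- list(pathways = x)
  }
  nms <- if (is.null(names(x))) paste0("collection", seq_along(x)) else names(x)
  stats::setNames(Map(as_coll, x, nms), nms)
}

# Case-insensitive, whitespace-stripped id matching for cross-dataset
# joins (bulk gene symbols vs screen gene ids). Returns the target-cased
# matches plus the unmatched query ids.
.match_ids <- function(query, target) {
  key <- function(v) toupper(trimws(v))
  idx <- match(key(query), key(target))
  list(matched = target[idx[!is.na(idx)]],
       unmatched = query[is.na(idx)])
}

# -- pipeline arms ------------------------------------------------------

#' Run the expression arm
#'
#' counts -> gene filtration -> size factors -> DE estimate (or an
#' externally supplied DE table) -> extreme up/down gene sets -> pathway
#' rank-bias classification. Writes `de.tsv`, `ba_sets.gmt`,
#' `pathway_bias.tsv` (when pathway collections are configured),
#' `run.log`, a provenance JSON and the resolved configuration into
#' `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with `de`, `sets` and `pathway_bias`.
#' @export
run_expression_arm <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  logger <- .log_open(cfg$out_dir)
  if (is.null(cfg$de_table) && is.null(cfg$counts)) {
    stop("missing input: supply 'counts' + 'condition' or 'de_table'")
  }

  if (!is.null(cfg$de_table)) {
    .require_paths(cfg["de_table"])
    de <- if (inherits(cfg$de_table, "de_result")) cfg$de_table
          else read_de_table(cfg$de_table)
    .log(logger, "expression arm: external DE table with ", nrow(de),
         " genes; estimation skipped")
  } else {
    .require_paths(cfg[c("counts", "condition")])
    cm <- if (inherits(cfg$counts, "count_matrix")) cfg$counts
          else read_counts(cfg$counts, cfg$condition)
    .log(logger, "expression arm: ", nrow(cm$counts), " genes x ",
         ncol(cm$counts), " samples")
    cm <- filter_genes(cm, cfg$min_total)
    .log(logger, "filtration (row total >= ", cfg$min_total, "): ",
         nrow(cm$counts), " genes retained")
    de <- estimate_de(cm, pseudocount = cfg$pseudocount)
  }
  write_de_table(de, file.path(cfg$out_dir, "de.tsv"))

  sets <- withCallingHandlers(
    select_extreme_sets(de, k = cfg$top_k),
    message = function(m) {
      logger$lines <- c(logger$lines, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  write_gmt(sets, file.path(cfg$out_dir, "ba_sets.gmt"))
  .log(logger, "extreme sets written: ", sets$up$name, " / ",
       sets$down$name, " (k = ", cfg$top_k, ")")

  bias <- NULL
  colls <- .resolve_collections(cfg$pathways)
  if (!is.null(colls)) {
    tabs <- lapply(names(colls), function(nm) {
      tab <- classify_pathways(de, colls[[nm]],
                               q_threshold = cfg$pathway_q,
                               min_overlap = cfg$min_overlap)
      skipped <- attr(tab, "skipped")
      if (length(skipped)) {
        .log(logger, "collection ", nm, ": skipped ", length(skipped),
             " pathways below overlap ", cfg$min_overlap)
      }
      cbind(collection = nm, as.data.frame(tab))
    })
    bias <- do.call(rbind, tabs)
    .write_tsv(bias, file.path(cfg$out_dir, "pathway_bias.tsv"))
    .log(logger, "pathway bias: ", nrow(bias), " pathways tested, ",
         sum(bias$enriched), " enriched at q < ", cfg$pathway_q)
  }

  .write_provenance(cfg, "expression")
  .write_resolved_config(cfg)
  .log_close(logger)
  invisible(list(de = de, sets = sets, pathway_bias = bias))
}

#' Run the activation arm
#'
#' screen -> perturbation effect score matrix -> differential activation
#' of the up/down disease gene sets -> four-way factor classification ->
#' hypergeometric pathway enrichment of each category. Writes
#' `effects.tsv` (+ JSON sidecar), `activation.tsv`, `categories.json`,
#' `enrichment.tsv` (when factor pathways are configured), `run.log` and
#' provenance into `cfg$out_dir`. Disease gene sets come from
#' `cfg$ba_sets` or, by default, from the expression arm's
#' `ba_sets.gmt` in the same output directory.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with `effects`, `activation`, `categories`
#'   and `enrichment`.
#' @export
run_activation_arm <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  logger <- .log_open(cfg$out_dir)
  if (is.null(cfg$screen)) stop("missing input: 'screen'")
  .require_paths(cfg["screen"])

  screen <- if (inherits(cfg$screen, "perturbation_screen")) cfg$screen
            else if (dir.exists(cfg$screen)) read_screen(cfg$screen)
            else read_screen_tsv(cfg$screen)
  .log(logger, "activation arm: screen with ", nrow(screen$z),
       " cells x ", ncol(screen$z), " genes, ", sum(screen$is_nt),
       " non-targeting")

  ba_path <- file.path(cfg$out_dir, "ba_sets.gmt")
  sets <- if (!is.null(cfg$ba_sets)) {
    if (is.character(cfg$ba_sets)) {
      .require_paths(cfg["ba_sets"])
      coll <- read_gmt(cfg$ba_sets)
      unname(coll$sets)
    } else cfg$ba_sets
  } else if (file.exists(ba_path)) {
    unname(read_gmt(ba_path)$sets)
  } else {
    stop("missing input: disease gene sets ",
         "(cfg$ba_sets or ", ba_path, ")")
  }
  if (length(sets) < 2L) stop("need both an up and a down gene set")

  # cross-dataset join: case-insensitive symbol matching, logged
  sets <- lapply(sets, function(gs) {
    m <- .match_ids(gs$genes, colnames(screen$z))
    .log(logger, "set '", gs$name, "': ", length(m$matched), " of ",
         length(gs$genes), " genes present in the screen")
    if (length(m$unmatched)) {
      .log(logger, "  unmatched ids: ",
           paste(utils::head(m$unmatched, 10), collapse = ", "),
           if (length(m$unmatched) > 10) " ..." else "")
    }
    if (length(m$matched) == 0L) {
      stop("no genes of set '", gs$name, "' are present in the screen")
    }
    gene_set(gs$name, m$matched)
  })

  em <- withCallingHandlers(
    effect_matrix(screen, min_cells = cfg$min_cells),
    message = function(m) {
      logger$lines <- c(logger$lines, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  write_effect_matrix(em, file.path(cfg$out_dir, "effects.tsv"))
  .log(logger, "effect matrix: ", nrow(em$score), " factors x ",
       ncol(em$score), " genes; ", length(em$skipped),
       " factors skipped (< ", cfg$min_cells, " cells)")

  act <- suppressWarnings(
    activation_table(em, sets, min_set_genes = cfg$min_set_genes)
  )
  .write_tsv(as.data.frame(act), file.path(cfg$out_dir, "activation.tsv"))

  up_nm <- sets[[1]]$name
  down_nm <- sets[[2]]$name
  cats <- classify_factors(act, thresholds = cfg$thresholds,
                           up_set = up_nm, down_set = down_nm)
  jsonlite::write_json(
    list(categories = cats$categories,
         thresholds = as.list(cats$thresholds),
         up_set = up_nm, down_set = down_nm),
    file.path(cfg$out_dir, "categories.json"),
    auto_unbox = TRUE, digits = NA
  )
  for (nm in names(cats$categories)) {
    .log(logger, "category ", nm, ": ",
         length(cats$categories[[nm]]), " factors")
  }

  enr <- NULL
  if (!is.null(cfg$factor_pathways)) {
    coll <- .resolve_collections(cfg$factor_pathways)[[1]]
    enr <- factor_enrichment(cats, coll,
                             universe = rownames(em$score),
                             q_threshold = cfg$enrichment_q)
    .write_tsv(as.data.frame(enr), file.path(cfg$out_dir, "enrichment.tsv"))
    .log(logger, "enrichment: ", nrow(enr), " tests, ",
         sum(enr$enriched), " enriched at q < ", cfg$enrichment_q)
  }

  .write_provenance(cfg, "activation")
  .write_resolved_config(cfg)
  .log_close(logger)
  invisible(list(effects = em, activation = act, categories = cats,
                 enrichment = enr))
}
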