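#' Rank bias of log2 fold changes within one pathway
#'
#' The differentially-expressed-pathway statistic: a Wilcoxon rank-sum
#' test of the log2 fold changes of the genes inside the pathway against
#' the remaining measured genes. "Remaining" means the DE universe minus
#' the pathway's intersection with it — only measured genes carry scores.
#' Direction is `"up"` when the in-set median fold change exceeds the
#' out-set median under the median/mean tie ladder, `"down"` otherwise.
#'
#' @param de a `de_result`.
#' @param gs a [gene_set()].
#' @param min_overlap minimum size of `gs` \eqn{\cap} DE universe for the
#'   test to run (default 5); smaller overlaps are skipped.
#' @return a list with `pathway`, `n_in`, `p`, `direction`, `median_in`,
#'   `median_out`; or, when skipped, a list with `skipped = TRUE` and the
#'   reason.
#' @export
pathway_bias_test <- function(de, gs, min_overlap = 5) {
  stopifnot(inherits(de, "de_result"), inherits(gs, "gene_set"))
  inside <- de$gene_id %in% gs$genes
  n_in <- sum(inside)
  if (n_in < min_overlap) {
    return(list(pathway = gs$name, skipped = TRUE,
                reason = sprintf("overlap %d < min_overlap %d",
                                 n_in, min_overlap)))
  }
  if (all(inside)) stop("pathway covers the entire DE universe")
  rt <- rank_sum_test(de$log2fc[inside], de$log2fc[!inside], "auto")
  list(pathway = gs$name, n_in = n_in, p = rt$p_value,
       direction = if (rt$direction > 0) "up" else "down",
       median_in = stats::median(de$log2fc[inside]),
       median_out = stats::median(de$log2fc[!inside]),
       skipped = FALSE)
}

#' Test and classify all pathways of a collection
#'
#' Runs [pathway_bias_test()] for every set, adjusts p-values by
#' Benjamini-Hochberg across exactly the tested pathways of this
#' collection, and flags pathways with `q < q_threshold` as enriched
#' ("differentially expressed pathways"; the conventional threshold here
#' is 0.005). Enriched pathways are up- or downregulated according to the
#' direction of the bias. When several repositories (e.g. KEGG and GO)
#' are supplied as separate collections, each gets its own correction.
#'
#' @param de a `de_result`.
#' @param coll a [gene_set_collection()].
#' @param q_threshold enrichment threshold on BH q (default 0.005).
#' @param min_overlap passed to [pathway_bias_test()].
#' @return a `pathway_bias_table`: data.frame with columns `pathway`,
#'   `n_in`, `p`, `q`, `direction`, `median_in`, `median_out`,
#'   `enriched`; skipped pathways are recorded in the `"skipped"`
#'   attribute.
#' @export
classify_pathways <- function(de, coll, q_threshold = 0.005,
                              min_overlap = 5) {
  stopifnot(inherits(coll, "gene_set_collection"))
  res <- lapply(coll$sets, pathway_bias_test, de = de,
                min_overlap = min_overlap)
  skipped <- Filter(function(r) isTRUE(r$skipped), res)
  tested <- Filter(function(r) !isTRUE(r$skipped), res)
  if (length(tested) == 0L) stop("no testable pathway in collection")
  for (s in skipped) {
    message("pathway skipped: ", s$pathway, " (", s$reason, ")")
  }
  tab <- data.frame(
    pathway = vapply(tested, `[[`, character(1), "pathway"),
    n_in = vapply(tested, `[[`, numeric(1), "n_in"),
    p = vapply(tested, `[[`, numeric(1), "p"),
    direction = vapply(tested, `[[`, character(1), "direction"),
    median_in = vapply(tested, `[[`, numeric(1), "median_in"),
    median_out = vapply(tested, `[[`, numeric(1), "median_out"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$q <- bh_fdr(tab$p)
  tab$enriched <- tab$q < q_threshold
  tab <- tab[, c("pathway", "n_in", "p", "q", "direction",
                 "median_in", "median_out", "enriched")]
  attr(tab, "skipped") <- unname(vapply(skipped, `[[`, character(1),
                                        "pathway"))
  attr(tab, "q_threshold") <- q_threshold
  class(tab) <- c("pathway_bias_table", "data.frame")
  tab
}

#' @export
print.pathway_bias_table <- function(x, n = 6L, ...) {
  cat("pathway_bias_table:", nrow(x), "pathways tested,",
      sum(x$enriched), "enriched at q <", attr(x, "q_threshold"), "\n")
  o <- order(x$q)
  print.data.frame(utils::head(as.data.frame(x)[o, ], n), digits = 4)
  invisible(x)
}
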