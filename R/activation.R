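#' Differential activation of a gene set under one perturbation
#'
#' The effect of a perturbation on a disease gene set: a Wilcoxon
#' rank-sum test of the factor's perturbation effect scores on the genes
#' inside the set against the remaining screen genes. A perturbation
#' upregulates (downregulates) the set when the in-set scores tend high
#' (low); the direction comes from the median/mean tie ladder.
#'
#' @param em an [effect_matrix()].
#' @param factor_id row of `em` to test.
#' @param gs a [gene_set()].
#' @param min_set_genes minimum overlap of `gs` with the screen's gene
#'   universe (default 3); below it the test is skipped (`NULL` with a
#'   message). Overlaps below 10 trigger a loud warning — the test runs,
#'   but on thin evidence.
#' @return list with `factor_id`, `set_name`, `n_in`, `p`, `direction`
#'   (`"up"`, `"down"` or `"none"`), or `NULL` when skipped.
#' @export
activation_test <- function(em, factor_id, gs, min_set_genes = 3) {
  stopifnot(inherits(em, "effect_matrix"), inherits(gs, "gene_set"))
  if (!factor_id %in% rownames(em$score)) {
    stop("unknown factor: ", factor_id)
  }
  s <- em$score[factor_id, ]
  inside <- colnames(em$score) %in% gs$genes
  n_in <- sum(inside)
  if (n_in < min_set_genes) {
    message("activation test skipped: ", gs$name, " x ", factor_id,
            " (overlap ", n_in, " < ", min_set_genes, ")")
    return(NULL)
  }
  if (all(inside)) stop("gene set covers the entire screen universe")
  if (n_in < 10L) {
    warning("only ", n_in, " of ", length(gs$genes), " '", gs$name,
            "' genes are present in the screen; ",
            "activation evidence is thin", call. = FALSE)
  }
  rt <- rank_sum_test(s[inside], s[!inside], "auto")
  list(factor_id = factor_id, set_name = gs$name, n_in = n_in,
       p = rt$p_value,
       direction = c("down", "none", "up")[rt$direction + 2L])
}

#' Differential-activation table over all factors and gene sets
#'
#' Runs [activation_test()] for every (factor, gene set) pair. The
#' overlap warning for a thin set is emitted once per set, not per
#' factor.
#'
#' @param em an [effect_matrix()].
#' @param sets list of [gene_set()]s (typically the up- and
#'   down-regulated disease sets).
#' @param min_set_genes passed to [activation_test()].
#' @return an `activation_table`: data.frame with columns `factor_id`,
#'   `set_name`, `n_set_genes_in_screen`, `p`, `direction`.
#' @export
activation_table <- function(em, sets, min_set_genes = 3) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  rows <- list()
  for (gs in sets) {
    n_in <- sum(colnames(em$score) %in% gs$genes)
    res <- withCallingHandlers(
      lapply(rownames(em$score), function(f) {
        activation_test(em, f, gs, min_set_genes)
      }),
      warning = function(w) {
        if (grepl("activation evidence is thin", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    if (n_in >= min_set_genes && n_in < 10L) {
      warning("only ", n_in, " of ", length(gs$genes), " '", gs$name,
              "' genes are present in the screen; ",
              "activation evidence is thin", call. = FALSE)
    }
    rows <- c(rows, Filter(Negate(is.null), res))
  }
  if (length(rows) == 0L) stop("no testable (factor, gene set) pair")
  tab <- data.frame(
    factor_id = vapply(rows, `[[`, character(1), "factor_id"),
    set_name = vapply(rows, `[[`, character(1), "set_name"),
    n_set_genes_in_screen = vapply(rows, `[[`, numeric(1), "n_in"),
    p = vapply(rows, `[[`, numeric(1), "p"),
    direction = vapply(rows, `[[`, character(1), "direction"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(tab) <- c("activation_table", "data.frame")
  tab
}

#' @export
print.activation_table <- function(x, n = 6L, ...) {
  cat("activation_table:", nrow(x), "(factor, gene set) tests\n")
  print.data.frame(utils::head(as.data.frame(x)[order(x$p), ], n),
                   digits = 4)
  invisible(x)
}

#' Default category thresholds for factor classification
#'
#' The four per-category p-value cutoffs for a significant perturbation
#' effect: factors that downregulate the down-set (p < 0.11),
#' downregulate the up-set (p < 0.01), upregulate the down-set
#' (p < 0.07), and upregulate the up-set (p < 0.08). Heterogeneous by
#' design — they are tunable configuration, not derived quantities.
#'
#' @return named numeric vector of four thresholds.
#' @export
default_category_thresholds <- function() {
  c(down_on_BA_Down = 0.11, down_on_BA_Up = 0.01,
    up_on_BA_Down = 0.07, up_on_BA_Up = 0.08)
}

#' Classify factors into four directional categories
#'
#' A factor joins a category when its activation direction on the named
#' set matches and its p-value is strictly below that category's
#' threshold. Categories are not forced disjoint: a factor may, for
#' example, downregulate both sets.
#'
#' @param act an [activation_table()] containing rows for both the up-
#'   and down-regulated sets.
#' @param thresholds named numeric vector with exactly the names of
#'   [default_category_thresholds()].
#' @param up_set,down_set the `set_name` values naming the up- and
#'   down-regulated disease sets (defaults `"BA-Up"` / `"BA-Down"`).
#' @return a `factor_categories`: list with `categories` (four character
#'   vectors of factor ids) and `thresholds`.
#' @export
classify_factors <- function(act,
                             thresholds = default_category_thresholds(),
                             up_set = "BA-Up", down_set = "BA-Down") {
  stopifnot(inherits(act, "activation_table"))
  valid <- names(default_category_thresholds())
  if (is.null(names(thresholds)) || !setequal(names(thresholds), valid)) {
    bad <- setdiff(names(thresholds), valid)
    stop("unknown threshold key(s): ",
         paste(if (length(bad)) bad else "<missing names>", collapse = ", "))
  }
  if (!all(c(up_set, down_set) %in% act$set_name)) {
    stop("activation table must contain rows for both '", up_set,
         "' and '", down_set, "'")
  }
  pick <- function(set, dir, thr) {
    sel <- act$set_name == set & act$direction == dir & act$p < thr
    sort(unique(act$factor_id[sel]))
  }
  cats <- list(
    down_on_BA_Down = pick(down_set, "down", thresholds[["down_on_BA_Down"]]),
    down_on_BA_Up = pick(up_set, "down", thresholds[["down_on_BA_Up"]]),
    up_on_BA_Down = pick(down_set, "up", thresholds[["up_on_BA_Down"]]),
    up_on_BA_Up = pick(up_set, "up", thresholds[["up_on_BA_Up"]])
  )
  structure(list(categories = cats,
                 thresholds = thresholds[valid],
                 up_set = up_set, down_set = down_set),
            class = "factor_categories")
}

#' @export
print.factor_categories <- function(x, ...) {
  cat("factor_categories:\n")
  for (nm in names(x$categories)) {
    cat(sprintf("  %-16s (p < %-5g): %d factors\n", nm,
                x$thresholds[[nm]], length(x$categories[[nm]])))
  }
  invisible(x)
}

#' Hypergeometric pathway enrichment of factor categories
#'
#' For each category and each pathway (whose "genes" are factor ids):
#' overlap `k` of category, pathway and universe; pathway-in-universe
#' size `K`; category size `n`; universe size `N` (all factors tested
#' for activation). Upper-tail hypergeometric p, BH-adjusted across the
#' pathways tested within the category; pathways with `q < q_threshold`
#' are the "differentially activated pathways". Pathways absent from the
#' universe (`K = 0`) are skipped.
#'
#' @param cats a [classify_factors()] result.
#' @param coll a [gene_set_collection()] of factor-level pathways.
#' @param universe character vector of all factors tested for
#'   activation; every category must be a subset of it.
#' @param q_threshold enrichment cutoff on q (default 0.05).
#' @return an `enrichment_table`: data.frame with columns `category`,
#'   `pathway`, `k`, `n`, `K`, `N`, `p`, `q`, `enriched`.
#' @export
factor_enrichment <- function(cats, coll, universe, q_threshold = 0.05) {
  stopifnot(inherits(cats, "factor_categories"),
            inherits(coll, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty factor universe")
  N <- length(universe)
  out <- list()
  for (cat_name in names(cats$categories)) {
    members <- intersect(cats$categories[[cat_name]], universe)
    if (length(members) < length(cats$categories[[cat_name]])) {
      stop("category '", cat_name, "' is not a subset of the universe")
    }
    n <- length(members)
    if (n == 0L) next
    rows <- list()
    for (gs in coll$sets) {
      inU <- intersect(gs$genes, universe)
      K <- length(inU)
      if (K == 0L) next
      k <- length(intersect(members, inU))
      rows[[gs$name]] <- data.frame(
        category = cat_name, pathway = gs$name, k = k, n = n, K = K,
        N = N, p = hypergeom_upper_tail(k, K, n, N),
        stringsAsFactors = FALSE
      )
    }
    if (length(rows) == 0L) next
    tab <- do.call(rbind, rows)
    tab$q <- bh_fdr(tab$p)
    tab$enriched <- tab$q < q_threshold
    out[[cat_name]] <- tab
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(category = character(0), pathway = character(0),
               k = numeric(0), n = numeric(0), K = numeric(0),
               N = numeric(0), p = numeric(0), q = numeric(0),
               enriched = logical(0))
  }
  rownames(res) <- NULL
  attr(res, "q_threshold") <- q_threshold
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' @export
print.enrichment_table <- function(x, n = 6L, ...) {
  cat("enrichment_table:", nrow(x), "(category, pathway) tests,",
      sum(x$enriched), "enriched at q <", attr(x, "q_threshold"), "\n")
  print.data.frame(utils::head(as.data.frame(x)[order(x$q), ], n),
                   digits = 4)
  invisible(x)
}
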