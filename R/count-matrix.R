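#' Construct a labelled count matrix
#'
#' Container for a genes x samples matrix of non-negative integer read
#' counts with a two-level condition label per sample (`"case"` = disease,
#' `"control"`). This is the input contract of the expression arm.
#'
#' @param counts integer matrix, genes in rows (unique rownames), samples
#'   in columns (unique colnames), all entries non-negative integers.
#' @param condition character or factor of length `ncol(counts)` with
#'   values `"case"` / `"control"`; if named, names are matched against
#'   the sample ids.
#' @return an object of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (!is.null(names(condition))) {
    if (!setequal(names(condition), colnames(counts))) {
      stop("condition names do not match sample ids")
    }
    condition <- condition[colnames(counts)]
  }
  if (length(condition) != ncol(counts)) {
    stop("condition must have one entry per sample")
  }
  condition <- factor(as.character(condition), levels = c("case", "control"))
  if (anyNA(condition)) stop("condition labels must be 'case' or 'control'")
  if (!all(c("case", "control") %in% condition)) {
    stop("need at least one case and one control sample")
  }
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$condition == "case"), "case /",
      sum(x$condition == "control"), "control )\n")
  invisible(x)
}

#' Filter genes by total read count
#'
#' Retains genes whose total count across all samples reaches
#' `min_total`; the default of 10 reads per gene is the conventional
#' minimum-count threshold for bulk RNA-seq prefiltering. Idempotent.
#'
#' @param cm a [count_matrix()].
#' @param min_total minimum row total (default 10).
#' @return a filtered `count_matrix` with the same samples.
#' @export
filter_genes <- function(cm, min_total = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowSums(cm$counts) >= min_total
  if (!any(keep)) stop("no genes survive filtration")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$condition)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors in the median-of-ratios style: for
#' every gene with strictly positive counts in all samples, form the ratio
#' of each sample's count to the gene's geometric mean; a sample's factor
#' is the median of its ratios, and the factors are rescaled to have
#' geometric mean 1.
#'
#' @param cm a [count_matrix()].
#' @return positive numeric vector, one factor per sample, named.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; ",
         "consider adding a pseudocount to the matrix")
  }
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- exp(apply(lc - geo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Lightweight differential-expression estimate
#'
#' A deliberately simple, fully documented stand-in for a full
#' negative-binomial DE fit, producing the per-gene `log2fc`/`p`/`q`
#' columns every downstream stage consumes. Counts are normalized by
#' [size_factors()]; the fold change is
#' `log2((mean normalized case + pseudocount) / (mean normalized control + pseudocount))`,
#' positive = upregulated in the case (disease) condition. With at least
#' three samples per group the p-value comes from [rank_sum_test()] on the
#' per-sample normalized values; with fewer, from a normal Wald statistic
#' on log2-normalized group means with pooled moment variance. Q-values
#' are Benjamini-Hochberg across genes. Published DE tables computed with
#' heavier machinery can be supplied instead via [read_de_table()]: every
#' downstream stage only needs the `log2fc` ranking.
#'
#' @param cm a filtered [count_matrix()].
#' @param pseudocount added to both group means before the ratio
#'   (default 0.5).
#' @param sf optional precomputed size factors (defaults to
#'   [size_factors()] of `cm`).
#' @return a `de_result`: a data.frame with columns `gene_id`,
#'   `base_mean`, `log2fc`, `p`, `q`.
#' @export
estimate_de <- function(cm, pseudocount = 0.5, sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  is_case <- cm$condition == "case"
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (n1 < 1L || n2 < 1L) stop("need at least one sample per group")
  if (is.null(sf)) sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2, sf, "/")
  mc <- rowMeans(norm[, is_case, drop = FALSE])
  mt <- rowMeans(norm[, !is_case, drop = FALSE])
  log2fc <- log2((mc + pseudocount) / (mt + pseudocount))
  base_mean <- rowMeans(norm)

  if (min(n1, n2) >= 3L) {
    p <- vapply(seq_len(nrow(norm)), function(g) {
      rank_sum_test(norm[g, is_case], norm[g, !is_case], "auto")$p_value
    }, numeric(1))
  } else {
    lx <- log2(norm + pseudocount)
    m1 <- rowMeans(lx[, is_case, drop = FALSE])
    m2 <- rowMeans(lx[, !is_case, drop = FALSE])
    ss <- rowSums((lx[, is_case, drop = FALSE] - m1)^2) +
      rowSums((lx[, !is_case, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2L
    se <- if (df > 0) sqrt(ss / df * (1 / n1 + 1 / n2)) else rep(0, nrow(norm))
    d <- m1 - m2
    p <- ifelse(se > 0, 2 * stats::pnorm(-abs(d) / se),
                ifelse(d == 0, 1, 1e-300))
    p <- pmin(1, pmax(p, 1e-300))
  }

  de_result(data.frame(
    gene_id = rownames(cm$counts), base_mean = base_mean,
    log2fc = log2fc, p = p, q = bh_fdr(p),
    row.names = NULL, stringsAsFactors = FALSE
  ))
}

#' Construct / validate a DE result table
#'
#' @param df data.frame with columns `gene_id`, `log2fc`, `p` and
#'   optionally `q` (recomputed by BH when absent) and `base_mean`.
#' @return the validated data.frame with class `"de_result"`.
#' @export
de_result <- function(df) {
  need <- c("gene_id", "log2fc", "p")
  if (!all(need %in% names(df))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in DE table")
  if (any(!is.finite(df$log2fc))) stop("non-finite log2fc")
  if (any(df$p < 0 | df$p > 1)) stop("p outside [0, 1]")
  if (is.null(df$q)) df$q <- bh_fdr(df$p)
  if (is.null(df$base_mean)) df$base_mean <- NA_real_
  df <- df[, c("gene_id", "base_mean", "log2fc", "p", "q")]
  class(df) <- c("de_result", "data.frame")
  df
}

#' @export
print.de_result <- function(x, n = 6L, ...) {
  cat("de_result:", nrow(x), "genes\n")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' Extract the extreme up/down gene sets
#'
#' Returns the `k` genes with the largest log2 fold changes (the "up" set,
#' e.g. BA-Up) and the `k` with the smallest (the "down" set, BA-Down).
#' Boundary ties are broken deterministically by smaller q, then
#' lexicographic gene id. The realized boundary fold changes are reported
#' via `message()` and attached as the `"boundaries"` attribute.
#'
#' @param de a `de_result`.
#' @param k set size (default 100).
#' @param names names for the two sets.
#' @return a list of two [gene_set()]s, `up` and `down`.
#' @export
select_extreme_sets <- function(de, k = 100,
                                names = c("BA-Up", "BA-Down")) {
  stopifnot(inherits(de, "de_result"))
  n <- nrow(de)
  if (k > n) {
    warning("k exceeds the number of genes; both sets contain all genes")
    up_ids <- down_ids <- de$gene_id
  } else {
    o_up <- order(-de$log2fc, de$q, de$gene_id)
    o_dn <- order(de$log2fc, de$q, de$gene_id)
    up_ids <- de$gene_id[o_up[seq_len(k)]]
    down_ids <- de$gene_id[o_dn[seq_len(k)]]
  }
  bounds <- c(up = min(de$log2fc[de$gene_id %in% up_ids]),
              down = max(de$log2fc[de$gene_id %in% down_ids]))
  message(sprintf("extreme sets: %s log2fc >= %.4g; %s log2fc <= %.4g",
                  names[1], bounds["up"], names[2], bounds["down"]))
  out <- list(up = gene_set(names[1], up_ids),
              down = gene_set(names[2], down_ids))
  attr(out, "boundaries") <- bounds
  out
}
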