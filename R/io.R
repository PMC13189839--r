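# File-format helpers: TSV count matrices, condition maps, DE tables,
# dense/sparse screens. Gzip is detected by extension and handled
# through gzfile() connections.

.open_conn <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.read_lines <- function(path) {
  con <- .open_conn(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.read_tsv <- function(path, header = TRUE, row_names = NULL) {
  con <- .open_conn(path)
  on.exit(close(con))
  utils::read.delim(con, header = header, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = row_names)
}

.write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Read a count matrix and its condition map
#'
#' The count file is TSV with gene ids in the first column and one column
#' per sample; the condition map is a two-column TSV (`sample_id`,
#' `condition`) with condition values `case`/`control`.
#'
#' @param counts_path path to the counts TSV (optionally gzipped).
#' @param condition_path path to the condition TSV.
#' @return a [count_matrix()].
#' @export
read_counts <- function(counts_path, condition_path) {
  tab <- .read_tsv(counts_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  cond <- .read_tsv(condition_path)
  if (ncol(cond) < 2L) stop("condition map needs columns sample_id, condition")
  condition <- stats::setNames(as.character(cond[[2]]), as.character(cond[[1]]))
  count_matrix(m, condition)
}

#' @rdname read_counts
#' @param cm a [count_matrix()] to serialize.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @export
write_counts <- function(cm, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  .write_tsv(df, file.path(dir, paste0(prefix, ".tsv")))
  .write_tsv(data.frame(sample_id = colnames(cm$counts),
                        condition = as.character(cm$condition)),
             file.path(dir, paste0(prefix, "_condition.tsv")))
  invisible(dir)
}

#' Read an externally computed DE table
#'
#' TSV with columns `gene_id`, `log2fc`, `p` and optionally `q` (BH q is
#' recomputed from `p` when the column is absent) and `base_mean`. This is
#' the bypass used to slot in published DE results from heavier fitters.
#'
#' @param path file path.
#' @return a `de_result`.
#' @export
read_de_table <- function(path) {
  de_result(.read_tsv(path))
}

#' @rdname read_de_table
#' @param de a `de_result` to serialize.
#' @export
write_de_table <- function(de, path) {
  .write_tsv(as.data.frame(de), path)
}
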