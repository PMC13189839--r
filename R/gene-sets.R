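#' Gene sets and collections
#'
#' A `gene_set` is a named, duplicate-free, non-empty set of identifiers;
#' a `gene_set_collection` is a list of gene sets with unique names —
#' the in-memory form of a GMT file.
#'
#' @param name set name.
#' @param genes character vector of member identifiers.
#' @return a `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @rdname gene_set
#' @param sets list of `gene_set` objects.
#' @param collection_name optional collection label.
#' @export
gene_set_collection <- function(sets, collection_name = "") {
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate set names in collection")
  names(sets) <- nms
  structure(list(name = collection_name, sets = sets),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection '", x$name, "': ", length(x$sets),
      " sets\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, `name TAB description TAB gene ids...`.
#' Gzip-compressed files are accepted transparently.
#'
#' @param path file path.
#' @param collection_name label for the returned collection (defaults to
#'   the file name).
#' @return `read_gmt()`: a [gene_set_collection()].
#' @export
read_gmt <- function(path, collection_name = basename(path)) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_set(f[1], f[-(1:2)])
  })
  gene_set_collection(sets, collection_name)
}

#' @rdname read_gmt
#' @param coll a [gene_set_collection()] (a single `gene_set` or a plain
#'   list of them is also accepted).
#' @export
write_gmt <- function(coll, path) {
  if (inherits(coll, "gene_set")) coll <- list(coll)
  if (inherits(coll, "gene_set_collection")) coll <- coll$sets
  lines <- vapply(coll, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
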