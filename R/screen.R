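#' Construct a perturbation screen
#'
#' Container for a CRISPRi Perturb-seq style screen in its processed
#' form: a cells x genes matrix of per-cell expression z-scores (already
#' normalized to control cells upstream), a per-cell label naming the
#' perturbed gene ("factor"), and a reserved non-targeting label marking
#' the control cells that anchor every comparison.
#'
#' @param z numeric matrix, cells in rows (unique cell ids as rownames),
#'   genes in columns (unique gene ids as colnames), all finite.
#' @param label character vector, one entry per cell: the perturbed
#'   factor id, or the non-targeting token for control cells.
#' @param nt_token reserved label for non-targeting control cells,
#'   matched case-insensitively after whitespace stripping
#'   (default `"non-targeting"`).
#' @return an object of class `"perturbation_screen"`.
#' @export
perturbation_screen <- function(z, label, nt_token = "non-targeting") {
  z <- as.matrix(z)
  if (is.null(rownames(z)) || is.null(colnames(z))) {
    stop("z must carry cell rownames and gene colnames")
  }
  if (anyDuplicated(rownames(z))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(z))) stop("duplicate gene ids")
  if (!all(is.finite(z))) stop("z-scores must be finite")
  if (length(label) != nrow(z)) stop("one label per cell required")
  label <- as.character(label)
  is_nt <- tolower(trimws(label)) == tolower(nt_token)
  if (!any(is_nt)) stop("screen has no non-targeting control cells")
  structure(list(z = z, label = label, is_nt = is_nt,
                 nt_token = nt_token),
            class = "perturbation_screen")
}

#' @export
print.perturbation_screen <- function(x, ...) {
  cat("perturbation_screen:", nrow(x$z), "cells x", ncol(x$z), "genes;",
      length(unique(x$label[!x$is_nt])), "factors,",
      sum(x$is_nt), "non-targeting cells\n")
  invisible(x)
}

#' Read / write a screen
#'
#' On-disk form: a MatrixMarket file `z.mtx` (cells x genes), a
#' single-column `genes.tsv`, and a `cells.tsv` with columns `cell_id`,
#' `label`. A dense TSV (cells in rows, first column `cell_id`, second
#' `label`, remaining columns genes) is accepted for small screens via
#' `read_screen_tsv()`.
#'
#' @param dir directory holding `z.mtx`, `genes.tsv`, `cells.tsv`.
#' @param nt_token passed to [perturbation_screen()].
#' @return a [perturbation_screen()].
#' @export
read_screen <- function(dir, nt_token = "non-targeting") {
  z <- as.matrix(Matrix::readMM(file.path(dir, "z.mtx")))
  genes <- .read_tsv(file.path(dir, "genes.tsv"))
  cells <- .read_tsv(file.path(dir, "cells.tsv"))
  rownames(z) <- as.character(cells[[1]])
  colnames(z) <- as.character(genes[[1]])
  perturbation_screen(z, as.character(cells$label), nt_token)
}

#' @rdname read_screen
#' @param screen a [perturbation_screen()] to serialize.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(screen$z, sparse = TRUE),
                  file.path(dir, "z.mtx"))
  .write_tsv(data.frame(gene_id = colnames(screen$z)),
             file.path(dir, "genes.tsv"))
  .write_tsv(data.frame(cell_id = rownames(screen$z),
                        label = screen$label),
             file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname read_screen
#' @param path dense TSV path.
#' @export
read_screen_tsv <- function(path, nt_token = "non-targeting") {
  tab <- .read_tsv(path)
  z <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(z) <- as.character(tab[[1]])
  perturbation_screen(z, as.character(tab[[2]]), nt_token)
}
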