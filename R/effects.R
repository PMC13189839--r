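#' Perturbation effect score profile of one factor
#'
#' For each gene, the z-scores of the cells carrying the factor's
#' perturbation are compared against all non-targeting control cells with
#' a Wilcoxon rank-sum test; p-values are Benjamini-Hochberg adjusted
#' across the genes of this profile, and the perturbation effect score is
#' the signed log10 of the q-value:
#' `score = direction * (-log10(max(q, 1e-300)))`, positive when the
#' gene's median z increases under the perturbation. A q of 1 or a tied
#' direction gives a score of exactly 0; the clamp at `1e-300` caps
#' magnitudes near 300.
#'
#' @param screen a [perturbation_screen()].
#' @param factor_id the perturbed factor to profile.
#' @param min_cells minimum cells carrying the perturbation (default 2);
#'   a factor below the floor is skipped (returns `NULL` with a message).
#' @param mode test mode for [rank_sum_test()]; the default `"auto"` uses
#'   exact enumeration at tiny cell counts and the tie-corrected normal
#'   approximation at screen scale.
#' @return named numeric vector of scores over all screen genes, or
#'   `NULL` when the factor is skipped.
#' @export
effect_profile <- function(screen, factor_id, min_cells = 2,
                           mode = "auto") {
  stopifnot(inherits(screen, "perturbation_screen"))
  pert <- !screen$is_nt & screen$label == factor_id
  if (!any(pert)) stop("unknown factor: ", factor_id)
  if (sum(pert) < min_cells) {
    message("factor skipped: ", factor_id, " (", sum(pert),
            " cells < min_cells ", min_cells, ")")
    return(NULL)
  }
  zp <- screen$z[pert, , drop = FALSE]
  zn <- screen$z[screen$is_nt, , drop = FALSE]
  G <- ncol(screen$z)
  p <- numeric(G)
  dir <- integer(G)
  for (g in seq_len(G)) {
    rt <- rank_sum_test(zp[, g], zn[, g], mode)
    p[g] <- rt$p_value
    dir[g] <- rt$direction
  }
  q <- bh_fdr(p)
  score <- dir * (-log10(pmax(q, 1e-300)))
  score[dir == 0L | q >= 1] <- 0
  names(score) <- colnames(screen$z)
  score
}

#' Perturbation effect score matrix of a screen
#'
#' One [effect_profile()] row per eligible factor (those with at least
#' `min_cells` perturbed cells), rows in lexicographic factor order so
#' reruns are byte-identical. Skipped factors are recorded in the result.
#'
#' @inheritParams effect_profile
#' @param min_cells minimum perturbed cells per factor (default 2).
#' @return an object of class `"effect_matrix"`: list with `score`
#'   (factors x genes matrix), `min_cells`, `clamp`, `skipped`.
#' @export
effect_matrix <- function(screen, min_cells = 2, mode = "auto") {
  stopifnot(inherits(screen, "perturbation_screen"))
  factors <- sort(unique(screen$label[!screen$is_nt]))
  counts <- vapply(factors, function(f) {
    sum(!screen$is_nt & screen$label == f)
  }, numeric(1))
  eligible <- factors[counts >= min_cells]
  skipped <- factors[counts < min_cells]
  if (length(eligible) == 0L) stop("no eligible factor in screen")
  for (f in skipped) {
    message("factor skipped: ", f, " (", counts[f],
            " cells < min_cells ", min_cells, ")")
  }
  score <- t(vapply(eligible, function(f) {
    effect_profile(screen, f, min_cells = min_cells, mode = mode)
  }, numeric(ncol(screen$z))))
  dimnames(score) <- list(eligible, colnames(screen$z))
  structure(list(score = score, min_cells = min_cells, clamp = 1e-300,
                 skipped = skipped),
            class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat("effect_matrix:", nrow(x$score), "factors x", ncol(x$score),
      "genes (signed log10 q)\n")
  if (length(x$skipped)) {
    cat("  skipped factors:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / deserialize an effect matrix
#'
#' TSV (factors in rows, first column `factor_id`) plus a JSON sidecar
#' recording `min_cells`, the q clamp and the skipped factors.
#'
#' @param em an `effect_matrix`.
#' @param path output TSV path; the sidecar is written alongside with
#'   extension `.json`.
#' @export
write_effect_matrix <- function(em, path) {
  df <- data.frame(factor_id = rownames(em$score), em$score,
                   check.names = FALSE)
  .write_tsv(df, path)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(min_cells = em$min_cells, clamp = em$clamp,
         skipped = as.character(em$skipped)),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_effect_matrix
#' @export
read_effect_matrix <- function(path) {
  tab <- .read_tsv(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(min_cells = NA, clamp = 1e-300, skipped = character(0))
  }
  structure(list(score = m, min_cells = meta$min_cells,
                 clamp = meta$clamp,
                 skipped = as.character(meta$skipped)),
            class = "effect_matrix")
}
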