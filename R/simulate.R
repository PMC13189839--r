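# Synthetic-data generators with planted ground truth. Every generator
# is a pure function of its arguments: the RNG state is saved, seeded
# locally and restored, so reruns are byte-identical and callers' RNG
# streams are untouched.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulate a bulk RNA-seq count matrix with planted DE genes
#'
#' Negative-binomial counts emulating a small case/control organoid
#' cohort (default 5 cases vs 3 controls). Gene means are drawn
#' log-uniformly over `nb_mean_log_range`; counts are
#' `NB(mean = s_j * mu_g * 2^(+/- effect_log2fc), size = 1/nb_dispersion)`
#' (variance `mu + mu^2 * dispersion`), with the fold-change factor
#' applied to planted up/down genes in case samples only. Deterministic
#' given `seed`.
#'
#' @param n_genes,n_case,n_control dimensions of the experiment.
#' @param n_up,n_down number of planted up-/down-regulated genes.
#' @param effect_log2fc planted absolute log2 fold change (> 0; a value
#'   of 0 plants nothing and yields a null matrix).
#' @param nb_mean_log_range range of `log(mu)` for baseline gene means.
#' @param nb_dispersion NB dispersion (> 0).
#' @param library_size_factors per-sample scale factors (default all 1).
#' @param seed RNG seed.
#' @return list with `cm` (a [count_matrix()]) and `truth` (data.frame
#'   `gene_id`, `log2fc` of planted genes; empty when nothing is
#'   planted).
#' @export
simulate_counts <- function(n_genes = 500, n_case = 5, n_control = 3,
                            n_up = 25, n_down = 25, effect_log2fc = 3,
                            nb_mean_log_range = c(log(20), log(2000)),
                            nb_dispersion = 0.02,
                            library_size_factors = NULL, seed = 1) {
  if (n_up + n_down > n_genes) stop("invalid config: n_up + n_down > n_genes")
  if (n_case < 1L || n_control < 1L) {
    stop("invalid config: need >= 1 sample per group")
  }
  if (nb_dispersion <= 0) stop("invalid config: nb_dispersion must be > 0")
  if (effect_log2fc < 0) stop("invalid config: effect_log2fc must be >= 0")
  n_samples <- n_case + n_control
  if (is.null(library_size_factors)) {
    library_size_factors <- rep(1, n_samples)
  }
  if (length(library_size_factors) != n_samples ||
      any(library_size_factors <= 0)) {
    stop("invalid config: library_size_factors")
  }
  .with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    sample_ids <- c(sprintf("case_%d", seq_len(n_case)),
                    sprintf("ctrl_%d", seq_len(n_control)))
    condition <- rep(c("case", "control"), c(n_case, n_control))
    mu <- exp(stats::runif(n_genes, nb_mean_log_range[1],
                           nb_mean_log_range[2]))
    planted <- sample.int(n_genes, n_up + n_down)
    sgn <- rep(c(1, -1), c(n_up, n_down))
    fold <- rep(1, n_genes)
    if (effect_log2fc > 0) fold[planted] <- 2^(sgn * effect_log2fc)

    counts <- matrix(0, n_genes, n_samples,
                     dimnames = list(gene_ids, sample_ids))
    for (j in seq_len(n_samples)) {
      mu_j <- library_size_factors[j] * mu *
        (if (condition[j] == "case") fold else 1)
      counts[, j] <- stats::rnbinom(n_genes, mu = mu_j,
                                    size = 1 / nb_dispersion)
    }
    truth <- if (effect_log2fc > 0) {
      data.frame(gene_id = gene_ids[planted],
                 log2fc = sgn * effect_log2fc,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(0), log2fc = numeric(0))
    }
    list(cm = count_matrix(counts, condition), truth = truth)
  })
}

#' Simulate a perturbation screen with planted factors
#'
#' Per-cell gene z-scores at the level the analysis consumes (Gaussian
#' baseline `N(0, noise_sd)`), with non-targeting control cells and, for
#' each planted factor, a constant shift `delta` added to its module
#' genes in that factor's cells. Deterministic given `seed`.
#'
#' @param n_genes,n_factors,cells_per_factor,n_nt_cells dimensions.
#' @param planted list of plantings, each a list with `factor_id` (an id
#'   among the simulated factors), `module` (gene ids) and `delta`
#'   (shift; negative = repressor-like).
#' @param noise_sd baseline z-score standard deviation.
#' @param seed RNG seed.
#' @return list with `screen` (a [perturbation_screen()]) and `truth`
#'   (the `planted` list).
#' @export
simulate_screen <- function(n_genes = 500, n_factors = 50,
                            cells_per_factor = 20, n_nt_cells = 100,
                            planted = list(), noise_sd = 1, seed = 1) {
  if (cells_per_factor < 2L) stop("invalid config: cells_per_factor < 2")
  if (n_nt_cells < 2L) stop("invalid config: n_nt_cells < 2")
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  factor_ids <- sprintf("F%03d", seq_len(n_factors))
  for (pl in planted) {
    if (!pl$factor_id %in% factor_ids) {
      stop("planted factor not in screen: ", pl$factor_id)
    }
    if (!all(pl$module %in% gene_ids)) {
      stop("module gene not in universe for factor ", pl$factor_id)
    }
  }
  n_cells <- n_factors * cells_per_factor + n_nt_cells
  label <- c(rep(factor_ids, each = cells_per_factor),
             rep("non-targeting", n_nt_cells))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  .with_seed(seed, {
    z <- matrix(stats::rnorm(n_cells * n_genes, sd = noise_sd),
                n_cells, n_genes, dimnames = list(cell_ids, gene_ids))
    for (pl in planted) {
      rows <- label == pl$factor_id
      cols <- gene_ids %in% pl$module
      z[rows, cols] <- z[rows, cols] + pl$delta
    }
    list(screen = perturbation_screen(z, label), truth = planted)
  })
}

#' Simulate a pathway collection with an optional planted set
#'
#' Random gene sets sampled without replacement from the universe, sizes
#' uniform over `set_size_range`; a planted set (e.g. a known-biased
#' pathway) is appended verbatim. GMT-serializable via [write_gmt()].
#'
#' @param n_pathways number of random sets.
#' @param set_size_range integer range of set sizes.
#' @param universe identifiers to sample from.
#' @param planted optional [gene_set()] appended unchanged.
#' @param seed RNG seed.
#' @return a [gene_set_collection()].
#' @export
simulate_pathways <- function(n_pathways = 50, set_size_range = c(10, 50),
                              universe, planted = NULL, seed = 1) {
  universe <- as.character(universe)
  if (length(universe) == 0L) stop("empty universe")
  if (max(set_size_range) > length(universe)) {
    stop("set size exceeds universe size")
  }
  .with_seed(seed, {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]),
                    n_pathways, replace = TRUE)
    sets <- lapply(seq_len(n_pathways), function(i) {
      gene_set(sprintf("PW%03d", i), sample(universe, sizes[i]))
    })
    if (!is.null(planted)) {
      stopifnot(inherits(planted, "gene_set"))
      sets <- c(sets, list(planted))
    }
    gene_set_collection(sets, "simulated")
  })
}
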