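# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sided rank-sum p: enumerate every size-|x| subset of
# the pooled mid-ranks with combn and double the smaller tail. Kept
# deliberately independent of the package's DP implementation.
ranksum_enum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  W <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  Ws <- colSums(matrix(r[combs], nrow = n1))
  eps <- 1e-9
  pl <- mean(Ws <= W + eps)
  pg <- mean(Ws >= W - eps)
  min(1, 2 * min(pl, pg))
}

# DE result fixture from a bare log2fc vector.
make_de <- function(log2fc, ids = sprintf("g%04d", seq_along(log2fc)),
                    p = rep(0.5, length(log2fc))) {
  de_result(data.frame(gene_id = ids, log2fc = log2fc, p = p,
                       stringsAsFactors = FALSE))
}

# Effect-matrix fixture from a bare factors x genes score matrix.
make_em <- function(score) {
  structure(list(score = score, min_cells = 2, clamp = 1e-300,
                 skipped = character(0)),
            class = "effect_matrix")
}

# Minimal screen: one factor's cells stacked over non-targeting cells.
make_screen <- function(z_pert, z_nt, factor_id = "F1") {
  z <- rbind(z_pert, z_nt)
  rownames(z) <- sprintf("c%03d", seq_len(nrow(z)))
  perturbation_screen(z, c(rep(factor_id, nrow(z_pert)),
                           rep("non-targeting", nrow(z_nt))))
}
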