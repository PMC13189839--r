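test_that("a screen with no signal yields all-zero scores", {
  z_nt <- matrix(c(0.1, 0.5, -0.3, 1.2, 0.4, -0.8), 3, 2,
                 dimnames = list(NULL, c("gA", "gB")))
  scr <- make_screen(z_nt, z_nt)   # perturbed cells identical to NT cells
  expect_equal(unname(effect_profile(scr, "F1")), c(0, 0))
})

test_that("the two-gene toy reproduces hand-computed signed log10 q scores", {
  z_nt <- matrix(c(0, 0.5, 1, -0.2, 0.3, 0.9), 3, 2,
                 dimnames = list(NULL, c("gA", "gB")))
  z_p <- z_nt
  z_p[, "gA"] <- z_p[, "gA"] + 10          # perfect upward separation
  scr <- make_screen(z_p, z_nt)
  prof <- effect_profile(scr, "F1")
  # gA: exact p = 0.1, BH q over 2 genes = 0.2, score = -log10(0.2)
  expect_equal(unname(prof), c(-log10(0.2), 0), tolerance = 1e-12)

  z_dn <- z_nt
  z_dn[, "gA"] <- z_dn[, "gA"] - 10        # perfect downward separation
  prof_dn <- effect_profile(make_screen(z_dn, z_nt), "F1")
  expect_lt(prof_dn[["gA"]], 0)
})

test_that("factors below the cell floor are dropped from the matrix", {
  set.seed(21)
  z <- matrix(rnorm(7 * 3), 7, 3,
              dimnames = list(sprintf("c%d", 1:7), c("g1", "g2", "g3")))
  scr <- perturbation_screen(z, c("A", "A", "B", "B", "C",
                                  "non-targeting", "non-targeting"))
  expect_message(em <- effect_matrix(scr, min_cells = 2), "skipped: C")
  expect_equal(rownames(em$score), c("A", "B"))
  expect_equal(em$skipped, "C")
  expect_error(effect_matrix(scr, min_cells = 10), "no eligible factor")
  expect_error(effect_profile(scr, "missing"), "unknown factor")
})

test_that("cell order does not affect the effect matrix", {
  set.seed(22)
  z <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(sprintf("c%02d", 1:30),
                              sprintf("g%02d", 1:10)))
  lab <- c(rep("A", 10), rep("B", 10), rep("non-targeting", 10))
  perm <- sample(30)
  em1 <- effect_matrix(perturbation_screen(z, lab))
  em2 <- effect_matrix(perturbation_screen(z[perm, ], lab[perm]))
  expect_equal(em1$score, em2$score)
})

test_that("relabeling perturbed and control cells negates the profile", {
  set.seed(24)
  z <- matrix(rnorm(16 * 20), 16, 20,
              dimnames = list(sprintf("c%02d", 1:16),
                              sprintf("g%02d", 1:20)))
  lab <- rep(c("A", "non-targeting"), each = 8)
  p1 <- effect_profile(perturbation_screen(z, lab), "A")
  p2 <- effect_profile(perturbation_screen(z, rev(lab)), "A")
  expect_equal(p1, -p2, tolerance = 1e-12)
})

test_that("a planted factor scores its module above the background", {
  mod <- sprintf("g%05d", 1:20)
  sim <- simulate_screen(n_genes = 200, n_factors = 5,
                         cells_per_factor = 20, n_nt_cells = 60,
                         planted = list(list(factor_id = "F002",
                                             module = mod, delta = 2)),
                         seed = 55)
  em <- effect_matrix(sim$screen)
  s <- em$score["F002", ]
  expect_gt(mean(s[mod]), mean(s[setdiff(names(s), mod)]))
})

test_that("module recovery strengthens monotonically with the planted shift", {
  mod <- sprintf("g%05d", 1:15)
  mean_mod <- vapply(c(0.5, 1, 2, 4), function(delta) {
    runs <- vapply(1:3, function(r) {
      sim <- simulate_screen(n_genes = 150, n_factors = 3,
                             cells_per_factor = 15, n_nt_cells = 50,
                             planted = list(list(factor_id = "F001",
                                                 module = mod,
                                                 delta = delta)),
                             seed = 300 + r)
      mean(effect_profile(sim$screen, "F001")[mod])
    }, numeric(1))
    mean(runs)
  }, numeric(1))
  expect_true(all(diff(mean_mod) >= 0))
})

test_that("effect matrices round-trip through TSV plus sidecar", {
  set.seed(26)
  em <- make_em(matrix(rnorm(6), 2, 3,
                       dimnames = list(c("A", "B"), c("g1", "g2", "g3"))))
  path <- file.path(withr::local_tempdir(), "effects.tsv")
  write_effect_matrix(em, path)
  back <- read_effect_matrix(path)
  expect_equal(back$score, em$score, tolerance = 1e-12)
  expect_equal(back$clamp, em$clamp)
  expect_true(file.exists(sub("tsv$", "json", path)))
})
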