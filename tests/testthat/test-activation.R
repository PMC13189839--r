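toy_em <- function() {
  score <- rbind(
    F1 = c(3, 4, 5, 0, 0, 0),      # strong up bias on the first three genes
    F2 = c(0, 0, 0, 0, 0, 0)       # no signal
  )
  colnames(score) <- sprintf("g%d", 1:6)
  make_em(score)
}

test_that("activation bias reproduces the exact toy p and direction", {
  em <- toy_em()
  gs <- gene_set("BA-Up", c("g1", "g2", "g3"))
  r <- suppressWarnings(activation_test(em, "F1", gs))
  expect_equal(r$p, 0.1)
  expect_equal(r$direction, "up")
  expect_equal(r$n_in, 3)

  flat <- suppressWarnings(activation_test(em, "F2", gs))
  expect_equal(flat$p, 1)
  expect_equal(flat$direction, "none")
})

test_that("thin and empty overlaps are handled as specified", {
  em <- toy_em()
  disjoint <- gene_set("off-screen", c("x1", "x2", "x3"))
  expect_message(r <- activation_test(em, "F1", disjoint), "skipped")
  expect_null(r)
  expect_warning(
    activation_test(em, "F1", gene_set("thin", c("g1", "g2", "g3"))),
    "thin"
  )
  expect_error(
    suppressWarnings(
      activation_test(em, "F1", gene_set("all", colnames(em$score)))
    ),
    "entire screen universe"
  )
  expect_error(activation_test(em, "nope", gene_set("s", "g1")),
               "unknown factor")
})

test_that("negating a profile flips activation direction and preserves p", {
  set.seed(33)
  score <- matrix(rnorm(5 * 60), 5, 60,
                  dimnames = list(sprintf("F%d", 1:5),
                                  sprintf("g%02d", 1:60)))
  em <- make_em(score)
  em_neg <- make_em(-score)
  gs <- gene_set("set", sprintf("g%02d", 1:15))
  for (f in rownames(score)) {
    a <- activation_test(em, f, gs)
    b <- activation_test(em_neg, f, gs)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    if (a$direction != "none") {
      expect_equal(b$direction, setdiff(c("up", "down"), a$direction))
    }
  }
})

test_that("factor classification applies strict per-category thresholds", {
  act <- structure(data.frame(
    factor_id = c("F1", "F2", "F3", "F4", "F5"),
    set_name = c("BA-Up", "BA-Up", "BA-Up", "BA-Down", "BA-Down"),
    n_set_genes_in_screen = 10,
    p = c(0.005, 0.01, 0.05, 0.06, 0.10),
    direction = c("down", "down", "up", "up", "down"),
    stringsAsFactors = FALSE
  ), class = c("activation_table", "data.frame"))

  expect_equal(unname(default_category_thresholds()),
               c(0.11, 0.01, 0.07, 0.08))

  cats <- classify_factors(act)
  expect_equal(cats$categories$down_on_BA_Up, "F1")   # 0.005 < 0.01
  # F2 at exactly 0.01 is excluded: strict inequality
  expect_false("F2" %in% cats$categories$down_on_BA_Up)
  expect_equal(cats$categories$up_on_BA_Up, "F3")     # 0.05 < 0.08
  expect_equal(cats$categories$up_on_BA_Down, "F4")   # 0.06 < 0.07
  expect_equal(cats$categories$down_on_BA_Down, "F5") # 0.10 < 0.11

  expect_error(classify_factors(act, thresholds = c(bogus = 0.1)),
               "unknown threshold key")
  only_up <- act[act$set_name == "BA-Up", ]
  class(only_up) <- class(act)
  expect_error(classify_factors(only_up), "both")
})

test_that("category enrichment matches the exact hypergeometric example", {
  universe <- sprintf("F%02d", 1:10)
  cats <- structure(list(
    categories = list(down_on_BA_Down = character(0),
                      down_on_BA_Up = universe[1:5],
                      up_on_BA_Down = character(0),
                      up_on_BA_Up = character(0)),
    thresholds = default_category_thresholds(),
    up_set = "BA-Up", down_set = "BA-Down"
  ), class = "factor_categories")
  coll <- gene_set_collection(list(
    gene_set("pw", universe[2:5]),            # K = 4, k = 4 of n = 5
    gene_set("off", c("X1", "X2"))            # K = 0 -> skipped
  ))
  enr <- factor_enrichment(cats, coll, universe)
  expect_equal(nrow(enr), 1)                  # empty categories: no rows
  expect_equal(enr$p, 6 / 252, tolerance = 1e-12)
  expect_equal(enr$q, enr$p)
  expect_true(enr$enriched)
  expect_equal(as.data.frame(enr)[, c("k", "n", "K", "N")],
               data.frame(k = 4, n = 5, K = 4, N = 10))
})

test_that("a pathway equal to a category attains the minimal achievable p", {
  universe <- sprintf("F%02d", 1:20)
  members <- universe[1:6]
  cats <- structure(list(
    categories = list(down_on_BA_Down = members,
                      down_on_BA_Up = character(0),
                      up_on_BA_Down = character(0),
                      up_on_BA_Up = character(0)),
    thresholds = default_category_thresholds(),
    up_set = "BA-Up", down_set = "BA-Down"
  ), class = "factor_categories")
  set.seed(44)
  random_sets <- lapply(1:10, function(i) {
    gene_set(paste0("r", i), sample(universe, 6))
  })
  coll <- gene_set_collection(c(list(gene_set("exact", members)),
                                random_sets))
  enr <- factor_enrichment(cats, coll, universe)
  # minimal achievable p for K = n = 6 drawn from N = 20
  expect_equal(min(enr$p), 1 / choose(20, 6), tolerance = 1e-12)
  expect_equal(enr$pathway[which.min(enr$p)], "exact")
})

test_that("end-to-end planted activator lands in up_on_BA_Up", {
  mod <- sprintf("g%05d", 1:25)
  sim <- simulate_screen(n_genes = 300, n_factors = 5,
                         cells_per_factor = 40, n_nt_cells = 100,
                         planted = list(list(factor_id = "F001",
                                             module = mod, delta = 3)),
                         seed = 61)
  em <- effect_matrix(sim$screen)
  sets <- list(gene_set("BA-Up", mod),
               gene_set("BA-Down", sprintf("g%05d", 250:280)))
  act <- suppressWarnings(activation_table(em, sets))
  cats <- classify_factors(act)
  expect_true("F001" %in% cats$categories$up_on_BA_Up)
  expect_false("F001" %in% cats$categories$down_on_BA_Up)
})
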