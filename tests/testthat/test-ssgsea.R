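test_that("rank_genes ranks highest expression at N and handles ties", {
  x <- matrix(c(5, 1, 3), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(rank_genes(x, "s1"), c(a = 3, b = 1, c = 2))
  x[] <- 2
  expect_equal(unname(rank_genes(x, "s1")), rep(2, 3))
  x[] <- c(2, 2, 9)
  expect_equal(unname(rank_genes(x, "s1")), c(1.5, 1.5, 3))
  expect_equal(unname(rank_genes(x, "s1", tie_rule = "min")), c(1, 1, 3))
  expect_error(rank_genes(x, "nope"), "unknown sample")
})

test_that("hand-derived enrichment scores for one-gene sets are exact", {
  ranks <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  expect_identical(enrichment_score(ranks, "g1", alpha = 1), 2)
  expect_identical(enrichment_score(ranks, "g4", alpha = 1), -2)
})

test_that("closed-form ES equals the naive position walk", {
  set.seed(101)
  for (i in 1:50) {
    inst <- random_instance(20)
    for (a in c(0, 0.25, 1)) {
      expect_equal(enrichment_score(inst$ranks, inst$set, alpha = a),
                   naive_es_walk(inst$ranks, inst$set, alpha = a),
                   tolerance = 1e-12)
    }
  }
})

test_that("ES is invariant under strictly increasing transforms and gene permutation", {
  set.seed(202)
  x <- matrix(rnorm(300), nrow = 30,
              dimnames = list(paste0("G", 1:30), paste0("s", 1:10)))
  sets <- list(A = paste0("G", 1:5), B = paste0("G", c(7, 12, 19)))
  e1 <- score_all(x, sets, norm = "none")
  e2 <- score_all(exp(x), sets, norm = "none")
  expect_identical(e1$es, e2$es)
  perm <- sample(nrow(x))
  e3 <- score_all(x[perm, ], sets, norm = "none")
  expect_equal(e3$es, e1$es)
})

test_that("complement sets have opposite ES at alpha = 0", {
  set.seed(303)
  for (i in 1:10) {
    inst <- random_instance(15)
    comp <- setdiff(inst$genes, inst$set)
    expect_equal(enrichment_score(inst$ranks, inst$set, alpha = 0),
                 -enrichment_score(inst$ranks, comp, alpha = 0),
                 tolerance = 1e-12)
  }
})

test_that("top-ranked sets score positive, bottom-ranked negative, for all alpha", {
  set.seed(404)
  expr <- setNames(rnorm(40), paste0("G", 1:40))
  r <- rank(expr)
  top <- names(sort(r, decreasing = TRUE))[1:8]
  bottom <- names(sort(r))[1:8]
  for (a in c(0, 0.25, 1, 2)) {
    expect_gt(enrichment_score(r, top, alpha = a), 0)
    expect_lt(enrichment_score(r, bottom, alpha = a), 0)
  }
})

test_that("score_all normalises by the global ES range", {
  ranks4 <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  x <- matrix(c(4, 3, 2, 1), ncol = 1, dimnames = list(names(ranks4), "s1"))
  x <- cbind(x, s2 = c(4, 3, 2, 1))
  sets <- list(TOP = "g1", BOT = "g4")
  enr <- score_all(x, sets, alpha = 1, norm = "global_range", min_size = 1L)
  expect_equal(enr$norm_constant, 4)
  expect_equal(unname(enr$nes["TOP", ]), c(0.5, 0.5))
  expect_equal(unname(enr$nes["BOT", ]), c(-0.5, -0.5))

  # norm = none is the identity; range mode spans exactly 1
  set.seed(9)
  x <- matrix(rnorm(50 * 10), nrow = 50,
              dimnames = list(paste0("G", 1:50), paste0("s", 1:10)))
  sets <- lapply(1:5, function(i) sample(rownames(x), 8))
  names(sets) <- paste0("S", 1:5)
  e0 <- score_all(x, sets, norm = "none")
  expect_identical(e0$nes, e0$es)
  e1 <- score_all(x, sets, norm = "global_range")
  expect_equal(max(e1$nes) - min(e1$nes), 1)
  expect_equal(e1$nes * e1$norm_constant, e1$es)
  expect_lte(max(abs(e1$nes)), 1)
})

test_that("score_all drops non-overlapping sets with a warning and errors on degenerate grids", {
  x <- matrix(rnorm(20), nrow = 5,
              dimnames = list(paste0("G", 1:5), paste0("s", 1:4)))
  sets <- list(A = c("G1", "G2"), MISSING = c("zz1", "zz2"))
  expect_warning(enr <- score_all(x, sets, norm = "none"), "MISSING")
  expect_identical(rownames(enr$es), "A")

  # identical samples + one set -> zero ES range
  xid <- matrix(rep(c(1, 2, 3, 4, 5), 2), ncol = 2,
                dimnames = list(paste0("G", 1:5), c("s1", "s2")))
  expect_error(score_all(xid, list(A = c("G1", "G2")), norm = "global_range"),
               "range-normalise")
  expect_error(score_all(x, list(ALL = rownames(x))), "covering|overlaps")
})

test_that("infiltration_scores matches score_all and keeps its own label", {
  set.seed(11)
  x <- matrix(rnorm(200), nrow = 20,
              dimnames = list(paste0("G", 1:20), paste0("s", 1:10)))
  sigs <- structure(lapply(1:4, function(i) sample(rownames(x), 5)),
                    names = paste0("CELL", 1:4), source_label = "stromal28")
  a <- infiltration_scores(x, sigs)
  b <- score_all(x, sigs)
  expect_identical(a$nes, b$nes)
  expect_identical(a$source_label, "stromal28")
  expect_equal(nrow(a$nes), 4L)
})
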