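test_that("range normalisation gives the documented weights", {
  m <- morph_matrix(
    c("A", "B", "C"),
    morph_defs(c("ordered", "continuous", "unordered", "unordered"),
               n_states = c(3L, NA, 2L, 2L)),
    list(mk_discrete(c(0, 1, 2)), c(2, 3, 4),
         mk_discrete(c(0, 1, 1)), mk_discrete(c(0, 0, 0))))
  w <- assign_range_weights(m)
  expect_equal(w$matrix$defs$weight[1], 0.5)        # three ordered states
  expect_equal(w$matrix$defs$weight[2], 0.5)        # continuous range 2
  expect_equal(w$matrix$defs$weight[3], 1)          # binary: no weighting
  expect_false(w$matrix$defs$active[4])             # invariant
  expect_equal(w$report$reason[4], "invariant")
})

test_that("a continuous character's observed span costs exactly one step", {
  m <- one_char_matrix(c("A", "B", "C"), "continuous", c(2, 3, 4))
  wm <- assign_range_weights(m)$matrix
  pair <- ape::read.tree(text = "((A,C),B);")
  # path A(2) .. C(4) spans the full range; total = weighted span = 1 + within
  b <- char_step_bounds(wm, 1)
  expect_equal(unname(b["min"]), 1)
})

test_that("weighting is idempotent", {
  m <- random_matrix(6L, seed = 4)
  w1 <- assign_range_weights(m)$matrix
  w2 <- assign_range_weights(w1)$matrix
  expect_equal(w1$defs$weight, w2$defs$weight)
  expect_equal(w1$defs$active, w2$defs$active)
})

test_that("polymorphic cells widen the observed range", {
  m <- one_char_matrix(c("A", "B"), "ordered", list(1L, c(0L, 2L)))
  w <- assign_range_weights(m)
  expect_equal(w$matrix$defs$weight[1], 0.5)
})

test_that("after weighting, the minimum possible weighted steps of every variable ordered or continuous character is 1", {
  # holds when the range endpoints are realised by monomorphic cells; a
  # polymorphic endpoint cell widens the weighting range (both its extreme
  # states are real observations) while scoring may satisfy it more
  # cheaply inside its interval, so polymorphism is excluded here
  for (seed in 1:8) {
    m <- random_matrix(6L, n_unord = 1L, n_ord = 3L, n_cont = 2L, seed = seed,
                       polymorphism_rate = 0)
    wm <- assign_range_weights(m)$matrix
    for (j in which(wm$defs$active & wm$defs$kind != "unordered")) {
      b <- char_step_bounds(wm, j)
      if (b["max"] > 1e-9) expect_equal(unname(b["min"]), 1, tolerance = 1e-9)
    }
  }
})

test_that("equal-width discretisation follows the half-open bin rule", {
  m <- one_char_matrix(c("A", "B", "C"), "continuous", c(0, 0.5, 1))
  d <- discretize_continuous(m, n_bins = 2L)
  expect_equal(d$defs$kind[1], "ordered")
  expect_equal(unlist(d$cells[[1]]), c(0L, 1L, 1L))   # midpoint in top bin
  # downstream weight 1/(n_bins - 1)
  w <- assign_range_weights(d)$matrix
  expect_equal(w$defs$weight[1], 1)
  d3 <- discretize_continuous(one_char_matrix(c("A", "B", "C"), "continuous",
                                              c(0, 1, 2)), n_bins = 3L)
  expect_equal(assign_range_weights(d3)$matrix$defs$weight[1], 0.5)
})

test_that("degenerate discretisation inputs are deactivated, not binned", {
  m <- one_char_matrix(c("A", "B"), "continuous", c(1, 1))
  m2 <- morph_matrix(m$taxa, rbind(m$defs, morph_defs("unordered", 2L)),
                     c(m$cells, list(mk_discrete(c(0, 1)))))
  d <- discretize_continuous(m2, 3L)
  expect_false(d$defs$active[1])
  expect_false(any(d$defs$kind == "continuous"))
})

test_that("a matrix with no surviving characters is rejected", {
  m <- one_char_matrix(c("A", "B"), "unordered", mk_discrete(c(0, 0)), 2L)
  expect_error(assign_range_weights(m), "no active characters")
})

test_that("missing cells keep their state through discretisation", {
  m <- one_char_matrix(c("A", "B", "C"), "continuous", c(0, NA, 2))
  d <- discretize_continuous(m, 2L)
  expect_identical(d$cells[[1]][[2]], NA_integer_)
})
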