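test_that("worked scoring examples match hand values", {
  tr <- read_trees("((A,B),(C,D));")[[1]]
  m <- one_char_matrix(c("A", "B", "C", "D"), "unordered",
                       mk_discrete(c(0, 1, 0, 1)), 2L)
  expect_equal(character_steps(tr, m, 1), 2)
  # ordered sisters at the endpoints of a three-state character, weight 0.5
  m2 <- one_char_matrix(c("A", "B", "C", "D"), "ordered",
                        mk_discrete(c(0, 2, 0, 0)), 3L, weight = 0.5)
  expect_equal(character_steps(tr, m2, 1), 1.0)
  # continuous on the 3-leaf star: L1 median
  m3 <- one_char_matrix(c("A", "B", "C"), "continuous", c(1, 2, 4),
                        weight = 1 / 3)
  star <- read_trees("(A,B,C);")[[1]]
  expect_equal(character_steps(star, m3, 1), 1.0)
})

test_that("DP equals brute force over internal assignments on random cases", {
  cases <- 0L
  for (seed in 1:12) {
    n <- sample(4:6, 1L)
    m <- random_matrix(n, n_unord = 2L, n_ord = 2L, n_cont = 1L, seed = seed)
    trees <- all_topologies(m$taxa)
    tr <- trees[[withr::with_seed(seed, sample(length(trees), 1L))]]
    for (j in seq_len(5L)) {
      expect_equal(character_steps(tr, m, j),
                   brute_force_steps(tr, m, j) * m$defs$weight[j],
                   tolerance = 1e-9)
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 50L)
})

test_that("unordered scoring on binary trees agrees with phangorn's Fitch", {
  for (seed in 1:5) {
    m <- random_matrix(6L, n_unord = 6L, n_ord = 0L, n_cont = 0L,
                       seed = seed, polymorphism_rate = 0)
    tr <- all_topologies(m$taxa)[[seed * 3L]]
    states <- do.call(cbind, lapply(m$cells, function(col)
      vapply(col, function(s) if (is.na(s[1]) || s[1] == -1L) "?" else
        as.character(s[1]), character(1L))))
    rownames(states) <- m$taxa
    pd <- phangorn::phyDat(states, type = "USER", levels = c("0", "1", "2"))
    expect_equal(tree_length(tr, m)$total_length,
                 phangorn::parsimony(tr, pd), tolerance = 1e-9)
  }
})

test_that("length is invariant to taxon row order and polytomies score exactly", {
  m <- random_matrix(6L, seed = 20)
  tr <- all_topologies(m$taxa)[[7L]]
  perm <- rev(m$taxa)
  expect_equal(tree_length(tr, m)$total_length,
               tree_length(tr, subset_taxa(m, perm))$total_length)
  star <- read_trees(paste0("(", paste(m$taxa, collapse = ","), ");"))[[1]]
  for (j in 1:6) {
    expect_equal(character_steps(star, m, j),
                 brute_force_steps(star, m, j) * m$defs$weight[j],
                 tolerance = 1e-9)
  }
})

test_that("continuous scoring shifts and scales correctly", {
  m <- one_char_matrix(c("A", "B", "C", "D"), "continuous", c(1, 2, 4, 7))
  tr <- read_trees("((A,B),(C,D));")[[1]]
  s0 <- character_steps(tr, m, 1)
  m_shift <- one_char_matrix(m$taxa, "continuous", c(1, 2, 4, 7) + 11.5)
  expect_equal(character_steps(tr, m_shift, 1), s0)
  m_scale <- one_char_matrix(m$taxa, "continuous", c(1, 2, 4, 7) * 3)
  expect_equal(character_steps(tr, m_scale, 1), 3 * s0)
  # weighted cost unchanged after re-weighting
  w0 <- assign_range_weights(m)$matrix
  w1 <- assign_range_weights(m_scale)$matrix
  expect_equal(character_steps(tr, w0, 1), character_steps(tr, w1, 1))
})

test_that("step bounds match their closed forms", {
  m <- one_char_matrix(LETTERS[1:5], "unordered",
                       mk_discrete(c(0, 0, 1, 1, 2)), 3L)
  expect_equal(char_step_bounds(m, 1), c(min = 2, max = 3))
  m2 <- one_char_matrix(c("A", "B"), "ordered", mk_discrete(c(0, 2)), 3L)
  expect_equal(char_step_bounds(m2, 1), c(min = 2, max = 2))
  m3 <- one_char_matrix(LETTERS[1:3], "continuous", c(1, 2, 4))
  expect_equal(char_step_bounds(m3, 1), c(min = 3, max = 3))
})

test_that("homoplasy indices follow their formulas", {
  tr <- read_trees("((A,B),(C,D));")[[1]]
  cong <- congruent_matrix(read_trees("((A,B),(C,D),E);")[[1]])
  tr5 <- read_trees("((A,B),(C,D),E);")[[1]]
  r <- homoplasy_indices(tr5, cong)
  expect_equal(r$CI, 1)
  expect_equal(r$RI, 1)
  m <- one_char_matrix(c("A", "B", "C", "D"), "unordered",
                       mk_discrete(c(0, 1, 0, 1)), 2L)
  r2 <- homoplasy_indices(tr, m)
  expect_equal(r2$CI, 0.5)
  expect_equal(r2$RI, 0)
  expect_equal(r2$total_length,
               sum(r2$per_character_steps, na.rm = TRUE))
})

test_that("forcing a homoplastic step strictly decreases CI", {
  taxa <- LETTERS[1:6]
  good <- read_trees("(((A,B),C),((D,E),F));")[[1]]
  cong <- congruent_matrix(good)
  # regraft A next to D: both (A,B) and (D,E) characters gain a step
  worse <- read_trees("((B,C),(((A,D),E),F));")[[1]]
  ci_good <- homoplasy_indices(good, cong)$CI
  ci_worse <- homoplasy_indices(worse, cong)$CI
  expect_lt(ci_worse, ci_good)
})

test_that("scoring errors are informative", {
  m <- one_char_matrix(c("A", "B", "C", "D"), "unordered",
                       mk_discrete(c(0, 1, 0, 1)), 2L)
  tr <- read_trees("((A,B),(C,E));")[[1]]
  expect_error(character_steps(tr, m, 1), "leaf without a matrix row: E")
  m$defs$active[1] <- FALSE
  m <- morph_matrix(m$taxa, m$defs, m$cells)
  expect_error(character_steps(read_trees("((A,B),(C,D));")[[1]], m, 1),
               "inactive")
  cons <- one_char_matrix(c("A", "B", "C"), "unordered",
                          mk_discrete(c(0, 0, 1)), 2L)
  expect_error(homoplasy_indices(read_trees("(A,B,C);")[[1]], cons),
               "uninformative")
})
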