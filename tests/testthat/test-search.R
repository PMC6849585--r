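make_test_scaffold <- function() {
  bb <- read_trees("((X,Y),(Z,W));")[[1]]
  constraint_scaffold(backbone = bb, floaters = "F")
}

test_that("admissibility: floaters invade, contradictions are rejected, polytomies may resolve", {
  sc <- make_test_scaffold()
  good <- read_trees("(((X,F),Y),(Z,W));")[[1]]      # floater inside (X,Y)
  expect_true(is_admissible(good, sc))
  bad <- read_trees("(((X,Z),Y),(W,F));")[[1]]       # X grouped with Z
  expect_false(is_admissible(bad, sc))
  expect_error(is_admissible(read_trees("((X,Y),(Z,Q));")[[1]], sc),
               "leaves do not match")
  # polytomy in the backbone resolved arbitrarily
  sc_poly <- constraint_scaffold(
    backbone = read_trees("((X,Y,Z),(W,V));")[[1]], floaters = character(0))
  res1 <- read_trees("(((X,Y),Z),(W,V));")[[1]]
  res2 <- read_trees("(((X,Z),Y),(W,V));")[[1]]
  expect_true(is_admissible(res1, sc_poly))
  expect_true(is_admissible(res2, sc_poly))
})

test_that("random addition is deterministic, admissible and optimal on clean data", {
  true <- read_trees("(((A,B),C),((D,E),F));")[[1]]
  m <- congruent_matrix(true)
  sc <- constraint_scaffold(floaters = m$taxa)
  t1 <- random_addition_tree(m, sc, seed = 5)
  t2 <- random_addition_tree(m, sc, seed = 5)
  expect_equal(write_trees(t1), write_trees(t2))
  expect_equal(tree_length(t1, m)$total_length, exhaustive_best_length(m))
  sc2 <- make_scaffold(true, c("A", "B", "D", "E"))
  t3 <- random_addition_tree(m, sc2, seed = 3)
  expect_true(is_admissible(t3, sc2))
})

test_that("search on a congruent matrix returns the generating tree as the single MPT", {
  true <- read_trees("(((A,B),C),((D,E),F));")[[1]]
  m <- congruent_matrix(true)
  ens <- tbr_search(m, n_starts = 2, seed = 1)
  expect_length(mpt_trees(ens), 1L)
  expect_equal(ens$best_length, exhaustive_best_length(m))
  expect_equal(phangorn::RF.dist(mpt_trees(ens)[[1]], ape::unroot(true)), 0)
})

test_that("search respects the scaffold and epsilon grows the pool monotonically", {
  true <- read_trees("(((A,B),C),((D,E),F));")[[1]]
  m <- assign_range_weights(
    simulate_matrix(sim_config(ape::compute.brlen(true, 1), n_unordered = 12L,
                               n_states = 2L, rate = 1.2, seed = 3))$matrix)$matrix
  sc <- make_scaffold(true, c("A", "B", "D", "E"))
  ens <- tbr_search(m, sc, n_starts = 2, seed = 2)
  for (tr in ens$trees) {
    expect_true(is_admissible(tr, sc))
    expect_true(displays_clade(ape::keep.tip(tr, c("A", "B", "D", "E")),
                               c("A", "B")))
  }
  e0 <- tbr_search(m, NULL, n_starts = 2, seed = 2, epsilon = 0)
  e1 <- tbr_search(m, NULL, n_starts = 2, seed = 2, epsilon = 1)
  k0 <- vapply(e0$trees, function(t) paste(sort(tree_splits(t)), collapse = ";"),
               character(1L))
  k1 <- vapply(e1$trees, function(t) paste(sort(tree_splits(t)), collapse = ";"),
               character(1L))
  expect_true(all(k0 %in% k1))
  # reproducibility of the whole ensemble
  e1b <- tbr_search(m, NULL, n_starts = 2, seed = 2, epsilon = 1)
  expect_equal(e1$lengths, e1b$lengths)
  expect_identical(lapply(e1$trees, write_trees), lapply(e1b$trees, write_trees))
})

test_that("multi-start search finds the exhaustive optimum on small random matrices", {
  for (seed in c(2, 5, 9)) {
    n <- if (seed == 9) 7L else 6L
    m <- assign_range_weights(random_matrix(n, n_unord = 5L, n_ord = 2L,
                                            n_cont = 1L, seed = seed))$matrix
    ens <- tbr_search(m, n_starts = 5, seed = seed)
    expect_equal(ens$best_length, exhaustive_best_length(m), tolerance = 1e-9)
  }
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- read_trees("((A,B),C,(D,E));")[[1]]
  t2 <- read_trees("((A,B),(C,D),E);")[[1]]
  cons <- strict_consensus(list(t1, t2))
  expect_equal(unclass(tree_splits(cons)),
               unclass(tree_splits(read_trees("((A,B),C,D,E);")[[1]])))
  expect_equal(length(tree_splits(cons)), 1L)
  # identical inputs reproduce the input topology
  same <- strict_consensus(list(t1, t1))
  expect_setequal(unclass(tree_splits(same)), unclass(tree_splits(t1)))
  # all binary topologies on 5 leaves give the star
  allt <- phangorn::allTrees(5, rooted = FALSE, tip.label = LETTERS[1:5])
  expect_equal(length(tree_splits(strict_consensus(allt))), 0L)
  expect_error(strict_consensus(list(t1, read_trees("((A,B),(C,F),E);")[[1]])),
               "differing leaf sets")
  # cross-check against ape on a non-trivial case
  cons_ape <- ape::consensus(c(t1, t2), p = 1)
  expect_equal(phangorn::RF.dist(cons, cons_ape), 0)
})

test_that("suboptimal collection matches exhaustive enumeration within the bound", {
  true <- read_trees("(((A,B),C),((D,E),F));")[[1]]
  m <- assign_range_weights(
    simulate_matrix(sim_config(ape::compute.brlen(true, 1), n_unordered = 15L,
                               n_states = 2L, rate = 0.5, seed = 3))$matrix)$matrix
  ens <- tbr_search(m, n_starts = 3, seed = 2)
  # schedule {0} returns exactly the MPT set
  sub0 <- collect_suboptimal(m, NULL, ens, epsilon_schedule = 0)
  expect_equal(length(sub0$trees), length(mpt_trees(ens)))
  sub2 <- collect_suboptimal(m, NULL, ens, epsilon_schedule = c(1, 2))
  lens <- vapply(all_topologies(m$taxa), function(t)
    tree_length(t, m)$total_length, numeric(1L))
  expect_equal(length(sub2$trees), sum(lens <= min(lens) + 2 + 1e-9))
  expect_true(all(sub2$lengths <= sub2$best_length + 2 + 1e-9))
  # cap truncates and flags
  capped <- collect_suboptimal(m, NULL, ens, epsilon_schedule = c(1, 2),
                               cap = 10)
  expect_lte(length(capped$trees), 10L)
  expect_true(capped$truncated)
})
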