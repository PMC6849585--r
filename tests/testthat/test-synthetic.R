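test_that("simulation honours missing_rate and is seed-reproducible", {
  tt <- ape::compute.brlen(balanced8(), 0.5)
  cfg <- sim_config(tt, n_unordered = 10L, n_ordered = 4L, n_continuous = 3L,
                    rate = 0.5, missing_rate = 0, seed = 4)
  sim <- simulate_matrix(cfg)
  for (j in seq_len(n_chars(sim$matrix))) {
    expect_equal(length(morphparsimony:::observed_values(sim$matrix, j)), 8L)
  }
  sim2 <- simulate_matrix(cfg)
  expect_true(identical_matrix(sim$matrix, sim2$matrix))
  cfg3 <- sim_config(tt, n_unordered = 10L, rate = 0.5, missing_rate = 0.4,
                     seed = 4)
  sim3 <- simulate_matrix(cfg3)
  n_missing <- sum(vapply(seq_len(10L), function(j)
    8L - length(morphparsimony:::observed_values(sim3$matrix, j)), integer(1L)))
  expect_gt(n_missing, 0L)
})

test_that("fossil-style multipliers concentrate missingness in chosen taxa", {
  tt <- ape::compute.brlen(balanced8(), 0.5)
  cfg <- sim_config(tt, n_unordered = 60L, rate = 0.5, missing_rate = 0.2,
                    taxon_missing_multiplier = c(A = 3, B = 3), seed = 5)
  sim <- simulate_matrix(cfg)
  miss_by_taxon <- vapply(seq_len(8L), function(i) {
    sum(vapply(sim$matrix$cells, function(col) is.na(col[[i]][1]), logical(1L)))
  }, numeric(1L))
  names(miss_by_taxon) <- sim$matrix$taxa
  expect_gt(mean(miss_by_taxon[c("A", "B")]),
            mean(miss_by_taxon[setdiff(names(miss_by_taxon), c("A", "B"))]))
})

test_that("homoplasy rises with the evolutionary rate", {
  tt <- ape::compute.brlen(balanced8(), 0.5)
  ci_at <- function(rate, seed) {
    cfg <- sim_config(tt, n_unordered = 40L, n_states = 3L, rate = rate,
                      missing_rate = 0, seed = seed)
    m <- assign_range_weights(simulate_matrix(cfg)$matrix)$matrix
    ens <- tbr_search(m, n_starts = 2, seed = seed)
    homoplasy_indices(mpt_trees(ens)[[1]], m)$CI
  }
  expect_gt(ci_at(0.05, 3), ci_at(3, 3))
  expect_gt(ci_at(0.05, 9), ci_at(3, 9))
})

test_that("scaffold construction restricts, collapses and stays consistent", {
  tt <- ape::compute.brlen(balanced8(), 0.5)
  sc0 <- make_scaffold(tt, c("A", "B", "E", "F"), collapse_fraction = 0)
  expect_setequal(sc0$backbone$tip.label, c("A", "B", "E", "F"))
  expect_true(displays_clade(sc0$backbone, c("A", "B")))
  sc1 <- make_scaffold(tt, c("A", "B", "E", "F", "G"), collapse_fraction = 1)
  expect_equal(length(tree_splits(sc1$backbone)), 0L)   # star backbone
  for (cf in c(0, 0.5, 1)) {
    sc <- make_scaffold(tt, c("A", "C", "E", "G"), collapse_fraction = cf,
                        seed = 2)
    expect_true(is_admissible(ape::unroot(tt), sc))
  }
  expect_error(make_scaffold(tt, c("A", "B", "C")), "at least 4")
})

test_that("the bundled study-shaped configuration scales", {
  ps <- paper_shaped_config(scale = 0.1, seed = 2)
  expect_s3_class(ps$config, "sim_config")
  expect_equal(length(ps$config$model_tree$tip.label), 18L)  # 177 * 0.1 rounded
  expect_equal(ps$outgroups, c("Outgroup1", "Outgroup2", "Outgroup3"))
  sim <- simulate_matrix(ps$config)
  expect_equal(n_chars(sim$matrix),
               ps$config$n_unordered + ps$config$n_ordered +
                 ps$config$n_continuous)
  sc <- make_scaffold(sim$true_tree, ps$non_floaters,
                      collapse_fraction = ps$collapse_fraction, seed = 2,
                      outgroups = ps$outgroups)
  expect_true(is_admissible(ape::unroot(sim$true_tree), sc))
  # sequential outgroups branch basally in the model tree: everything but
  # the first two outgroups forms a clade, and likewise for the first three
  rooted <- root_at_outgroups(sim$true_tree, ps$outgroups)
  expect_true(displays_clade(rooted,
                             setdiff(rooted$tip.label,
                                     c("Outgroup1", "Outgroup2"))))
  expect_true(displays_clade(rooted,
                             setdiff(rooted$tip.label, ps$outgroups)))
})
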