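rooted4 <- function() {
  ape::root(read_trees("((A,B),(C,D));")[[1]], outgroup = "A",
            resolve.root = TRUE)
}

test_that("a congruent character reconstructs without ambiguity", {
  tr <- rooted4()
  m <- one_char_matrix(c("A", "B", "C", "D"), "unordered",
                       mk_discrete(c(0, 0, 1, 1)), 2L)
  rt <- mpr_sets(tr, m, 1)
  node_cd <- clade_node <- ape::getMRCA(tr, c("C", "D"))
  expect_equal(rt$node_states[[node_cd]], 1L)
  root <- length(tr$tip.label) + 1L
  expect_equal(rt$node_states[[root]], 0L)
  syn <- unambiguous_synapomorphies(tr, m, c("C", "D"))
  expect_equal(syn$character, 1L)
  expect_true(syn$unambiguous)
  expect_equal(syn$ancestral, "0")
  expect_equal(syn$derived, "1")
})

test_that("the textbook ambiguous case yields {0,1} internal MPR sets", {
  tr <- rooted4()
  m <- one_char_matrix(c("A", "B", "C", "D"), "unordered",
                       mk_discrete(c(0, 1, 0, 1)), 2L)
  rt <- mpr_sets(tr, m, 1)
  internals <- (length(tr$tip.label) + 1L):(length(tr$tip.label) + tr$Nnode)
  ambiguous <- vapply(rt$node_states[internals], length, integer(1L))
  expect_true(all(ambiguous == 2L))
})

test_that("continuous MPR intervals collapse to the observed endpoints", {
  tr <- rooted4()
  m <- one_char_matrix(c("A", "B", "C", "D"), "continuous", c(1, 1, 4, 4))
  rt <- mpr_sets(tr, m, 1)
  node_cd <- ape::getMRCA(tr, c("C", "D"))
  expect_equal(rt$node_states[[node_cd]], 4)
  syn <- unambiguous_synapomorphies(tr, m, c("C", "D"))
  expect_true(syn$unambiguous)
})

test_that("polytomies are refused with guidance", {
  star <- ape::root(read_trees("(A,B,C,D);")[[1]], outgroup = "A",
                    resolve.root = TRUE)
  m <- one_char_matrix(c("A", "B", "C", "D"), "unordered",
                       mk_discrete(c(0, 0, 1, 1)), 2L)
  expect_error(mpr_sets(star, m, 1), "binary")
})

test_that("every MPR-consistent assignment attains the DP cost, and no other", {
  for (seed in c(3, 11)) {
    m <- random_matrix(5L, n_unord = 2L, n_ord = 1L, n_cont = 1L, seed = seed)
    tr <- ape::root(all_topologies(m$taxa)[[4L]], outgroup = sort(m$taxa)[1],
                    resolve.root = TRUE)
    for (j in seq_len(4L)) {
      rt <- mpr_sets(tr, m, j)
      expect_equal(rt$steps, brute_force_steps(tr, m, j), tolerance = 1e-9)
      expect_true(all(lengths(rt$node_states) > 0L))
    }
  }
})

test_that("a gain with two equally parsimonious placements is flagged ambiguous", {
  # ((Out,E),(X,(A,B))) with character 0 0 1 1 1 on (X,A,B):
  # the single gain can sit on the branch to (X,(A,B)) or deeper; make the
  # derived state shared by X and (A,B) but with one reversal candidate
  tr <- ape::root(read_trees("((Out,E),(X,(A,B)));")[[1]], outgroup = "Out",
                  resolve.root = TRUE)
  m <- one_char_matrix(c("Out", "E", "X", "A", "B"), "unordered",
                       mk_discrete(c(0, 1, 0, 1, 1)), 2L)
  # two MPRs: gain on (A,B) + gain on E, or gain at the (X,(A,B))/E level
  # with a loss in X; the branch to (A,B) changes only in some MPRs
  syn <- unambiguous_synapomorphies(tr, m, c("A", "B"))
  if (nrow(syn)) expect_false(any(syn$unambiguous))
})

test_that("sum of unambiguous change magnitudes never exceeds the step count", {
  m <- random_matrix(6L, seed = 21)
  tr <- ape::root(all_topologies(m$taxa)[[10L]], outgroup = sort(m$taxa)[1],
                  resolve.root = TRUE)
  for (j in which(m$defs$active)) {
    rt <- mpr_sets(tr, m, j)
    kind <- m$defs$kind[j]
    total <- 0
    for (e in seq_len(nrow(tr$edge))) {
      P <- rt$node_states[[tr$edge[e, 1]]]
      Cn <- rt$node_states[[tr$edge[e, 2]]]
      if (length(P) && length(Cn) &&
          morphparsimony:::mpr_disjoint(P, Cn, kind)) {
        total <- total + if (kind == "unordered") 1 else
          max(min(Cn) - max(P), min(P) - max(Cn))
      }
    }
    expect_lte(total, rt$steps + 1e-9)
  }
})

test_that("consistent synapomorphies intersect across trees", {
  t1 <- ape::root(read_trees("((O,(A,B)),(C,D));")[[1]], outgroup = "O",
                  resolve.root = TRUE)
  t2 <- ape::root(read_trees("((O,C),((A,B),D));")[[1]], outgroup = "O",
                  resolve.root = TRUE)
  m <- morph_matrix(c("O", "A", "B", "C", "D"),
                    morph_defs(rep("unordered", 2), 2L),
                    list(mk_discrete(c(0, 1, 1, 0, 0)),    # clean (A,B)
                         mk_discrete(c(0, 1, 1, 0, 1))))   # also in D
  res <- consistent_synapomorphies(list(t1, t2), m, c("A", "B"))
  expect_true(1L %in% res$character)
  expect_equal(attr(res, "n_trees"), 2L)
  expect_error(consistent_synapomorphies(list(t1), m, c("A", "C")), "absent")
})
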