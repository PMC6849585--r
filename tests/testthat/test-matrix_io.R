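test_that("a minimal TNT matrix parses with correct dimensions and kinds", {
  m <- read_matrix("xread\n2 3\nA 00\nB 01\nC 11\n;")
  expect_equal(m$taxa, c("A", "B", "C"))
  expect_equal(dim(m), c(3L, 2L))
  expect_true(all(m$defs$kind == "unordered"))
  expect_true(all(m$defs$n_states == 2L))
})

test_that("cell tokens carry their documented semantics", {
  m <- read_matrix("xread\n3 2\nA ?[01]-\nB 111\n;")
  expect_identical(m$cells[[1]][[1]], NA_integer_)      # '?' missing
  expect_identical(m$cells[[2]][[1]], c(0L, 1L))        # '[01]' polymorphism
  expect_identical(m$cells[[3]][[1]], -1L)              # '-' inapplicable
})

test_that("read/write round-trips are the identity in both dialects", {
  for (seed in 1:6) {
    m <- random_matrix(5L, seed = seed)
    # decorate with the full definition surface
    m$defs$weight[2] <- 0.25
    m$defs$active[4] <- FALSE
    m$defs$label[1] <- "snout length"
    m$defs$anatomy[c(1, 3)] <- c("cranial", "dental")
    m <- morph_matrix(m$taxa, m$defs, m$cells)
    expect_true(identical_matrix(m, read_matrix(write_matrix(m, "tnt"))))
    expect_true(identical_matrix(m, read_matrix(write_matrix(m, "nexus"))))
  }
})

test_that("interleaved character kinds keep their column order", {
  defs <- morph_defs(c("unordered", "continuous", "ordered"),
                     n_states = c(2L, NA, 3L))
  cells <- list(mk_discrete(c(0, 1, 0)), c(1.5, 2.5, NA),
                mk_discrete(c(0, 2, 1)))
  m <- morph_matrix(c("A", "B", "C"), defs, cells)
  for (d in c("tnt", "nexus")) {
    m2 <- read_matrix(write_matrix(m, d))
    expect_identical(m2$defs$kind, defs$kind)
    expect_true(identical_matrix(m, m2))
  }
})

test_that("continuous values appear literally in the output", {
  m <- one_char_matrix(c("A", "B"), "continuous", c(2, 4))
  txt <- write_matrix(m, "tnt")
  expect_match(txt, "&\\[continuous\\]")
  expect_match(txt, "2\\.0")
  expect_match(txt, "4\\.0")
})

test_that("format errors name the offending row or token", {
  expect_error(read_matrix("xread\n2 3\nA 00\nB 0\nC 11\n;"), "taxon B")
  expect_error(read_matrix("xread\n2 3\nA 00\nB 0x\nC 11\n;"),
               "unknown state token 'x'.*taxon B.*column 2")
  expect_error(read_matrix("xread\n2 2\nA 00\nA 01\n;"), "duplicate taxon")
  expect_error(read_matrix("xread\n3 2\nA 00\nB 01\n;"), "declares 3")
  expect_error(read_matrix("xread\n2 3\nA 00\nB 01\n;"), "declares 3 taxa")
})

test_that("single-token corruptions of a valid file are all rejected", {
  m <- random_matrix(4L, seed = 9)
  good <- write_matrix(m, "tnt")
  expect_true(identical_matrix(m, read_matrix(good)))
  corruptions <- list(
    function(s) sub("^xread", "xrea", s),
    function(s) sub("(\\d+) (\\d+)\n", "\\1 9\n", s),         # taxon count
    function(s) sub("&\\[num\\]", "&[wat]", s),
    function(s) sub("0", "X", s),
    function(s) sub("\\[", "", s),
    function(s) sub("ccode \\+", "ccode *", s))
  for (corrupt in corruptions) {
    bad <- corrupt(good)
    if (identical(bad, good)) next
    expect_error(read_matrix(bad))
  }
})

test_that("writer refuses what a dialect configuration cannot express", {
  m <- one_char_matrix(c("A", "B"), "continuous", c(1, 2))
  expect_error(write_matrix(m, "tnt", continuous = FALSE), "capability")
  expect_error(morph_matrix(character(0), morph_defs("unordered", 2),
                            list(list())), "empty taxon set")
})

test_that("NEXUS assumptions restore kinds, weights and exclusions", {
  txt <- paste0("#NEXUS\nBEGIN TAXA; DIMENSIONS NTAX=3; TAXLABELS A B C; END;\n",
                "BEGIN CHARACTERS; DIMENSIONS NCHAR=3;\n",
                "FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=? GAP=-;\n",
                "MATRIX\nA 012\nB 000\nC 211\n;\nEND;\n",
                "BEGIN ASSUMPTIONS;\nTYPESET * default = ord: 2;\n",
                "WTSET * default = 0.5: 2;\nEXSET * default = 3;\nEND;\n")
  m <- read_matrix(txt)
  expect_equal(m$defs$kind, c("unordered", "ordered", "unordered"))
  expect_equal(m$defs$weight[2], 0.5)
  expect_false(m$defs$active[3])
})

test_that("Newick trees round-trip with annotations and validation", {
  trees <- read_trees("((A,B),(C,D),E);")
  expect_length(trees, 1L)
  expect_equal(length(tree_splits(trees[[1]])), 2L)
  # annotation round trip
  tr <- trees[[1]]
  txt <- write_trees(tr, annotations = list(c("", "87", "42")))
  tr2 <- read_trees(txt)[[1]]
  expect_equal(tr2$node.label, c("", "87", "42"))
  expect_error(read_trees("((A,B),(A,C));"), "duplicate leaf label")
  expect_error(read_trees("((A,B),(C,D);"), "unbalanced parentheses")
})
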