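# Fixture builders shared by the suite.  Everything is generated in code.

mk_discrete <- function(states) as.list(as.integer(states))

# one-character matrix
one_char_matrix <- function(taxa, kind, cells, n_states = 3L, weight = 1) {
  morph_matrix(taxa, morph_defs(kind, n_states = n_states, weight = weight),
               list(cells))
}

# a perfectly congruent binary matrix encoding every non-trivial clade of
# `tree` once
congruent_matrix <- function(tree) {
  splits <- tree_splits(tree)
  sets <- attr(splits, "sets")
  taxa <- sort(tree$tip.label)
  cells <- lapply(sets, function(s) mk_discrete(as.integer(taxa %in% s)))
  morph_matrix(taxa, morph_defs(rep("unordered", length(cells)), 2L), cells)
}

# random mixed-kind matrix for property tests
random_matrix <- function(n_taxa, n_unord = 3L, n_ord = 2L, n_cont = 1L,
                          seed = 1L, missing_rate = 0.15,
                          polymorphism_rate = 0.1) {
  taxa <- paste0("t", seq_len(n_taxa))
  withr::with_seed(seed, {
    kinds <- rep(c("unordered", "ordered", "continuous"),
                 c(n_unord, n_ord, n_cont))
    cells <- lapply(kinds, function(kind) {
      if (kind == "continuous") {
        v <- round(stats::runif(n_taxa, 0, 5), 2)
        v[stats::runif(n_taxa) < missing_rate] <- NA_real_
        v
      } else {
        col <- lapply(seq_len(n_taxa), function(i) {
          if (stats::runif(1) < missing_rate) return(NA_integer_)
          if (stats::runif(1) < polymorphism_rate) {
            sort(sample(0:2, 2L))
          } else sample(0:2, 1L)
        })
        col
      }
    })
    morph_matrix(taxa, morph_defs(kinds, n_states = 3L), cells)
  })
}

balanced8 <- function() {
  ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
}

# canonical split key (mirrors the package's internal representation)
skey <- function(x) paste(sort(x), collapse = "|")
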