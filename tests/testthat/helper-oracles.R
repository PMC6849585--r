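# Independent oracles used across the suite: brute-force parsimony by
# exhaustive enumeration of internal-node assignments, and exact
# signed-rank p-values by literal enumeration of all 2^n sign patterns.

# raw (unweighted) minimum steps of character j on `tree` by enumerating
# every assignment of candidate states to every internal node
brute_force_steps <- function(tree, matrix, j) {
  kind <- matrix$defs$kind[j]
  col <- matrix$cells[[j]]
  taxa <- matrix$taxa
  if (kind == "continuous") {
    cand <- sort(unique(col[!is.na(col)]))
    cost <- function(a, b) abs(a - b)
    allowed <- lapply(seq_along(taxa), function(i) {
      if (is.na(col[i])) cand else col[i]
    })
  } else {
    cand <- 0:(matrix$defs$n_states[j] - 1L)
    cost <- if (kind == "ordered") function(a, b) abs(a - b) else
      function(a, b) as.numeric(a != b)
    allowed <- lapply(seq_along(taxa), function(i) {
      s <- col[[i]]
      if (length(s) == 1L && (is.na(s) || s == -1L)) cand
      else if (kind == "ordered") min(s):max(s)
      else s
    })
  }
  ntip <- length(tree$tip.label)
  rows <- match(tree$tip.label, taxa)
  nnode <- tree$Nnode
  grids <- rep(list(cand), nnode)
  combos <- as.matrix(expand.grid(grids))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    assign_int <- combos[r, ]
    state_of <- function(v) assign_int[v - ntip]
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      sp <- state_of(p)
      if (ch <= ntip) {
        tot <- tot + min(vapply(allowed[[rows[ch]]], cost, numeric(1L), b = sp))
      } else {
        tot <- tot + cost(sp, state_of(ch))
      }
      if (tot >= best) break
    }
    if (tot < best) best <- tot
  }
  unname(best)
}

# exact two-tailed signed-rank p by enumerating all sign patterns
brute_force_signed_rank_p <- function(ranks) {
  n <- length(ranks)
  total <- sum(ranks)
  ws <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    pos <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    ws[mask + 1] <- sum(ranks[pos])
  }
  function(W_obs) {
    mean(ws <= W_obs + 1e-12 | ws >= total - W_obs - 1e-12)
  }
}

# all unrooted topologies on the taxa of a matrix (phangorn enumeration)
all_topologies <- function(taxa) {
  phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = sort(taxa))
}

exhaustive_best_length <- function(matrix) {
  lens <- vapply(all_topologies(matrix$taxa), function(t)
    tree_length(t, matrix)$total_length, numeric(1L))
  min(lens)
}
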