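## Parsimony ancestral-state reconstruction (marginal MPR sets) and
## unambiguous-synapomorphy listing on branches subtending named clades.

#' Most-parsimonious reconstruction sets
#'
#' Two-pass dynamic programme on a rooted binary tree: the down-pass
#' computes subtree cost vectors, the up-pass marginalises over the rest
#' of the tree, yielding for every node exactly the states (discrete) or
#' candidate values (ordered/continuous) attained in at least one
#' minimum-cost reconstruction.  Leaf entries equal the observed cell;
#' missing leaves are unconstrained.
#'
#' @param tree a rooted, binary `phylo` (root reported trees with
#'   [root_at_outgroups()] first); polytomies are not supported — use a
#'   binary MPT.
#' @param matrix a [morph_matrix()].
#' @param char_index 1-based active character index.
#' @return a `reconstruction_table`: list with `node_states` (per phylo
#'   node id, the vector of MPR states/values), `kind`, `candidates` and
#'   `steps` (raw minimum cost).
#' @export
mpr_sets <- function(tree, matrix, char_index) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    stop("unsupported operation: ancestral reconstruction needs a rooted ",
         "binary tree; resolve polytomies by using a binary MPT")
  }
  j <- as.integer(char_index)
  if (!matrix$defs$active[j]) stop("usage error: character ", j, " is inactive")
  cc <- build_char_cost(matrix, j)
  kind <- matrix$defs$kind[j]
  po <- phylo_postorder(tree)
  ntip <- po$n_tip
  rows <- match(po$tip_label, matrix$taxa)
  if (anyNA(rows)) {
    stop("lookup error: leaf without a matrix row: ",
         po$tip_label[is.na(rows)][1L])
  }
  tip_row <- integer(po$n_nodes)
  tip_row[seq_len(ntip)] <- rows
  D <- sankoff_down(po$edge, po$n_nodes, tip_row, cc$tip_cost, cc$cost)
  k <- ncol(D)
  root <- po$edge[nrow(po$edge), 1L]
  total <- min(D[root, ])
  ## up-pass: A[v, s] = cost of the rest of the tree given state s at v
  children <- vector("list", po$n_nodes)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    children[[p]] <- c(children[[p]], ch)
  }
  ## S[u, t] = min_s cost(t, s) + D[u, s]
  S <- matrix(0, po$n_nodes, k)
  for (v in seq_len(po$n_nodes)) {
    if (tip_row[v] > 0L || length(children[[v]])) {
      S[v, ] <- apply(cc$cost + rep(D[v, ], each = k), 1L, min)
    }
  }
  A <- matrix(0, po$n_nodes, k)
  for (e in rev(seq_len(nrow(po$edge)))) {     # preorder
    p <- po$edge[e, 1L]; v <- po$edge[e, 2L]
    M <- A[p, ]
    for (u in children[[p]]) if (u != v) M <- M + S[u, ]
    A[v, ] <- apply(cc$cost + rep(M, each = k), 1L, min)
  }
  node_states <- vector("list", po$n_nodes)
  for (v in seq_len(po$n_nodes)) {
    att <- which(D[v, ] + A[v, ] <= total + SCORE_TOL)
    node_states[[v]] <- cc$candidates[att]
  }
  structure(list(node_states = node_states, kind = kind,
                 candidates = cc$candidates, steps = total,
                 char_index = j, n_tip = ntip),
            class = "reconstruction_table")
}

#' @export
print.reconstruction_table <- function(x, ...) {
  cat(sprintf("reconstruction_table: character %d (%s), %g steps, %d nodes\n",
              x$char_index, x$kind, x$steps, length(x$node_states)))
  invisible(x)
}

condense_states <- function(states, kind) {
  if (length(states) == 0L) return("-")
  if (kind == "continuous") {
    if (length(states) == 1L) sprintf("%.6g", states) else
      sprintf("[%.6g,%.6g]", min(states), max(states))
  } else {
    if (length(states) == 1L) as.character(states) else
      paste0("{", paste(sort(states), collapse = ","), "}")
  }
}

mpr_disjoint <- function(a, b, kind) {
  if (length(a) == 0L || length(b) == 0L) return(FALSE)
  if (kind == "unordered") length(intersect(a, b)) == 0L else
    (max(a) < min(b) - SCORE_TOL) || (max(b) < min(a) - SCORE_TOL)
}

#' Unambiguous synapomorphies of a clade
#'
#' Lists the characters whose MPR set at the clade's ancestral node is
#' disjoint from the MPR set at that node's parent — i.e. every
#' most-parsimonious reconstruction places a change on the subtending
#' branch.  Characters whose reconstruction changes in only some MPRs
#' (overlapping, unequal sets) are reported with `unambiguous = FALSE`.
#' Character numbers are 1-based.
#'
#' @param tree a rooted binary `phylo`.
#' @param matrix a [morph_matrix()].
#' @param clade character vector of taxon names forming a clade of `tree`.
#' @return a `data.frame`: character, ancestral, derived, unambiguous.
#' @export
unambiguous_synapomorphies <- function(tree, matrix, clade) {
  node <- clade_node(tree, clade)
  parent <- tree$edge[tree$edge[, 2L] == node, 1L]
  if (length(parent) == 0L) {
    stop("lookup error: clade spans the root; no subtending branch")
  }
  rows <- list()
  for (j in which(matrix$defs$active)) {
    rt <- mpr_sets(tree, matrix, j)
    P <- rt$node_states[[parent]]
    Cn <- rt$node_states[[node]]
    same <- length(P) == length(Cn) &&
      all(abs(sort(P) - sort(Cn)) < SCORE_TOL)
    if (same) next
    disjoint <- mpr_disjoint(P, Cn, rt$kind)
    rows[[length(rows) + 1L]] <- data.frame(
      character = j,
      ancestral = condense_states(P, rt$kind),
      derived = condense_states(Cn, rt$kind),
      unambiguous = disjoint, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(character = integer(0), ancestral = character(0),
               derived = character(0), unambiguous = logical(0))
}

## phylo node id whose descendant tips are exactly `clade`
clade_node <- function(tree, clade) {
  labs <- tree$tip.label
  if (!all(clade %in% labs)) {
    stop("lookup error: unknown taxa in clade: ",
         paste(setdiff(clade, labs), collapse = ", "))
  }
  if (length(clade) == 1L) return(match(clade, labs))
  node <- ape::getMRCA(tree, clade)
  desc <- labs[unlist(phangorn::Descendants(tree, node, type = "tips"))]
  if (!setequal(desc, clade)) {
    stop("lookup error: taxa do not form a clade of the tree")
  }
  node
}

#' Synapomorphies consistent across an ensemble
#'
#' A character is a consistent synapomorphy of a clade when it is
#' unambiguous on every tree (of those displaying the clade); the
#' intersection semantics used for reporting support "across all
#' analyses".
#'
#' @param trees list of rooted binary `phylo` trees (e.g. rooted MPTs).
#' @param matrix a [morph_matrix()].
#' @param clade character vector of taxon names.
#' @return `data.frame` of consistent entries (from the first displaying
#'   tree), with attribute `n_trees` = number of trees displaying the
#'   clade.
#' @export
consistent_synapomorphies <- function(trees, matrix, clade) {
  trees <- ensemble_tree_list(trees)
  per_tree <- list()
  for (tr in trees) {
    ok <- tryCatch({ clade_node(tr, clade); TRUE }, error = function(e) FALSE)
    if (ok) per_tree[[length(per_tree) + 1L]] <- unambiguous_synapomorphies(tr, matrix, clade)
  }
  if (length(per_tree) == 0L) {
    stop("lookup error: clade absent from every tree")
  }
  consistent <- Reduce(intersect,
                       lapply(per_tree, function(d) d$character[d$unambiguous]))
  out <- per_tree[[1L]][per_tree[[1L]]$character %in% consistent, , drop = FALSE]
  attr(out, "n_trees") <- length(per_tree)
  out
}

#' Write a synapomorphy table as TSV
#'
#' @param synapomorphies output of [unambiguous_synapomorphies()].
#' @param file output path.
#' @export
write_synapomorphies <- function(synapomorphies, file) {
  utils::write.table(synapomorphies, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
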