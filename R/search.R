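## Heuristic parsimony search under backbone ('scaffold') constraints:
## seeded random-addition starting trees, steepest-descent hill climbing
## over the TBR neighbourhood (which contains all SPR moves), pooling of
## equal-best and near-optimal trees, and suboptimal-pool growth for
## support calculation.

#' Backbone constraint with floating taxa
#'
#' A scaffold fixes the relationships among designated "non-floater" taxa
#' (typically extant clades with molecular support) while "floaters"
#' (typically fossils) may attach anywhere.  Polytomies in the backbone
#' are unresolved regions that admissible trees may resolve arbitrarily.
#'
#' @param backbone a `phylo` over the non-floater taxa, or `NULL` for an
#'   unconstrained analysis.
#' @param floaters character vector of floating taxa (disjoint from the
#'   backbone leaves).
#' @param outgroups ordered character vector of sequential outgroup taxa
#'   (must be backbone leaves when a backbone is given); used to root
#'   reported trees.
#' @return an object of class `constraint_scaffold`.
#' @export
constraint_scaffold <- function(backbone = NULL, floaters = character(0),
                                outgroups = character(0)) {
  if (!is.null(backbone)) {
    bb_leaves <- backbone$tip.label
    if (length(intersect(bb_leaves, floaters))) {
      stop("validation error: floaters overlap backbone leaves: ",
           paste(intersect(bb_leaves, floaters), collapse = ", "))
    }
    if (!all(outgroups %in% bb_leaves)) {
      stop("validation error: outgroups must be backbone leaves")
    }
  }
  structure(list(backbone = backbone, floaters = as.character(floaters),
                 outgroups = as.character(outgroups)),
            class = "constraint_scaffold")
}

scaffold_taxa <- function(scaffold) {
  c(if (!is.null(scaffold$backbone)) scaffold$backbone$tip.label,
    scaffold$floaters)
}

#' @export
print.constraint_scaffold <- function(x, ...) {
  nb <- if (is.null(x$backbone)) 0L else length(x$backbone$tip.label)
  cat(sprintf("constraint_scaffold: %d backbone taxa, %d floaters, %d outgroups%s\n",
              nb, length(x$floaters), length(x$outgroups),
              if (nb == 0L) " (unconstrained)" else ""))
  invisible(x)
}

#' Is a tree admissible under a scaffold?
#'
#' `TRUE` iff the tree, restricted to the non-floater taxa (suppressing
#' degree-2 nodes), displays every non-trivial clade of the backbone.
#' Floaters place no restriction; backbone polytomies may be resolved
#' arbitrarily.
#'
#' @param tree a `phylo` whose leaves are exactly the backbone leaves plus
#'   the floaters.
#' @param scaffold a [constraint_scaffold()].
#' @return logical scalar.
#' @export
is_admissible <- function(tree, scaffold) {
  want <- scaffold_taxa(scaffold)
  if (length(want) && !setequal(tree$tip.label, want)) {
    stop("validation error: tree leaves do not match backbone + floaters")
  }
  if (is.null(scaffold$backbone)) return(TRUE)
  nf <- scaffold$backbone$tip.label
  if (length(nf) < 4L) return(TRUE)
  need <- tree_splits(scaffold$backbone)
  all(need %in% restricted_splits(tree, nf))
}

## split keys of a graph restricted to a leaf-name subset
graph_restricted_splits <- function(g, subset) {
  n <- g$n_tip
  sub_ids <- match(subset, g$labels)
  po <- graph_postorder(g)
  below <- vector("list", po$n_nodes)
  for (v in seq_len(n)) below[[v]] <- v
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  ns <- length(sub_ids)
  ref <- sort(g$labels[sub_ids])[1L]
  out <- character(0)
  for (e in seq_len(nrow(po$edge))) {
    ch <- po$edge[e, 2L]
    if (ch <= n) next
    s <- intersect(below[[ch]], sub_ids)
    nm <- g$labels[s]
    if (ref %in% nm) nm <- setdiff(g$labels[sub_ids], nm)
    if (length(nm) < 2L || length(nm) > ns - 2L) next
    out <- c(out, split_key(nm))
  }
  unique(out)
}

## admissibility of a (possibly partial) search graph; `present` are the
## leaf names currently in the tree
graph_admissible <- function(g, scaffold, present = g$labels) {
  if (is.null(scaffold$backbone)) return(TRUE)
  nf <- intersect(scaffold$backbone$tip.label, present)
  if (length(nf) < 4L) return(TRUE)
  bb <- if (length(nf) == length(scaffold$backbone$tip.label)) {
    scaffold$backbone
  } else ape::keep.tip(scaffold$backbone, nf)
  need <- tree_splits(bb)
  length(need) == 0L || all(need %in% graph_restricted_splits(g, nf))
}

## total weighted length of a search graph under a scoring context
score_graph <- function(ctx, g) {
  po <- graph_postorder(g)
  tip_row <- integer(po$n_nodes)
  tip_row[seq_len(g$n_tip)] <- match(g$labels, ctx$taxa)
  raw <- sankoff_scores(po$edge, po$n_nodes, tip_row, ctx$tip_costs,
                        ctx$cost_mats)
  sum(raw * ctx$weights)
}

random_addition_graph <- function(ctx, scaffold, seed, labels) {
  n <- length(labels)
  ord <- with_seed(seed, sample(labels))
  nf_set <- if (is.null(scaffold$backbone)) character(0) else
    scaffold$backbone$tip.label
  first3 <- match(ord[1:3], labels)
  v0 <- n + 1L
  g <- list(edges = cbind(rep(v0, 3L), first3), n_tip = n, labels = labels)
  storage.mode(g$edges) <- "integer"
  present <- ord[1:3]
  for (t_name in ord[-(1:3)]) {
    t <- match(t_name, labels)
    present2 <- c(present, t_name)
    check <- t_name %in% nf_set
    best_len <- Inf; best_g <- NULL
    for (e in seq_len(nrow(g$edges))) {
      gn <- graph_insert_tip(g, t, e)
      if (check && !graph_admissible(gn, scaffold, present2)) next
      l <- score_graph(ctx, gn)
      if (l < best_len - SCORE_TOL) { best_len <- l; best_g <- gn }
    }
    if (is.null(best_g)) {
      stop("internal error: no admissible insertion for taxon ", t_name)
    }
    g <- best_g
    present <- present2
  }
  g
}

#' Random-addition starting tree
#'
#' Builds a binary, scaffold-admissible tree by stepwise addition in a
#' seeded random taxon order, inserting each taxon at the admissible
#' position of minimal length increase (ties broken by lowest edge
#' index).  Deterministic for a fixed seed.
#'
#' @param matrix a [morph_matrix()].
#' @param scaffold a [constraint_scaffold()] (use
#'   `constraint_scaffold(floaters = matrix$taxa)` for unconstrained).
#' @param seed integer seed.
#' @return a `phylo`.
#' @export
random_addition_tree <- function(matrix, scaffold = NULL, seed = 1L) {
  if (is.null(scaffold)) scaffold <- constraint_scaffold(floaters = matrix$taxa)
  check_scaffold_matrix(scaffold, matrix)
  ctx <- scoring_context(matrix)
  labels <- sort(matrix$taxa)
  graph_to_phylo(random_addition_graph(ctx, scaffold, seed, labels))
}

check_scaffold_matrix <- function(scaffold, matrix) {
  want <- scaffold_taxa(scaffold)
  if (length(want) && !setequal(want, matrix$taxa)) {
    stop("validation error: backbone leaves + floaters must equal the ",
         "matrix taxon set")
  }
}

climb_graph <- function(ctx, g, scaffold) {
  len <- score_graph(ctx, g)
  repeat {
    best <- len; best_g <- NULL
    for (gn in tbr_neighbor_graphs(g)) {
      if (!graph_admissible(gn, scaffold)) next
      l <- score_graph(ctx, gn)
      if (l < best - SCORE_TOL) { best <- l; best_g <- gn }
    }
    if (is.null(best_g)) return(list(g = g, len = len))
    g <- best_g; len <- best
  }
}

#' Heuristic tree search under constraints
#'
#' Runs `n_starts` random-addition + TBR hill-climbing searches, then
#' pools all distinct admissible trees within `epsilon` weighted steps of
#' the best length found (breadth-first closure over TBR neighbourhoods).
#' Trees at exactly the best length are the most parsimonious trees
#' (MPTs); the rest are the near-optimal pool.
#'
#' @inheritParams random_addition_tree
#' @param n_starts number of random-addition starts (>= 1).
#' @param epsilon suboptimality threshold (weighted steps, >= 0).
#' @param cap maximum number of stored trees (default 99999); exceeding it
#'   flags the ensemble as truncated.
#' @return a `tree_ensemble`: list with `trees` (phylo list), `lengths`,
#'   `best_length`, `epsilon`, `cap`, `truncated`, `seed`.
#' @export
tbr_search <- function(matrix, scaffold = NULL, n_starts = 5L, seed = 1L,
                       epsilon = 0, cap = 99999L) {
  stopifnot(n_starts >= 1L, epsilon >= 0, cap >= 1L)
  if (is.null(scaffold)) scaffold <- constraint_scaffold(floaters = matrix$taxa)
  check_scaffold_matrix(scaffold, matrix)
  ctx <- scoring_context(matrix)
  labels <- sort(matrix$taxa)
  optima <- list()
  for (s in seq_len(n_starts)) {
    g0 <- random_addition_graph(ctx, scaffold, seed + s - 1L, labels)
    optima[[s]] <- climb_graph(ctx, g0, scaffold)
  }
  best <- min(vapply(optima, `[[`, numeric(1L), "len"))
  pool <- new.env(hash = TRUE, parent = emptyenv())
  frontier <- character(0)
  truncated <- FALSE
  for (o in optima) {
    if (o$len <= best + epsilon + SCORE_TOL) {
      k <- graph_key(o$g)
      if (!exists(k, pool)) {
        assign(k, list(g = o$g, len = o$len), pool)
        frontier <- c(frontier, k)
      }
    }
  }
  res <- expand_pool(ctx, scaffold, pool, frontier, best, epsilon, cap)
  ensemble_from_pool(pool, res$best, epsilon, cap, res$truncated, seed)
}

## breadth-first closure of the pool under TBR moves within best+epsilon
expand_pool <- function(ctx, scaffold, pool, frontier, best, epsilon, cap) {
  truncated <- FALSE
  while (length(frontier)) {
    k <- frontier[1L]; frontier <- frontier[-1L]
    if (!exists(k, pool)) next
    entry <- get(k, pool)
    if (entry$len > best + epsilon + SCORE_TOL) next
    for (gn in tbr_neighbor_graphs(entry$g)) {
      kn <- graph_key(gn)
      if (exists(kn, pool)) next
      if (!graph_admissible(gn, scaffold)) next
      l <- score_graph(ctx, gn)
      if (l > best + epsilon + SCORE_TOL) next
      if (l < best - SCORE_TOL) {
        best <- l
        ## drop pool members that fell outside the new window
        for (kk in ls(pool)) {
          if (get(kk, pool)$len > best + epsilon + SCORE_TOL) rm(list = kk, envir = pool)
        }
        frontier <- intersect(frontier, ls(pool))
      }
      if (length(ls(pool)) >= cap) { truncated <- TRUE; break }
      assign(kn, list(g = gn, len = l), pool)
      frontier <- c(frontier, kn)
    }
    if (truncated) break
  }
  list(best = best, truncated = truncated)
}

ensemble_from_pool <- function(pool, best, epsilon, cap, truncated, seed) {
  keys <- sort(ls(pool))
  entries <- lapply(keys, get, envir = pool)
  lens <- vapply(entries, `[[`, numeric(1L), "len")
  ord <- order(lens, keys)
  structure(list(
    trees = lapply(entries[ord], function(e) graph_to_phylo(e$g)),
    lengths = lens[ord],
    best_length = best,
    epsilon = epsilon, cap = cap, truncated = truncated, seed = seed
  ), class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("tree_ensemble: %d trees (%d MPTs at length %.6g), epsilon %.3g%s\n",
              length(x$trees), sum(x$lengths <= x$best_length + SCORE_TOL),
              x$best_length, x$epsilon,
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Most parsimonious trees of an ensemble
#'
#' @param ensemble a `tree_ensemble`.
#' @return list of `phylo` trees at the best length.
#' @export
mpt_trees <- function(ensemble) {
  ensemble$trees[ensemble$lengths <= ensemble$best_length + SCORE_TOL]
}

#' Grow a suboptimal-tree pool
#'
#' Iteratively raises the suboptimality threshold through
#' `epsilon_schedule`, re-running TBR sweeps that retain admissible trees
#' within the current bound, stopping when the schedule is exhausted or
#' the storage cap is reached — the usual way of assembling a
#' suboptimal-tree pool up to a storage limit for relative Bremer
#' support.
#'
#' @inheritParams tbr_search
#' @param ensemble a `tree_ensemble` holding the current MPTs.
#' @param epsilon_schedule increasing numeric vector of thresholds.
#' @return a `tree_ensemble` at the last threshold reached.
#' @export
collect_suboptimal <- function(matrix, scaffold = NULL, ensemble,
                               epsilon_schedule, cap = 99999L) {
  if (is.null(scaffold)) scaffold <- constraint_scaffold(floaters = matrix$taxa)
  stopifnot(length(epsilon_schedule) >= 1L, !is.unsorted(epsilon_schedule))
  ctx <- scoring_context(matrix)
  labels <- sort(matrix$taxa)
  pool <- new.env(hash = TRUE, parent = emptyenv())
  truncated <- FALSE
  ord <- order(ensemble$lengths)       # keep the best trees if cap binds
  for (i in ord) {
    if (length(ls(pool)) >= cap) { truncated <- TRUE; break }
    g <- phylo_to_graph(ensemble$trees[[i]], labels)
    assign(graph_key(g), list(g = g, len = ensemble$lengths[i]), pool)
  }
  best <- ensemble$best_length
  eps <- epsilon_schedule[1L]
  for (eps in epsilon_schedule) {
    if (truncated) break
    frontier <- ls(pool)
    res <- expand_pool(ctx, scaffold, pool, frontier, best, eps, cap)
    best <- res$best
    truncated <- truncated || res$truncated
    if (truncated) break
  }
  eps_final <- if (truncated) eps else epsilon_schedule[length(epsilon_schedule)]
  out <- ensemble_from_pool(pool, best, eps_final, cap, truncated,
                            ensemble$seed)
  ## members above the final bound can remain only if best dropped; filter
  keep <- out$lengths <= best + eps_final + SCORE_TOL
  out$trees <- out$trees[keep]; out$lengths <- out$lengths[keep]
  out
}
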