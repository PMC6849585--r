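## Bipartition (split) bookkeeping and low-level unrooted-tree surgery.
##
## Splits are canonicalised as the side NOT containing the reference
## taxon (the lexicographically smallest leaf of the universe), encoded
## as sorted names joined with "|" — so topological identity is string
## identity on sorted key sets.

split_key <- function(members) paste(sort(members), collapse = "|")

#' Non-trivial bipartitions of a tree
#'
#' @param tree a `phylo` (rooted or unrooted, polytomies allowed).
#' @return character vector of canonical split keys, with the member sets
#'   in attribute `"sets"`.
#' @export
tree_splits <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4L) return(structure(character(0), sets = list()))
  ref <- sort(labs)[1L]
  pp <- ape::prop.part(tree)
  sets <- list(); keys <- character(0)
  for (ix in pp) {
    s <- labs[ix]
    if (ref %in% s) s <- setdiff(labs, s)
    if (length(s) < 2L || length(s) > n - 2L) next
    k <- split_key(s)
    if (!k %in% keys) { keys <- c(keys, k); sets[[length(sets) + 1L]] <- s }
  }
  structure(keys, sets = sets)
}

## splits of the tree restricted to a leaf subset (suppressing degree-2
## nodes), canonicalised over that subset
restricted_splits <- function(tree, subset) {
  full <- tree_splits(tree)
  sets <- attr(full, "sets")
  ns <- length(subset)
  if (ns < 4L) return(character(0))
  ref <- sort(subset)[1L]
  out <- character(0)
  for (s in sets) {
    r <- intersect(s, subset)
    if (ref %in% r) r <- setdiff(subset, r)
    if (length(r) < 2L || length(r) > ns - 2L) next
    out <- c(out, split_key(r))
  }
  unique(out)
}

## do two splits (member vectors over the same universe) conflict?
splits_incompatible <- function(a, b, n_universe) {
  ab <- length(intersect(a, b))
  ab > 0L && ab < length(a) && ab < length(b) &&
    (length(a) + length(b) - ab) < n_universe
}

#' Does a tree display a clade?
#'
#' `TRUE` iff the taxon set `clade` forms one side of a bipartition of
#' `tree`.
#'
#' @param tree a `phylo`.
#' @param clade character vector of taxon names (a proper subset of the
#'   leaves, size >= 2).
#' @return logical scalar.
#' @export
displays_clade <- function(tree, clade) {
  labs <- tree$tip.label
  if (!all(clade %in% labs)) stop("clade contains unknown taxa")
  s <- clade
  if (sort(labs)[1L] %in% s) s <- setdiff(labs, s)
  split_key(s) %in% tree_splits(tree)
}

#' Does a tree contradict a clade?
#'
#' `TRUE` iff the tree contains a bipartition incompatible with `clade`.
#' A polytomous tree can neither display nor contradict a clade.
#'
#' @inheritParams displays_clade
#' @return logical scalar.
#' @export
contradicts_clade <- function(tree, clade) {
  labs <- tree$tip.label
  n <- length(labs)
  sets <- attr(tree_splits(tree), "sets")
  for (s in sets) {
    if (splits_incompatible(s, clade, n)) return(TRUE)
    if (splits_incompatible(setdiff(labs, s), clade, n)) return(TRUE)
  }
  FALSE
}

#' Strict consensus of a set of trees
#'
#' Returns the tree containing exactly the non-trivial bipartitions shared
#' by every input tree.
#'
#' @param trees a list of `phylo` objects (or a `multiPhylo`) over
#'   identical leaf sets.
#' @return a `phylo`, generally polytomous.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("validation error: no trees")
  labs <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), labs)) {
      stop("validation error: trees have differing leaf sets")
    }
  }
  splits <- tree_splits(trees[[1L]])
  sets <- attr(splits, "sets")
  keep <- rep(TRUE, length(splits))
  for (tr in trees[-1L]) {
    keep <- keep & (splits %in% tree_splits(tr))
  }
  tree_from_splits(sets[keep], labs)
}

#' Build a tree from a compatible split set
#'
#' @param sets list of split member vectors (each canonicalised to exclude
#'   the reference taxon); may be empty (gives the star tree).
#' @param taxa full leaf set.
#' @return a `phylo`.
#' @export
tree_from_splits <- function(sets, taxa) {
  taxa <- sort(taxa)
  n <- length(taxa)
  sets <- sets[!duplicated(vapply(sets, split_key, character(1L)))]
  ord <- order(lengths(sets))
  sets <- sets[ord]
  nset <- length(sets)
  ## node ids: tips 1..n, root n+1, one node per set n+1+i
  parent_of_set <- integer(nset)
  for (i in seq_len(nset)) {
    parent_of_set[i] <- n + 1L
    if (i < nset) for (j in (i + 1L):nset) {
      if (all(sets[[i]] %in% sets[[j]])) { parent_of_set[i] <- n + 1L + j; break }
    }
  }
  tip_parent <- rep(n + 1L, n)
  for (t in seq_len(n)) {
    for (j in seq_len(nset)) {
      if (taxa[t] %in% sets[[j]]) { tip_parent[t] <- n + 1L + j; break }
    }
  }
  edge <- rbind(cbind(tip_parent, seq_len(n)),
                if (nset) cbind(parent_of_set, n + 1L + seq_len(nset)))
  storage.mode(edge) <- "integer"
  tr <- structure(list(edge = edge, tip.label = taxa, Nnode = nset + 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Root a tree for reporting
#'
#' Places the first sequential outgroup as sister to everything else, the
#' convention used for all printed trees.
#'
#' @param tree a `phylo`.
#' @param outgroups ordered character vector of outgroup taxa (may be
#'   empty, in which case the tree is returned unchanged).
#' @return a rooted `phylo`.
#' @export
root_at_outgroups <- function(tree, outgroups) {
  og <- intersect(outgroups, tree$tip.label)
  if (length(og) == 0L) return(tree)
  ape::root(tree, outgroup = og[1L], resolve.root = TRUE)
}

## ------------------------------------------------------- graph surgery ----
## Internal unrooted-tree representation used by the search: a 2-column
## integer edge matrix over node ids, where ids 1..n_tip are the tips (in
## `labels` order) and internal ids are arbitrary.  All search trees over
## one taxon set share tip ids, so topologies compare by edge structure.

phylo_to_graph <- function(tree, labels = NULL) {
  tips <- tree$tip.label
  n <- length(tips)
  if (is.null(labels)) labels <- sort(tips)
  perm <- match(tips, labels)
  if (anyNA(perm)) stop("tree leaves not in label universe")
  E <- tree$edge
  remap <- function(v) ifelse(v <= n, perm[v], v)
  E[, 1L] <- remap(E[, 1L]); E[, 2L] <- remap(E[, 2L])
  list(edges = E, n_tip = n, labels = labels)
}

graph_adjacency <- function(g) {
  nmax <- max(g$edges)
  adj <- vector("list", nmax)
  for (r in seq_len(nrow(g$edges))) {
    a <- g$edges[r, 1L]; b <- g$edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## postorder directed edge matrix (parent, child) from an internal root
graph_postorder <- function(g) {
  adj <- graph_adjacency(g)
  n <- g$n_tip
  deg <- lengths(adj)
  root <- which(deg >= 2L)[1L]
  if (is.na(root)) root <- which(deg >= 1L)[1L]
  nmax <- length(adj)
  parent <- integer(nmax)
  order_v <- integer(0)
  stack <- root; parent[root] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_v <- c(order_v, v)
    for (u in adj[[v]]) if (u != parent[v]) {
      parent[u] <- v
      stack <- c(stack, u)
    }
  }
  ord <- rev(order_v)           # children before parents
  ord <- ord[ord != root]
  edge <- cbind(parent[ord], ord)
  storage.mode(edge) <- "integer"
  list(edge = edge, n_nodes = nmax, root = root)
}

graph_to_phylo <- function(g) {
  po <- graph_postorder(g)
  n <- g$n_tip
  used <- sort(unique(as.integer(po$edge)))
  internals <- used[used > n]
  ## phylo wants internal ids n+1..n+Nnode with root first
  remap <- integer(max(used))
  remap[seq_len(n)] <- seq_len(n)
  ## preorder over edges reversed gives root-first internal ordering
  pre <- rev(seq_len(nrow(po$edge)))
  nxt <- n + 1L
  seen <- logical(max(used))
  for (e in pre) {
    p <- po$edge[e, 1L]
    if (!seen[p]) { seen[p] <- TRUE; remap[p] <- nxt; nxt <- nxt + 1L }
  }
  for (e in pre) {
    ch <- po$edge[e, 2L]
    if (ch > n && !seen[ch]) { seen[ch] <- TRUE; remap[ch] <- nxt; nxt <- nxt + 1L }
  }
  edge <- cbind(remap[po$edge[, 1L]], remap[po$edge[, 2L]])
  storage.mode(edge) <- "integer"
  tr <- structure(list(edge = edge[rev(seq_len(nrow(edge))), , drop = FALSE],
                       tip.label = g$labels[seq_len(n)],
                       Nnode = length(internals)),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

## canonical topology key of a graph (sorted split keys)
graph_key <- function(g) {
  n <- g$n_tip
  po <- graph_postorder(g)
  nmax <- po$n_nodes
  below <- vector("list", nmax)
  for (v in seq_len(n)) below[[v]] <- v
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(po$edge))) {
    ch <- po$edge[e, 2L]
    if (ch <= n) next
    s <- sort(below[[ch]])
    if (1L %in% s) s <- setdiff(seq_len(n), s)
    if (length(s) < 2L || length(s) > n - 2L) next
    keys <- c(keys, paste(s, collapse = "."))
  }
  paste(sort(unique(keys)), collapse = ";")
}

## insert tip (id t) into edge row e of graph, subdividing with a new node
graph_insert_tip <- function(g, t, e) {
  E <- g$edges
  newv <- max(E, g$n_tip) + 1L
  a <- E[e, 1L]; b <- E[e, 2L]
  E[e, ] <- c(a, newv)
  g$edges <- rbind(E, c(newv, b), c(newv, t))
  g
}

## nodes reachable from v in the edge set E (2-col matrix)
reachable_nodes <- function(E, v) {
  if (nrow(E) == 0L) return(v)
  seen <- v
  repeat {
    hit <- E[, 1L] %in% seen | E[, 2L] %in% seen
    nxt <- unique(c(E[hit, 1L], E[hit, 2L]))
    if (all(nxt %in% seen)) break
    seen <- union(seen, nxt)
  }
  seen
}

## suppress a degree-2 node v in edge matrix E (joins its two neighbours)
suppress_node <- function(E, v) {
  inc <- which(E[, 1L] == v | E[, 2L] == v)
  if (length(inc) != 2L) return(E)
  nb <- c(E[inc[1L], ], E[inc[2L], ])
  nb <- nb[nb != v]
  E <- E[-inc, , drop = FALSE]
  rbind(E, nb)
}

## All tree-bisection-reconnection neighbours of an unrooted binary graph.
## Cutting a pendant edge yields the SPR moves of that tip; cutting an
## internal edge and re-subdividing both sides yields the full TBR set.
tbr_neighbor_graphs <- function(g) {
  E <- g$edges
  ne <- nrow(E)
  out <- list()
  for (e in seq_len(ne)) {
    a <- E[e, 1L]; b <- E[e, 2L]
    E2 <- E[-e, , drop = FALSE]
    compA <- reachable_nodes(E2, a)
    inA <- E2[, 1L] %in% compA
    EA <- E2[inA, , drop = FALSE]
    EB <- E2[!inA, , drop = FALSE]
    ## suppress the cut endpoints if they became degree-2
    EA <- suppress_node(EA, a)
    EB <- suppress_node(EB, b)
    attachA <- if (nrow(EA) == 0L) list(NULL) else seq_len(nrow(EA))
    attachB <- if (nrow(EB) == 0L) list(NULL) else seq_len(nrow(EB))
    ## suppressed internal endpoints are reusable as subdivision nodes;
    ## tip endpoints are not (they stay in the tree as leaves)
    free_ids <- c(a, b)[c(a, b) > g$n_tip]
    for (ea in attachA) for (eb in attachB) {
      EA2 <- EA; EB2 <- EB
      ids <- free_ids; take <- function() { v <- ids[1L]; ids <<- ids[-1L]; v }
      if (is.null(ea)) pa <- a else {
        pa <- take()
        u <- EA2[ea, 1L]; w <- EA2[ea, 2L]
        EA2[ea, ] <- c(u, pa)
        EA2 <- rbind(EA2, c(pa, w))
      }
      if (is.null(eb)) pb <- b else {
        pb <- take()
        u <- EB2[eb, 1L]; w <- EB2[eb, 2L]
        EB2[eb, ] <- c(u, pb)
        EB2 <- rbind(EB2, c(pb, w))
      }
      gn <- g
      gn$edges <- rbind(EA2, EB2, c(pa, pb))
      out[[length(out) + 1L]] <- gn
    }
  }
  out
}
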