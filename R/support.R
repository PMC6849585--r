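## Relative Bremer support over suboptimal-tree pools, and greedy
## detection of unstable (rogue) taxa whose removal resolves the
## consensus.

#' Relative Bremer support
#'
#' For each non-trivial clade of `reference`, counts the ensemble trees
#' that display the clade (S) and those that contain a bipartition
#' incompatible with it (C; trees that do neither — possible for
#' polytomous pool members — count in neither), and scores the clade
#' `100 * (S - C) / max(S, C)`: 100 for clades present in every tree, -100
#' for clades contradicted by every tree, 50 when contradicting trees are
#' half as many as supporting ones.  Clades with support <= 0 are
#' collapsed in the reported consensus.
#'
#' @param ensemble a `tree_ensemble` (see [tbr_search()],
#'   [collect_suboptimal()]) or a list of `phylo` trees.
#' @param reference a `phylo` over the same leaf set whose clades are
#'   scored (typically the strict consensus of the MPTs).
#' @return a `support_report`: list with `consensus` (annotated `phylo`),
#'   `table` (`data.frame`: clade, S, C, support) and `pruned_taxa`.
#' @export
relative_bremer <- function(ensemble, reference) {
  trees <- ensemble_tree_list(ensemble)
  labs <- sort(reference$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), labs)) {
      stop("validation error: ensemble and reference leaf sets differ")
    }
  }
  ref_splits <- tree_splits(reference)
  sets <- attr(ref_splits, "sets")
  n_uni <- length(labs)
  tree_keys <- lapply(trees, tree_splits)
  S <- C <- integer(length(sets))
  for (i in seq_along(sets)) {
    k <- ref_splits[i]
    for (t in seq_along(trees)) {
      if (k %in% tree_keys[[t]]) { S[i] <- S[i] + 1L; next }
      tsets <- attr(tree_keys[[t]], "sets")
      contra <- FALSE
      for (s in tsets) {
        if (splits_incompatible(s, sets[[i]], n_uni) ||
            splits_incompatible(setdiff(labs, s), sets[[i]], n_uni)) {
          contra <- TRUE; break
        }
      }
      if (contra) C[i] <- C[i] + 1L
    }
  }
  support <- ifelse(S == 0L & C == 0L, 0, 100 * (S - C) / pmax(S, C))
  tab <- data.frame(clade = vapply(sets, split_key, character(1L)),
                    S = S, C = C, support = support,
                    stringsAsFactors = FALSE)
  keep <- support > 0
  cons <- tree_from_splits(sets[keep], labs)
  cons <- annotate_supports(cons, sets[keep], support[keep])
  structure(list(consensus = cons, table = tab,
                 pruned_taxa = data.frame(taxon = character(0),
                                          gain = integer(0))),
            class = "support_report")
}

ensemble_tree_list <- function(ensemble) {
  trees <- if (inherits(ensemble, "tree_ensemble")) ensemble$trees else ensemble
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("validation error: empty ensemble")
  trees
}

## attach support values as node labels of the matching clades
annotate_supports <- function(tree, sets, support) {
  labs <- tree$tip.label
  ref <- sort(labs)[1L]
  pp <- ape::prop.part(tree)
  node_lab <- character(tree$Nnode)
  keys <- vapply(sets, split_key, character(1L))
  for (i in seq_along(pp)) {
    s <- labs[pp[[i]]]
    if (ref %in% s) s <- setdiff(labs, s)
    hit <- match(split_key(s), keys)
    if (!is.na(hit)) node_lab[i] <- format(round(support[hit], 1))
  }
  tree$node.label <- node_lab
  tree
}

#' @export
print.support_report <- function(x, ...) {
  cat(sprintf("support_report: %d clades scored, %d with positive support",
              nrow(x$table), sum(x$table$support > 0)))
  if (nrow(x$pruned_taxa)) {
    cat(sprintf("; pruned: %s", paste(x$pruned_taxa$taxon, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Find and prune unstable (rogue) taxa
#'
#' Greedy loop: compute the strict-consensus resolution (number of
#' non-trivial splits); for each remaining taxon, compute the resolution
#' of the consensus of the taxon-pruned trees; prune the taxon with the
#' largest positive gain (ties broken lexicographically); stop when no
#' positive gain remains or `max_prune` taxa are removed.
#'
#' @param ensemble a `tree_ensemble` or list of `phylo` trees (>= 2).
#' @param max_prune maximum number of taxa to remove.
#' @return a `support_report` on the pruned leaf set, with `pruned_taxa`
#'   listing the removals in order with their per-step resolution gains.
#' @export
find_unstable_taxa <- function(ensemble, max_prune = 5L) {
  trees <- ensemble_tree_list(ensemble)
  if (length(trees) < 2L) stop("validation error: need >= 2 trees")
  pruned <- character(0); gains <- integer(0)
  cur <- trees
  resolution <- function(trs) length(tree_splits(strict_consensus(trs)))
  r <- resolution(cur)
  while (length(pruned) < max_prune) {
    taxa <- sort(cur[[1L]]$tip.label)
    if (length(taxa) <= 4L) break
    cand_gain <- vapply(taxa, function(t) {
      resolution(lapply(cur, ape::drop.tip, tip = t)) - r
    }, integer(1L))
    best <- max(cand_gain)
    if (best <= 0L) break
    t_star <- taxa[which(cand_gain == best)[1L]]   # lexicographic tie-break
    cur <- lapply(cur, ape::drop.tip, tip = t_star)
    r <- r + best
    pruned <- c(pruned, t_star); gains <- c(gains, best)
  }
  mpt_idx <- if (inherits(ensemble, "tree_ensemble")) {
    which(ensemble$lengths <= ensemble$best_length + SCORE_TOL)
  } else seq_along(trees)
  ref <- strict_consensus(lapply(trees[mpt_idx], function(tr) {
    if (length(pruned)) ape::drop.tip(tr, pruned) else tr
  }))
  rep0 <- relative_bremer(cur, ref)
  rep0$pruned_taxa <- data.frame(taxon = pruned, gain = gains,
                                 stringsAsFactors = FALSE)
  rep0
}

#' Export a support report
#'
#' Writes the per-clade table and the pruned-taxa list as TSV, and the
#' annotated consensus as Newick (support values as node labels).
#'
#' @param report a `support_report`.
#' @param clades_tsv,pruned_tsv,consensus_nwk optional output paths.
#' @return `report`, invisibly.
#' @export
write_support_report <- function(report, clades_tsv = NULL,
                                 pruned_tsv = NULL, consensus_nwk = NULL) {
  if (!is.null(clades_tsv)) {
    utils::write.table(report$table, clades_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(pruned_tsv)) {
    utils::write.table(report$pruned_taxa, pruned_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(consensus_nwk)) write_trees(report$consensus, consensus_nwk)
  invisible(report)
}
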