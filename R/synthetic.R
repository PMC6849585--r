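## Synthetic character matrices with the statistical structure of a
## genus-level morphological data set: mixed character kinds (~7%
## continuous), heavy and taxon-correlated missing data, tunable
## homoplasy via the evolutionary rate, and a molecular-style backbone
## scaffold with sequential outgroups.

#' Simulation configuration
#'
#' @param model_tree rooted `phylo` with positive branch lengths.
#' @param n_unordered,n_ordered,n_continuous character counts (total >= 1).
#' @param n_states number of states for discrete characters (>= 2).
#' @param rate expected state changes per unit branch length (> 0).
#' @param bm_sigma Brownian-motion step scale per unit sqrt branch length
#'   (> 0).
#' @param missing_rate probability a cell is missing, in [0, 1).
#' @param taxon_missing_multiplier optional named numeric vector of
#'   per-taxon multipliers on `missing_rate` (fossil-style row-correlated
#'   missingness); unnamed taxa get 1.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(model_tree, n_unordered = 0L, n_ordered = 0L,
                       n_continuous = 0L, n_states = 3L, rate = 1,
                       bm_sigma = 1, missing_rate = 0,
                       taxon_missing_multiplier = NULL, seed = 1L) {
  stopifnot(inherits(model_tree, "phylo"), !is.null(model_tree$edge.length),
            all(model_tree$edge.length > 0),
            n_unordered >= 0L, n_ordered >= 0L, n_continuous >= 0L,
            n_unordered + n_ordered + n_continuous >= 1L,
            n_states >= 2L, rate > 0, bm_sigma > 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(model_tree = model_tree, n_unordered = as.integer(n_unordered),
                 n_ordered = as.integer(n_ordered),
                 n_continuous = as.integer(n_continuous),
                 n_states = as.integer(n_states), rate = rate,
                 bm_sigma = bm_sigma, missing_rate = missing_rate,
                 taxon_missing_multiplier = taxon_missing_multiplier,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## simulate one character down the rooted tree; returns leaf values
sim_character <- function(tree, kind, n_states, rate, bm_sigma) {
  po <- ape::reorder.phylo(tree, "postorder")
  n_nodes <- length(tree$tip.label) + tree$Nnode
  root <- po$edge[nrow(po$edge), 1L]
  val <- numeric(n_nodes)
  val[root] <- switch(kind,
                      unordered = sample.int(n_states, 1L) - 1L,
                      ordered = sample.int(n_states, 1L) - 1L,
                      continuous = 0)
  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder: parent before child
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    bl <- po$edge.length[e]
    if (kind == "continuous") {
      val[ch] <- val[p] + stats::rnorm(1L, 0, bm_sigma * sqrt(bl))
    } else {
      x <- val[p]
      nev <- stats::rpois(1L, rate * bl)
      if (nev > 0L) for (ev in seq_len(nev)) {
        if (kind == "unordered") {
          alt <- setdiff(0:(n_states - 1L), x)
          x <- if (length(alt) == 1L) alt else sample(alt, 1L)
        } else {
          ## +/-1 stepwise walk reflected at the state boundaries
          step <- if (x == 0L) 1L else if (x == n_states - 1L) -1L else
            sample(c(-1L, 1L), 1L)
          x <- x + step
        }
      }
      val[ch] <- x
    }
  }
  val[seq_along(tree$tip.label)]
}

#' Simulate a character matrix on a model tree
#'
#' Unordered characters evolve under a symmetric k-state Markov process
#' (Poisson change events, each picking a different state uniformly);
#' ordered characters under a +/-1 stepwise walk reflected at the boundary
#' states; continuous characters under Brownian motion.  Cells are then
#' masked missing independently at `missing_rate` (times the per-taxon
#' multiplier, capped at 0.95).
#'
#' @param config a [sim_config()].
#' @return a `simulated_dataset`: list with `matrix` (a [morph_matrix()]),
#'   `true_tree`, `scaffold` (unconstrained placeholder; see
#'   [make_scaffold()]) and `config`.
#' @export
simulate_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$model_tree
  taxa <- tree$tip.label
  nt <- length(taxa)
  kinds <- rep(c("unordered", "ordered", "continuous"),
               c(config$n_unordered, config$n_ordered, config$n_continuous))
  mult <- rep(1, nt)
  if (!is.null(config$taxon_missing_multiplier)) {
    hit <- match(names(config$taxon_missing_multiplier), taxa)
    mult[hit[!is.na(hit)]] <- config$taxon_missing_multiplier[!is.na(hit)]
  }
  p_miss <- pmin(0.95, config$missing_rate * mult)
  cells <- with_seed(config$seed, {
    lapply(kinds, function(kind) {
      v <- sim_character(tree, kind, config$n_states, config$rate,
                         config$bm_sigma)
      drop <- stats::runif(nt) < p_miss
      if (kind == "continuous") {
        v[drop] <- NA_real_
        v
      } else {
        col <- as.list(as.integer(v))
        col[drop] <- list(NA_integer_)
        col
      }
    })
  })
  defs <- morph_defs(kind = kinds,
                     n_states = ifelse(kinds == "continuous", NA_integer_,
                                       config$n_states))
  mat <- morph_matrix(taxa, defs, cells)
  structure(list(matrix = mat, true_tree = tree,
                 scaffold = constraint_scaffold(floaters = taxa),
                 config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d taxa, %d characters (seed %d)\n",
              length(x$matrix$taxa), n_chars(x$matrix), x$config$seed))
  invisible(x)
}

#' Derive a scaffold from a true tree
#'
#' Restricts the true tree to the designated non-floaters and collapses a
#' seeded fraction of the internal edges to polytomies (emulating the
#' unresolved regions a molecular scaffold leaves open); the remaining
#' taxa become floaters.  The true tree is always admissible under the
#' result.
#'
#' @param true_tree a `phylo`.
#' @param non_floaters character vector (>= 4) of backbone taxa.
#' @param collapse_fraction fraction of internal backbone edges to
#'   collapse, in [0, 1].
#' @param seed integer seed for the choice of collapsed edges.
#' @param outgroups ordered character vector (subset of `non_floaters`).
#' @return a [constraint_scaffold()].
#' @export
make_scaffold <- function(true_tree, non_floaters, collapse_fraction = 0,
                          seed = 1L, outgroups = character(0)) {
  if (length(non_floaters) < 4L) {
    stop("validation error: need at least 4 non-floater taxa")
  }
  if (!all(non_floaters %in% true_tree$tip.label)) {
    stop("validation error: non-floaters must be leaves of the true tree")
  }
  bb <- ape::keep.tip(true_tree, non_floaters)
  internal <- which(bb$edge[, 2L] > length(bb$tip.label))
  ncol_edges <- round(collapse_fraction * length(internal))
  if (ncol_edges > 0L) {
    sel <- with_seed(seed, sample(internal, ncol_edges))
    if (is.null(bb$edge.length)) bb$edge.length <- rep(1, nrow(bb$edge))
    bb$edge.length[sel] <- 0
    bb <- ape::di2multi(bb, tol = 1e-8)
  }
  bb$edge.length <- NULL
  constraint_scaffold(backbone = bb,
                      floaters = setdiff(true_tree$tip.label, non_floaters),
                      outgroups = outgroups)
}

#' Configuration shaped like the motivating data set
#'
#' A bundled configuration emulating a 177-taxon genus-level matrix with
#' 680 characters (48 of them continuous, ~18% of the discrete ones
#' ordered), three sequential outgroups branching basally, a scaffold
#' over 18 "extant" backbone taxa, and fossil-style missing data.
#' `scale < 1` yields proportionally smaller variants for fast tests
#' (taxon and character counts scaled, structure preserved).
#'
#' @param scale positive scaling factor (1 = full size).
#' @param seed integer seed (drives the model tree and the simulation).
#' @param missing_rate cell missing probability (default 0.3, doubled for
#'   the fossil-style half of the ingroup via the per-taxon multiplier).
#' @return list with `config` (a [sim_config()]), `non_floaters`,
#'   `outgroups` and `collapse_fraction` — ready for [simulate_matrix()]
#'   and [make_scaffold()].
#' @export
paper_shaped_config <- function(scale = 1, seed = 1L, missing_rate = 0.3) {
  stopifnot(scale > 0)
  n_taxa <- max(8L, round(177 * scale))
  n_cont <- max(1L, round(48 * scale))
  n_ord <- max(1L, round(112 * scale))
  n_unord <- max(4L, round(520 * scale))
  n_backbone <- max(4L, round(18 * scale))
  outgroups <- c("Outgroup1", "Outgroup2", "Outgroup3")
  n_in <- n_taxa - 3L
  tree <- with_seed(seed, {
    ingroup <- ape::rtree(n_in, tip.label = sprintf("Taxon%03d", seq_len(n_in)))
    ingroup$root.edge <- 0.3
    ## sequential outgroups: (og1,(og2,(og3, ingroup)))
    base <- ape::read.tree(text = paste0(
      "(Outgroup1:1,(Outgroup2:0.8,(Outgroup3:0.6,PLACEHOLDER:0.1):0.2):0.2);"))
    ape::bind.tree(base, ingroup, where = which(base$tip.label == "PLACEHOLDER"))
  })
  tree$edge.length[tree$edge.length <= 0] <- 0.05
  fossil_like <- sprintf("Taxon%03d", seq_len(floor(n_in / 2)))
  mult <- stats::setNames(rep(2, length(fossil_like)), fossil_like)
  cfg <- sim_config(model_tree = tree, n_unordered = n_unord,
                    n_ordered = n_ord, n_continuous = n_cont,
                    n_states = 3L, rate = 1.2, bm_sigma = 1,
                    missing_rate = missing_rate,
                    taxon_missing_multiplier = mult, seed = seed)
  extant_like <- sprintf("Taxon%03d", (n_in - (n_backbone - 1L)):n_in)
  list(config = cfg,
       non_floaters = unique(c(outgroups, extant_like)),
       outgroups = outgroups,
       collapse_fraction = 0.25)
}
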