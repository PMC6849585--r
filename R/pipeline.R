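## End-to-end analysis driver: parse -> weight -> constrained searches ->
## consensus -> supports -> pairwise Templeton table, over a grid of
## (data set x constraint level) cells named in the CU/CM/CF/CP /
## DU/DM/DF/DP style.

#' Run the full analysis pipeline
#'
#' Executes, for every cell of the (data set x constraint) grid, the whole
#' workflow: range-normalisation weighting, constrained TBR search,
#' strict consensus of the MPTs and of the near-optimal pool, score and
#' homoplasy report, relative Bremer supports with rogue-taxon pruning;
#' then pairwise Templeton's tests across the cells of each data set, a
#' per-cell summary TSV and a JSON manifest with all seeds.  A failing
#' cell is logged and skipped; other cells proceed.
#'
#' @param config a YAML file path or a list with elements:
#'   \describe{
#'     \item{matrices}{named list of matrix paths or [morph_matrix()]
#'       objects; names (e.g. `continuous`, `discrete`) supply the cell
#'       prefix (their initial, upper-cased).}
#'     \item{constraints}{named list mapping a level name (e.g. `U`, `M`)
#'       to `"none"`, a backbone Newick path, or a `phylo`.}
#'     \item{outgroups}{ordered character vector (may be empty).}
#'     \item{search}{list: `starts`, `seed`, `epsilon`, `cap`.}
#'     \item{max_prune}{rogue-pruning budget (default 3).}
#'     \item{out_dir}{output directory.}
#'   }
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$matrices),
            !is.null(config$constraints), !is.null(config$out_dir))
  search_cfg <- utils::modifyList(
    list(starts = 3L, seed = 1L, epsilon = 1.0, cap = 200L),
    as.list(config$search %||% list()))
  max_prune <- config$max_prune %||% 3L
  outgroups <- as.character(config$outgroups %||% character(0))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  matrices <- lapply(config$matrices, function(mx) {
    if (inherits(mx, "morph_matrix")) mx else read_matrix(mx)
  })
  backbones <- lapply(config$constraints, function(cs) {
    if (is.null(cs) || identical(cs, "none")) NULL
    else if (inherits(cs, "phylo")) cs
    else read_trees(cs)[[1L]]
  })

  manifest <- list(search = search_cfg, outgroups = outgroups,
                   cells = list())
  summary_rows <- list()
  cell_mpts <- list()

  for (ds in names(matrices)) {
    prefix <- toupper(substr(ds, 1L, 1L))
    weighted <- assign_range_weights(matrices[[ds]])
    for (lev in names(backbones)) {
      cell <- paste0(prefix, lev)
      cell_dir <- file.path(out_dir, cell)
      res <- tryCatch(
        run_cell(weighted$matrix, weighted$report, backbones[[lev]],
                 outgroups, search_cfg, max_prune, cell, cell_dir),
        error = function(e) list(error = conditionMessage(e)))
      if (!is.null(res$error)) {
        message("cell ", cell, " failed: ", res$error)
        manifest$cells[[cell]] <- list(status = "error", error = res$error)
        next
      }
      manifest$cells[[cell]] <- res$manifest
      summary_rows[[cell]] <- res$summary
      cell_mpts[[cell]] <- res$first_mpt
    }
  }

  if (length(summary_rows)) {
    summary_df <- do.call(rbind, summary_rows)
    utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ## pairwise Templeton table within each data set (same matrix, so
  ## lengths are comparable across constraint levels)
  for (ds in names(matrices)) {
    prefix <- toupper(substr(ds, 1L, 1L))
    cells <- grep(paste0("^", prefix), names(cell_mpts), value = TRUE)
    if (length(cells) >= 2L) {
      weighted <- assign_range_weights(matrices[[ds]])
      tab <- templeton_pairwise(weighted$matrix, cell_mpts[cells],
                                file = file.path(out_dir,
                                                 paste0("templeton_", ds, ".tsv")))
      manifest[[paste0("templeton_", ds)]] <- nrow(tab)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_cell <- function(matrix, weight_report, backbone, outgroups, search_cfg,
                     max_prune, cell, cell_dir) {
  dir.create(cell_dir, showWarnings = FALSE, recursive = TRUE)
  scaffold <- if (is.null(backbone)) {
    constraint_scaffold(floaters = matrix$taxa,
                        outgroups = character(0))
  } else {
    constraint_scaffold(backbone = backbone,
                        floaters = setdiff(matrix$taxa, backbone$tip.label),
                        outgroups = intersect(outgroups, backbone$tip.label))
  }
  write_weighting_report(weight_report, file.path(cell_dir, "weights.tsv"))
  ens <- tbr_search(matrix, scaffold, n_starts = search_cfg$starts,
                    seed = search_cfg$seed, epsilon = search_cfg$epsilon,
                    cap = search_cfg$cap)
  mpts <- mpt_trees(ens)
  cons_mpt <- strict_consensus(mpts)
  cons_sub <- strict_consensus(ens$trees)
  write_trees(ens$trees, file.path(cell_dir, "ensemble.nwk"))
  write_trees(root_at_outgroups(cons_mpt, outgroups),
              file.path(cell_dir, "consensus_mpt.nwk"))
  write_trees(root_at_outgroups(cons_sub, outgroups),
              file.path(cell_dir, "consensus_suboptimal.nwk"))
  score <- homoplasy_indices(mpts[[1L]], matrix)
  write_score_report(score, tsv = file.path(cell_dir, "score.tsv"),
                     json = file.path(cell_dir, "score.json"))
  sup <- relative_bremer(ens, cons_mpt)
  write_support_report(sup, clades_tsv = file.path(cell_dir, "support.tsv"),
                       consensus_nwk = file.path(cell_dir, "support.nwk"))
  pruned <- if (length(ens$trees) >= 2L) {
    pr <- find_unstable_taxa(ens, max_prune = max_prune)
    write_support_report(pr,
                         clades_tsv = file.path(cell_dir, "support_pruned.tsv"),
                         pruned_tsv = file.path(cell_dir, "pruned_taxa.tsv"),
                         consensus_nwk = file.path(cell_dir, "support_pruned.nwk"))
    pr$pruned_taxa$taxon
  } else character(0)
  n_sub1 <- sum(ens$lengths <= ens$best_length + 1 + SCORE_TOL) - length(mpts)
  summary <- data.frame(
    analysis = cell, n_mpts = length(mpts),
    best_length = ens$best_length,
    n_suboptimal_within_1 = n_sub1,
    CI = score$CI, RI = score$RI,
    pruned = paste(pruned, collapse = ","), stringsAsFactors = FALSE)
  list(manifest = list(status = "ok", seed = search_cfg$seed,
                       n_trees = length(ens$trees), n_mpts = length(mpts),
                       best_length = ens$best_length,
                       truncated = ens$truncated),
       summary = summary,
       first_mpt = mpts[[1L]])
}

#' Topology-recovery benchmark
#'
#' The package's parameter-recovery experiment: on an 8-taxon balanced
#' model tree (internal branches 1.5, terminal branches 0.5 — four
#' well-separated cherries), simulates 200 mixed characters
#' (140 unordered, 40 ordered, 20 continuous; 3 states; rate 0.2
#' changes per unit branch, giving roughly 2.6 expected changes per
#' character across the tree — visible homoplasy without saturation;
#' Brownian sigma 1) with 30% missing cells, then searches with and
#' without a correct scaffold (backbone over 5 taxa, a quarter of its
#' edges collapsed) and reports the Robinson-Foulds distance between the
#' strict consensus of the MPTs and the true unrooted topology.
#'
#' @param n_replicates number of seeded replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param n_starts random-addition starts per search.
#' @return `data.frame`: replicate, rf_unconstrained, rf_scaffold.
#' @export
recovery_benchmark <- function(n_replicates = 20L, seed = 1L, n_starts = 2L) {
  true_tree <- ape::read.tree(text = paste0(
    "(((A:0.5,B:0.5):1.5,(C:0.5,D:0.5):1.5):1.5,",
    "((E:0.5,F:0.5):1.5,(G:0.5,H:0.5):1.5):1.5);"))
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- sim_config(model_tree = true_tree, n_unordered = 140L,
                      n_ordered = 40L, n_continuous = 20L, n_states = 3L,
                      rate = 0.2, bm_sigma = 1, missing_rate = 0.3,
                      seed = seed + r)
    sim <- simulate_matrix(cfg)
    wm <- assign_range_weights(sim$matrix)$matrix
    scaffold <- make_scaffold(true_tree, c("A", "C", "E", "G", "H"),
                              collapse_fraction = 0.25, seed = seed + r)
    rf <- function(sc) {
      ens <- tbr_search(wm, sc, n_starts = n_starts, seed = seed + r,
                        epsilon = 0, cap = 50L)
      cons <- strict_consensus(mpt_trees(ens))
      phangorn::RF.dist(ape::unroot(cons), ape::unroot(true_tree))
    }
    data.frame(replicate = r,
               rf_unconstrained = rf(constraint_scaffold(floaters = wm$taxa)),
               rf_scaffold = rf(scaffold))
  })
  do.call(rbind, rows)
}
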