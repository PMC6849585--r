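## Exact parsimony scoring for unordered, ordered and continuous
## characters via one generalised Sankoff DP (src/sankoff.cpp).
##
## Terminal cost conventions: a discrete cell's state set costs 0 on its
## states (ordered polymorphisms are widened to the interval [min, max])
## and BIG_COST elsewhere; missing and inapplicable cells cost 0
## everywhere.  Continuous characters run the DP over the observed leaf
## values of that character, which is exact for L1 (Wagner) parsimony
## because an optimal Steiner assignment always exists on input values.

BIG_COST <- 1e9
SCORE_TOL <- 1e-9

#' Build a reusable scoring context
#'
#' Precomputes, for every active character, the terminal-cost matrix over
#' the matrix's taxa, the state-change cost matrix and the weight, so that
#' many trees can be scored against one matrix cheaply (as the tree search
#' does).
#'
#' @param matrix a [morph_matrix()].
#' @return an opaque list of class `scoring_context`.
#' @export
scoring_context <- function(matrix) {
  validate_morph_matrix(matrix)
  defs <- matrix$defs
  act <- which(defs$active)
  chars <- lapply(act, function(j) build_char_cost(matrix, j))
  structure(list(taxa = matrix$taxa, char_index = act,
                 weights = defs$weight[act],
                 tip_costs = lapply(chars, `[[`, "tip_cost"),
                 cost_mats = lapply(chars, `[[`, "cost"),
                 kinds = defs$kind[act],
                 candidates = lapply(chars, `[[`, "candidates")),
            class = "scoring_context")
}

build_char_cost <- function(m, j) {
  kind <- m$defs$kind[j]
  col <- m$cells[[j]]
  nt <- length(m$taxa)
  if (kind == "continuous") {
    cand <- sort(unique(col[!is.na(col)]))
    if (length(cand) == 0L) cand <- 0
    k <- length(cand)
    cost <- abs(outer(cand, cand, "-"))
    tc <- matrix(0, nt, k)
    for (i in seq_len(nt)) {
      v <- col[i]
      if (!is.na(v)) {
        tc[i, ] <- BIG_COST
        tc[i, match(v, cand)] <- 0
      }
    }
    list(tip_cost = tc, cost = cost, candidates = cand)
  } else {
    k <- m$defs$n_states[j]
    st <- 0:(k - 1L)
    cost <- if (kind == "ordered") abs(outer(st, st, "-")) else
      matrix(1, k, k) - diag(k)
    tc <- matrix(0, nt, k)
    for (i in seq_len(nt)) {
      s <- col[[i]]
      if (length(s) == 1L && (is.na(s) || s == -1L)) next
      allowed <- if (kind == "ordered") min(s):max(s) else s
      tc[i, ] <- BIG_COST
      tc[i, allowed + 1L] <- 0
    }
    list(tip_cost = tc, cost = cost, candidates = st)
  }
}

## postorder edge matrix + node bookkeeping for a phylo tree
phylo_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, n_nodes = length(tr$tip.label) + tr$Nnode,
       tip_label = tr$tip.label, n_tip = length(tr$tip.label))
}

## raw (unweighted) per-character steps of a tree given a context
context_steps <- function(ctx, tree) {
  po <- phylo_postorder(tree)
  rows <- match(po$tip_label, ctx$taxa)
  if (anyNA(rows)) {
    stop("lookup error: leaf without a matrix row: ",
         po$tip_label[is.na(rows)][1L])
  }
  tip_row <- integer(po$n_nodes)
  tip_row[seq_len(po$n_tip)] <- rows
  sankoff_scores(po$edge, po$n_nodes, tip_row, ctx$tip_costs, ctx$cost_mats)
}

#' Weighted parsimony steps of one character on a tree
#'
#' Minimum number of state changes of character `char_index` on `tree`,
#' multiplied by the character's weight.  Unordered characters use uniform
#' change cost, ordered characters cost `|i - j|` between states (with
#' polymorphic terminals as state intervals), continuous characters use
#' linear (Wagner) parsimony.  Taxa in the matrix but absent from the tree
#' are ignored; every tree leaf must have a matrix row.
#'
#' @param tree a `phylo`.
#' @param matrix a [morph_matrix()].
#' @param char_index 1-based character index; must be active.
#' @return weighted step count (numeric scalar).
#' @export
character_steps <- function(tree, matrix, char_index) {
  validate_morph_matrix(matrix)
  j <- as.integer(char_index)
  if (j < 1L || j > n_chars(matrix)) stop("character index out of range: ", j)
  if (!matrix$defs$active[j]) {
    stop("usage error: character ", j, " is inactive and excluded from scoring")
  }
  cc <- build_char_cost(matrix, j)
  ctx <- structure(list(taxa = matrix$taxa, char_index = j,
                        weights = matrix$defs$weight[j],
                        tip_costs = list(cc$tip_cost),
                        cost_mats = list(cc$cost)),
                   class = "scoring_context")
  as.numeric(context_steps(ctx, tree)) * matrix$defs$weight[j]
}

#' Total weighted tree length
#'
#' Sum of [character_steps()] over all active characters; the quantity the
#' parsimony search minimises.
#'
#' @inheritParams character_steps
#' @param context optional precomputed [scoring_context()].
#' @return a `score_report` with `total_length` and `per_character_steps`
#'   (a full-length vector, `NA` for inactive characters).
#' @export
tree_length <- function(tree, matrix, context = NULL) {
  if (is.null(context)) context <- scoring_context(matrix)
  raw <- context_steps(context, tree)
  steps <- rep(NA_real_, n_chars(matrix))
  steps[context$char_index] <- raw * context$weights
  new_score_report(matrix, steps)
}

#' Per-character minimum and maximum step bounds
#'
#' The minimum `m` is the weighted steps attainable on the best possible
#' tree; the maximum `g` is the weighted steps on the completely
#' unresolved (star) tree.  Polymorphic cells contribute their cheapest
#' state to both bounds; missing cells are excluded.
#'
#' @inheritParams character_steps
#' @return named numeric vector `c(min = m, max = g)` (weighted).
#' @export
char_step_bounds <- function(matrix, char_index) {
  j <- as.integer(char_index)
  if (!matrix$defs$active[j]) stop("usage error: character ", j, " is inactive")
  w <- matrix$defs$weight[j]
  kind <- matrix$defs$kind[j]
  col <- matrix$cells[[j]]
  if (kind == "continuous") {
    obs <- col[!is.na(col)]
    if (length(obs) < 2L) return(c(min = 0, max = 0))
    m <- max(obs) - min(obs)
    g <- sum(abs(obs - stats::median(obs)))
    return(c(min = m * w, max = g * w))
  }
  cells <- Filter(function(s) !(length(s) == 1L && (is.na(s) || s == -1L)), col)
  if (length(cells) < 2L) return(c(min = 0, max = 0))
  if (kind == "ordered") {
    lo <- vapply(cells, min, numeric(1L))
    hi <- vapply(cells, max, numeric(1L))
    ## choose one state per interval minimising the spread
    m <- max(0, max(lo) - min(hi))
    cand <- 0:(matrix$defs$n_states[j] - 1L)
    star <- vapply(cand, function(t)
      sum(vapply(seq_along(lo), function(i)
        max(0, lo[i] - t, t - hi[i]), numeric(1L))), numeric(1L))
    g <- min(star)
  } else {
    mono <- unique(unlist(cells[lengths(cells) == 1L]))
    need <- mono
    for (s in cells[lengths(cells) > 1L]) {
      if (!any(s %in% need)) need <- c(need, min(s))
    }
    m <- max(0L, length(need) - 1L)
    cand <- 0:(matrix$defs$n_states[j] - 1L)
    star <- vapply(cand, function(t)
      sum(vapply(cells, function(s) as.numeric(!(t %in% s)), numeric(1L))),
      numeric(1L))
    g <- min(star)
  }
  c(min = m * w, max = g * w)
}

#' Ensemble homoplasy indices
#'
#' Scores `tree` on `matrix` and fills in the ensemble consistency index
#' `CI = sum(m) / sum(s)` and retention index
#' `RI = (sum(g) - sum(s)) / (sum(g) - sum(m))`, with sums over active,
#' parsimony-informative characters (those with `g > m`).
#'
#' @inheritParams character_steps
#' @return a `score_report` with `CI` and `RI` filled.
#' @export
homoplasy_indices <- function(tree, matrix) {
  rep0 <- tree_length(tree, matrix)
  nc <- n_chars(matrix)
  mn <- mx <- rep(NA_real_, nc)
  for (j in which(matrix$defs$active)) {
    b <- char_step_bounds(matrix, j)
    mn[j] <- b[["min"]]; mx[j] <- b[["max"]]
  }
  informative <- which(matrix$defs$active & (mx - mn) > SCORE_TOL)
  if (length(informative) == 0L) {
    stop("undefined-index error: all characters are parsimony-uninformative")
  }
  s <- sum(rep0$per_character_steps[informative])
  rep0$per_character_min <- mn
  rep0$per_character_max <- mx
  rep0$CI <- sum(mn[informative]) / s
  rep0$RI <- (sum(mx[informative]) - s) / (sum(mx[informative]) - sum(mn[informative]))
  rep0
}

new_score_report <- function(matrix, steps, mn = NULL, mx = NULL) {
  structure(list(
    total_length = sum(steps, na.rm = TRUE),
    per_character_steps = steps,
    per_character_min = mn,
    per_character_max = mx,
    CI = NA_real_, RI = NA_real_
  ), class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("score_report: length %.6g", x$total_length))
  if (!is.na(x$CI)) cat(sprintf(", CI %.4f, RI %.4f", x$CI, x$RI))
  cat("\n")
  invisible(x)
}

#' Export a score report
#'
#' Writes the per-character step table as TSV (1-based character numbers)
#' and/or the whole report as JSON.
#'
#' @param report a `score_report`.
#' @param tsv,json optional output paths.
#' @return the per-character `data.frame`, invisibly.
#' @export
write_score_report <- function(report, tsv = NULL, json = NULL) {
  df <- data.frame(character = seq_along(report$per_character_steps),
                   steps = report$per_character_steps)
  if (!is.null(report$per_character_min)) {
    df$min_steps <- report$per_character_min
    df$max_steps <- report$per_character_max
  }
  if (!is.null(tsv)) {
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(total_length = report$total_length,
                              CI = report$CI, RI = report$RI,
                              per_character = df),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(df)
}
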