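## Range-normalisation weighting: any variable character's full observed
## range costs exactly one weighted step, making continuous, ordered
## multistate and binary characters commensurable.

#' Assign range-normalised weights
#'
#' Continuous characters get weight `1 / (max - min)` over their
#' non-missing values, so traversing the whole observed range costs one
#' step.  Ordered discrete characters get `1 / (max state - min state)`
#' over the observed states (a three-state character spanning 0..2 is
#' weighted 0.5: it takes two changes to get from one endpoint to the
#' other).  Unordered and binary characters keep weight 1, which requires
#' no adjustment.  Characters with zero observed range are deactivated
#' with reason `"invariant"`.
#'
#' Polymorphic cells contribute both their extreme states to the observed
#' range.  The weighting is idempotent.
#'
#' @param matrix a [morph_matrix()].
#' @return list with elements `matrix` (re-weighted [morph_matrix()]) and
#'   `report` (a `data.frame`: character, kind, observed_min, observed_max,
#'   weight, active, reason).
#' @export
assign_range_weights <- function(matrix) {
  validate_morph_matrix(matrix)
  defs <- matrix$defs
  nc <- nrow(defs)
  rep_df <- data.frame(character = seq_len(nc), kind = defs$kind,
                       observed_min = NA_real_, observed_max = NA_real_,
                       weight = defs$weight, active = defs$active,
                       reason = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(nc)) {
    if (!defs$active[j]) { rep_df$reason[j] <- "pre-existing inactive"; next }
    kind <- defs$kind[j]
    if (kind == "continuous") {
      obs <- matrix$cells[[j]]
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0L) {
        stop("continuous character ", j, " has no non-missing values")
      }
      lo <- min(obs); hi <- max(obs)
      rep_df$observed_min[j] <- lo; rep_df$observed_max[j] <- hi
      if (hi - lo < SCORE_TOL) {
        defs$active[j] <- FALSE; rep_df$reason[j] <- "invariant"
      } else {
        defs$weight[j] <- 1 / (hi - lo)
      }
    } else {
      cells <- Filter(function(s) !(length(s) == 1L && (is.na(s) || s == -1L)),
                      matrix$cells[[j]])
      obs <- unlist(cells)
      if (length(obs) == 0L) {
        defs$active[j] <- FALSE; rep_df$reason[j] <- "invariant"
        next
      }
      lo <- min(obs); hi <- max(obs)
      rep_df$observed_min[j] <- lo; rep_df$observed_max[j] <- hi
      if (hi == lo) {
        defs$active[j] <- FALSE; rep_df$reason[j] <- "invariant"
      } else if (kind == "ordered") {
        defs$weight[j] <- 1 / (hi - lo)
      } else {
        defs$weight[j] <- 1   # unordered (incl. binary): no weighting
      }
    }
  }
  if (!any(defs$active)) {
    stop("validation error: no active characters remain after weighting")
  }
  rep_df$weight <- defs$weight
  rep_df$active <- defs$active
  matrix$defs <- defs
  list(matrix = morph_matrix(matrix$taxa, defs, matrix$cells), report = rep_df)
}

#' Write a weighting report as TSV
#'
#' @param report the `report` element of [assign_range_weights()].
#' @param file output path.
#' @export
write_weighting_report <- function(report, file) {
  utils::write.table(report, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Discretise continuous characters
#'
#' Converts every continuous character to an ordered character with states
#' `0..n_bins-1` by equal-width binning over its observed range (half-open
#' bins, the maximum value falling in the last bin), producing the
#' "traditionally discrete" variant of a mixed matrix.  Missing cells stay
#' missing; zero-range characters are deactivated rather than binned.
#' Applying [assign_range_weights()] afterwards gives each binned
#' character weight `1 / (n_bins - 1)`.
#'
#' @param matrix a [morph_matrix()].
#' @param n_bins integer >= 2.
#' @return a [morph_matrix()] with no continuous characters.
#' @export
discretize_continuous <- function(matrix, n_bins = 3L) {
  stopifnot(n_bins >= 2L)
  validate_morph_matrix(matrix)
  defs <- matrix$defs
  cells <- matrix$cells
  for (j in which(defs$kind == "continuous")) {
    col <- cells[[j]]
    obs <- col[!is.na(col)]
    newcol <- vector("list", length(col))
    if (length(obs) == 0L || max(obs) - min(obs) < SCORE_TOL) {
      defs$kind[j] <- "ordered"; defs$n_states[j] <- 2L
      defs$active[j] <- FALSE
      for (i in seq_along(col)) {
        newcol[[i]] <- if (is.nan(col[i])) -1L else if (is.na(col[i]))
          NA_integer_ else 0L
      }
    } else {
      lo <- min(obs); w <- (max(obs) - lo) / n_bins
      for (i in seq_along(col)) {
        v <- col[i]
        newcol[[i]] <- if (is.nan(v)) -1L else if (is.na(v)) NA_integer_ else
          min(n_bins - 1L, as.integer(floor((v - lo) / w)))
      }
      defs$kind[j] <- "ordered"
      defs$n_states[j] <- n_bins
    }
    cells[[j]] <- newcol
  }
  morph_matrix(matrix$taxa, defs, cells)
}
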