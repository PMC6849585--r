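#' @useDynLib morphparsimony, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Cell encoding, used throughout the package:
##  * discrete column (kind "unordered"/"ordered"): a list, one element per
##    taxon; element is a sorted integer vector of observed states (length > 1
##    = polymorphism), NA_integer_ = missing, -1L = inapplicable.
##  * continuous column: a double vector; NA = missing, NaN = inapplicable.
## Inapplicable is stored distinctly but scored exactly like missing.

CHAR_KINDS <- c("unordered", "ordered", "continuous")
ANATOMY_TAGS <- c("dental", "cranial", "postcranial")

#' Character definition table
#'
#' Builds the per-character definition table of a [morph_matrix()]: one row
#' per character giving its kind, declared number of states (discrete kinds
#' only), weight, active flag, free-text label and optional anatomical
#' region tag.
#'
#' @param kind character vector; each element one of `"unordered"`,
#'   `"ordered"`, `"continuous"`.
#' @param n_states integer vector of declared state counts (>= 2) for
#'   discrete characters; `NA` for continuous characters.
#' @param weight positive numeric vector of character weights (default 1).
#' @param active logical; inactive characters are excluded from all scoring.
#' @param label character vector of free-text labels.
#' @param anatomy optional tag per character: `"dental"`, `"cranial"`,
#'   `"postcranial"` or `NA`.
#' @return A `data.frame` with one row per character.
#' @export
morph_defs <- function(kind, n_states = NULL, weight = 1, active = TRUE,
                       label = NA_character_, anatomy = NA_character_) {
  kind <- match.arg(kind, CHAR_KINDS, several.ok = TRUE)
  nc <- length(kind)
  if (is.null(n_states)) {
    n_states <- ifelse(kind == "continuous", NA_integer_, 2L)
  }
  defs <- data.frame(
    kind = kind,
    n_states = as.integer(rep_len(n_states, nc)),
    weight = as.numeric(rep_len(weight, nc)),
    active = rep_len(as.logical(active), nc),
    label = rep_len(as.character(label), nc),
    anatomy = rep_len(as.character(anatomy), nc),
    stringsAsFactors = FALSE
  )
  defs$n_states[defs$kind == "continuous"] <- NA_integer_
  defs
}

#' Mixed-kind character matrix
#'
#' The central data container: an ordered set of taxa, a character
#' definition table ([morph_defs()]) and a list of cell columns.  Discrete
#' cells are state sets (polymorphism allowed), continuous cells are real
#' values; missing (`?`) and inapplicable (`-`) are represented explicitly.
#'
#' @param taxa character vector of unique, non-empty taxon names.
#' @param defs data.frame as returned by [morph_defs()].
#' @param cells list with one element per character: for discrete characters
#'   a list of integer state vectors (`NA` missing, `-1` inapplicable); for
#'   continuous characters a double vector (`NA` missing, `NaN`
#'   inapplicable).
#' @return An object of class `morph_matrix`.
#' @seealso [read_matrix()], [write_matrix()], [assign_range_weights()]
#' @export
morph_matrix <- function(taxa, defs, cells) {
  m <- structure(list(taxa = as.character(taxa), defs = defs, cells = cells),
                 class = "morph_matrix")
  validate_morph_matrix(m)
  m
}

#' Validate a morph_matrix
#'
#' Checks taxon-name uniqueness, grid dimensions, kind/cell consistency and
#' state-range invariants.  Called by all constructors and parsers.
#'
#' @param m a [morph_matrix()].
#' @return `m`, invisibly; stops with a descriptive error on violation.
#' @export
validate_morph_matrix <- function(m) {
  taxa <- m$taxa
  if (length(taxa) == 0L) stop("matrix has an empty taxon set")
  if (anyNA(taxa) || any(!nzchar(taxa))) stop("taxon names must be non-empty")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name: ", taxa[duplicated(taxa)][1L])
  }
  defs <- m$defs
  req <- c("kind", "n_states", "weight", "active", "label", "anatomy")
  if (!all(req %in% names(defs))) stop("defs lacks required columns")
  if (!all(defs$kind %in% CHAR_KINDS)) stop("unknown character kind")
  if (any(!is.na(defs$anatomy) & !(defs$anatomy %in% ANATOMY_TAGS))) {
    stop("unknown anatomy tag")
  }
  if (any(defs$weight <= 0 | !is.finite(defs$weight))) {
    stop("character weights must be positive and finite")
  }
  disc <- defs$kind != "continuous"
  if (any(is.na(defs$n_states[disc]) | defs$n_states[disc] < 2L)) {
    stop("discrete characters need n_states >= 2")
  }
  if (length(m$cells) != nrow(defs)) {
    stop("cells/defs length mismatch: ", length(m$cells), " vs ", nrow(defs))
  }
  for (j in seq_along(m$cells)) {
    col <- m$cells[[j]]
    if (length(col) != length(taxa)) {
      stop("character ", j, ": column length ", length(col),
           " != number of taxa ", length(taxa))
    }
    if (defs$kind[j] == "continuous") {
      if (!is.numeric(col)) stop("character ", j, ": continuous column must be numeric")
      bad <- which(is.infinite(col))
      if (length(bad)) stop("character ", j, ", taxon ", taxa[bad[1L]],
                            ": continuous value must be finite")
    } else {
      if (!is.list(col)) stop("character ", j, ": discrete column must be a list")
      k <- defs$n_states[j]
      for (i in seq_along(col)) {
        s <- col[[i]]
        if (!is.numeric(s) || length(s) == 0L) {
          stop("character ", j, ", taxon ", taxa[i], ": empty state cell")
        }
        if (length(s) == 1L && (is.na(s) || s == -1L)) next
        if (anyNA(s) || any(s < 0L) || any(s >= k)) {
          stop("character ", j, ", taxon ", taxa[i],
               ": state outside 0..", k - 1L)
        }
      }
    }
  }
  invisible(m)
}

#' @export
print.morph_matrix <- function(x, ...) {
  nk <- table(factor(x$defs$kind, levels = CHAR_KINDS))
  cat(sprintf("morph_matrix: %d taxa x %d characters (%d unordered, %d ordered, %d continuous; %d active)\n",
              length(x$taxa), nrow(x$defs), nk[["unordered"]], nk[["ordered"]],
              nk[["continuous"]], sum(x$defs$active)))
  invisible(x)
}

#' @export
dim.morph_matrix <- function(x) c(length(x$taxa), nrow(x$defs))

n_taxa <- function(m) length(m$taxa)
n_chars <- function(m) nrow(m$defs)

is_missing_cell <- function(col, i, kind) {
  if (kind == "continuous") is.na(col[i]) else {
    s <- col[[i]]
    length(s) == 1L && (is.na(s) || s == -1L)
  }
}

## observed (non-missing, non-inapplicable) entries of one character column
observed_values <- function(m, j) {
  kind <- m$defs$kind[j]
  col <- m$cells[[j]]
  if (kind == "continuous") {
    col[!is.na(col)]
  } else {
    keep <- !vapply(seq_along(col), function(i) is_missing_cell(col, i, kind),
                    logical(1L))
    col[keep]
  }
}

#' Compare two character matrices cell-for-cell
#'
#' Used by round-trip tests: `TRUE` iff taxa, definitions (kind, n_states,
#' weight, active, label, anatomy) and every cell agree exactly.
#'
#' @param a,b [morph_matrix()] objects.
#' @return logical scalar.
#' @export
identical_matrix <- function(a, b) {
  if (!identical(a$taxa, b$taxa)) return(FALSE)
  da <- a$defs; db <- b$defs
  for (cn in c("kind", "n_states", "active", "label", "anatomy")) {
    if (!identical(da[[cn]], db[[cn]])) return(FALSE)
  }
  if (!isTRUE(all.equal(da$weight, db$weight, tolerance = 1e-12))) return(FALSE)
  for (j in seq_len(n_chars(a))) {
    ca <- a$cells[[j]]; cb <- b$cells[[j]]
    if (da$kind[j] == "continuous") {
      if (!all(is.na(ca) == is.na(cb))) return(FALSE)
      if (!all(is.nan(ca) == is.nan(cb))) return(FALSE)
      obs <- !is.na(ca)
      if (!all(abs(ca[obs] - cb[obs]) < 1e-9)) return(FALSE)
    } else {
      for (i in seq_along(ca)) if (!identical(ca[[i]], cb[[i]])) return(FALSE)
    }
  }
  TRUE
}

#' Restrict a matrix to a subset of taxa
#'
#' @param m a [morph_matrix()].
#' @param taxa character vector of taxon names to keep (order preserved as
#'   given).
#' @return a [morph_matrix()] over `taxa`.
#' @export
subset_taxa <- function(m, taxa) {
  idx <- match(taxa, m$taxa)
  if (anyNA(idx)) {
    stop("unknown taxon: ", paste(taxa[is.na(idx)], collapse = ", "))
  }
  cells <- lapply(m$cells, function(col) col[idx])
  morph_matrix(m$taxa[idx], m$defs, cells)
}
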