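## TNT (xread) and NEXUS matrix I/O.
##
## Supported TNT subset: an xread block with an optional quoted title, a
## "nchar ntax" header, data rows optionally split into &[continuous] /
## &[num] sub-blocks, then commands: ccode (+ ordered, - unordered,
## ] deactivate, /w weight), cnames {i label; groups, and two extension
## commands of the same shape: ctags {i tag; (anatomical region) and
## cstates {i k; (declared state counts exceeding the observed ones).
## Character indices in TNT commands are 0-based, as in TNT itself.
##
## Supported NEXUS subset: TAXA block, one or more CHARACTERS blocks
## (DATATYPE=STANDARD or CONTINUOUS; characters numbered globally across
## blocks in file order), CHARSTATELABELS, and an ASSUMPTIONS block with
## TYPESET (ord/unord), WTSET, EXSET (excluded = inactive) plus
## ANATOMYSET and STATESET extensions mirroring TYPESET syntax.

#' Read a character matrix
#'
#' Parses a mixed discrete/continuous character matrix from TNT (`xread`)
#' or NEXUS text.  Cell tokens: digits (single state), bracketed digit runs
#' (polymorphism), `?` (missing), `-` (inapplicable), and decimal reals in
#' continuous blocks.  Character kinds, weights and active flags are taken
#' from the file's command section (TNT `ccode`, NEXUS `ASSUMPTIONS`) when
#' present; characters default to unordered, weight 1, active.
#'
#' @param source a file path, or the matrix text itself (anything containing
#'   a newline is treated as text).
#' @param dialect `"tnt"`, `"nexus"` or `"auto"` (detects `#NEXUS`).
#' @return a [morph_matrix()].
#' @export
read_matrix <- function(source, dialect = c("auto", "tnt", "nexus")) {
  dialect <- match.arg(dialect)
  txt <- read_source_text(source)
  if (dialect == "auto") {
    dialect <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) "nexus" else "tnt"
  }
  if (dialect == "tnt") parse_tnt(txt) else parse_nexus(txt)
}

read_source_text <- function(source) {
  if (length(source) > 1L) return(paste(source, collapse = "\n"))
  if (!grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    return(paste(readLines(source, warn = FALSE), collapse = "\n"))
  }
  source
}

#' Write a character matrix
#'
#' Serialises a [morph_matrix()] to TNT or NEXUS text such that
#' `read_matrix(write_matrix(m))` reproduces `m` cell-for-cell and
#' definition-for-definition.  Labels are written with spaces encoded as
#' underscores (the TNT convention), so labels containing literal
#' underscores do not round-trip verbatim.
#'
#' @param matrix a [morph_matrix()].
#' @param dialect `"tnt"` or `"nexus"`.
#' @param file optional path; when given the text is also written there.
#' @param continuous allow continuous characters in the output
#'   (default `TRUE`); with `FALSE` a matrix containing continuous
#'   characters raises a capability error.
#' @return the matrix text, invisibly when `file` is given.
#' @export
write_matrix <- function(matrix, dialect = c("tnt", "nexus"), file = NULL,
                         continuous = TRUE) {
  dialect <- match.arg(dialect)
  validate_morph_matrix(matrix)
  if (!continuous && any(matrix$defs$kind == "continuous")) {
    stop("capability error: dialect configured without a continuous block ",
         "cannot express continuous characters")
  }
  txt <- if (dialect == "tnt") format_tnt(matrix) else format_nexus(matrix)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

## ---------------------------------------------------------------- TNT ----

parse_tnt <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !grepl("^xread", lines[1L], ignore.case = TRUE)) {
    stop("format error: TNT input must start with 'xread'")
  }
  i <- 2L
  if (i <= length(lines) && grepl("^'", lines[i])) i <- i + 1L  # title
  hdr <- strsplit(lines[i], "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("format error: expected 'nchar ntax' header, got: ", lines[i])
  }
  nchar_decl <- as.integer(hdr[1L]); ntax_decl <- as.integer(hdr[2L])
  i <- i + 1L
  ## split data section (up to terminating ';') into blocks
  data_end <- i
  while (data_end <= length(lines) && lines[data_end] != ";") data_end <- data_end + 1L
  if (data_end > length(lines)) stop("format error: missing ';' after data rows")
  data_lines <- if (data_end > i) lines[i:(data_end - 1L)] else character(0)
  cmd_lines <- if (data_end < length(lines)) lines[(data_end + 1L):length(lines)] else character(0)

  block_kind <- "num"
  blocks <- list()   # each: list(kind, rows = named character rows)
  cur <- NULL
  flush_block <- function() {
    if (!is.null(cur) && length(cur$rows)) blocks[[length(blocks) + 1L]] <<- cur
  }
  cur <- list(kind = "num", rows = list())
  for (ln in data_lines) {
    if (grepl("^&\\[", ln)) {
      flush_block()
      block_kind <- sub("^&\\[([a-zA-Z]+)\\].*$", "\\1", ln)
      if (!block_kind %in% c("continuous", "num")) {
        stop("format error: unknown block marker ", ln)
      }
      cur <- list(kind = block_kind, rows = list())
    } else {
      sp <- regmatches(ln, regexpr("\\s", ln))
      if (length(sp) == 0L) stop("format error: row without data: ", ln)
      pos <- regexpr("\\s", ln)
      taxon <- substr(ln, 1L, pos - 1L)
      body <- trimws(substr(ln, pos + 1L, nchar(ln)))
      if (taxon %in% names(cur$rows)) {
        stop("validation error: duplicate taxon name ", taxon, " in block")
      }
      cur$rows[[taxon]] <- body
    }
  }
  flush_block()
  if (length(blocks) == 0L) stop("format error: no data rows")

  taxa <- names(blocks[[1L]]$rows)
  if (length(taxa) != ntax_decl) {
    stop("format error: header declares ", ntax_decl, " taxa but block has ",
         length(taxa))
  }
  defs_list <- list(); cells <- list()
  for (b in blocks) {
    if (!setequal(names(b$rows), taxa) || length(b$rows) != length(taxa)) {
      miss <- setdiff(taxa, names(b$rows))
      stop("format error: block taxa differ from first block",
           if (length(miss)) paste0(" (missing ", miss[1L], ")"))
    }
    rows <- b$rows[taxa]
    if (b$kind == "continuous") {
      vals <- lapply(rows, parse_continuous_row)
      ncol_b <- unique(vapply(vals, length, integer(1L)))
      if (length(ncol_b) != 1L) {
        bad <- taxa[which(vapply(vals, length, integer(1L)) != ncol_b[1L])[1L]]
        stop("format error: ragged continuous row for taxon ", bad)
      }
      for (j in seq_len(ncol_b)) {
        colv <- vapply(vals, `[[`, numeric(1L), j)
        names(colv) <- NULL
        cells[[length(cells) + 1L]] <- colv
        defs_list[[length(defs_list) + 1L]] <-
          list(kind = "continuous", n_states = NA_integer_)
      }
    } else {
      vals <- lapply(seq_along(rows), function(r) {
        parse_discrete_row(rows[[r]], taxa[r])
      })
      ncol_b <- unique(vapply(vals, length, integer(1L)))
      if (length(ncol_b) != 1L) {
        lens <- vapply(vals, length, integer(1L))
        stop("format error: row for taxon ", taxa[which(lens != ncol_b[1L])[1L]],
             " has ", lens[which(lens != ncol_b[1L])[1L]],
             " characters, expected ", ncol_b[1L])
      }
      for (j in seq_len(ncol_b)) {
        col <- lapply(vals, `[[`, j)
        obs <- unlist(col)
        obs <- obs[!is.na(obs) & obs >= 0L]
        ns <- max(2L, if (length(obs)) max(obs) + 1L else 2L)
        cells[[length(cells) + 1L]] <- col
        defs_list[[length(defs_list) + 1L]] <-
          list(kind = "unordered", n_states = ns)
      }
    }
  }
  nc <- length(cells)
  if (nc != nchar_decl) {
    stop("format error: header declares ", nchar_decl,
         " characters but rows contain ", nc)
  }
  defs <- morph_defs(kind = vapply(defs_list, `[[`, character(1L), "kind"),
                     n_states = vapply(defs_list, `[[`, integer(1L), "n_states"))
  m <- list(taxa = taxa, defs = defs, cells = cells)
  m <- apply_tnt_commands(m, cmd_lines)
  morph_matrix(m$taxa, m$defs, m$cells)
}

parse_continuous_row <- function(body) {
  toks <- strsplit(trimws(body), "\\s+")[[1L]]
  vapply(toks, function(t) {
    if (t == "?") return(NA_real_)
    if (t == "-") return(NaN)
    v <- suppressWarnings(as.numeric(t))
    if (is.na(v)) stop("format error: unknown continuous token '", t, "'")
    v
  }, numeric(1L), USE.NAMES = FALSE)
}

parse_discrete_row <- function(body, taxon) {
  body <- gsub("\\s+", "", body)
  out <- list(); i <- 1L; n <- nchar(body); col <- 0L
  while (i <= n) {
    ch <- substr(body, i, i); col <- col + 1L
    if (ch == "?") { out[[col]] <- NA_integer_; i <- i + 1L }
    else if (ch == "-") { out[[col]] <- -1L; i <- i + 1L }
    else if (grepl("^[0-9]$", ch)) { out[[col]] <- as.integer(ch); i <- i + 1L }
    else if (ch == "[") {
      close <- regexpr("]", substr(body, i, n), fixed = TRUE)
      if (close < 0L) stop("format error: unterminated '[' in row for taxon ",
                           taxon, ", column ", col)
      run <- substr(body, i + 1L, i + close - 2L)
      if (!grepl("^[0-9]+$", run)) {
        stop("format error: unknown state token '[", run, "]' in row for taxon ",
             taxon, ", column ", col)
      }
      out[[col]] <- sort(unique(as.integer(strsplit(run, "")[[1L]])))
      i <- i + close
    } else {
      stop("format error: unknown state token '", ch, "' in row for taxon ",
           taxon, ", column ", col)
    }
  }
  out
}

## ccode/cnames/ctags commands; indices 0-based in the file
apply_tnt_commands <- function(m, cmd_lines) {
  txt <- paste(cmd_lines, collapse = "\n")
  stmts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  nc <- nrow(m$defs)
  last_field <- NULL    # continuation state for multi-group commands
  set_group <- function(field, j, value) {
    if (field == "n_states") {
      k <- as.integer(value)
      if (is.na(k) || k < 2L) stop("format error: bad state count '", value, "'")
      m$defs$n_states[j] <<- k
    } else {
      m$defs[[field]][j] <<- gsub("_", " ", value)
    }
  }
  for (s in stmts) {
    if (grepl("^\\{", s) && !is.null(last_field)) {
      g <- trimws(sub("^\\{", "", s))
      parts <- strsplit(g, "\\s+")[[1L]]
      j <- parse_tnt_index(parts[1L], nc)
      set_group(last_field, j, paste(parts[-1L], collapse = " "))
      next
    }
    if (!grepl("^\\{", s)) last_field <- NULL
    if (grepl("^ccode", s, ignore.case = TRUE)) {
      body <- trimws(sub("^ccode", "", s, ignore.case = TRUE))
      toks <- strsplit(body, "\\s+")[[1L]]
      mode <- NULL; w <- NULL
      for (t in toks) {
        if (t %in% c("+", "-", "[", "]")) { mode <- t; w <- NULL }
        else if (grepl("^/", t)) { mode <- "/"; w <- as.numeric(sub("^/", "", t)) }
        else {
          idx <- parse_tnt_index(t, nc)
          for (j in idx) {
            if (is.null(mode)) stop("format error: ccode index before modifier")
            if (mode == "+") {
              m$defs$kind[j] <- if (m$defs$kind[j] == "continuous") "continuous" else "ordered"
            } else if (mode == "-") {
              if (m$defs$kind[j] != "continuous") m$defs$kind[j] <- "unordered"
            } else if (mode == "]") m$defs$active[j] <- FALSE
            else if (mode == "[") m$defs$active[j] <- TRUE
            else if (mode == "/") m$defs$weight[j] <- w
          }
        }
      }
    } else if (grepl("^cnames", s, ignore.case = TRUE) ||
               grepl("^ctags", s, ignore.case = TRUE) ||
               grepl("^cstates", s, ignore.case = TRUE)) {
      field <- if (grepl("^cnames", s, ignore.case = TRUE)) "label"
      else if (grepl("^cstates", s, ignore.case = TRUE)) "n_states"
      else "anatomy"
      last_field <- field
      groups <- regmatches(s, gregexpr("\\{[^{}]*", s))[[1L]]
      for (g in groups) {
        g <- trimws(sub("^\\{", "", g))
        parts <- strsplit(g, "\\s+")[[1L]]
        j <- parse_tnt_index(parts[1L], nc)
        set_group(field, j, trimws(paste(parts[-1L], collapse = " ")))
      }
    } else if (grepl("^proc", s, ignore.case = TRUE)) {
      ## terminator; ignore
    } else {
      stop("format error: unknown TNT command '", s, "'")
    }
  }
  m
}

parse_tnt_index <- function(tok, nc) {
  if (grepl("^[0-9]+\\.[0-9]+$", tok)) {
    ab <- as.integer(strsplit(tok, ".", fixed = TRUE)[[1L]])
    j <- (ab[1L]:ab[2L]) + 1L
  } else if (grepl("^[0-9]+$", tok)) {
    j <- as.integer(tok) + 1L
  } else stop("format error: bad character index '", tok, "'")
  if (any(j < 1L | j > nc)) stop("format error: character index out of range: ", tok)
  j
}

format_real <- function(x) {
  ifelse(x == round(x), sprintf("%.1f", x), vapply(x, function(v)
    sprintf("%.15g", v), character(1L)))
}

format_tnt <- function(m) {
  defs <- m$defs
  nt <- length(m$taxa); nc <- nrow(defs)
  out <- c("xread", "'morphparsimony matrix'", paste(nc, nt))
  pad <- formatC(m$taxa, width = max(nchar(m$taxa)) + 1L, flag = "-")
  ## emit one &[continuous]/&[num] sub-block per run of same-category
  ## characters, preserving column order across the file
  categ <- ifelse(defs$kind == "continuous", "continuous", "num")
  runs <- rle(categ)
  start <- cumsum(c(1L, runs$lengths))
  for (r in seq_along(runs$values)) {
    js <- start[r]:(start[r] + runs$lengths[r] - 1L)
    out <- c(out, paste0("&[", runs$values[r], "]"))
    if (runs$values[r] == "continuous") {
      for (i in seq_len(nt)) {
        toks <- vapply(js, function(j) {
          v <- m$cells[[j]][i]
          if (is.nan(v)) "-" else if (is.na(v)) "?" else format_real(v)
        }, character(1L))
        out <- c(out, paste0(pad[i], paste(toks, collapse = " ")))
      }
    } else {
      for (i in seq_len(nt)) {
        toks <- vapply(js, function(j) {
          s <- m$cells[[j]][[i]]
          if (length(s) == 1L && is.na(s)) "?"
          else if (length(s) == 1L && s == -1L) "-"
          else if (length(s) == 1L) as.character(s)
          else paste0("[", paste(s, collapse = ""), "]")
        }, character(1L))
        out <- c(out, paste0(pad[i], paste(toks, collapse = "")))
      }
    }
  }
  out <- c(out, ";")
  file_idx0 <- function(j) j - 1L   # 0-based file index; file order = column order
  ord <- which(defs$kind == "ordered")
  if (length(ord)) {
    out <- c(out, paste("ccode +", paste(vapply(ord, file_idx0, integer(1L)),
                                         collapse = " "), ";"))
  }
  inact <- which(!defs$active)
  if (length(inact)) {
    out <- c(out, paste("ccode ]", paste(vapply(inact, file_idx0, integer(1L)),
                                         collapse = " "), ";"))
  }
  wdiff <- which(abs(defs$weight - 1) > 1e-12)
  for (j in wdiff) {
    out <- c(out, paste0("ccode /", sprintf("%.15g", defs$weight[j]), " ",
                         file_idx0(j), " ;"))
  }
  lab <- which(!is.na(defs$label))
  if (length(lab)) {
    out <- c(out, "cnames",
             vapply(lab, function(j) paste0("{", file_idx0(j), " ",
                                            gsub(" ", "_", defs$label[j]), ";"),
                    character(1L)), ";")
  }
  tags <- which(!is.na(defs$anatomy))
  if (length(tags)) {
    out <- c(out, "ctags",
             vapply(tags, function(j) paste0("{", file_idx0(j), " ",
                                             defs$anatomy[j], ";"),
                    character(1L)), ";")
  }
  ## declared state counts, where they exceed what the cells imply
  nst <- which(defs$kind != "continuous" &
                 defs$n_states != vapply(seq_len(nc), function(j)
                   inferred_n_states(m$cells[[j]], defs$kind[j]), integer(1L)))
  if (length(nst)) {
    out <- c(out, "cstates",
             vapply(nst, function(j) paste0("{", file_idx0(j), " ",
                                            defs$n_states[j], ";"),
                    character(1L)), ";")
  }
  out <- c(out, "proc /;")
  paste(out, collapse = "\n")
}

inferred_n_states <- function(col, kind) {
  if (kind == "continuous") return(NA_integer_)
  obs <- unlist(col)
  obs <- obs[!is.na(obs) & obs >= 0L]
  max(2L, if (length(obs)) max(obs) + 1L else 2L)
}

## -------------------------------------------------------------- NEXUS ----

parse_nexus <- function(txt) {
  if (!grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    stop("format error: NEXUS input must start with #NEXUS")
  }
  body <- sub("^\\s*#NEXUS", "", txt, ignore.case = TRUE)
  stmts <- strsplit(body, ";", fixed = TRUE)[[1L]]
  stmts <- trimws(gsub("\\s+", " ", stmts))
  stmts <- stmts[nzchar(stmts)]

  taxa <- NULL
  defs_list <- list(); cells <- list()
  cur_datatype <- "STANDARD"; in_chars <- FALSE
  assumptions <- character(0)
  labels <- list()
  i <- 1L
  while (i <= length(stmts)) {
    s <- stmts[i]; up <- toupper(s)
    if (startsWith(up, "BEGIN TAXA")) in_chars <- FALSE
    else if (startsWith(up, "BEGIN CHARACTERS") || startsWith(up, "BEGIN DATA")) {
      in_chars <- TRUE; cur_datatype <- "STANDARD"
    } else if (startsWith(up, "BEGIN ASSUMPTIONS")) in_chars <- FALSE
    else if (startsWith(up, "TAXLABELS")) {
      taxa <- strsplit(trimws(sub("^TAXLABELS", "", s, ignore.case = TRUE)),
                       "\\s+")[[1L]]
      if (anyDuplicated(taxa)) {
        stop("validation error: duplicate taxon name ",
             taxa[duplicated(taxa)][1L])
      }
    } else if (startsWith(up, "FORMAT")) {
      if (grepl("DATATYPE\\s*=\\s*CONTINUOUS", up)) cur_datatype <- "CONTINUOUS"
      else cur_datatype <- "STANDARD"
    } else if (startsWith(up, "MATRIX")) {
      if (is.null(taxa)) stop("format error: MATRIX before TAXLABELS")
      ## statements are whitespace-normalised; recover rows by taxon names
      toks <- strsplit(trimws(sub("^MATRIX", "", s, ignore.case = TRUE)),
                       "\\s+")[[1L]]
      res <- parse_nexus_matrix(toks, taxa, cur_datatype)
      cells <- c(cells, res$cells)
      defs_list <- c(defs_list, res$defs)
    } else if (startsWith(up, "TYPESET") || startsWith(up, "WTSET") ||
               startsWith(up, "EXSET") || startsWith(up, "ANATOMYSET") ||
               startsWith(up, "STATESET")) {
      assumptions <- c(assumptions, s)
    } else if (startsWith(up, "CHARSTATELABELS")) {
      lab_body <- trimws(sub("^CHARSTATELABELS", "", s, ignore.case = TRUE))
      for (item in strsplit(lab_body, ",", fixed = TRUE)[[1L]]) {
        parts <- strsplit(trimws(item), "\\s+")[[1L]]
        if (length(parts) >= 2L) {
          labels[[parts[1L]]] <- gsub("_", " ", paste(parts[-1L], collapse = " "))
        }
      }
    } else if (startsWith(up, "DIMENSIONS") || startsWith(up, "END") ||
               startsWith(up, "TITLE")) {
      ## DIMENSIONS validated post hoc; END/TITLE structural
      if (startsWith(up, "DIMENSIONS") && grepl("NCHAR", up)) {
        nch <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", up))
        attr(cells, "pending_nchar") <- c(attr(cells, "pending_nchar"), nch)
      }
    } else stop("format error: unknown NEXUS statement '", substr(s, 1, 40), "'")
    i <- i + 1L
  }
  if (is.null(taxa)) stop("format error: no TAXA block")
  if (length(cells) == 0L) stop("format error: no CHARACTERS block")
  pend <- attr(cells, "pending_nchar")
  if (!is.null(pend) && sum(pend, na.rm = TRUE) != length(cells)) {
    stop("format error: DIMENSIONS NCHAR=", sum(pend, na.rm = TRUE),
         " but matrix has ", length(cells), " characters")
  }
  attr(cells, "pending_nchar") <- NULL
  defs <- morph_defs(kind = vapply(defs_list, `[[`, character(1L), "kind"),
                     n_states = vapply(defs_list, `[[`, integer(1L), "n_states"))
  for (k in names(labels)) {
    j <- as.integer(k)
    if (!is.na(j) && j >= 1L && j <= nrow(defs)) defs$label[j] <- labels[[k]]
  }
  m <- list(taxa = taxa, defs = defs, cells = cells)
  m <- apply_nexus_assumptions(m, assumptions)
  morph_matrix(m$taxa, m$defs, m$cells)
}

parse_nexus_matrix <- function(toks, taxa, datatype) {
  nt <- length(taxa)
  rows <- list(); cur_taxon <- NULL; cur <- character(0)
  for (t in toks) {
    if (t %in% taxa) {
      if (!is.null(cur_taxon)) {
        if (cur_taxon %in% names(rows)) {
          stop("validation error: duplicate taxon row ", cur_taxon)
        }
        rows[[cur_taxon]] <- cur
      }
      cur_taxon <- t; cur <- character(0)
    } else {
      if (is.null(cur_taxon)) stop("format error: matrix token before taxon name: ", t)
      cur <- c(cur, t)
    }
  }
  if (!is.null(cur_taxon)) rows[[cur_taxon]] <- cur
  if (!setequal(names(rows), taxa)) {
    stop("format error: matrix rows do not cover the taxon set (missing ",
         setdiff(taxa, names(rows))[1L], ")")
  }
  rows <- rows[taxa]
  if (datatype == "CONTINUOUS") {
    vals <- lapply(rows, function(r) parse_continuous_row(paste(r, collapse = " ")))
    ncol_b <- unique(vapply(vals, length, integer(1L)))
    if (length(ncol_b) != 1L) stop("format error: ragged continuous NEXUS rows")
    cells <- lapply(seq_len(ncol_b), function(j)
      vapply(vals, `[[`, numeric(1L), j, USE.NAMES = FALSE))
    defs <- rep(list(list(kind = "continuous", n_states = NA_integer_)), ncol_b)
  } else {
    vals <- lapply(seq_along(rows), function(r) {
      body <- paste(rows[[r]], collapse = "")
      body <- gsub("[(]", "[", body); body <- gsub("[)]", "]", body)
      body <- gsub("[{]", "[", body); body <- gsub("[}]", "]", body)
      parse_discrete_row(body, taxa[r])
    })
    ncol_b <- unique(vapply(vals, length, integer(1L)))
    if (length(ncol_b) != 1L) {
      lens <- vapply(vals, length, integer(1L))
      stop("format error: row for taxon ", taxa[which(lens != ncol_b[1L])[1L]],
           " has wrong character count")
    }
    cells <- list(); defs <- list()
    for (j in seq_len(ncol_b)) {
      col <- lapply(vals, `[[`, j)
      obs <- unlist(col); obs <- obs[!is.na(obs) & obs >= 0L]
      cells[[j]] <- col
      defs[[j]] <- list(kind = "unordered",
                        n_states = max(2L, if (length(obs)) max(obs) + 1L else 2L))
    }
  }
  list(cells = cells, defs = defs)
}

apply_nexus_assumptions <- function(m, assumptions) {
  nc <- nrow(m$defs)
  idxs <- function(part) {
    out <- integer(0)
    for (t in strsplit(trimws(part), "\\s+")[[1L]]) {
      if (grepl("^[0-9]+-[0-9]+$", t)) {
        ab <- as.integer(strsplit(t, "-", fixed = TRUE)[[1L]])
        out <- c(out, ab[1L]:ab[2L])
      } else out <- c(out, as.integer(t))
    }
    if (any(is.na(out) | out < 1L | out > nc)) {
      stop("format error: assumptions index out of range in '", part, "'")
    }
    out
  }
  for (s in assumptions) {
    up <- toupper(s)
    body <- sub("^[A-Za-z]+\\s*\\*?\\s*[A-Za-z]*\\s*=", "", s)
    if (startsWith(up, "EXSET")) {
      m$defs$active[idxs(body)] <- FALSE
    } else if (startsWith(up, "TYPESET")) {
      for (grp in strsplit(body, ",", fixed = TRUE)[[1L]]) {
        kv <- strsplit(grp, ":", fixed = TRUE)[[1L]]
        if (length(kv) != 2L) stop("format error: bad TYPESET group '", grp, "'")
        ty <- tolower(trimws(kv[1L])); j <- idxs(kv[2L])
        if (ty %in% c("ord", "ordered")) {
          m$defs$kind[j] <- ifelse(m$defs$kind[j] == "continuous",
                                   "continuous", "ordered")
        } else if (!ty %in% c("unord", "unordered")) {
          stop("format error: unknown character type '", ty, "'")
        }
      }
    } else if (startsWith(up, "WTSET")) {
      for (grp in strsplit(body, ",", fixed = TRUE)[[1L]]) {
        kv <- strsplit(grp, ":", fixed = TRUE)[[1L]]
        if (length(kv) != 2L) stop("format error: bad WTSET group '", grp, "'")
        m$defs$weight[idxs(kv[2L])] <- as.numeric(trimws(kv[1L]))
      }
    } else if (startsWith(up, "ANATOMYSET")) {
      for (grp in strsplit(body, ",", fixed = TRUE)[[1L]]) {
        kv <- strsplit(grp, ":", fixed = TRUE)[[1L]]
        tag <- tolower(trimws(kv[1L]))
        m$defs$anatomy[idxs(kv[2L])] <- tag
      }
    } else if (startsWith(up, "STATESET")) {
      for (grp in strsplit(body, ",", fixed = TRUE)[[1L]]) {
        kv <- strsplit(grp, ":", fixed = TRUE)[[1L]]
        k <- as.integer(trimws(kv[1L]))
        if (is.na(k) || k < 2L) stop("format error: bad STATESET count")
        m$defs$n_states[idxs(kv[2L])] <- k
      }
    }
  }
  m
}

format_nexus <- function(m) {
  defs <- m$defs; nt <- length(m$taxa)
  pad <- formatC(m$taxa, width = max(nchar(m$taxa)) + 1L, flag = "-")
  out <- c("#NEXUS", "BEGIN TAXA;",
           paste0("  DIMENSIONS NTAX=", nt, ";"),
           paste0("  TAXLABELS ", paste(m$taxa, collapse = " "), ";"),
           "END;")
  ## one CHARACTERS block per run of same-datatype characters, preserving
  ## column order; characters are numbered globally across blocks
  categ <- ifelse(defs$kind == "continuous", "continuous", "standard")
  runs <- rle(categ)
  start <- cumsum(c(1L, runs$lengths))
  for (r in seq_along(runs$values)) {
    js <- start[r]:(start[r] + runs$lengths[r] - 1L)
    if (runs$values[r] == "standard") {
      maxst <- max(defs$n_states[js])
      out <- c(out, "BEGIN CHARACTERS;",
               paste0("  DIMENSIONS NCHAR=", length(js), ";"),
               paste0("  FORMAT DATATYPE=STANDARD SYMBOLS=\"",
                      paste(0:(maxst - 1L), collapse = ""),
                      "\" MISSING=? GAP=-;"),
               "  MATRIX")
      for (i in seq_len(nt)) {
        toks <- vapply(js, function(j) {
          s <- m$cells[[j]][[i]]
          if (length(s) == 1L && is.na(s)) "?"
          else if (length(s) == 1L && s == -1L) "-"
          else if (length(s) == 1L) as.character(s)
          else paste0("(", paste(s, collapse = ""), ")")
        }, character(1L))
        out <- c(out, paste0("    ", pad[i], paste(toks, collapse = "")))
      }
      out <- c(out, "  ;", "END;")
    } else {
      out <- c(out, "BEGIN CHARACTERS;",
               paste0("  DIMENSIONS NCHAR=", length(js), ";"),
               "  FORMAT DATATYPE=CONTINUOUS MISSING=?;",
               "  MATRIX")
      for (i in seq_len(nt)) {
        toks <- vapply(js, function(j) {
          v <- m$cells[[j]][i]
          if (is.nan(v)) "-" else if (is.na(v)) "?" else format_real(v)
        }, character(1L))
        out <- c(out, paste0("    ", pad[i], paste(toks, collapse = " ")))
      }
      out <- c(out, "  ;", "END;")
    }
  }
  fpos <- function(j) j   # file numbering = column order
  assum <- character(0)
  ord <- which(defs$kind == "ordered")
  if (length(ord)) {
    assum <- c(assum, paste0("  TYPESET * default = ord: ",
                             paste(vapply(ord, fpos, integer(1L)), collapse = " "), ";"))
  }
  wdiff <- which(abs(defs$weight - 1) > 1e-12)
  if (length(wdiff)) {
    grps <- vapply(wdiff, function(j) paste0(sprintf("%.15g", defs$weight[j]),
                                             ": ", fpos(j)), character(1L))
    assum <- c(assum, paste0("  WTSET * default = ", paste(grps, collapse = ", "), ";"))
  }
  inact <- which(!defs$active)
  if (length(inact)) {
    assum <- c(assum, paste0("  EXSET * default = ",
                             paste(vapply(inact, fpos, integer(1L)), collapse = " "), ";"))
  }
  tags <- which(!is.na(defs$anatomy))
  if (length(tags)) {
    grps <- vapply(split(tags, defs$anatomy[tags]), function(js)
      paste0(defs$anatomy[js[1L]], ": ",
             paste(vapply(js, fpos, integer(1L)), collapse = " ")), character(1L))
    assum <- c(assum, paste0("  ANATOMYSET * default = ",
                             paste(grps, collapse = ", "), ";"))
  }
  nst <- which(defs$kind != "continuous" &
                 defs$n_states != vapply(seq_len(nrow(defs)), function(j)
                   inferred_n_states(m$cells[[j]], defs$kind[j]), integer(1L)))
  if (length(nst)) {
    grps <- vapply(split(nst, defs$n_states[nst]), function(js)
      paste0(defs$n_states[js[1L]], ": ",
             paste(vapply(js, fpos, integer(1L)), collapse = " ")),
      character(1L))
    assum <- c(assum, paste0("  STATESET * default = ",
                             paste(grps, collapse = ", "), ";"))
  }
  lab <- which(!is.na(defs$label))
  labstmt <- character(0)
  if (length(lab)) {
    items <- vapply(lab, function(j) paste0(fpos(j), " ",
                                            gsub(" ", "_", defs$label[j])),
                    character(1L))
    labstmt <- paste0("  CHARSTATELABELS ", paste(items, collapse = ", "), ";")
  }
  if (length(assum) || length(labstmt)) {
    out <- c(out, "BEGIN ASSUMPTIONS;", labstmt, assum, "END;")
  }
  paste(out, collapse = "\n")
}

## --------------------------------------------------------------- trees ----

#' Read Newick trees
#'
#' Reads one or more Newick trees from text or a file path via \pkg{ape},
#' with validation (duplicate leaf labels rejected) and normalisation of
#' degree-2 internal nodes.  Node labels are preserved as annotations
#' (e.g. support values).
#'
#' @param source Newick text (with `;` separators) or a file path.
#' @return a list of `phylo` objects.
#' @export
read_trees <- function(source) {
  txt <- read_source_text(source)
  txt <- trimws(txt)
  if (!nzchar(txt)) stop("parse error: empty tree source")
  op <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  cl <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (op != cl) {
    stop("parse error: unbalanced parentheses (", op, " '(' vs ", cl,
         " ')') at position ", min(nchar(txt), op + cl))
  }
  trees <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) stop("parse error: ", conditionMessage(e)))
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    if (anyDuplicated(tr$tip.label)) {
      stop("validation error: duplicate leaf label ",
           tr$tip.label[duplicated(tr$tip.label)][1L])
    }
    ape::collapse.singles(tr)
  })
  trees
}

#' Write Newick trees
#'
#' @param trees a `phylo`, `multiPhylo` or list of `phylo` objects.
#' @param file optional output path.
#' @param annotations optional list (parallel to `trees`) of node-label
#'   vectors to attach before writing (support values round-trip as node
#'   labels).
#' @return Newick text, invisibly when `file` is given.
#' @export
write_trees <- function(trees, file = NULL, annotations = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!is.null(annotations)) {
    for (i in seq_along(annotations)) {
      if (!is.null(annotations[[i]])) trees[[i]]$node.label <- as.character(annotations[[i]])
    }
  }
  txt <- paste(vapply(trees, ape::write.tree, character(1L)), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
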