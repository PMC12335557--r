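# Atom selection language.
#
# Grammar (whitespace-separated tokens):
#   expr      := term ("or" term)*
#   term      := factor ("and" factor)*
#   factor    := "not" factor | "(" expr ")" | primitive
#   primitive := field value+
#   field     := name | resname | segid | element | resid | index
#
# String fields (name, resname, segid, element) take one or more literal
# values; a value may contain the globs "*" and "?". Numeric fields (resid,
# index; index is 1-based) take integers or ranges "a:b". Multiple values of
# one primitive are OR-ed. Selections are pure functions of the frame
# metadata and the expression.

sel_tokenize <- function(expression) {
  m <- gregexpr("\\(|\\)|[^[:space:]()]+", expression)[[1]]
  if (m[1] == -1L) return(data.frame(tok = character(), pos = integer()))
  data.frame(
    tok = regmatches(expression, gregexpr("\\(|\\)|[^[:space:]()]+", expression))[[1]],
    pos = as.integer(m),
    stringsAsFactors = FALSE
  )
}

.sel_fields <- c("name", "resname", "segid", "element", "resid", "index")
.sel_reserved <- c(.sel_fields, "and", "or", "not", "(", ")")

sel_error <- function(pos, msg) {
  stop(sprintf("selection syntax error at position %d: %s", pos, msg),
       call. = FALSE)
}

sel_parse <- function(tokens, atoms) {
  i <- 1L
  n <- nrow(tokens)
  peek <- function() if (i <= n) tokens$tok[i] else NA_character_
  pos <- function() if (i <= n) tokens$pos[i] else
    if (n > 0L) tokens$pos[n] + nchar(tokens$tok[n]) else 1L

  match_string <- function(field, values) {
    col <- atoms[[field]]
    hit <- rep(FALSE, length(col))
    for (v in values) {
      if (grepl("[*?]", v)) hit <- hit | grepl(utils::glob2rx(v), col)
      else hit <- hit | (col == v)
    }
    hit
  }
  match_numeric <- function(field, values, at) {
    vals <- if (field == "index") seq_len(nrow(atoms)) else atoms$resid
    hit <- rep(FALSE, length(vals))
    for (v in values) {
      if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
        ab <- as.integer(strsplit(v, ":")[[1]])
        hit <- hit | (vals >= min(ab) & vals <= max(ab))
      } else if (grepl("^-?[0-9]+$", v)) {
        hit <- hit | (vals == as.integer(v))
      } else sel_error(at, sprintf("'%s' is not an integer or range for %s", v, field))
    }
    hit
  }

  parse_primitive <- function() {
    field <- peek()
    at <- pos()
    if (is.na(field) || !(field %in% .sel_fields)) {
      sel_error(at, sprintf("expected a field keyword, got '%s'",
                            if (is.na(field)) "end of expression" else field))
    }
    i <<- i + 1L
    values <- character()
    vpos <- pos()
    while (!is.na(peek()) && !(peek() %in% .sel_reserved)) {
      values <- c(values, peek())
      i <<- i + 1L
    }
    if (length(values) == 0L) {
      sel_error(vpos, sprintf("field '%s' needs at least one value", field))
    }
    if (field %in% c("resid", "index")) match_numeric(field, values, vpos)
    else match_string(field, values)
  }

  parse_factor <- function() {
    t <- peek()
    if (!is.na(t) && t == "not") {
      i <<- i + 1L
      return(!parse_factor())
    }
    if (!is.na(t) && t == "(") {
      i <<- i + 1L
      v <- parse_or()
      if (is.na(peek()) || peek() != ")") sel_error(pos(), "expected ')'")
      i <<- i + 1L
      return(v)
    }
    parse_primitive()
  }
  parse_and <- function() {
    v <- parse_factor()
    while (!is.na(peek()) && peek() == "and") {
      i <<- i + 1L
      v <- v & parse_factor()
    }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    while (!is.na(peek()) && peek() == "or") {
      i <<- i + 1L
      v <- v | parse_and()
    }
    v
  }

  if (n == 0L) sel_error(1L, "empty expression")
  v <- parse_or()
  if (i <= n) sel_error(pos(), sprintf("unexpected trailing token '%s'", peek()))
  v
}

#' Select atoms of a frame by a small expression language
#'
#' @param frame an `atom_frame` or `frame_series` (metadata is shared).
#' @param expression selection string, e.g.
#'   `"resname TIP3 and name OH2"`, `"name CA and segid S6A"`,
#'   `"resid 305:320 or name C2* C3*"`.
#' @return an `atom_selection`: list with `indices` (1-based, increasing) and
#'   `label` (the expression). An expression matching nothing yields an empty
#'   selection, not an error.
#' @export
select_atoms <- function(frame, expression) {
  atoms <- frame$atoms
  hit <- sel_parse(sel_tokenize(expression), atoms)
  atom_selection(which(hit), label = expression, n_total = nrow(atoms))
}

#' Construct an atom selection from explicit indices
#'
#' @param indices unique 1-based atom indices.
#' @param label free-text label.
#' @param n_total optional topology atom count for range checking.
#' @return an `atom_selection`.
#' @export
atom_selection <- function(indices, label = "", n_total = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (length(indices) && (any(is.na(indices)) || any(indices < 1L))) {
    stop("selection indices must be positive integers")
  }
  if (!is.null(n_total) && length(indices) && max(indices) > n_total) {
    stop("selection index ", max(indices), " outside topology range ", n_total)
  }
  structure(list(indices = sort(indices), label = label),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection:", length(x$indices), "atoms",
      if (nzchar(x$label)) paste0("[", x$label, "]") else "", "\n")
  invisible(x)
}

#' Number of atoms in a selection
#' @param selection an `atom_selection`.
#' @return integer.
#' @export
n_selected <- function(selection) length(selection$indices)

# Resolve a selection argument to integer indices. Accepts an atom_selection,
# an integer vector, a selection expression string, or NULL (all atoms).
as_indices <- function(selection, frame) {
  if (is.null(selection)) return(seq_len(nrow(frame$atoms)))
  if (inherits(selection, "atom_selection")) return(selection$indices)
  if (is.character(selection) && length(selection) == 1L) {
    return(select_atoms(frame, selection)$indices)
  }
  if (is.numeric(selection)) return(as.integer(selection))
  stop("cannot interpret selection argument")
}
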