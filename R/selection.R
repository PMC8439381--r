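#' Atom selections
#'
#' A small selection grammar resolves expressions against a topology to a
#' sorted, deduplicated vector of 1-based atom indices. Grammar (keywords
#' take one or more values, consumed until the next keyword or operator):
#'
#' ```
#' expr     := and_expr ("or" and_expr)*
#' and_expr := unary ("and" unary)*
#' unary    := "not" unary | "(" expr ")" | primary
#' primary  := "all" | "none" | "water" | "protein" | "backbone" | "calpha"
#'           | "heavy" | "hydrogen" | "het"
#'           | "name" <v>+ | "resname" <v>+ | "chain" <v>+ | "element" <v>+
#'           | "resid" (<n> | <a>:<b>)+ | "serial" (<n> | <a>:<b>)+
#' ```
#'
#' `resid a:b` is a closed interval (both ends included). Resolution is
#' deterministic and idempotent; indices are always ascending.
#'
#' @param top a `topology`.
#' @param expression selection string, or an integer vector of atom indices
#'   (passed through after validation).
#' @return object of class `selection`: sorted integer vector of atom
#'   indices with attribute `expression`.
#' @examples
#' ## select(top, "name CA and resid 300")
#' ## select(top, "water or (chain A and not hydrogen)")
#' @export
select_atoms <- function(top, expression) {
  stopifnot(inherits(top, "topology"))
  if (is.numeric(expression)) {
    idx <- sort(unique(as.integer(expression)))
    if (length(idx) && (min(idx) < 1L || max(idx) > n_atoms(top))) {
      stop("selection indices out of range")
    }
    return(structure(idx, expression = "<indices>", class = "selection"))
  }
  toks <- .tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  mask <- .sel_expr(st, top)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("selection grammar error: unexpected token '%s' at position %d",
                 st$toks[st$pos], st$pos))
  }
  structure(which(mask), expression = expression, class = "selection")
}

.tokenize_selection <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (!length(toks) || !nzchar(toks[1])) stop("empty selection expression")
  toks
}

.SEL_KEYWORDS <- c("all", "none", "water", "protein", "backbone", "calpha",
                   "heavy", "hydrogen", "het", "name", "resname", "chain",
                   "element", "resid", "serial", "and", "or", "not", "(", ")")

.sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.sel_expr <- function(st, top) {
  m <- .sel_and(st, top)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    m <- m | .sel_and(st, top)
  }
  m
}

.sel_and <- function(st, top) {
  m <- .sel_unary(st, top)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    m <- m & .sel_unary(st, top)
  }
  m
}

.sel_unary <- function(st, top) {
  tk <- .sel_peek(st)
  if (is.na(tk)) stop("selection grammar error: unexpected end of expression")
  if (tolower(tk) == "not") {
    st$pos <- st$pos + 1L
    return(!.sel_unary(st, top))
  }
  if (tk == "(") {
    st$pos <- st$pos + 1L
    m <- .sel_expr(st, top)
    if (is.na(.sel_peek(st)) || .sel_peek(st) != ")") {
      stop(sprintf("selection grammar error: missing ')' at position %d", st$pos))
    }
    st$pos <- st$pos + 1L
    return(m)
  }
  .sel_primary(st, top)
}

.sel_values <- function(st) {
  vals <- character(0)
  repeat {
    tk <- .sel_peek(st)
    if (is.na(tk) || tolower(tk) %in% .SEL_KEYWORDS) break
    vals <- c(vals, tk)
    st$pos <- st$pos + 1L
  }
  vals
}

.sel_int_values <- function(vals, what, pos) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
      ab <- as.integer(strsplit(v, ":")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop(sprintf("selection grammar error: bad %s value '%s' near position %d",
                   what, v, pos))
    }
  }
  out
}

.sel_primary <- function(st, top) {
  a <- top$atoms
  tk <- tolower(.sel_peek(st)); pos <- st$pos
  st$pos <- st$pos + 1L
  nb <- nrow(a)
  switch(tk,
    all      = rep(TRUE, nb),
    none     = rep(FALSE, nb),
    water    = a$is_water,
    protein  = toupper(a$resname) %in% .STANDARD_AA,
    backbone = (toupper(a$resname) %in% .STANDARD_AA) &
               a$name %in% c("N", "CA", "C", "O"),
    calpha   = (toupper(a$resname) %in% .STANDARD_AA) & a$name == "CA",
    heavy    = toupper(a$element) != "H",
    hydrogen = toupper(a$element) == "H",
    het      = a$is_het,
    name     = a$name %in% .need_vals(.sel_values(st), "name", pos),
    resname  = toupper(a$resname) %in% toupper(.need_vals(.sel_values(st), "resname", pos)),
    chain    = a$chain %in% .need_vals(.sel_values(st), "chain", pos),
    element  = toupper(a$element) %in% toupper(.need_vals(.sel_values(st), "element", pos)),
    resid    = a$resid %in% .sel_int_values(.need_vals(.sel_values(st), "resid", pos), "resid", pos),
    serial   = a$serial %in% .sel_int_values(.need_vals(.sel_values(st), "serial", pos), "serial", pos),
    stop(sprintf("selection grammar error: unknown token '%s' at position %d",
                 .sel_peek_at(st, pos), pos))
  )
}

.sel_peek_at <- function(st, pos) st$toks[pos]

.need_vals <- function(vals, what, pos) {
  if (!length(vals)) {
    stop(sprintf("selection grammar error: '%s' at position %d needs at least one value",
                 what, pos))
  }
  vals
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> %d atoms: %s\n", length(x), attr(x, "expression")))
  invisible(x)
}

# Internal: coerce selection-ish input to validated indices; optionally
# require a non-empty result.
.as_indices <- function(top, sel, require_nonempty = TRUE, what = "selection") {
  idx <- if (inherits(sel, "selection")) as.integer(sel)
         else if (is.character(sel)) as.integer(select_atoms(top, sel))
         else sort(unique(as.integer(sel)))
  if (length(idx) && (min(idx) < 1L || max(idx) > n_atoms(top))) {
    stop(what, ": atom indices out of range")
  }
  if (require_nonempty && !length(idx)) stop(what, " resolves to zero atoms")
  idx
}
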