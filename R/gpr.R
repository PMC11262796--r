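# Gene-reaction rule (GPR) parsing and three-valued evaluation.
# Grammar:  expr := term ('or' term)* ;  term := factor ('and' factor)* ;
#           factor := gene | '(' expr ')'
# Keywords are case-insensitive; gene ids are case-sensitive.

gpr_tokenize <- function(gpr) {
  gpr <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(gpr), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene-reaction rule into an AND/OR tree
#'
#' @param gpr rule string, e.g. `"(g1 and g2) or g3"`; `""` or `NA` denotes no
#'   gene dependency.
#' @return A nested list AST: `list(op = "and"/"or", args = ...)` or
#'   `list(op = "gene", id = ...)`; `NULL` for the empty rule.
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || length(gpr) == 0 || is.na(gpr) || !nzchar(trimws(gpr))) {
    return(NULL)
  }
  toks <- gpr_tokenize(gpr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("GPR syntax error: unexpected end of rule in '", gpr, "'")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) {
        stop("GPR syntax error: missing ')' in '", gpr, "'")
      }
      return(e)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or")) {
      stop("GPR syntax error: unexpected token '", t, "' in '", gpr, "'")
    }
    list(op = "gene", id = t)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) { take(); args <- c(args, list(parse_term())) }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  ast <- parse_expr()
  if (pos <= length(toks)) {
    stop("GPR syntax error: trailing token '", peek(), "' in '", gpr, "'")
  }
  ast
}

gpr_genes <- function(gpr) {
  ast <- if (is.list(gpr) || is.null(gpr)) gpr else parse_gpr(gpr)
  if (is.null(ast)) return(character())
  if (ast$op == "gene") return(ast$id)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

#' Evaluate a gene-reaction rule against presence calls
#'
#' Three-valued logic: a gene called `present` is active, `absent` is
#' inactive, `unmeasured` (or missing from the call set) is unknown. An AND
#' node is inactive if any child is inactive; an OR node is active if any
#' child is active; otherwise an unknown child propagates `"unknown"`. The
#' empty rule (no gene dependency) evaluates to `"active"`.
#'
#' @param gpr rule string or AST from [parse_gpr()].
#' @param calls a `presence_calls` object from [call_presence()] /
#'   [merge_presence()], or a named character vector of
#'   `present`/`absent`/`unmeasured`.
#' @return One of `"active"`, `"inactive"`, `"unknown"`.
#' @export
evaluate_gpr <- function(gpr, calls) {
  lut <- if (inherits(calls, "presence_calls")) calls$calls else calls
  ast <- if (is.list(gpr) || is.null(gpr)) gpr else parse_gpr(gpr)
  ev <- function(node) {
    if (node$op == "gene") {
      s <- unname(lut[node$id])
      if (length(s) == 0 || is.na(s) || s == "unmeasured") return("unknown")
      return(switch(s, present = "active", absent = "inactive",
                    stop("invalid presence call '", s, "' for gene ", node$id)))
    }
    vals <- vapply(node$args, ev, character(1))
    if (node$op == "and") {
      if (any(vals == "inactive")) "inactive"
      else if (any(vals == "unknown")) "unknown"
      else "active"
    } else {
      if (any(vals == "active")) "active"
      else if (any(vals == "unknown")) "unknown"
      else "inactive"
    }
  }
  if (is.null(ast)) "active" else ev(ast)
}
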