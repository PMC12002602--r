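# Gene-protein-reaction rules: "and" joins subunits of a complex (all genes
# required), "or" joins isozymes (any gene suffices). Grammar:
#   expr   := term ("or" term)*
#   term   := factor ("and" factor)*
#   factor := gene | "(" expr ")"
# "and" binds tighter than "or"; identifiers are [A-Za-z0-9_.-]+ and keywords
# are case-insensitive.

#' Parse a gene-protein-reaction rule
#'
#' @param expression GPR string, e.g. `"(g1 and g2) or g3"`. Empty or `NA`
#'   input yields the empty tree (no gene association).
#' @return An object of class `gpr` — either `NULL` wrapped as an empty rule,
#'   a leaf (gene id), or a node `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(expression) {
  if (is.null(expression) || length(expression) == 0L || is.na(expression) ||
      !nzchar(trimws(expression))) {
    return(structure(list(tree = NULL), class = "gpr"))
  }
  toks <- gpr_tokenize(expression)
  st <- list(tokens = toks, pos = 1L, src = expression)
  res <- gpr_parse_expr(st)
  if (res$state$pos <= length(toks)) {
    bad <- toks[[res$state$pos]]
    stop("GPR parse error at position ", bad$at, " in '", expression,
         "': unexpected '", bad$text, "'")
  }
  structure(list(tree = res$node), class = "gpr")
}

gpr_tokenize <- function(s) {
  pat <- "\\(|\\)|[A-Za-z0-9_.-]+"
  m <- gregexpr(pat, s)[[1L]]
  if (m[1L] == -1L) stop("GPR parse error: no tokens in '", s, "'")
  texts <- regmatches(s, gregexpr(pat, s))[[1L]]
  # anything outside tokens must be whitespace
  resid <- s
  for (t in texts) resid <- sub(t, strrep(" ", nchar(t)), resid, fixed = TRUE)
  if (grepl("[^ \t]", resid)) {
    stop("GPR parse error: illegal character in '", s, "'")
  }
  Map(function(text, at) {
    type <- if (text == "(") "lpar" else if (text == ")") "rpar"
            else if (tolower(text) %in% c("and", "or")) tolower(text)
            else "gene"
    list(text = text, type = type, at = at)
  }, texts, as.integer(m))
}

gpr_peek <- function(st) {
  if (st$pos > length(st$tokens)) NULL else st$tokens[[st$pos]]
}

gpr_parse_expr <- function(st) {
  res <- gpr_parse_term(st)
  args <- list(res$node); st <- res$state
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_term(st)
    args <- c(args, list(res$node)); st <- res$state
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  list(node = node, state = st)
}

gpr_parse_term <- function(st) {
  res <- gpr_parse_factor(st)
  args <- list(res$node); st <- res$state
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_factor(st)
    args <- c(args, list(res$node)); st <- res$state
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  list(node = node, state = st)
}

gpr_parse_factor <- function(st) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop("GPR parse error at position ", nchar(st$src) + 1L, " in '", st$src,
         "': unexpected end of expression")
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(list(node = tk$text, state = st))
  }
  if (tk$type == "lpar") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_expr(st)
    st <- res$state
    cl <- gpr_peek(st)
    if (is.null(cl) || cl$type != "rpar") {
      stop("GPR parse error at position ",
           if (is.null(cl)) nchar(st$src) + 1L else cl$at,
           " in '", st$src, "': expected ')'")
    }
    st$pos <- st$pos + 1L
    return(list(node = res$node, state = st))
  }
  stop("GPR parse error at position ", tk$at, " in '", st$src,
       "': unexpected '", tk$text, "'")
}

#' Genes referenced by a GPR rule
#'
#' @param x A `gpr` object from [parse_gpr()].
#' @return Character vector of gene ids (sorted, unique); empty for the
#'   empty rule.
#' @export
gpr_genes <- function(x) {
  stopifnot(inherits(x, "gpr"))
  walk <- function(node) {
    if (is.null(node)) character(0)
    else if (is.character(node)) node
    else unlist(lapply(node$args, walk))
  }
  sort(unique(walk(x$tree)))
}

#' Evaluate a GPR rule under a gene-presence assignment
#'
#' @param x A `gpr` object.
#' @param present Character vector of gene ids considered present.
#' @return `TRUE` iff the rule is satisfied. The empty rule evaluates `TRUE`
#'   (no gene requirement).
#' @export
gpr_eval <- function(x, present) {
  stopifnot(inherits(x, "gpr"))
  walk <- function(node) {
    if (is.null(node)) TRUE
    else if (is.character(node)) node %in% present
    else if (node$op == "and") all(vapply(node$args, walk, TRUE))
    else any(vapply(node$args, walk, TRUE))
  }
  walk(x$tree)
}

#' @export
print.gpr <- function(x, ...) {
  fmt <- function(node) {
    if (is.null(node)) ""
    else if (is.character(node)) node
    else paste0("(", paste(vapply(node$args, fmt, ""),
                           collapse = paste0(" ", node$op, " ")), ")")
  }
  cat("<gpr>", fmt(x$tree), "\n")
  invisible(x)
}
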