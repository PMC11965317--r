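#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers that state which
#' gene products are required for a reaction to be catalysed: `and` joins
#' subunits of a complex (all required), `or` joins isozymes (any suffices).
#' Parentheses are honoured; in their absence `and` binds tighter than `or`,
#' the common convention in genome-scale models. `&&`/`&` and `||`/`|` are
#' accepted as synonyms.
#'
#' @param x a GPR string, e.g. `"(g1 and g2) or g3"`. Empty or all-whitespace
#'   strings return `NULL` (no GPR).
#' @return a `gpr` tree: either a leaf `list(gene = <id>)` or a node
#'   `list(op = "and"|"or", children = <list of gpr trees>)`, or `NULL`.
#' @examples
#' g <- parse_gpr("(g1 and g2) or g3")
#' gpr_to_string(g)
#' gpr_genes(g)
#' @export
parse_gpr <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NULL)
  x <- trimws(x)
  if (!nzchar(x)) return(NULL)
  toks <- gpr_tokenize(x)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error: unexpected token '", st$toks[st$pos], "' in: ", x)
  }
  tree
}

gpr_tokenize <- function(x) {
  x <- gsub("&&|&", " and ", x)
  x <- gsub("\\|\\||\\|", " or ", x)
  x <- gsub("\\(", " ( ", x)
  x <- gsub("\\)", " ) ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  low <- tolower(toks)
  toks[low == "and"] <- "and"
  toks[low == "or"] <- "or"
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  kids <- list(gpr_parse_and(st))
  while (identical(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_and(st)))
  }
  if (length(kids) == 1L) kids[[1L]] else gpr_node("or", kids)
}

gpr_parse_and <- function(st) {
  kids <- list(gpr_parse_atom(st))
  while (identical(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_atom(st)))
  }
  if (length(kids) == 1L) kids[[1L]] else gpr_node("and", kids)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("GPR parse error: unexpected end of expression")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) stop("GPR parse error: missing ')'")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok %in% c(")", "and", "or")) {
    stop("GPR parse error: unexpected token '", tok, "'")
  }
  st$pos <- st$pos + 1L
  structure(list(gene = tok), class = "gpr")
}

gpr_node <- function(op, children) {
  # flatten nested nodes of the same operator so trees normalise
  flat <- list()
  for (ch in children) {
    if (!is.null(ch$op) && ch$op == op) flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  structure(list(op = op, children = flat), class = "gpr")
}

#' Render a GPR tree back to its normalized string form
#'
#' @param g a `gpr` tree (or `NULL`).
#' @return a string; `""` for `NULL`.
#' @export
gpr_to_string <- function(g) {
  if (is.null(g)) return("")
  if (!is.null(g$gene)) return(g$gene)
  parts <- vapply(g$children, function(ch) {
    s <- gpr_to_string(ch)
    # parenthesize an OR child under AND to keep precedence explicit
    if (!is.null(ch$op) && g$op == "and" && ch$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", g$op, " "))
}

#' List the gene identifiers appearing in a GPR tree
#'
#' @param g a `gpr` tree (or `NULL`).
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(g) {
  if (is.null(g)) return(character(0))
  if (!is.null(g$gene)) return(g$gene)
  unique(unlist(lapply(g$children, gpr_genes)))
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}
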