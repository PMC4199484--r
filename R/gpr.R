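#' Gene-protein-reaction (GPR) Boolean expressions
#'
#' A GPR rule is a Boolean tree over gene identifiers with `and` / `or`
#' internal nodes, e.g. `"(g1 and g2) or g3"`: `and` joins subunits of a
#' protein complex, `or` joins isoenzymes or alternative complexes.  The
#' empty expression (no gene association) is represented by `NULL` and, by
#' convention, always evaluates `TRUE` -- a reaction without gene
#' association is never disabled by a knockout.
#'
#' Internally a parsed GPR is either a character scalar (a gene leaf) or a
#' list `list(op = "and"|"or", args = list(...))`.  [gpr_string()] emits a
#' canonical form: lowercase operators, genes sorted lexicographically
#' within a clause, clause strings sorted within the parent, and full
#' parenthesization whenever operators are mixed, so serialization is
#' deterministic and round-trips losslessly through [gpr_parse()].
#'
#' @param x a GPR string (for [gpr_parse()]) or parsed GPR tree.
#' @name gpr
NULL

gpr_tokenize <- function(x) {
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR string
#'
#' @param x character scalar such as `"(g1 and g2) or g3"`.  `NA`, `""`
#'   and whitespace-only strings parse to the empty expression (`NULL`).
#' @return parsed GPR tree (`NULL`, a gene id, or an and/or node).
#' @export
gpr_parse <- function(x) {
  if (is.null(x) || length(x) == 0) return(NULL)
  stopifnot(length(x) == 1)
  if (is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- gpr_tokenize(x)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("GPR parse error: unexpected end of expression in ", sQuote(x))
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")"))
        stop("GPR parse error: missing ')' in ", sQuote(x))
      return(e)
    }
    if (t %in% c(")", "and", "or", "AND", "OR"))
      stop("GPR parse error: unexpected token ", sQuote(t), " in ", sQuote(x))
    t
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  e <- parse_or()
  if (!is.na(peek()))
    stop("GPR parse error: trailing tokens starting at ", sQuote(peek()),
         " in ", sQuote(x))
  gpr_canonicalize(e)
}

# flatten nested same-op nodes and sort arguments for a canonical tree
gpr_canonicalize <- function(g) {
  if (is.null(g) || is.character(g)) return(g)
  args <- lapply(g$args, gpr_canonicalize)
  flat <- list()
  for (a in args) {
    if (is.list(a) && identical(a$op, g$op)) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  keys <- vapply(flat, gpr_string_node, character(1))
  flat <- flat[order(keys)]
  # drop duplicate branches (e.g. the same gene twice in an OR clause)
  keys <- vapply(flat, gpr_string_node, character(1))
  flat <- flat[!duplicated(keys)]
  if (length(flat) == 1) return(flat[[1]])
  list(op = g$op, args = flat)
}

gpr_string_node <- function(g) {
  if (is.character(g)) return(g)
  parts <- vapply(g$args, function(a) {
    s <- gpr_string_node(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", g$op, " "))
}

#' Serialize a parsed GPR to its canonical string
#'
#' @param g parsed GPR tree (or already a string, returned canonicalized).
#' @return character scalar; `""` for the empty expression.
#' @export
gpr_string <- function(g) {
  if (is.null(g)) return("")
  if (is.character(g) && length(g) == 1) {
    if (is.na(g) || !nzchar(trimws(g))) return("")
    g <- gpr_parse(g)      # accepts a bare gene id too
    if (is.null(g)) return("")
  }
  gpr_string_node(gpr_canonicalize(g))
}

#' Evaluate a GPR under a set of gene knockouts
#'
#' A gene leaf is `FALSE` iff the gene is knocked out; `and`/`or` combine
#' conventionally; the empty expression is `TRUE`.
#'
#' @param g GPR string or parsed tree.
#' @param knocked_out character vector of knocked-out gene ids.
#' @return logical scalar.
#' @export
evaluate_gpr <- function(g, knocked_out = character()) {
  if (is.character(g) && length(g) == 1) g <- gpr_parse(g)
  rec <- function(node) {
    if (is.character(node)) return(!(node %in% knocked_out))
    vals <- vapply(node$args, rec, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  if (is.null(g)) return(TRUE)
  rec(g)
}

#' Genes referenced by a GPR
#'
#' @param g GPR string or parsed tree.
#' @return sorted character vector of unique gene ids.
#' @export
gpr_genes <- function(g) {
  if (is.character(g) && length(g) == 1) g <- gpr_parse(g)
  rec <- function(node) {
    if (is.null(node)) return(character())
    if (is.character(node)) return(node)
    unlist(lapply(node$args, rec))
  }
  sort(unique(rec(g)))
}

# build an OR node over gene leaves / subtrees (NULL-safe)
gpr_or <- function(args) {
  args <- args[!vapply(args, is.null, logical(1))]
  if (length(args) == 0) return(NULL)
  if (length(args) == 1) return(gpr_canonicalize(args[[1]]))
  gpr_canonicalize(list(op = "or", args = args))
}

gpr_and <- function(args) {
  args <- args[!vapply(args, is.null, logical(1))]
  if (length(args) == 0) return(NULL)
  if (length(args) == 1) return(gpr_canonicalize(args[[1]]))
  gpr_canonicalize(list(op = "and", args = args))
}
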