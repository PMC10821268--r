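#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' Grammar: gene tokens combined with `and` / `or` (case-insensitive) and
#' parentheses; `and` binds tighter than `or`; chains of the same operator
#' are flattened into n-ary nodes.
#'
#' @param gpr_string the rule, e.g. `"(A and B) or C"`.
#' @return A tree of nested lists of class `gpr_node`; each node has `kind`
#'   (`"GENE"`, `"AND"` or `"OR"`) and either `gene` (leaves) or `children`.
#' @examples
#' parse_gpr("(A and B) or C")
#' @export
parse_gpr <- function(gpr_string) {
  if (!is.character(gpr_string) || length(gpr_string) != 1L ||
      is.na(gpr_string)) {
    stopf("GPR must be a single character string")
  }
  if (!nzchar(trimws(gpr_string))) stopf("GPR parse error: empty rule")

  # tokenise, remembering character positions for error messages
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, gpr_string)[[1L]]
  toks <- regmatches(gpr_string, gregexpr(pat, gpr_string))[[1L]]
  pos <- as.integer(m)
  type <- ifelse(toks == "(", "LPAR",
          ifelse(toks == ")", "RPAR",
          ifelse(tolower(toks) == "and", "AND",
          ifelse(tolower(toks) == "or", "OR", "GENE"))))

  i <- 0L
  peek <- function() if (i < length(toks)) type[i + 1L] else "EOF"
  advance <- function() {
    i <<- i + 1L
    toks[i]
  }
  err <- function(msg, at = if (i < length(toks)) pos[i + 1L]
                            else nchar(gpr_string) + 1L) {
    stopf("GPR parse error at position %d: %s", at, msg)
  }

  parse_factor <- function() {
    t <- peek()
    if (t == "GENE") {
      structure(list(kind = "GENE", gene = advance()), class = "gpr_node")
    } else if (t == "LPAR") {
      advance()
      node <- parse_or()
      if (peek() != "RPAR") err("expected ')'")
      advance()
      node
    } else if (t == "EOF") {
      err("unexpected end of rule")
    } else {
      err(sprintf("unexpected token '%s'", toks[i + 1L]))
    }
  }
  parse_and <- function() {
    kids <- list(parse_factor())
    while (peek() == "AND") {
      advance()
      kids <- c(kids, list(parse_factor()))
    }
    if (length(kids) == 1L) kids[[1L]]
    else structure(list(kind = "AND", children = flatten_same(kids, "AND")),
                   class = "gpr_node")
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (peek() == "OR") {
      advance()
      kids <- c(kids, list(parse_and()))
    }
    if (length(kids) == 1L) kids[[1L]]
    else structure(list(kind = "OR", children = flatten_same(kids, "OR")),
                   class = "gpr_node")
  }

  node <- parse_or()
  if (peek() != "EOF") {
    err(sprintf("unexpected token '%s' after complete rule", toks[i + 1L]))
  }
  node
}

flatten_same <- function(kids, kind) {
  out <- list()
  for (k in kids) {
    if (inherits(k, "gpr_node") && k$kind == kind) {
      out <- c(out, k$children)
    } else {
      out <- c(out, list(k))
    }
  }
  out
}

#' @export
print.gpr_node <- function(x, ...) {
  cat(deparse_gpr(x), "\n")
  invisible(x)
}

#' Render a GPR tree back to rule text
#' @param node a `gpr_node`.
#' @return A character string.
#' @export
deparse_gpr <- function(node) {
  if (node$kind == "GENE") return(node$gene)
  op <- if (node$kind == "AND") " and " else " or "
  paste0("(", paste(vapply(node$children, deparse_gpr, character(1L)),
                    collapse = op), ")")
}

#' Gene ids referenced by a GPR tree
#' @param node a `gpr_node`.
#' @return Character vector of unique gene ids.
#' @export
gpr_genes <- function(node) {
  if (node$kind == "GENE") return(node$gene)
  unique(unlist(lapply(node$children, gpr_genes)))
}

#' Evaluate a GPR tree against gene expression values
#'
#' Follows the expression-to-reaction mapping in which `OR` is the sum of
#' its children (isoenzymes add capacity) and `AND` is the minimum
#' (complex subunits are limiting).
#'
#' Missing genes are handled per `missing`:
#' * `"identity"` (default): an absent leaf contributes the identity of its
#'   parent operator — 0 under `OR`, ignored under `AND` when at least one
#'   sibling resolves; a rule in which no leaf resolves yields `NA`.
#' * `"error"`: any absent gene is an error.
#'
#' @param tree a `gpr_node` from [parse_gpr()].
#' @param gene_expression named numeric vector of non-negative expression
#'   values.
#' @param missing missing-gene policy.
#' @return A single numeric score, or `NA` when the rule is unresolvable.
#' @examples
#' resolve_gpr(parse_gpr("A or B"), c(A = 2, B = 3))   # 5
#' resolve_gpr(parse_gpr("A and B"), c(A = 2, B = 3))  # 2
#' @export
resolve_gpr <- function(tree, gene_expression,
                        missing = c("identity", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(tree, "gpr_node"))
  if (is.null(names(gene_expression))) {
    stopf("'gene_expression' must be named by gene id")
  }
  if (any(gene_expression < 0, na.rm = TRUE)) {
    stopf("expression values must be non-negative")
  }
  eval_node <- function(node) {
    if (node$kind == "GENE") {
      v <- gene_expression[node$gene]
      if (is.na(v)) {
        if (missing == "error") {
          stopf("gene '%s' absent from the expression map", node$gene)
        }
        return(NA_real_)
      }
      return(unname(v))
    }
    vals <- vapply(node$children, eval_node, numeric(1L))
    ok <- !is.na(vals)
    if (!any(ok)) return(NA_real_)
    if (node$kind == "OR") sum(vals[ok]) else min(vals[ok])
  }
  eval_node(tree)
}
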