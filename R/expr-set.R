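#' Gene-by-sample expression set
#'
#' A light container for an FPKM-like abundance matrix together with the
#' condition label of each sample, in the spirit of limma's `EList`. Values
#' are non-negative, genes are rows, samples are columns.
#'
#' @param values numeric matrix, genes x samples, with unique rownames (gene
#'   ids) and colnames (sample ids). No missing values allowed.
#' @param groups character or factor of condition labels, one per sample.
#'   Either named by sample id or in column order.
#' @return An object of class `expr_set`: a list with elements `values`
#'   (the matrix) and `groups` (a factor named by sample id).
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' es <- expr_set(m, rep(c("Control", "Treated"), each = 2))
#' es
#' @export
expr_set <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stopf("duplicate gene id: %s",
          rownames(values)[anyDuplicated(rownames(values))])
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicate sample id: %s",
          colnames(values)[anyDuplicated(colnames(values))])
  }
  if (anyNA(values)) stopf("'values' contains missing entries")
  if (any(values < 0)) stopf("'values' contains negative entries")
  if (ncol(values) < 2L) stopf("need at least 2 samples")
  groups <- as.factor(groups)
  if (length(groups) != ncol(values)) {
    stopf("'groups' must have one label per sample (%d needed, %d given)",
          ncol(values), length(groups))
  }
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(values))) {
      stopf("'groups' names do not match sample ids")
    }
    groups <- groups[colnames(values)]
  } else {
    names(groups) <- colnames(values)
  }
  structure(list(values = values, groups = groups), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Select the most variable genes
#'
#' Ranks genes by the variance of `log2(value + 1)` across all samples and
#' keeps the top `k`, mirroring the common practice of restricting network
#' inference to the most variable genes. Order of the result is by
#' decreasing variance, ties broken by gene id.
#'
#' @param expr an [expr_set].
#' @param k number of genes to keep, `1 <= k <=` number of genes.
#' @return An `expr_set` with `k` genes.
#' @export
select_most_variable <- function(expr, k) {
  stopifnot(inherits(expr, "expr_set"))
  p <- nrow(expr$values)
  if (!is_count(k) || k < 1L || k > p) {
    stopf("'k' must be an integer in [1, %d], got %s", p, format(k))
  }
  v <- apply(log2(expr$values + 1), 1L, var)
  ord <- order(-v, rownames(expr$values))
  keep <- ord[seq_len(k)]
  expr_set(expr$values[keep, , drop = FALSE], expr$groups)
}

#' Read an expression matrix and its sample groups from TSV files
#'
#' The expression file is tab-separated with a header row of sample ids and
#' gene ids in the first column. The groups file has two columns,
#' `sample` and `group`.
#'
#' @param path path to the expression TSV.
#' @param groups_path path to the sample-to-group TSV; alternatively
#'   `groups` may be given directly as a vector.
#' @param groups optional vector of labels (used when `groups_path` is NULL).
#' @return An [expr_set].
#' @export
read_expression <- function(path, groups_path = NULL, groups = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 2L) stopf("expression file needs gene ids plus >=1 sample")
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate gene id: %s", dup[1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1L)))[1L]
    nonnum <- which(is.na(suppressWarnings(as.numeric(tab[[bad + 1L]]))))[1L]
    stopf("non-numeric value at row %d, column '%s'", nonnum,
          colnames(tab)[bad + 1L])
  }
  rownames(m) <- ids
  if (!is.null(groups_path)) {
    g <- read.delim(groups_path, stringsAsFactors = FALSE, comment.char = "#")
    if (!all(c("sample", "group") %in% colnames(g))) {
      stopf("groups file must have columns 'sample' and 'group'")
    }
    groups <- stats::setNames(g$group, g$sample)
  }
  if (is.null(groups)) stopf("either 'groups_path' or 'groups' is required")
  expr_set(m, groups)
}

#' Write an expression set as TSV (matrix plus sample-group sidecar)
#'
#' @param expr an [expr_set].
#' @param path output path of the expression TSV.
#' @param groups_path output path of the sample-to-group TSV (default:
#'   `path` with a `.groups.tsv` suffix).
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(expr, path,
                             groups_path = paste0(path, ".groups.tsv")) {
  stopifnot(inherits(expr, "expr_set"))
  tab <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- data.frame(sample = names(expr$groups),
                  group = as.character(expr$groups))
  write.table(g, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, groups_path))
}
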