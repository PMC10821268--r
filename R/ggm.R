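# Decomposable Gaussian graphical model over genes: maximum-likelihood
# spanning tree, then greedy forward selection of chordality-preserving
# edges under BIC, then functional-structure extraction.

# log2(x + 1)-transformed data matrix (samples x genes) for likelihoods
log_expr <- function(expr) {
  x <- t(log2(expr$values + 1))
  const <- which(apply(x, 2L, var) == 0)
  if (length(const)) {
    stopf("gene '%s' is constant across samples", colnames(x)[const[1L]])
  }
  x
}

#' Maximum-likelihood spanning tree of a gene set
#'
#' Under a Gaussian model, the spanning tree maximising the likelihood is
#' the maximum spanning tree under edge weight `-log(1 - r^2)/2`, with `r`
#' the Pearson correlation of the `log2(FPKM + 1)` values (a monotone
#' transform of `|r|`, so the same tree as maximising `|r|`). Ties are
#' broken lexicographically by gene-id pair, making the result
#' deterministic.
#'
#' @param expr an [expr_set] with at least 3 samples and no constant gene.
#' @return An igraph spanning tree with genes as named vertices.
#' @export
max_likelihood_spanning_tree <- function(expr) {
  stopifnot(inherits(expr, "expr_set"))
  if (ncol(expr$values) < 3L) stopf("need at least 3 samples")
  x <- log_expr(expr)
  p <- ncol(x)
  genes <- colnames(x)
  if (p < 2L) stopf("need at least 2 genes")
  r <- cor(x)
  w <- -0.5 * log(pmax(1 - r^2, 1e-12))

  ij <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[ij], genes[ij[, 1L]], genes[ij[, 2L]])
  ij <- ij[ord, , drop = FALSE]

  parent <- seq_len(p)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  sel <- matrix(integer(0L), ncol = 2L)
  for (k in seq_len(nrow(ij))) {
    ra <- find(ij[k, 1L])
    rb <- find(ij[k, 2L])
    if (ra != rb) {
      parent[max(ra, rb)] <- min(ra, rb)
      sel <- rbind(sel, ij[k, , drop = FALSE])
      if (nrow(sel) == p - 1L) break
    }
  }
  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  igraph::add_edges(g, t(sel))
}

#' Gaussian decomposable model score (log-likelihood, df, BIC)
#'
#' The maximised log-likelihood of a decomposable Gaussian model factorises
#' clique-wise over a junction tree: `l = sum_C l_C - sum_S l_S`, where
#' `l_A` is the maximised log-likelihood of the saturated Gaussian on the
#' margin `A` (MLE covariance, denominator n). Degrees of freedom count one
#' mean and one variance per vertex plus one free parameter per edge
#' (`df = 2p + |E|`); `bic = -2 l + df log(n)`.
#'
#' @param graph a chordal igraph whose vertex names are genes of `expr`.
#' @param expr an [expr_set].
#' @return List of class `model_score` with `log_likelihood`, `df`, `n`,
#'   `bic`.
#' @export
model_bic <- function(graph, expr) {
  stopifnot(inherits(expr, "expr_set"))
  x <- log_expr(expr)
  missing_genes <- setdiff(igraph::V(graph)$name, colnames(x))
  if (length(missing_genes)) {
    stopf("graph vertex '%s' not among the expression genes",
          missing_genes[1L])
  }
  x <- x[, igraph::V(graph)$name, drop = FALSE]
  n <- nrow(x)
  S <- crossprod(scale(x, center = TRUE, scale = FALSE)) / n

  dec <- clique_decomposition(graph)
  margin_ll <- function(a) {
    k <- length(a)
    Sa <- S[a, a, drop = FALSE]
    ld <- determinant(Sa, logarithm = TRUE)
    if (ld$sign <= 0) {
      stopf("singular covariance on clique {%s}", paste(a, collapse = ", "))
    }
    -n / 2 * (k * log(2 * pi) + as.numeric(ld$modulus) + k)
  }
  ll <- sum(vapply(dec$cliques, margin_ll, numeric(1L))) -
    (if (length(dec$separators))
       sum(vapply(dec$separators, margin_ll, numeric(1L))) else 0)
  p <- igraph::vcount(graph)
  df <- 2L * p + igraph::ecount(graph)
  new_model_score(ll, df, n)
}

new_model_score <- function(ll, df, n) {
  structure(list(log_likelihood = ll, df = as.integer(df), n = as.integer(n),
                 bic = -2 * ll + df * log(n)),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("model_score: logLik %.3f, df %d, n %d, BIC %.3f\n",
              x$log_likelihood, x$df, x$n, x$bic))
  invisible(x)
}

#' Greedy BIC forward selection of decomposability-preserving edges
#'
#' Starting from a spanning tree, repeatedly adds the addable edge with
#' the largest BIC reduction and stops when no addable edge reduces BIC
#' (a local BIC minimum). The gain of an addable edge (u, v) with unique
#' minimal separator S is closed-form:
#' `delta_ll = -n/2 log(1 - pcor(u, v | S)^2)`, `delta_bic = -2 delta_ll +
#' log n`, because the junction tree changes only locally (the new clique
#' is S + {u, v}). Deltas are cached by (u, v, S) across iterations; ties
#' are broken lexicographically by gene-id pair.
#'
#' @param tree a spanning (chordal) igraph over the genes of `expr`.
#' @param expr an [expr_set].
#' @param max_steps optional cap on the number of edges added.
#' @return List with `graph` (the selected chordal graph) and `score`
#'   (the final `model_score`).
#' @export
forward_select_edges <- function(tree, expr, max_steps = Inf) {
  stopifnot(inherits(expr, "expr_set"))
  if (!is_decomposable(tree)) stopf("input graph is not chordal")
  x <- log_expr(expr)
  x <- x[, igraph::V(tree)$name, drop = FALSE]
  n <- nrow(x)
  R <- cor(x)
  genes <- colnames(x)

  pcor_given <- function(u, v, s) {
    idx <- c(u, v, s)
    K <- tryCatch(solve(R[idx, idx, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(K)) {
      stopf("singular covariance on clique {%s}",
            paste(idx, collapse = ", "))
    }
    -K[1L, 2L] / sqrt(K[1L, 1L] * K[2L, 2L])
  }

  cache <- new.env(parent = emptyenv())
  delta_for <- function(u, v, s) {
    key <- paste(u, v, paste(s, collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    rho <- pcor_given(u, v, s)
    d <- n * log(max(1 - rho^2, 1e-300)) + log(n)   # -2*delta_ll + log n
    cache[[key]] <- d
    d
  }

  g <- tree
  score <- model_bic(g, expr)
  steps <- 0L
  repeat {
    if (steps >= max_steps) break
    cand <- addable_edges(g)
    if (!nrow(cand)) break
    deltas <- vapply(seq_len(nrow(cand)), function(k) {
      delta_for(cand$u[k], cand$v[k], cand$separator[[k]])
    }, numeric(1L))
    best <- which.min(deltas)   # candidates are already in lexicographic order
    if (deltas[best] >= 0) break
    g <- igraph::add_edges(g, c(cand$u[best], cand$v[best]))
    score <- new_model_score(score$log_likelihood - deltas[best] / 2 +
                               log(n) / 2,
                             score$df + 1L, n)
    steps <- steps + 1L
  }
  # internal consistency: incremental score must match a full recomputation
  full <- model_bic(g, expr)
  if (abs(full$bic - score$bic) > 1e-6 * max(1, abs(full$bic))) {
    stopf("internal error: incremental BIC (%.6f) disagrees with full BIC (%.6f)",
          score$bic, full$bic)
  }
  list(graph = g, score = full)
}

#' Partition a gene graph into functional branches
#'
#' Divisive edge-betweenness community detection, cutting the dendrogram
#' at maximum modularity, then merging communities smaller than `min_size`
#' into the neighbouring community with the most connecting edges (ties to
#' the lowest community id). Deterministic given the graph.
#'
#' @param graph a connected igraph with named vertices.
#' @param min_size smallest allowed branch size.
#' @return List of character vectors (gene sets), ordered by their first
#'   vertex in the graph's vertex order.
#' @export
detect_branches <- function(graph, min_size = 2L) {
  if (!is_count(min_size)) stopf("'min_size' must be an integer >= 1")
  if (min_size > igraph::vcount(graph)) {
    stopf("'min_size' (%d) exceeds the number of vertices (%d)",
          min_size, igraph::vcount(graph))
  }
  if (!igraph::is_connected(graph)) stopf("graph must be connected")
  comm <- igraph::cluster_edge_betweenness(graph, weights = NULL)
  memb <- igraph::membership(comm)

  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) == 1L) break
    cid <- small[order(sizes[small], as.integer(small))][1L]
    members <- which(memb == as.integer(cid))
    others <- setdiff(unique(memb), as.integer(cid))
    links <- vapply(others, function(o) {
      sum(adj[members, memb == o, drop = FALSE])
    }, numeric(1L))
    target <- others[links == max(links)]
    memb[members] <- min(target)
  }
  ids <- unique(memb)                   # order of first appearance
  lapply(ids, function(i) igraph::V(graph)$name[memb == i])
}

#' Functional node
#'
#' @param node_id integer id.
#' @param genes character vector of member genes.
#' @param label overrepresented-function label (may be `NA`).
#' @param enrichment_p adjusted enrichment p-value (may be `NA`).
#' @return A list of class `functional_node`.
#' @export
functional_node <- function(node_id, genes, label = NA_character_,
                            enrichment_p = NA_real_) {
  if (!length(genes)) stopf("a functional node needs at least one gene")
  if (!is.na(enrichment_p) && !is_prob(enrichment_p)) {
    stopf("'enrichment_p' must lie in [0, 1]")
  }
  structure(list(node_id = as.integer(node_id), genes = as.character(genes),
                 label = label, enrichment_p = enrichment_p),
            class = "functional_node")
}

#' Hypergeometric enrichment of a gene set against a collection
#'
#' One-sided hypergeometric tail probability of the observed overlap for
#' every candidate set, Benjamini-Hochberg adjusted across the collection;
#' the minimum-adjusted-p label wins (ties broken alphabetically). An
#' offline replacement for web-based over-representation tools.
#'
#' @param genes gene ids of the node; must be contained in `universe`.
#' @param gene_sets named list of character vectors (e.g. from a GMT file).
#' @param universe all gene ids considered.
#' @return List with `label`, `p_adjusted`, `p_raw` and `table` (all
#'   candidates with raw and adjusted p).
#' @export
enrich_node <- function(genes, gene_sets, universe) {
  if (!length(gene_sets)) stopf("empty gene-set collection")
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stopf("'gene_sets' must be a named list")
  }
  extra <- setdiff(genes, universe)
  if (length(extra)) {
    stopf("node gene '%s' is not in the universe", extra[1L])
  }
  N <- length(universe)
  k <- length(genes)
  praw <- vapply(gene_sets, function(set) {
    set <- intersect(set, universe)
    m <- length(set)
    ov <- length(intersect(genes, set))
    phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
  }, numeric(1L))
  padj <- p.adjust(praw, method = "BH")
  ord <- order(padj, names(gene_sets))
  list(label = names(gene_sets)[ord[1L]],
       p_adjusted = unname(padj[ord[1L]]),
       p_raw = unname(praw[ord[1L]]),
       table = data.frame(label = names(gene_sets)[ord],
                          p_raw = unname(praw[ord]),
                          p_adjusted = unname(padj[ord]),
                          stringsAsFactors = FALSE))
}

#' Functional-node activities
#'
#' The activity of a node in a sample is the arithmetic mean of the node's
#' gene expression values in that sample.
#'
#' @param expr an [expr_set].
#' @param nodes list of [functional_node]s or of plain gene-id vectors.
#' @return A `node_activity` object: matrix nodes x samples with the
#'   sample groups attached as attribute `groups`.
#' @export
node_activity <- function(expr, nodes) {
  stopifnot(inherits(expr, "expr_set"))
  gene_sets <- lapply(nodes, function(nd) {
    if (inherits(nd, "functional_node")) nd$genes else as.character(nd)
  })
  if (any(!lengths(gene_sets))) stopf("empty functional node")
  missing_genes <- setdiff(unlist(gene_sets), rownames(expr$values))
  if (length(missing_genes)) {
    stopf("node gene '%s' absent from the expression matrix",
          missing_genes[1L])
  }
  act <- t(vapply(gene_sets, function(gs) {
    colMeans(expr$values[gs, , drop = FALSE])
  }, numeric(ncol(expr$values))))
  rownames(act) <- if (!is.null(names(nodes))) names(nodes) else
    sprintf("node_%02d", seq_along(nodes))
  structure(act, groups = expr$groups, class = c("node_activity", "matrix"))
}

#' Kruskal-Wallis comparison of node activities across groups
#'
#' Non-parametric rank test per node (tie-corrected H statistic,
#' chi-square p with groups - 1 degrees of freedom). Nodes whose
#' activities are identical across all samples get H = 0, p = 1.
#'
#' @param activity a `node_activity` from [node_activity()].
#' @return data.frame with columns `node`, `H`, `df`, `p`.
#' @export
compare_node_activity <- function(activity) {
  groups <- attr(activity, "groups")
  if (is.null(groups)) stopf("activity table lacks sample groups")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    small <- names(which(table(groups) < 2L))[1L]
    stopf("group '%s' has fewer than 2 samples", small)
  }
  res <- lapply(rownames(activity), function(nd) {
    y <- as.numeric(activity[nd, ])
    if (length(unique(y)) == 1L) {
      data.frame(node = nd, H = 0, df = nlevels(groups) - 1L, p = 1)
    } else {
      kt <- kruskal.test(y, groups)
      data.frame(node = nd, H = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value)
    }
  })
  do.call(rbind, res)
}

#' End-to-end graphical-model pipeline
#'
#' Selects the `top_k` most variable genes (dropping constant genes with a
#' warning), fits the spanning tree, forward-selects edges under BIC,
#' partitions the graph into branches, optionally labels each branch by
#' gene-set enrichment, and computes node activities plus Kruskal-Wallis
#' group comparisons.
#'
#' @param expr an [expr_set].
#' @param top_k number of most variable genes to keep (capped at the
#'   number of genes).
#' @param gene_sets optional named list for [enrich_node()].
#' @param min_branch smallest branch size for [detect_branches()].
#' @return List of class `ggm_fit`: `graph`, `score`, `nodes` (list of
#'   [functional_node]), `activity`, `comparison`.
#' @export
ggm_network <- function(expr, top_k = 2000L, gene_sets = NULL,
                        min_branch = 2L) {
  stopifnot(inherits(expr, "expr_set"))
  keep <- apply(log2(expr$values + 1), 1L, var) > 0
  if (!all(keep)) {
    warnf("dropping %d constant gene(s) before correlation", sum(!keep))
    expr <- expr_set(expr$values[keep, , drop = FALSE], expr$groups)
  }
  expr <- select_most_variable(expr, min(top_k, nrow(expr$values)))
  tree <- max_likelihood_spanning_tree(expr)
  fit <- forward_select_edges(tree, expr)
  branches <- detect_branches(fit$graph, min_size = min_branch)
  universe <- rownames(expr$values)
  nodes <- lapply(seq_along(branches), function(i) {
    if (is.null(gene_sets)) {
      functional_node(i, branches[[i]])
    } else {
      en <- enrich_node(branches[[i]], gene_sets, universe)
      functional_node(i, branches[[i]], label = en$label,
                      enrichment_p = en$p_adjusted)
    }
  })
  act <- node_activity(expr, nodes)
  comp <- compare_node_activity(act)
  structure(list(graph = fit$graph, score = fit$score, nodes = nodes,
                 activity = act, comparison = comp),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf("ggm_fit: %d genes, %d edges, %d functional nodes, BIC %.2f\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$nodes), x$score$bic))
  invisible(x)
}
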