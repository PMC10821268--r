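# Chordal (decomposable) graph utilities built on igraph.
#
# Graphs are igraph objects whose vertex names are gene ids. A graph is
# decomposable iff it is chordal; its maximal cliques and the separators
# of any junction tree then give the closed-form Gaussian likelihood
# decomposition used by model_bic().

#' Is a graph decomposable (chordal)?
#'
#' @param graph an igraph object.
#' @return Logical flag.
#' @export
is_decomposable <- function(graph) {
  igraph::is_chordal(graph)$chordal
}

#' Maximal cliques and junction-tree separators of a chordal graph
#'
#' Computes the maximal cliques and, via a maximum-weight spanning forest
#' of the clique graph (weight = separator size, ties broken by clique
#' order), the separator multiset of a junction tree. For a chordal graph
#' any maximum-weight spanning tree of the clique graph satisfies the
#' running-intersection property.
#'
#' @param graph a chordal igraph object with named vertices.
#' @return List with `cliques` (list of character vectors, each sorted)
#'   and `separators` (list of character vectors, possibly with repeats).
#' @export
clique_decomposition <- function(graph) {
  if (!is_decomposable(graph)) stopf("graph is not chordal")
  cl <- lapply(igraph::max_cliques(graph),
               function(v) sort(igraph::V(graph)$name[v]))
  cl <- cl[order(vapply(cl, paste, character(1L), collapse = "\r"))]
  nc <- length(cl)
  if (nc <= 1L) return(list(cliques = cl, separators = list()))

  # candidate junction edges: clique pairs with non-empty intersection
  cand <- list()
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      w <- length(intersect(cl[[i]], cl[[j]]))
      if (w > 0L) cand[[length(cand) + 1L]] <- c(i, j, w)
    }
  }
  separators <- list()
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3L], cm[, 1L], cm[, 2L]), , drop = FALSE]
    parent <- seq_len(nc)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    for (k in seq_len(nrow(cm))) {
      ri <- find(cm[k, 1L])
      rj <- find(cm[k, 2L])
      if (ri != rj) {
        parent[max(ri, rj)] <- min(ri, rj)
        separators[[length(separators) + 1L]] <-
          intersect(cl[[cm[k, 1L]]], cl[[cm[k, 2L]]])
      }
    }
  }
  list(cliques = cl, separators = separators)
}

# minimal (u, v)-separator closest to v: the neighbourhood of the
# component of u in G - N[v]. u and v must be non-adjacent.
minimal_separator_near <- function(graph, u, v) {
  nv <- c(v, as.integer(igraph::neighbors(graph, v)))
  keep <- setdiff(seq_len(igraph::vcount(graph)), nv)
  sub <- igraph::induced_subgraph(graph, keep)
  comp <- igraph::components(sub)
  iu <- match(u, keep)
  if (is.na(iu)) return(integer(0L))     # u adjacent to v (not expected)
  cu <- keep[comp$membership == comp$membership[iu]]
  nb <- unique(unlist(igraph::adjacent_vertices(graph, cu)))
  sort(setdiff(as.integer(nb), cu))
}

#' Edges whose addition preserves decomposability
#'
#' Returns exactly those non-adjacent vertex pairs whose addition leaves
#' the graph chordal. A non-edge (u, v) of a chordal graph is addable iff
#' u and v have a unique minimal separator, i.e. the minimal separators
#' closest to u and to v coincide; the common set S is attached to each
#' pair (it conditions the likelihood gain of the new edge, whose clique
#' in the larger graph is S plus the endpoints).
#'
#' @param graph a chordal igraph object with named vertices.
#' @return A data.frame with columns `u`, `v` (vertex names, `u < v`
#'   lexicographically) and a list-column `separator` of character
#'   vectors.
#' @export
addable_edges <- function(graph) {
  if (!is_decomposable(graph)) stopf("graph is not chordal")
  n <- igraph::vcount(graph)
  nms <- igraph::V(graph)$name
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0

  # per-vertex component structure of G - N[x], reused across candidates
  comp_of <- vector("list", n)     # component id per kept vertex
  sep_of <- vector("list", n)      # neighbourhood of each component
  for (x in seq_len(n)) {
    nx <- c(x, which(adj[x, ]))
    keep <- setdiff(seq_len(n), nx)
    sub <- igraph::induced_subgraph(graph, keep)
    comp <- igraph::components(sub)
    memb <- rep(NA_integer_, n)
    memb[keep] <- comp$membership
    seps <- lapply(seq_len(comp$no), function(ci) {
      cu <- keep[comp$membership == ci]
      nb <- unique(unlist(igraph::adjacent_vertices(graph, cu)))
      sort(setdiff(as.integer(nb), cu))
    })
    comp_of[[x]] <- memb
    sep_of[[x]] <- seps
  }

  us <- integer(0L)
  vs <- integer(0L)
  seps <- list()
  for (u in seq_len(n - 1L)) {
    for (v in (u + 1L):n) {
      if (adj[u, v]) next
      cu <- comp_of[[v]][u]      # component of u in G - N[v]
      cv <- comp_of[[u]][v]
      s1 <- if (is.na(cu)) integer(0L) else sep_of[[v]][[cu]]
      s2 <- if (is.na(cv)) integer(0L) else sep_of[[u]][[cv]]
      if (identical(s1, s2)) {
        us <- c(us, u)
        vs <- c(vs, v)
        seps[[length(seps) + 1L]] <- nms[s1]
      }
    }
  }
  # order pairs lexicographically by name
  un <- nms[us]
  vn <- nms[vs]
  swap <- un > vn
  tmp <- un[swap]; un[swap] <- vn[swap]; vn[swap] <- tmp
  ord <- order(un, vn)
  out <- data.frame(u = un[ord], v = vn[ord], stringsAsFactors = FALSE)
  out$separator <- seps[ord]
  out
}
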