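# Independent oracles used to cross-check the package's implementations.
# Everything here is deliberately naive (enumeration, direct evaluation)
# and shares no code with the functions under test.

# ---- graphs ----------------------------------------------------------------

# all labelled graphs on n vertices as upper-triangle bit masks
enumerate_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(0:(2^m - 1L), function(mask) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    adj <- matrix(FALSE, n, n)
    for (k in which(sel)) {
      adj[pairs[k, 1L], pairs[k, 2L]] <- TRUE
      adj[pairs[k, 2L], pairs[k, 1L]] <- TRUE
    }
    adj
  })
}

adj_to_igraph <- function(adj, names = letters[seq_len(nrow(adj))]) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::set_vertex_attr(g, "name", value = names)
}

# chordality via maximum cardinality search + perfect elimination check,
# implemented from scratch (independent of igraph::is_chordal)
chordal_mcs <- function(adj) {
  n <- nrow(adj)
  if (n <= 2L) return(TRUE)
  weight <- rep(0L, n)
  order <- integer(n)
  numbered <- rep(FALSE, n)
  for (i in n:1) {
    cand <- which(!numbered)
    v <- cand[which.max(weight[cand])]
    order[i] <- v
    numbered[v] <- TRUE
    weight[adj[v, ] & !numbered] <- weight[adj[v, ] & !numbered] + 1L
  }
  pos <- match(seq_len(n), order)
  for (i in seq_len(n)) {
    v <- order[i]
    later <- which(adj[v, ] & pos > pos[v])
    if (length(later) > 1L) {
      w <- later[which.min(pos[later])]
      rest <- setdiff(later, w)
      if (any(!adj[w, rest])) return(FALSE)
    }
  }
  TRUE
}

connected_adj <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# random connected chordal graph by chordality-preserving edge additions
random_chordal <- function(n, p_extra = 0.5) {
  g <- igraph::sample_tree(n)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("g%02d", 1:n))
  repeat {
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    ne <- which(!adj & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(ne) || stats::runif(1) > p_extra) break
    cand <- ne[sample.int(nrow(ne), 1L), ]
    g2 <- igraph::add_edges(g, as.vector(cand))
    if (igraph::is_chordal(g2)$chordal) g <- g2 else break
  }
  g
}

# ---- Gaussian likelihood ---------------------------------------------------

# graph-constrained Gaussian MLE covariance by iterative proportional
# scaling on the concentration matrix, then the direct joint density
ips_loglik <- function(adj, x, iter = 2000L, tol = 1e-12) {
  n <- nrow(x)
  p <- ncol(x)
  S <- crossprod(scale(x, center = TRUE, scale = FALSE)) / n
  cl <- igraph::max_cliques(adj_to_igraph(adj, colnames(x)))
  cl <- lapply(cl, as.integer)
  K <- diag(1 / diag(S))
  for (it in seq_len(iter)) {
    K_old <- K
    for (C in cl) {
      Sigma <- solve(K)
      K[C, C] <- solve(S[C, C, drop = FALSE]) +
        K[C, C, drop = FALSE] - solve(Sigma[C, C, drop = FALSE])
    }
    if (max(abs(K - K_old)) < tol) break
  }
  Sigma <- solve(K)
  mu <- colMeans(x)
  sum(mvtnorm::dmvnorm(x, mean = mu, sigma = Sigma, log = TRUE))
}

# Kruskal-Wallis H by the rank-sum formula with tie correction
kw_h_oracle <- function(y, g) {
  g <- as.factor(g)
  N <- length(y)
  r <- rank(y)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# ---- linear programming ----------------------------------------------------

# brute-force optimum of max c'v s.t. S v = 0, lb <= v <= ub by
# enumerating candidate vertices (subsets of active bounds)
vertex_enum_fba <- function(S, lb, ub, cvec) {
  n <- ncol(S)
  best <- -Inf
  for (k in 0:n) {
    fixes <- if (k == 0L) list(integer(0L)) else
      asplit(combn(n, k), 2L)
    for (fix in fixes) {
      free <- setdiff(seq_len(n), fix)
      grids <- if (k == 0L) list(integer(0L)) else
        asplit(as.matrix(expand.grid(rep(list(1:2), k))), 1L)
      for (gr in grids) {
        v <- rep(NA_real_, n)
        if (k > 0L) v[fix] <- ifelse(gr == 1L, lb[fix], ub[fix])
        if (length(free)) {
          A <- S[, free, drop = FALSE]
          if (qr(A)$rank < length(free)) next
          rhs <- if (k > 0L) -S[, fix, drop = FALSE] %*% v[fix] else
            matrix(0, nrow(S), 1L)
          sol <- tryCatch(qr.coef(qr(A), rhs), error = function(e) NULL)
          if (is.null(sol) || anyNA(sol)) next
          v[free] <- sol
        }
        if (max(abs(S %*% v)) < 1e-7 && all(v >= lb - 1e-8) &&
            all(v <= ub + 1e-8)) {
          best <- max(best, sum(cvec * v))
        }
      }
    }
  }
  best
}

random_toy_fba <- function(seed, n_rxn = 5L, n_met = 3L) {
  withr::with_seed(seed, {
    S <- matrix(sample(c(-1, 0, 1), n_met * n_rxn, TRUE,
                       prob = c(.3, .4, .3)), n_met, n_rxn)
    lb <- ifelse(stats::runif(n_rxn) < .3, -1, 0)
    ub <- stats::runif(n_rxn, .5, 2)
    cvec <- rep(0, n_rxn)
    cvec[sample.int(n_rxn, 1L)] <- 1
    list(S = S, lb = lb, ub = ub, cvec = cvec)
  })
}

fba_from_matrices <- function(S, lb, ub, cvec) {
  mets <- sprintf("m%02d", seq_len(nrow(S)))
  obj <- sprintf("r%02d", which(cvec != 0)[1L])
  rxns <- lapply(seq_len(ncol(S)), function(j) {
    st <- S[, j]
    names(st) <- mets
    list(stoichiometry = st[st != 0], lower_bound = lb[j],
         upper_bound = ub[j], reversible = lb[j] < 0,
         gpr = "", subsystem = "toy")
  })
  names(rxns) <- sprintf("r%02d", seq_len(ncol(S)))
  metabolic_model(mets, rxns, obj)
}

# ---- G4 scanning -----------------------------------------------------------

# naive window scanner: per-window mean recomputed from scratch, merging by
# a simple per-position qualifying mask union (no cumulative sums)
naive_g4_scan <- function(seq, window = 25L, threshold = 1.2) {
  s <- base_scores(seq)
  L <- seq$length
  w <- as.integer(window)
  starts <- if (seq$circular) seq_len(L) else seq_len(L - w + 1L)
  res <- list()
  for (sgn in c(1, -1)) {
    qual <- integer(0L)
    for (i in starts) {
      idx <- ((i - 1L + 0:(w - 1L)) %% L) + 1L
      if (sgn * mean(s[idx]) >= threshold) qual <- c(qual, i)
    }
    if (!length(qual)) next
    # union of covered positions in extended coordinates
    grp <- cumsum(c(1L, diff(qual) > w - 1L))
    for (g in unique(grp)) {
      gs <- qual[grp == g]
      res[[length(res) + 1L]] <- data.frame(
        start = min(gs), end = max(gs) + w - 1L,
        strand = if (sgn > 0) "+" else "-")
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0L), end = integer(0L),
                      strand = character(0L)))
  }
  out <- do.call(rbind, res)
  # circular: merge a wrapping last group with the first, per sign
  final <- list()
  for (sgn in c("+", "-")) {
    iv <- out[out$strand == sgn, , drop = FALSE]
    if (!nrow(iv)) next
    if (seq$circular && nrow(iv) > 1L) {
      last <- nrow(iv)
      if (iv$end[last] > L && iv$end[last] - L >= iv$start[1L]) {
        iv$start[1L] <- iv$start[last] - L
        iv <- iv[-last, , drop = FALSE]
      }
    }
    iv$start2 <- ((iv$start - 1L) %% L) + 1L
    iv$end2 <- ((pmin(iv$end, iv$start + L - 1L) - 1L) %% L) + 1L
    final[[length(final) + 1L]] <-
      data.frame(start = iv$start2, end = iv$end2, strand = sgn)
  }
  out <- do.call(rbind, final)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(seed, L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = ""))
}

# do two (possibly wrapping) intervals on a circle of length L intersect?
circ_overlap <- function(s1, e1, s2, e2, L) {
  cover <- function(s, e) {
    if (e >= s) s:e else c(s:L, 1:e)
  }
  length(intersect(cover(s1, e1), cover(s2, e2))) > 0
}
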