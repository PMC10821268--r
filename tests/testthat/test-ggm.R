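make_expr <- function(x, groups = NULL) {
  # x: samples x genes
  m <- t(x)
  m <- m - min(m)   # expression sets are non-negative
  if (is.null(groups)) groups <- rep(c("A", "B"), length.out = ncol(m))
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  expr_set(m, groups)
}

tree_weight <- function(edges, w) {
  sum(vapply(edges, function(e) w[e[1L], e[2L]], numeric(1L)))
}

test_that("the spanning tree maximises total tree weight", {
  # two genes: the only spanning tree is the single edge
  withr::with_seed(1, x2 <- matrix(rnorm(20), 10, 2))
  t2 <- max_likelihood_spanning_tree(make_expr(x2))
  expect_equal(igraph::ecount(t2), 1)

  # three genes: brute force over the three possible spanning trees
  withr::with_seed(2, {
    z <- rnorm(50)
    x3 <- cbind(z + rnorm(50, sd = 0.4),        # A ~ B strongly
                z,
                rnorm(50))                      # C weak
  })
  es <- make_expr(x3)
  got <- max_likelihood_spanning_tree(es)
  lx <- t(log2(es$values + 1))
  w <- -0.5 * log(1 - cor(lx)^2)
  trees <- list(list(c(1, 2), c(2, 3)), list(c(1, 2), c(1, 3)),
                list(c(1, 3), c(2, 3)))
  weights <- vapply(trees, tree_weight, numeric(1L), w = w)
  best <- trees[[which.max(weights)]]
  want <- sort(vapply(best, function(e) {
    paste(sort(rownames(es$values)[e]), collapse = "-")
  }, character(1L)))
  el <- igraph::as_edgelist(got)
  have <- sort(apply(el, 1L, function(e) paste(sort(e), collapse = "-")))
  expect_equal(have, want)

  # a constant gene is reported by name
  xc <- cbind(x3, 0)
  expect_error(max_likelihood_spanning_tree(make_expr(xc)), "g04")
})

test_that("|r| and -log(1 - r^2)/2 give the same spanning tree", {
  withr::with_seed(3, {
    for (trial in 1:10) {
      p <- sample(4:8, 1L)
      x <- matrix(rnorm(30 * p), 30, p) %*%
        matrix(rnorm(p * p, sd = 0.5) + diag(p), p, p)
      es <- make_expr(x)
      got <- max_likelihood_spanning_tree(es)
      r <- abs(cor(t(log2(es$values + 1))))
      g_full <- igraph::graph_from_adjacency_matrix(
        r, mode = "undirected", weighted = TRUE, diag = FALSE)
      mst <- igraph::mst(g_full,
                         weights = -igraph::E(g_full)$weight)
      key <- function(g) sort(apply(igraph::as_edgelist(g), 1L,
                                    function(e) paste(sort(e), collapse = "-")))
      expect_equal(key(got), key(mst))
    }
  })
})

test_that("decomposable log-likelihood matches direct density evaluation", {
  # independence graph: sum of univariate Gaussian log-likelihoods
  withr::with_seed(4, x <- matrix(rnorm(25 * 4), 25, 4))
  es <- make_expr(x)
  lx <- t(log2(es$values + 1))
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  g0 <- igraph::set_vertex_attr(g0, "name", value = rownames(es$values))
  sc <- model_bic(g0, es)
  n <- nrow(lx)
  uni <- sum(vapply(seq_len(4), function(j) {
    s2 <- mean((lx[, j] - mean(lx[, j]))^2)
    -n / 2 * (log(2 * pi) + log(s2) + 1)
  }, numeric(1L)))
  expect_equal(sc$log_likelihood, uni, tolerance = 1e-10)
  expect_equal(sc$bic, -2 * uni + (2 * 4) * log(n))

  # random decomposable graphs on <= 5 vertices vs an IPS oracle
  withr::with_seed(5, {
    for (trial in 1:12) {
      p <- sample(3:5, 1L)
      xr <- matrix(rnorm(30 * p), 30, p)
      esr <- make_expr(xr)
      g <- random_chordal(p, p_extra = 0.7)
      g <- igraph::set_vertex_attr(g, "name",
                                   value = rownames(esr$values))
      sc <- model_bic(g, esr)
      adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
      ll <- ips_loglik(adj, t(log2(esr$values + 1)))
      expect_equal(sc$log_likelihood, ll, tolerance = 1e-8)
    }
  })
})

test_that("adding an edge never decreases the maximised log-likelihood", {
  withr::with_seed(6, x <- matrix(rnorm(40 * 5), 40, 5))
  es <- make_expr(x)
  g <- max_likelihood_spanning_tree(es)
  ll <- model_bic(g, es)$log_likelihood
  for (step in 1:3) {
    ae <- addable_edges(g)
    if (!nrow(ae)) break
    g <- igraph::add_edges(g, c(ae$u[1L], ae$v[1L]))
    ll2 <- model_bic(g, es)$log_likelihood
    expect_gte(ll2, ll - 1e-9)
    ll <- ll2
  }
})

test_that("forward selection stops at a local BIC minimum", {
  # independent genes with many samples: the BIC penalty dominates and
  # (almost) no edge beyond the tree should be added
  added <- vapply(1:20, function(s) {
    withr::with_seed(s, x <- matrix(rnorm(500 * 8), 500, 8))
    es <- make_expr(x)
    tree <- max_likelihood_spanning_tree(es)
    fit <- forward_select_edges(tree, es)
    igraph::ecount(fit$graph) - igraph::ecount(tree)
  }, numeric(1L))
  expect_gte(mean(added == 0), 0.95)

  # BIC is never above the input tree's BIC
  withr::with_seed(77, x <- matrix(rnorm(60 * 6), 60, 6))
  es <- make_expr(x)
  tree <- max_likelihood_spanning_tree(es)
  fit <- forward_select_edges(tree, es)
  expect_lte(fit$score$bic, model_bic(tree, es)$bic + 1e-9)
})

test_that("a dense triple is recovered and matches exhaustive BIC search", {
  withr::with_seed(8, {
    z <- rnorm(500)
    x <- cbind(z + rnorm(500, sd = 0.45),
               z + rnorm(500, sd = 0.45),
               z + rnorm(500, sd = 0.45),
               rnorm(500))                      # D weakly attached
  })
  es <- make_expr(x)
  tree <- max_likelihood_spanning_tree(es)
  fit <- forward_select_edges(tree, es)
  nms <- rownames(es$values)
  adj <- igraph::as_adjacency_matrix(fit$graph, sparse = FALSE) > 0
  expect_true(adj[nms[1L], nms[2L]] && adj[nms[1L], nms[3L]] &&
                adj[nms[2L], nms[3L]])

  # exhaustive search over all connected decomposable graphs on 4 vertices
  best_bic <- Inf
  best_adj <- NULL
  for (cand in enumerate_graphs(4)) {
    if (!connected_adj(cand) || !chordal_mcs(cand)) next
    g <- adj_to_igraph(cand, nms)
    b <- model_bic(g, es)$bic
    if (b < best_bic) {
      best_bic <- b
      best_adj <- cand
    }
  }
  dimnames(adj) <- NULL
  expect_equal(adj, best_adj)
  expect_equal(fit$score$bic, best_bic, tolerance = 1e-8)
})

test_that("branch detection splits at bridges and respects min_size", {
  # two 4-cliques joined by one bridge edge
  adj <- matrix(FALSE, 8, 8)
  adj[1:4, 1:4] <- TRUE
  adj[5:8, 5:8] <- TRUE
  diag(adj) <- FALSE
  adj[4, 5] <- adj[5, 4] <- TRUE
  g <- adj_to_igraph(adj)
  br <- detect_branches(g, min_size = 2)
  expect_equal(length(br), 2L)
  expect_setequal(br[[1L]], letters[1:4])
  expect_setequal(br[[2L]], letters[5:8])

  # modularity check by brute force over all 2-partitions: the bridge cut
  # must be the best one
  memb_best <- NULL
  q_best <- -Inf
  for (mask in 1:(2^8 - 2L)) {
    memb <- as.integer(intToBits(mask)[1:8]) + 1L
    q <- igraph::modularity(g, memb)
    if (q > q_best) {
      q_best <- q
      memb_best <- memb
    }
  }
  expect_equal(as.integer(sort(table(memb_best))), c(4L, 4L))
  expect_equal(length(unique(memb_best[1:4])), 1L)

  # complete graph: a single branch
  k5 <- adj_to_igraph(matrix(TRUE, 5, 5) & !diag(5) > 0)
  expect_equal(length(detect_branches(k5, min_size = 2)), 1L)

  expect_error(detect_branches(k5, min_size = 6), "exceeds")
})

test_that("hypergeometric enrichment reproduces closed-form probabilities", {
  universe <- sprintf("u%02d", 1:20)
  node <- universe[1:5]
  sets <- list(exact = universe[1:5], other = universe[10:14])
  en <- enrich_node(node, sets, universe)
  expect_equal(en$label, "exact")
  # full overlap: P = 1 / C(20, 5)
  expect_equal(en$p_raw, 1 / choose(20, 5), tolerance = 1e-12)

  # node disjoint from all sets: adjusted p = 1 everywhere
  en2 <- enrich_node(universe[15:18], list(s1 = universe[1:5],
                                           s2 = universe[6:9]), universe)
  expect_true(all(en2$table$p_adjusted == 1))

  expect_error(enrich_node(node, list(), universe), "empty")
  expect_error(enrich_node(c(node, "zzz"), sets, universe), "zzz")
})

test_that("node activities are per-sample gene means", {
  m <- rbind(g1 = c(1, 5), g2 = c(3, 7), g3 = c(10, 20))
  colnames(m) <- c("s1", "s2")
  es <- expr_set(m, c("A", "B"))
  act <- node_activity(es, list(n1 = c("g1", "g2"), n2 = "g3"))
  expect_equal(unname(act["n1", ]), c(2, 6))      # mean of 1,3 and 5,7
  expect_equal(unname(act["n2", ]), c(10, 20))    # single-gene node: the row
  expect_error(node_activity(es, list(character(0))), "empty")
  expect_error(node_activity(es, list("nope")), "nope")
})

test_that("Kruskal-Wallis comparisons match the rank-sum formula", {
  # worked example: groups {1,2}, {3,4}, {5,6} -> H = 32/7
  act <- matrix(c(1, 2, 3, 4, 5, 6), 1,
                dimnames = list("n1", sprintf("s%d", 1:6)))
  attr(act, "groups") <- factor(rep(c("A", "B", "C"), each = 2))
  class(act) <- c("node_activity", "matrix")
  cmp <- compare_node_activity(act)
  expect_equal(cmp$H, 32 / 7, tolerance = 1e-12)
  expect_equal(cmp$df, 2)

  # all activities equal -> H = 0
  act0 <- act
  act0[1, ] <- 5
  expect_equal(compare_node_activity(act0)$H, 0)

  # random small inputs (with ties) against the hand formula
  withr::with_seed(10, {
    for (trial in 1:25) {
      y <- sample(1:4, 8, TRUE)                  # heavy ties
      g <- factor(rep(c("A", "B"), each = 4))
      a <- matrix(y, 1, dimnames = list("n", sprintf("s%d", 1:8)))
      attr(a, "groups") <- g
      class(a) <- c("node_activity", "matrix")
      if (length(unique(y)) == 1L) next
      expect_equal(compare_node_activity(a)$H, kw_h_oracle(y, g),
                   tolerance = 1e-12)
    }
  })

  # group size validation
  bad <- act
  attr(bad, "groups") <- factor(c("A", "A", "A", "A", "A", "B"))
  expect_error(compare_node_activity(bad), "fewer than 2")
})
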