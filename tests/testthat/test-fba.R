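chain_model <- function(k = 3, ub = rep(1, k)) {
  # uptake -> M1 -> ... -> Mk -> biomass, all default bounds as given
  mets <- sprintf("M%d", seq_len(k))
  rxns <- list(EX_upt = list(stoichiometry = c(M1 = 1), lower_bound = 0,
                             upper_bound = ub[1L], gpr = "",
                             subsystem = "Exchange"))
  for (j in seq_len(k - 1L)) {
    st <- stats::setNames(c(-1, 1), c(sprintf("M%d", j), sprintf("M%d", j + 1L)))
    rxns[[sprintf("R%d", j)]] <- list(stoichiometry = st, lower_bound = 0,
                                      upper_bound = ub[j + 1L], gpr = "",
                                      subsystem = "OXPHOS")
  }
  rxns$biomass <- list(stoichiometry = stats::setNames(-1, sprintf("M%d", k)),
                       lower_bound = 0, upper_bound = 1000,
                       gpr = "", subsystem = "Biomass")
  metabolic_model(mets, rxns, "biomass")
}

test_that("model construction validates structure", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_error(metabolic_model("A", list(r1 = list(stoichiometry = c(B = 1))),
                               "r1"), "undeclared metabolite")
  expect_error(metabolic_model("A", list(r1 = list(stoichiometry = c(A = 1),
                                                   lower_bound = 2,
                                                   upper_bound = 1)), "r1"),
               "lower_bound")
  expect_error(metabolic_model("A", list(r1 = list(stoichiometry = c(A = 1))),
                               "nope"), "objective")
  expect_error(metabolic_model("A", list(r1 = list(stoichiometry = c(A = 1),
                                                   gpr = "(X and")), "r1"),
               "r1")
})

test_that("FBA solves worked examples and reports failures as status", {
  expect_equal(run_fba(chain_model(3))$objective_value, 1, tolerance = 1e-9)

  # two parallel capacity-1 paths
  mets <- c("A", "B", "T")
  rxns <- list(
    up1 = list(stoichiometry = c(A = 1), upper_bound = 1),
    up2 = list(stoichiometry = c(B = 1), upper_bound = 1),
    pa = list(stoichiometry = c(A = -1, T = 1), upper_bound = 1),
    pb = list(stoichiometry = c(B = -1, T = 1), upper_bound = 1),
    biomass = list(stoichiometry = c(T = -1), upper_bound = 1000))
  par2 <- metabolic_model(mets, rxns, "biomass")
  expect_equal(run_fba(par2)$objective_value, 2, tolerance = 1e-9)

  # closed uptakes: zero optimum, still optimal status
  closed <- chain_model(3, ub = c(0, 1, 1))
  sol0 <- run_fba(closed)
  expect_equal(sol0$status, "optimal")
  expect_equal(sol0$objective_value, 0)

  # an infeasible model (forced flux into a dead end) is reported, not zeroed
  bad <- metabolic_model("A",
                         list(up = list(stoichiometry = c(A = 1),
                                        lower_bound = 0.5, upper_bound = 1)),
                         "up")
  expect_equal(run_fba(bad)$status, "infeasible")
})

test_that("optimal solutions satisfy mass balance and bounds", {
  for (seed in 1:10) {
    prob <- random_toy_fba(seed)
    model <- fba_from_matrices(prob$S, prob$lb, prob$ub, prob$cvec)
    sol <- run_fba(model)
    expect_equal(sol$status, "optimal")
    expect_lt(max(abs(prob$S %*% sol$flux)), 1e-6)
    expect_true(all(sol$flux >= prob$lb - 1e-8))
    expect_true(all(sol$flux <= prob$ub + 1e-8))
  }
})

test_that("FBA optima equal the vertex-enumeration oracle", {
  for (seed in 1:25) {
    prob <- random_toy_fba(seed, n_rxn = sample(3:6, 1L))
    model <- fba_from_matrices(prob$S, prob$lb, prob$ub, prob$cvec)
    sol <- run_fba(model)
    oracle <- vertex_enum_fba(prob$S, prob$lb, prob$ub, prob$cvec)
    expect_equal(sol$objective_value, oracle, tolerance = 1e-8)
  }
})

test_that("tightening a bound never increases the optimum", {
  withr::with_seed(17, {
    for (trial in 1:10) {
      prob <- random_toy_fba(trial + 100)
      model <- fba_from_matrices(prob$S, prob$lb, prob$ub, prob$cvec)
      base <- run_fba(model)$objective_value
      j <- sample.int(length(prob$ub), 1L)
      ub2 <- prob$ub
      ub2[j] <- ub2[j] * stats::runif(1)
      tighter <- fba_from_matrices(prob$S, prob$lb, ub2, prob$cvec)
      sol2 <- run_fba(tighter)
      if (sol2$status == "optimal") expect_lte(sol2$objective_value,
                                               base + 1e-8)
    }
  })
})

test_that("max-min normalisation maps scores onto [0, 1]", {
  expect_equal(unname(normalize_scores(c(a = 0, b = 10))), c(0, 1))
  expect_equal(unname(normalize_scores(c(a = 2, b = 4, c = 6))),
               c(0, 0.5, 1))
  # degenerate: uniform expression leaves the network open
  expect_equal(unname(normalize_scores(c(a = 3, b = 3))), c(1, 1))
  # absent scores pass through
  out <- normalize_scores(c(a = 2, b = NA, c = 6))
  expect_true(is.na(out["b"]))
  expect_equal(unname(out[c("a", "c")]), c(0, 1))
  expect_error(normalize_scores(c(a = NA_real_)), "no resolvable")
})

test_that("E-flux bounds scale with scores and leave the input untouched", {
  m <- chain_model(3)
  sc <- stats::setNames(rep(NA_real_, length(m$rxns)), m$rxns)

  sc["R1"] <- 0
  closed <- apply_eflux_bounds(m, sc)
  expect_equal(run_fba(closed)$objective_value, 0)
  expect_equal(m$ub[m$rxns == "R1"], 1)   # original model unchanged

  sc["R1"] <- 1
  expect_equal(apply_eflux_bounds(m, sc)$ub, m$ub)

  sc["R1"] <- 0.5
  half <- apply_eflux_bounds(m, sc)
  expect_equal(run_fba(half)$objective_value, 0.5, tolerance = 1e-9)

  # reversible reactions get a mirrored lower bound
  mets <- c("A", "B")
  rxns <- list(up = list(stoichiometry = c(A = 1), upper_bound = 1),
               rev = list(stoichiometry = c(A = -1, B = 1),
                          lower_bound = -2, upper_bound = 2,
                          reversible = TRUE),
               out = list(stoichiometry = c(B = -1), upper_bound = 1000))
  mr <- metabolic_model(mets, rxns, "out")
  b <- apply_eflux_bounds(mr, c(up = NA, rev = 0.25, out = NA))
  expect_equal(b$ub[b$rxns == "rev"], 0.5)
  expect_equal(b$lb[b$rxns == "rev"], -0.5)
})

test_that("pathway activities sum |v| per subsystem", {
  m <- chain_model(4)                     # three OXPHOS reactions
  sol <- run_fba(m)
  act <- pathway_flux_activity(sol, m)
  expect_equal(unname(act["OXPHOS"]), 3)  # chain flux 1 x 3 reactions
  expect_equal(unname(act["Biomass"]), 1)

  closed <- chain_model(4, ub = c(0, 1, 1, 1))
  act0 <- pathway_flux_activity(run_fba(closed), closed)
  expect_true(all(act0 == 0))

  # signed vs absolute on a reversible cycle
  mets <- c("A", "B")
  rxns <- list(f = list(stoichiometry = c(A = -1, B = 1), lower_bound = -1,
                        upper_bound = 1, subsystem = "P"),
               g = list(stoichiometry = c(B = -1, A = 1), lower_bound = -1,
                        upper_bound = 1, subsystem = "P"),
               dummy = list(stoichiometry = c(), upper_bound = 1,
                            subsystem = "Q"))
  mcyc <- metabolic_model(mets, rxns, "dummy")
  sol <- run_fba(mcyc)
  expect_equal(pathway_flux_activity(sol, mcyc, signed = TRUE)[["P"]],
               sum(sol$flux[c("f", "g")]))
  expect_equal(pathway_flux_activity(sol, mcyc)[["P"]],
               sum(abs(sol$flux[c("f", "g")])))
})

test_that("parsimonious FBA removes gratuitous cycles", {
  mets <- c("A", "B")
  rxns <- list(up = list(stoichiometry = c(A = 1), upper_bound = 1),
               conv = list(stoichiometry = c(A = -1, B = 1), upper_bound = 5),
               loop1 = list(stoichiometry = c(A = -1, B = 1),
                            lower_bound = -5, upper_bound = 5),
               biomass = list(stoichiometry = c(B = -1), upper_bound = 1000))
  m <- metabolic_model(mets, rxns, "biomass")
  sol <- run_fba(m, parsimonious = TRUE)
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  # total |v| is minimal: 1 (uptake) + 1 (one conversion) + 1 (biomass)
  expect_equal(sum(abs(sol$flux)), 3, tolerance = 1e-8)
})

test_that("delta is treated minus control with key checking", {
  expect_equal(delta_flux_activity(c(P = 1, Q = 2), c(P = 1, Q = 2)),
               c(P = 0, Q = 0))
  expect_equal(delta_flux_activity(c(P = 1.5), c(P = 2)), c(P = -0.5))
  expect_error(delta_flux_activity(c(P = 1), c(P = 1, Q = 2)), "Q")
})

test_that("condition_pipeline is deterministic and scale-invariant", {
  tm <- simulate_toy_model(seed = 31, n_linear_chain = 4, with_branch = TRUE)
  sim <- simulate_expression(sim_config(seed = 31, n_per_group = c(
    Control = 4, Treated = 4, TreatedInactive = 4)))

  res <- condition_pipeline(tm$model, sim$expr)
  expect_s3_class(res, "pathway_activity_table")
  expect_equal(colnames(res$delta), c("Treated", "TreatedInactive"))

  # identical samples give identical per-sample activity vectors
  vals <- sim$expr$values
  vals[] <- vals[, 1L]
  same <- expr_set(vals, sim$expr$groups)
  res_same <- condition_pipeline(tm$model, same)
  expect_true(all(apply(res_same$per_sample_activity, 1L,
                        function(r) max(r) - min(r)) < 1e-12))

  # global rescaling of expression leaves activities unchanged
  scaled <- expr_set(sim$expr$values * 7.5, sim$expr$groups)
  res_scaled <- condition_pipeline(tm$model, scaled)
  expect_equal(res_scaled$activity, res$activity, tolerance = 1e-9)
  expect_equal(res_scaled$delta, res$delta, tolerance = 1e-9)
})

test_that("model JSON round-trips through read/write", {
  tm <- simulate_toy_model(seed = 41, n_linear_chain = 3, with_branch = TRUE)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model(tm$model, tmp)
  back <- read_model(tmp)
  expect_equal(back$mets, tm$model$mets)
  expect_equal(back$S, tm$model$S)
  expect_equal(back$lb, tm$model$lb)
  expect_equal(back$ub, tm$model$ub)
  expect_equal(back$gpr, tm$model$gpr)
  expect_equal(back$subsystem, tm$model$subsystem)
  expect_equal(back$objective, tm$model$objective)

  # malformed GPR fails at load naming the reaction
  doc <- jsonlite::read_json(tmp)
  doc$reactions[[2L]]$gpr <- "(A and"
  tmp2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, tmp2, auto_unbox = TRUE)
  expect_error(read_model(tmp2), doc$reactions[[2L]]$id)

  doc$objective <- NULL
  jsonlite::write_json(doc, tmp2, auto_unbox = TRUE)
  expect_error(read_model(tmp2), "objective")
})
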