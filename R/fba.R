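#' Construct a metabolic model
#'
#' A stoichiometric network with reaction bounds, boolean gene-protein-
#' reaction rules and subsystem (pathway) labels, plus a designated
#' objective (biomass) reaction.
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions named list; each element describes one reaction with
#'   fields `stoichiometry` (named numeric, metabolite -> coefficient,
#'   negative = consumed), `lower_bound`, `upper_bound`, `reversible`
#'   (flag, defaults to `lower_bound < 0`), `gpr` (rule string, may be
#'   empty) and `subsystem`.
#' @param objective id of the objective reaction.
#' @return An object of class `metabolic_model` with elements `mets`,
#'   `rxns`, `S` (metabolite x reaction matrix), `lb`, `ub`, `reversible`,
#'   `gpr`, `subsystem`, `objective`.
#' @export
metabolic_model <- function(metabolites, reactions, objective) {
  metabolites <- as.character(metabolites)
  if (anyDuplicated(metabolites)) stopf("duplicate metabolite ids")
  rxn_ids <- names(reactions)
  if (is.null(rxn_ids) || anyDuplicated(rxn_ids) || any(!nzchar(rxn_ids))) {
    stopf("reactions must be uniquely named")
  }
  nr <- length(reactions)
  S <- matrix(0, length(metabolites), nr,
              dimnames = list(metabolites, rxn_ids))
  lb <- ub <- numeric(nr)
  rev <- logical(nr)
  gpr <- sub <- character(nr)
  for (j in seq_len(nr)) {
    r <- reactions[[j]]
    st <- r$stoichiometry %||% numeric(0L)
    if (length(st)) {
      unknown <- setdiff(names(st), metabolites)
      if (length(unknown)) {
        stopf("reaction '%s' references undeclared metabolite '%s'",
              rxn_ids[j], unknown[1L])
      }
      S[names(st), j] <- st
    }
    lb[j] <- r$lower_bound %||% 0
    ub[j] <- r$upper_bound %||% 1000
    if (lb[j] > ub[j]) {
      stopf("reaction '%s': lower_bound (%g) exceeds upper_bound (%g)",
            rxn_ids[j], lb[j], ub[j])
    }
    rev[j] <- isTRUE(r$reversible %||% (lb[j] < 0))
    gpr[j] <- r$gpr %||% ""
    sub[j] <- r$subsystem %||% "Unassigned"
  }
  if (!objective %in% rxn_ids) {
    stopf("objective reaction '%s' not found in the model", objective)
  }
  # fail fast on malformed rules
  for (j in which(nzchar(gpr))) {
    tryCatch(parse_gpr(gpr[j]),
             error = function(e) stopf("reaction '%s': %s", rxn_ids[j],
                                       conditionMessage(e)))
  }
  structure(list(mets = metabolites, rxns = rxn_ids, S = S, lb = lb, ub = ub,
                 reversible = rev, gpr = gpr, subsystem = sub,
                 objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "metabolic_model: %d metabolites, %d reactions, objective '%s'\n",
    length(x$mets), length(x$rxns), x$objective))
  cat("subsystems:", paste(unique(x$subsystem), collapse = ", "), "\n")
  invisible(x)
}

#' Expression scores for every reaction of a model
#'
#' Resolves each reaction's GPR (OR = sum, AND = min) against one sample's
#' expression values. Reactions without a rule, or whose rule has no
#' resolvable gene, score `NA` ("absent") and later keep their default
#' bounds.
#'
#' @param model a [metabolic_model].
#' @param gene_expression named numeric vector for one sample.
#' @inheritParams resolve_gpr
#' @return Named numeric vector (reaction -> score, `NA` = absent).
#' @export
reaction_scores <- function(model, gene_expression,
                            missing = c("identity", "error")) {
  stopifnot(inherits(model, "metabolic_model"))
  missing <- match.arg(missing)
  out <- rep(NA_real_, length(model$rxns))
  names(out) <- model$rxns
  for (j in which(nzchar(model$gpr))) {
    out[j] <- resolve_gpr(parse_gpr(model$gpr[j]), gene_expression,
                          missing = missing)
  }
  out
}

#' Max-min normalisation of reaction scores to [0, 1]
#'
#' Linear map `(x - min) / (max - min)` over the resolvable (non-`NA`)
#' scores; `NA` entries pass through. When all scores are equal the map is
#' degenerate and every score becomes 1 (uniform expression should leave
#' the network open, not close it).
#'
#' @param scores named numeric vector from [reaction_scores()].
#' @return Normalised scores in `[0, 1]` with `NA`s preserved.
#' @export
normalize_scores <- function(scores) {
  ok <- !is.na(scores)
  if (!any(ok)) stopf("no resolvable score to normalise")
  lo <- min(scores[ok])
  hi <- max(scores[ok])
  out <- scores
  if (hi - lo <= 0) {
    out[ok] <- 1
  } else {
    out[ok] <- (scores[ok] - lo) / (hi - lo)
  }
  out
}

#' Constrain reaction bounds by normalised expression scores (E-flux)
#'
#' For a reaction with score `s`, the upper bound becomes `s * ub` and, if
#' the reaction is reversible, the lower bound becomes `-s * |lb|`.
#' Reactions with an absent (`NA`) score keep their default bounds. The
#' input model is not modified; a bounded copy is returned.
#'
#' @param model a [metabolic_model].
#' @param normalized named score vector in `[0, 1]` (NAs allowed).
#' @return A new `metabolic_model` with tightened bounds.
#' @export
apply_eflux_bounds <- function(model, normalized) {
  stopifnot(inherits(model, "metabolic_model"))
  normalized <- normalized[model$rxns]
  ok <- !is.na(normalized)
  if (any(normalized[ok] < -LP_TOL | normalized[ok] > 1 + LP_TOL)) {
    stopf("normalised scores must lie in [0, 1]")
  }
  out <- model
  out$ub[ok] <- normalized[ok] * model$ub[ok]
  idx <- ok & model$reversible
  out$lb[idx] <- -normalized[idx] * abs(model$lb[idx])
  out
}

#' Flux balance analysis
#'
#' Maximises flux through the model's objective reaction subject to
#' steady-state mass balance `S v = 0` and the reaction bounds, by linear
#' programming. Infeasibility and unboundedness are reported in `status`,
#' never as silent zeros.
#'
#' Optimal flux distributions are generally non-unique; with
#' `parsimonious = TRUE` a second LP minimises total absolute flux at the
#' optimal objective value, which makes the reported distribution
#' deterministic in the usual parsimonious-FBA sense.
#'
#' @param model a [metabolic_model].
#' @param parsimonious minimise total `sum(|v|)` at the optimum.
#' @return An object of class `flux_solution`: list with `flux` (named
#'   vector), `objective_value` and `status` (`"optimal"`, `"infeasible"`
#'   or `"unbounded"`).
#' @export
run_fba <- function(model, parsimonious = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  nr <- length(model$rxns)
  cvec <- as.numeric(model$rxns == model$objective)
  sol <- lp_solve_max(cvec, model$S, rep(0, length(model$mets)),
                      model$lb, model$ub)
  if (sol$status != "optimal") {
    return(structure(list(flux = stats::setNames(rep(NA_real_, nr),
                                                 model$rxns),
                          objective_value = NA_real_, status = sol$status),
                     class = "flux_solution"))
  }
  flux <- sol$x
  if (parsimonious) {
    # split v = p - q, p,q >= 0; minimise sum(p + q) at fixed optimum
    S2 <- cbind(model$S, -model$S)
    S2 <- rbind(S2, c(cvec, -cvec))             # pin the objective value
    beq <- c(rep(0, length(model$mets)), sol$value)
    lb2 <- rep(0, 2L * nr)
    ub2 <- c(pmax(model$ub, 0), pmax(-model$lb, 0))
    sol2 <- lp_solve_max(rep(-1, 2L * nr), S2, beq, lb2, ub2)
    if (sol2$status == "optimal") {
      flux <- sol2$x[seq_len(nr)] - sol2$x[nr + seq_len(nr)]
    }
  }
  names(flux) <- model$rxns
  imbalance <- max(abs(model$S %*% flux))
  if (imbalance > 1e-6) {
    stopf("FBA solution violates mass balance (max |S v| = %g)", imbalance)
  }
  structure(list(flux = flux, objective_value = sol$value,
                 status = "optimal"),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: status %s, objective %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Per-pathway flux activity
#'
#' Sums fluxes of the reactions sharing a subsystem label. By default the
#' absolute value `sum(|v|)` is used so that opposing reversible fluxes in
#' one pathway do not cancel; `signed = TRUE` restores the literal signed
#' sum. Pathways with no active reaction report 0.
#'
#' @param solution an optimal [run_fba()] result.
#' @param model the matching [metabolic_model].
#' @param signed use the signed sum instead of `sum(|v|)`.
#' @return Named numeric vector, pathway -> activity.
#' @export
pathway_flux_activity <- function(solution, model, signed = FALSE) {
  stopifnot(inherits(solution, "flux_solution"),
            inherits(model, "metabolic_model"))
  if (solution$status != "optimal") {
    stopf("pathway activities require an optimal solution (status: %s)",
          solution$status)
  }
  v <- solution$flux[model$rxns]
  contrib <- if (signed) v else abs(v)
  subs <- sort(unique(model$subsystem))
  vapply(stats::setNames(subs, subs),
         function(s) sum(contrib[model$subsystem == s]), numeric(1L))
}

#' Treated-minus-control pathway deltas
#'
#' `delta = treated - control`, so a pathway whose flux activity drops
#' under treatment has a negative delta.
#'
#' @param treated,control named activity vectors over the same pathways.
#' @return Named numeric vector of deltas.
#' @export
delta_flux_activity <- function(treated, control) {
  missing_t <- setdiff(names(control), names(treated))
  missing_c <- setdiff(names(treated), names(control))
  if (length(missing_t) || length(missing_c)) {
    stopf("pathway keys differ: missing in treated [%s]; missing in control [%s]",
          paste(missing_t, collapse = ", "),
          paste(missing_c, collapse = ", "))
  }
  treated - control[names(treated)]
}

#' Expression-constrained FBA across conditions
#'
#' The full E-flux pipeline: for every sample, resolve GPRs against its
#' expression values, max-min normalise the scores, tighten the reaction
#' bounds, solve the biomass LP and sum per-pathway flux activities. Per
#' condition, activities are averaged across its samples; each non-control
#' condition gets a `treated - control` delta per pathway.
#'
#' @param model a [metabolic_model].
#' @param expr an [expr_set]; gene ids should overlap the GPR gene ids
#'   (partial overlap is allowed, see [resolve_gpr()]).
#' @param control label of the reference condition.
#' @param per_sample run one FBA per sample (default) and average
#'   activities; `FALSE` averages expression within a condition first and
#'   runs a single FBA per condition.
#' @param signed,parsimonious passed to [pathway_flux_activity()] and
#'   [run_fba()].
#' @inheritParams resolve_gpr
#' @return List of class `pathway_activity_table` with `activity` (pathway
#'   x condition matrix), `delta` (pathway x non-control-condition matrix)
#'   and `per_sample_activity`.
#' @export
condition_pipeline <- function(model, expr, control = "Control",
                               per_sample = TRUE, signed = FALSE,
                               parsimonious = FALSE,
                               missing = c("identity", "error")) {
  stopifnot(inherits(model, "metabolic_model"), inherits(expr, "expr_set"))
  missing <- match.arg(missing)
  groups <- expr$groups
  if (!control %in% levels(groups)) {
    stopf("control condition '%s' has no samples", control)
  }
  if (any(table(groups) == 0L)) {
    empty <- names(which(table(groups) == 0L))
    stopf("condition '%s' has no samples", empty[1L])
  }

  one_run <- function(values, label) {
    sc <- normalize_scores(reaction_scores(model, values, missing = missing))
    bounded <- apply_eflux_bounds(model, sc)
    sol <- run_fba(bounded, parsimonious = parsimonious)
    if (sol$status != "optimal") {
      stopf("FBA not optimal for %s (status: %s)", label, sol$status)
    }
    pathway_flux_activity(sol, bounded, signed = signed)
  }

  conds <- levels(groups)
  per_sample_act <- NULL
  if (per_sample) {
    samples <- colnames(expr$values)
    per_sample_act <- vapply(
      samples,
      function(s) one_run(expr$values[, s], paste("sample", s)),
      numeric(length(unique(model$subsystem))))
    activity <- vapply(
      conds,
      function(g) rowMeans(per_sample_act[, groups == g, drop = FALSE]),
      numeric(nrow(per_sample_act)))
  } else {
    activity <- vapply(
      conds,
      function(g) one_run(rowMeans(expr$values[, groups == g, drop = FALSE]),
                          paste("condition", g)),
      numeric(length(unique(model$subsystem))))
  }
  treated_conds <- setdiff(conds, control)
  delta <- vapply(treated_conds,
                  function(g) delta_flux_activity(activity[, g],
                                                  activity[, control]),
                  numeric(nrow(activity)))
  if (is.null(dim(delta))) {
    delta <- matrix(delta, ncol = length(treated_conds),
                    dimnames = list(rownames(activity), treated_conds))
  }
  structure(list(activity = activity, delta = delta,
                 per_sample_activity = per_sample_act, control = control),
            class = "pathway_activity_table")
}

#' @export
print.pathway_activity_table <- function(x, ...) {
  cat("pathway_activity_table\n")
  cat("activity:\n")
  print(round(x$activity, 4))
  cat("delta (vs ", x$control, "):\n", sep = "")
  print(round(x$delta, 4))
  invisible(x)
}
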