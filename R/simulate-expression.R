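#' Configuration for the synthetic expression generator
#'
#' Describes a grouped FPKM-like dataset with correlated gene modules and a
#' block of mtDNA-encoded genes that is down-regulated in the treated group.
#' Defaults mirror a three-arm design (vehicle control, an active compound,
#' and an inactive analogue that behaves like control) with 20 replicates
#' per arm, eleven gene modules of ten genes each, and a halving of the
#' mitochondrial block under treatment.
#'
#' @param seed integer seed; all randomness of [simulate_expression()] flows
#'   from it.
#' @param n_per_group named integer vector of samples per condition.
#' @param n_genes total number of genes.
#' @param module_sizes integer vector of module sizes; `sum(module_sizes)`
#'   must not exceed `n_genes`.
#' @param n_modules number of modules; must equal `length(module_sizes)`.
#' @param within_module_correlation latent-scale correlation of gene pairs
#'   within a module, in `[0, 1)`.
#' @param mt_block_size number of genes tagged mtDNA-encoded; they occupy
#'   the first positions of the last module and must fit inside it.
#' @param mt_downregulation_factor multiplier in `(0, 1]` applied to the
#'   expected abundance of mt genes in the `affected_group`.
#' @param noise_sd standard deviation (> 0) of the latent log-scale signal.
#' @param affected_group label of the condition receiving the mt
#'   down-regulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = c(Control = 20L, Treated = 20L,
                                       TreatedInactive = 20L),
                       n_genes = 110L,
                       module_sizes = rep(10L, 11L),
                       n_modules = length(module_sizes),
                       within_module_correlation = 0.7,
                       mt_block_size = 10L,
                       mt_downregulation_factor = 0.5,
                       noise_sd = 1,
                       affected_group = "Treated") {
  if (!is_count(seed, min = -.Machine$integer.max)) {
    stopf("invalid 'seed': must be a single integer")
  }
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stopf("invalid 'n_per_group': must be named by condition label")
  }
  if (!all(vapply(n_per_group, is_count, logical(1L)))) {
    stopf("invalid 'n_per_group': all counts must be integers >= 1")
  }
  if (!is_count(n_genes)) stopf("invalid 'n_genes': must be an integer >= 1")
  if (!length(module_sizes) || !all(vapply(module_sizes, is_count, logical(1L)))) {
    stopf("invalid 'module_sizes': all sizes must be integers >= 1")
  }
  if (sum(module_sizes) > n_genes) {
    stopf("invalid 'module_sizes': sum (%d) exceeds n_genes (%d)",
          sum(module_sizes), n_genes)
  }
  if (!is_count(n_modules) || n_modules != length(module_sizes)) {
    stopf("invalid 'n_modules': must equal length(module_sizes)")
  }
  if (!is_prob(within_module_correlation) || within_module_correlation >= 1) {
    stopf("invalid 'within_module_correlation': must lie in [0, 1)")
  }
  if (!is_count(mt_block_size, min = 0L)) {
    stopf("invalid 'mt_block_size': must be an integer >= 0")
  }
  if (mt_block_size > module_sizes[length(module_sizes)]) {
    stopf("invalid 'mt_block_size': exceeds the last module size (%d)",
          module_sizes[length(module_sizes)])
  }
  if (!is.numeric(mt_downregulation_factor) ||
      length(mt_downregulation_factor) != 1L ||
      is.na(mt_downregulation_factor) ||
      mt_downregulation_factor <= 0 || mt_downregulation_factor > 1) {
    stopf("invalid 'mt_downregulation_factor': must lie in (0, 1]")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd <= 0) {
    stopf("invalid 'noise_sd': must be > 0")
  }
  if (mt_block_size > 0L && !affected_group %in% names(n_per_group)) {
    stopf("invalid 'affected_group': '%s' not among condition labels",
          affected_group)
  }
  structure(list(seed = as.integer(seed),
                 n_per_group = vapply(n_per_group, as.integer, integer(1L)),
                 n_genes = as.integer(n_genes),
                 module_sizes = as.integer(module_sizes),
                 n_modules = as.integer(n_modules),
                 within_module_correlation = within_module_correlation,
                 mt_block_size = as.integer(mt_block_size),
                 mt_downregulation_factor = mt_downregulation_factor,
                 noise_sd = noise_sd,
                 affected_group = affected_group),
            class = "sim_config")
}

#' Simulate a grouped expression matrix with correlated modules
#'
#' Generates log-normal FPKM-like abundances on a module-structured Gaussian
#' latent: genes of module `m` share a common factor so that every within-
#' module pair has latent correlation `within_module_correlation`
#' (equicorrelated blocks); genes outside modules are independent. Gene
#' baselines are drawn once from a log-normal so abundances span realistic
#' orders of magnitude. In the affected group the mtDNA-encoded block is
#' multiplied by `mt_downregulation_factor`, so its expectation is exactly
#' that multiple of the control expectation; all other groups (including the
#' inactive-analogue arm) are drawn from the control distribution.
#'
#' mtDNA-encoded genes are named `MT-G01`, `MT-G02`, ... and occupy the
#' first positions of the last module; remaining genes are `G0001`, ...
#'
#' @param config a [sim_config].
#' @return A list with elements
#'   * `expr`: an [expr_set];
#'   * `truth`: list with `module_membership` (named integer vector, 0 for
#'     genes outside any module) and `mt_genes` (character vector).
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_per_group = c(
#'   Control = 3, Treated = 3, TreatedInactive = 3)))
#' sim$expr
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_genes
  sizes <- config$module_sizes
  k <- config$n_modules
  rho <- config$within_module_correlation
  sd0 <- config$noise_sd

  membership <- integer(p)
  idx <- 1L
  for (m in seq_len(k)) {
    membership[idx:(idx + sizes[m] - 1L)] <- m
    idx <- idx + sizes[m]
  }

  # mt block sits at the head of the last module
  mt_pos <- integer(0L)
  if (config$mt_block_size > 0L) {
    last_start <- sum(sizes[-k]) + 1L
    mt_pos <- last_start:(last_start + config$mt_block_size - 1L)
  }
  gene_ids <- sprintf("G%04d", seq_len(p))
  if (length(mt_pos)) gene_ids[mt_pos] <- sprintf("MT-G%02d", seq_along(mt_pos))
  names(membership) <- gene_ids

  groups <- rep(names(config$n_per_group), config$n_per_group)
  n_tot <- length(groups)
  sample_ids <- sprintf("%s_%02d", groups,
                        unlist(lapply(config$n_per_group, seq_len),
                               use.names = FALSE))

  vals <- with_seed(config$seed, {
    baseline <- rnorm(p, mean = log(20), sd = 1.25)   # FPKM-scale spread
    z <- matrix(rnorm(p * n_tot), p, n_tot)
    if (rho > 0) {
      fac <- matrix(rnorm(k * n_tot), k, n_tot)
      inmod <- membership > 0L
      z[inmod, ] <- sqrt(rho) * fac[membership[inmod], , drop = FALSE] +
        sqrt(1 - rho) * z[inmod, , drop = FALSE]
    }
    v <- exp(baseline + sd0 * z)
    if (length(mt_pos)) {
      aff <- groups == config$affected_group
      v[mt_pos, aff] <- v[mt_pos, aff] * config$mt_downregulation_factor
    }
    v
  })
  dimnames(vals) <- list(gene_ids, sample_ids)

  list(expr = expr_set(vals, stats::setNames(groups, sample_ids)),
       truth = list(module_membership = membership,
                    mt_genes = gene_ids[mt_pos]))
}
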