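#' Generate a small feasible metabolic network with GPRs
#'
#' Builds a desk-scale network with a known biomass optimum: an uptake
#' reaction feeds a linear chain of internal conversions labelled "OXPHOS"
#' that drains into biomass; optionally a parallel capacity-1 branch
#' ("Glycolysis") also feeds biomass. Two decoupled anchor pathways
#' ("Other") carry extreme rules — an `and` over many genes (a reliably
#' low minimum) and an `or` over many genes (a reliably high sum) — so
#' that max-min score normalisation has stable extremes and the OXPHOS
#' scores land in the interior of [0, 1].
#'
#' Every internal reaction carries a GPR string and a subsystem label.
#' Chain GPRs are `or`-pairs drawn from the mtDNA-encoded gene pool, so
#' down-regulating those genes tightens the OXPHOS bounds under E-flux.
#'
#' @param seed integer seed controlling gene assignment to rules.
#' @param n_linear_chain number of metabolites in the chain (>= 2).
#' @param with_branch add the parallel capacity-1 branch.
#' @param uptake_bound upper bound of the uptake reaction(s).
#' @param mt_genes gene pool for the OXPHOS rules (defaults to the ids
#'   used by [simulate_expression()]).
#' @param nuclear_genes gene pool for non-OXPHOS rules.
#' @return A list with `model` (a [metabolic_model]) and `truth` (list
#'   with `toy_lp_optimum`, the analytically known biomass optimum).
#' @examples
#' tm <- simulate_toy_model(seed = 1, n_linear_chain = 3)
#' tm$truth$toy_lp_optimum
#' @export
simulate_toy_model <- function(seed = 1L, n_linear_chain = 3L,
                               with_branch = FALSE, uptake_bound = 1,
                               mt_genes = sprintf("MT-G%02d", 1:10),
                               nuclear_genes = sprintf("G%04d", 1:100)) {
  if (!is_count(n_linear_chain, min = 2L)) {
    stopf("'n_linear_chain' must be an integer >= 2")
  }
  if (!is.numeric(uptake_bound) || uptake_bound < 0) {
    stopf("'uptake_bound' must be >= 0")
  }
  k <- as.integer(n_linear_chain)

  with_seed(seed, {
    mets <- c(sprintf("M%02d", seq_len(k)), "DL", "DH",
              if (with_branch) "B1")
    rxns <- list()
    rxns[["EX_upt"]] <- list(stoichiometry = c(M01 = 1),
                             lower_bound = 0, upper_bound = uptake_bound,
                             gpr = "", subsystem = "Exchange")
    pick <- function(pool, n) sample(pool, n)
    for (j in seq_len(k - 1L)) {
      pair <- pick(mt_genes, 2L)
      st <- stats::setNames(c(-1, 1),
                            c(sprintf("M%02d", j), sprintf("M%02d", j + 1L)))
      rxns[[sprintf("R_chain_%02d", j)]] <- list(
        stoichiometry = st, lower_bound = 0, upper_bound = 1,
        gpr = paste(pair, collapse = " or "), subsystem = "OXPHOS")
    }
    if (with_branch) {
      rxns[["EX_upt2"]] <- list(stoichiometry = c(B1 = 1),
                                lower_bound = 0, upper_bound = uptake_bound,
                                gpr = "", subsystem = "Exchange")
      pair <- pick(nuclear_genes, 2L)
      rxns[["R_branch"]] <- list(
        stoichiometry = stats::setNames(c(-1, 1),
                                        c("B1", sprintf("M%02d", k))),
        lower_bound = 0, upper_bound = 1,
        gpr = paste(pair, collapse = " or "), subsystem = "Glycolysis")
    }
    # anchor pathways: a min-of-5 rule (reliably low score) and an
    # or-of-20 rule (reliably high), decoupled from biomass
    rxns[["EX_low"]] <- list(stoichiometry = c(DL = 1), lower_bound = 0,
                             upper_bound = 1, gpr = "", subsystem = "Exchange")
    rxns[["R_low"]] <- list(
      stoichiometry = c(DL = -1), lower_bound = 0, upper_bound = 1,
      gpr = paste(pick(nuclear_genes, min(15L, length(nuclear_genes))),
                  collapse = " and "),
      subsystem = "Other")
    rxns[["EX_high"]] <- list(stoichiometry = c(DH = 1), lower_bound = 0,
                              upper_bound = 1, gpr = "", subsystem = "Exchange")
    rxns[["R_high"]] <- list(
      stoichiometry = c(DH = -1), lower_bound = 0, upper_bound = 1,
      gpr = paste(pick(nuclear_genes, min(40L, length(nuclear_genes))),
                  collapse = " or "),
      subsystem = "Other")
    rxns[["biomass"]] <- list(
      stoichiometry = stats::setNames(-1, sprintf("M%02d", k)),
      lower_bound = 0, upper_bound = 1000, gpr = "", subsystem = "Biomass")

    model <- metabolic_model(mets, rxns, "biomass")
    # analytic optimum: chain is capped by its tightest bound, the branch
    # (when present) adds its own capacity
    chain_cap <- min(uptake_bound, 1)
    opt <- chain_cap + if (with_branch) min(uptake_bound, 1) else 0
    list(model = model,
         truth = list(toy_lp_optimum = opt))
  })
}
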