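# shared fixtures: tiny metabolic models, random LP generator, and
# independent oracles used across the suite

# linear chain: glucose uptake (lb -10) -> transport -> biomass consumes
# glucose; mass balance forces v_biomass = uptake
chain_model <- function(uptake = 10) {
  mets <- data.frame(id = c("glc_e", "glc_c"),
                     name = c("glucose", "glucose"),
                     compartment = c("e", "c"))
  rxns <- list(
    EX_glc_e = list(stoichiometry = c(glc_e = -1),
                    lower_bound = -uptake, upper_bound = 1000),
    GLCt = list(stoichiometry = c(glc_e = -1, glc_c = 1),
                lower_bound = 0, upper_bound = 1000),
    BIOMASS = list(stoichiometry = c(glc_c = -1),
                   lower_bound = 0, upper_bound = 1000))
  metabolic_model("chain", mets, rxns, "BIOMASS")
}

# branched toy: glucose -> 2 pyruvate; pyruvate -> lactate (secreted) or
# biomass precursor; biomass needs 1 precursor + 1 pyruvate.
branched_model <- function(uptake = 10) {
  mets <- data.frame(
    id = c("glc_e", "glc_c", "pyr_c", "pre_c", "lac_e"),
    name = c("glucose", "glucose", "pyruvate", "precursor", "lactate"),
    compartment = c("e", "c", "c", "c", "e"))
  rxns <- list(
    EX_glc_e = list(stoichiometry = c(glc_e = -1),
                    lower_bound = -uptake, upper_bound = 1000),
    GLCt = list(stoichiometry = c(glc_e = -1, glc_c = 1),
                lower_bound = 0, upper_bound = 1000),
    GLYC = list(stoichiometry = c(glc_c = -1, pyr_c = 2),
                lower_bound = 0, upper_bound = 1000),
    PRE = list(stoichiometry = c(pyr_c = -1, pre_c = 1),
               lower_bound = 0, upper_bound = 1000),
    LDH = list(stoichiometry = c(pyr_c = -1, lac_e = 1),
               lower_bound = 0, upper_bound = 1000),
    EX_lac_e = list(stoichiometry = c(lac_e = -1),
                    lower_bound = 0, upper_bound = 1000),
    BIOMASS = list(stoichiometry = c(pre_c = -1, pyr_c = -1),
                   lower_bound = 0, upper_bound = 1000))
  metabolic_model("branched", mets, rxns, "BIOMASS")
}

# random box-bounded FBA-like LP (always feasible at v = 0, bounded)
random_lp <- function(n_met = sample(3:10, 1), n_rxn = sample(5:30, 1)) {
  S <- matrix(sample(c(0, 0, 0, 1, -1, 2, -2), n_met * n_rxn,
                     replace = TRUE), n_met, n_rxn)
  list(S = S,
       lb = sample(c(-10, 0), n_rxn, replace = TRUE),
       ub = sample(c(5, 10), n_rxn, replace = TRUE),
       obj = rnorm(n_rxn))
}

# two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins (point-probability convention, with the same
# relative tolerance on ties that the reference implementation uses)
fisher_p_enum <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random coalescent tree plus random abundance columns over its leaves
random_tree_abundance <- function(n_leaves = 8, n_cols = 2,
                                  sparsity = 0.4) {
  tree <- ape::rcoal(n_leaves, tip.label = sprintf("t%02d", 1:n_leaves))
  amat <- matrix(0, n_leaves, n_cols,
                 dimnames = list(tree$tip.label, NULL))
  for (j in 1:n_cols) {
    pres <- runif(n_leaves) > sparsity
    if (sum(pres) < 1) pres[sample.int(n_leaves, 1)] <- TRUE
    amat[pres, j] <- rgamma(sum(pres), 2)
    amat[, j] <- amat[, j] / sum(amat[, j])
  }
  list(tree = tree, a = amat)
}
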