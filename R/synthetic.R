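#' Specification of a toy chassis metabolic network
#'
#' The chassis is a minimal gut-bacterium-like network built around
#' pyruvate as the central precursor: glucose is taken up and split into a
#' pyruvate pool and a second generic precursor pool plus ATP; each amino
#' acid has a lumped one-step biosynthesis reaction from one of the two
#' pools (the pyruvate family - Ala, Ile, Leu, Val - draws two pyruvate
#' per amino acid, all others draw the generic precursor), an extracellular
#' exchange, and an uptake transporter; biomass consumes all 20 amino
#' acids plus ATP; fermentation branches drain the precursor pools into
#' secreted by-products.  Knocking out an amino acid's biosynthesis plants
#' an auxotrophy, and because the branched-chain amino acids drain
#' pyruvate, their knockouts mechanically redirect pyruvate into lactate.
#'
#' @param knockout_set amino acids whose biosynthesis reaction is absent.
#' @param transporter_set amino acids with an uptake transporter
#'   (default: all 20).
#' @param branches fermentation branches present, subset of
#'   `c("lactate", "acetate", "butyrate", "propionate", "succinate")`.
#' @param glucose_uptake maximal glucose uptake, mmol/gDW/hr.
#' @param biomass_aa_coef biomass coefficient per amino acid.
#' @param biomass_atp_coef biomass ATP coefficient; together with the
#'   branch stoichiometry this sets the growth-normalized secretion scale.
#' @return list of class `chassis_spec`.
#' @export
chassis_spec <- function(knockout_set = character(),
                         transporter_set = amino_acids()$amino_acid,
                         branches = c("lactate", "acetate"),
                         glucose_uptake = 10,
                         biomass_aa_coef = 0.05,
                         biomass_atp_coef = 2.5) {
  aa <- amino_acids()$amino_acid
  stopifnot(all(knockout_set %in% aa), all(transporter_set %in% aa),
            all(branches %in% c("lactate", "acetate", "butyrate",
                                "propionate", "succinate")))
  structure(list(knockout_set = knockout_set,
                 transporter_set = transporter_set,
                 branches = branches,
                 glucose_uptake = glucose_uptake,
                 biomass_aa_coef = biomass_aa_coef,
                 biomass_atp_coef = biomass_atp_coef),
            class = "chassis_spec")
}

PYRUVATE_FAMILY <- c("ala", "ile", "leu", "val")

#' Build a chassis metabolic model from its specification
#'
#' See [chassis_spec()] for the network layout.  A chassis with
#' `knockout_set` contained in `transporter_set` grows on the full
#' 20-amino-acid medium; a prototroph (empty knockout set) grows on
#' glucose alone.
#'
#' @param spec a `chassis_spec`.
#' @param id model id.
#' @return a validated `metabolic_model`.
#' @export
make_chassis_model <- function(spec, id = "chassis") {
  aa_tab <- amino_acids()
  aa <- aa_tab$amino_acid

  mets <- rbind(
    data.frame(id = c("glc_e", "glc_c", "pyr_c", "prec_c", "atp_c"),
               name = c("glucose", "glucose", "pyruvate",
                        "generic precursor", "ATP"),
               compartment = c("e", "c", "c", "c", "c")),
    data.frame(id = paste0(aa, "_c"), name = aa, compartment = "c"),
    data.frame(id = paste0(aa, "_e"), name = aa, compartment = "e"))

  rxns <- list(
    EX_glc_e = list(stoichiometry = c(glc_e = -1),
                    lower_bound = -spec$glucose_uptake, upper_bound = 1000),
    GLCt = list(stoichiometry = c(glc_e = -1, glc_c = 1),
                lower_bound = 0, upper_bound = 1000),
    GLYC = list(stoichiometry = c(glc_c = -1, pyr_c = 1, prec_c = 1,
                                  atp_c = 2),
                lower_bound = 0, upper_bound = 1000),
    ATPM = list(stoichiometry = c(atp_c = -1),
                lower_bound = 0, upper_bound = 1000))

  for (a in aa) {
    if (!(a %in% spec$knockout_set)) {
      sto <- if (a %in% PYRUVATE_FAMILY)
        setNames(c(-2, 1), c("pyr_c", paste0(a, "_c")))
      else
        setNames(c(-1, 1), c("prec_c", paste0(a, "_c")))
      rxns[[paste0("BS_", a)]] <-
        list(stoichiometry = sto, lower_bound = 0, upper_bound = 1000)
    }
    if (a %in% spec$transporter_set)
      rxns[[paste0("T_", a)]] <-
        list(stoichiometry = setNames(c(-1, 1),
                                      paste0(a, c("_e", "_c"))),
             lower_bound = 0, upper_bound = 1000)
    rxns[[paste0("EX_", a, "_e")]] <-
      list(stoichiometry = setNames(-1, paste0(a, "_e")),
           lower_bound = 0, upper_bound = 1000)
  }

  branch_rxns <- list(
    lactate = list(LDH_D = c(pyr_c = -1, lac__D_e = 1),
                   LDH_L = c(pyr_c = -1, lac__L_e = 1)),
    acetate = list(ACKr = c(prec_c = -1, ac_e = 1)),
    butyrate = list(BUTS = c(prec_c = -1, but_e = 1)),
    propionate = list(PPAS = c(prec_c = -1, ppa_e = 1)),
    succinate = list(SUCS = c(prec_c = -1, succ_e = 1)))
  branch_met_names <- c(lac__D_e = "D-lactate", lac__L_e = "L-lactate",
                        ac_e = "acetate", but_e = "butyrate",
                        ppa_e = "propionate", succ_e = "succinate")
  for (br in spec$branches) {
    for (rid in names(branch_rxns[[br]])) {
      sto <- branch_rxns[[br]][[rid]]
      prod_met <- names(sto)[sto > 0]
      if (!prod_met %in% mets$id)
        mets <- rbind(mets, data.frame(id = prod_met,
                                       name = branch_met_names[[prod_met]],
                                       compartment = "e"))
      rxns[[rid]] <- list(stoichiometry = sto, lower_bound = 0,
                          upper_bound = 1000)
      rxns[[paste0("EX_", prod_met)]] <-
        list(stoichiometry = setNames(-1, prod_met),
             lower_bound = 0, upper_bound = 1000)
    }
  }

  biomass <- c(setNames(rep(-spec$biomass_aa_coef, length(aa)),
                        paste0(aa, "_c")),
               atp_c = -spec$biomass_atp_coef)
  rxns$BIOMASS <- list(stoichiometry = biomass, lower_bound = 0,
                       upper_bound = 1000)

  metabolic_model(id, mets, rxns, "BIOMASS")
}

#' Standard media for chassis models
#'
#' The full medium supplies glucose and all 20 amino acids (default
#' uptake limit 10 mmol/gDW/hr each); the minimal medium supplies glucose
#' only.
#'
#' @param aa_uptake per-amino-acid uptake limit.
#' @param glucose_uptake glucose uptake limit.
#' @return a `medium`.
#' @export
full_medium <- function(aa_uptake = 10, glucose_uptake = 10) {
  medium(c(setNames(rep(aa_uptake, 20), amino_acids()$exchange_met),
           glc_e = glucose_uptake))
}

#' @rdname full_medium
#' @export
minimal_medium <- function(glucose_uptake = 10) {
  medium(c(glc_e = glucose_uptake))
}

#' Specification of a synthetic cohort
#'
#' Gathers the knobs of the synthetic-data generator: collection size,
#' per-amino-acid knockout probability, the planted diversity-auxotrophy
#' effect, the stability link slope, metabolome effect sizes and
#' confounder loadings, and the seed (Mersenne-Twister; a fixed seed gives
#' byte-identical outputs).
#'
#' @param n_genomes genomes in the collection.
#' @param n_samples cross-sectional samples.
#' @param n_subjects longitudinal subjects (paired samples).
#' @param auxotrophy_prob per-amino-acid knockout probability (scalar or
#'   length-20 vector named by amino acid).
#' @param diversity_effect strength of the latent community-auxotrophy
#'   load that couples evenness, presence tilt and auxotrophy frequency;
#'   0 removes the planted diversity link.
#' @param stability_slope decrease of compositional turnover per standard
#'   deviation of the weighted auxotrophy count; 0 removes the planted
#'   stability link.
#' @param metabolome_effect planted metabolite effect size (standardized
#'   scale); 0 removes the planted metabolome links.
#' @param confounder_loadings named loadings of age, sex and BMI on the
#'   synthetic metabolites.
#' @param noise_sd residual noise of the synthetic metabolites.
#' @param completeness_coupling extra knockout probability per percent of
#'   completeness lost below 100; > 0 plants the completeness-bias
#'   phenomenon.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genomes = 200, n_samples = 185,
                        n_subjects = 100, auxotrophy_prob = 0.3,
                        diversity_effect = 1.0, stability_slope = 1.5,
                        metabolome_effect = 0.8,
                        confounder_loadings = c(age = 0.3, sex = 0.2,
                                                bmi = 0.4),
                        noise_sd = 1, completeness_coupling = 0,
                        seed = 1L) {
  aa <- amino_acids()$amino_acid
  if (length(auxotrophy_prob) == 1)
    auxotrophy_prob <- setNames(rep(auxotrophy_prob, 20), aa)
  stopifnot(all(auxotrophy_prob >= 0 & auxotrophy_prob <= 1),
            identical(sort(names(auxotrophy_prob)), sort(aa)))
  structure(list(n_genomes = n_genomes, n_samples = n_samples,
                 n_subjects = n_subjects,
                 auxotrophy_prob = auxotrophy_prob[aa],
                 diversity_effect = diversity_effect,
                 stability_slope = stability_slope,
                 metabolome_effect = metabolome_effect,
                 confounder_loadings = confounder_loadings,
                 noise_sd = noise_sd,
                 completeness_coupling = completeness_coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

standardize <- function(x) {
  if (length(x) < 2) return(rep(0, length(x)))
  s <- sd(x)
  if (!isTRUE(s > 0)) return(rep(0, length(x)))
  (x - mean(x)) / s
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a synthetic genome collection with planted auxotrophies
#'
#' Draws independent per-amino-acid biosynthesis knockouts at the
#' specified probabilities, builds one chassis model per genome (all
#' transporters present, so every planted auxotrophy is evaluable), and
#' draws assembly metadata: completeness 100 minus an exponential deficit
#' (mean 5%, capped at 40%), contamination exponential (mean 1%).  With
#' `completeness_coupling > 0`, genomes with lower completeness receive
#' additional knockouts, reproducing the completeness-bias phenomenon;
#' the truth table records the realized knockouts either way.
#'
#' @param spec a `cohort_spec`.
#' @return list: `models` (named list of `metabolic_model`), `truth`
#'   (profile-table-shaped data.frame of planted knockouts), `metadata`
#'   (genome_id, completeness, contamination, taxonomy).
#' @export
generate_genome_collection <- function(spec) {
  aa <- amino_acids()$amino_acid
  ids <- sprintf("g%04d", seq_len(spec$n_genomes))
  with_seed(spec$seed, {
    deficit <- pmin(rexp(spec$n_genomes, rate = 1 / 5), 40)
    completeness <- 100 - deficit
    contamination <- pmin(rexp(spec$n_genomes, rate = 1), 25)
    prob <- matrix(rep(spec$auxotrophy_prob, each = spec$n_genomes),
                   nrow = spec$n_genomes,
                   dimnames = list(ids, aa))
    if (spec$completeness_coupling > 0)
      prob <- pmin(prob + spec$completeness_coupling * deficit, 1)
    B <- matrix(rbinom(length(prob), 1, prob), nrow = spec$n_genomes,
                dimnames = dimnames(prob))
    models <- lapply(ids, function(g)
      make_chassis_model(chassis_spec(knockout_set = aa[B[g, ] == 1]),
                         id = g))
    names(models) <- ids
    truth <- data.frame(genome_id = ids, B, n_auxotrophies = rowSums(B),
                        row.names = NULL, stringsAsFactors = FALSE)
    metadata <- data.frame(genome_id = ids, completeness = completeness,
                           contamination = contamination,
                           taxonomy = "synthetic chassis",
                           stringsAsFactors = FALSE)
    list(models = models, truth = truth, metadata = metadata)
  })
}

# tilted sparse Dirichlet community for one sample given latent load z
draw_sample <- function(z, a_std, effect, base_presence = 0.35) {
  n <- length(a_std)
  pres_p <- stats::plogis(stats::qlogis(base_presence) + effect * z * a_std)
  present <- runif(n) < pres_p
  if (sum(present) < 2)
    present[sample.int(n, min(2, n))] <- TRUE
  # evenness rises with the load through the Dirichlet concentration; the
  # abundance tilt toward auxotroph-rich genomes is kept mild because a
  # strong tilt concentrates mass and works against the evenness link
  shape <- exp(0.6 * effect * z)
  w <- rgamma(sum(present), shape = shape, rate = 1) *
    exp(0.25 * effect * z * a_std[present])
  w[w <= 0] <- .Machine$double.xmin
  p <- numeric(n)
  p[present] <- w / sum(w)
  p
}

#' Generate synthetic community abundance profiles and a phylogeny
#'
#' Per sample, a latent community-auxotrophy load tilts both which
#' genomes are present and how evenly abundance is spread (Dirichlet
#' weights whose concentration increases with the load), so that samples
#' with more auxotroph-rich communities are also more diverse - the
#' planted diversity-auxotrophy link, with strength
#' `spec$diversity_effect` (0 = no link).  The phylogeny is a random
#' coalescent tree over the genomes.
#'
#' @param spec a `cohort_spec`.
#' @param truth truth table from [generate_genome_collection()].
#' @param sample_prefix prefix for sample ids.
#' @return list: `abundance` (a `community_abundance`), `tree`
#'   (`ape::phylo`), `latent` (the per-sample load, for diagnostics).
#' @export
generate_communities <- function(spec, truth, sample_prefix = "s") {
  ids <- truth$genome_id
  a <- truth$n_auxotrophies
  a_std <- standardize(a)
  samples <- sprintf("%s%03d", sample_prefix, seq_len(spec$n_samples))
  with_seed(spec$seed + 1L, {
    z <- rnorm(spec$n_samples)
    P <- vapply(z, function(zj)
      draw_sample(zj, a_std, spec$diversity_effect), numeric(length(ids)))
    if (!is.matrix(P)) P <- matrix(P, nrow = length(ids))
    dimnames(P) <- list(ids, samples)
    tree <- if (length(ids) < 2)
      ape::read.tree(text = sprintf("(%s:1);", ids))
    else ape::rcoal(length(ids), tip.label = ids)
    list(abundance = abundance_matrix(P), tree = tree,
         latent = setNames(z, samples))
  })
}

#' Generate paired two-timepoint samples with auxotrophy-linked turnover
#'
#' For each subject, the first `n_subjects` cross-sectional samples serve
#' as time point 1; time point 2 replaces a fraction `f` of the community
#' mass by a freshly drawn community, where `f` decreases with the
#' subject's weighted auxotrophy count at t1 through a logistic link with
#' slope `spec$stability_slope` (0 = turnover independent of
#' auxotrophies).  `f = 0` reproduces t1 exactly (stability 1).
#'
#' @param spec a `cohort_spec`.
#' @param communities output of [generate_communities()].
#' @param truth truth table (for the weighted auxotrophy count at t1).
#' @return list: `abundance` (t1 + t2 columns), `manifest` (subject_id,
#'   sample_t1, sample_t2), `turnover` (per-subject f).
#' @export
generate_longitudinal <- function(spec, communities, truth) {
  p <- communities$abundance
  stopifnot(spec$n_subjects <= ncol(p))
  t1 <- colnames(p)[seq_len(spec$n_subjects)]
  yj <- weighted_auxotrophy_count(p[, t1, drop = FALSE], truth)
  y_std <- standardize(yj)
  a_std <- standardize(truth$n_auxotrophies)
  with_seed(spec$seed + 2L, {
    f <- stats::plogis(stats::qlogis(0.4) - spec$stability_slope * y_std)
    t2 <- matrix(0, nrow = nrow(p), ncol = spec$n_subjects,
                 dimnames = list(rownames(p), paste0(t1, "_t2")))
    for (i in seq_along(t1)) {
      fresh <- draw_sample(rnorm(1), a_std, spec$diversity_effect)
      t2[, i] <- (1 - f[i]) * p[, t1[i]] + f[i] * fresh
    }
    manifest <- data.frame(subject_id = sprintf("subj%03d",
                                                seq_len(spec$n_subjects)),
                           sample_t1 = t1, sample_t2 = colnames(t2),
                           stringsAsFactors = FALSE)
    list(abundance = abundance_matrix(cbind(unclass(p), t2)),
         manifest = manifest, turnover = setNames(f, manifest$subject_id))
  })
}

#' Generate a confounded synthetic metabolome
#'
#' Synthetic serum-like metabolites as linear combinations of selected
#' amino-acid auxotrophy frequencies, confounder loadings (age, sex, BMI)
#' and Gaussian noise.  The planted panel mirrors the analyte classes the
#' analysis targets: a tryptophan-driven "indole-like" metabolite
#' (positive effect), a tyrosine-driven "cresol-like" metabolite
#' (positive), a threonine-driven "bileacid-like" metabolite (negative),
#' one metabolite driven only by BMI (pure confounding) and one pure
#' noise.  Effect sizes scale with `spec$metabolome_effect` (0 = null
#' metabolome).
#'
#' @param spec a `cohort_spec`.
#' @param frequencies samples x amino-acids matrix from
#'   [auxotrophy_frequency()].
#' @return list: `metabolome` (data.frame, rownames = samples),
#'   `confounders` (age, sex, bmi), `planted` (metabolite, amino_acid,
#'   direction).
#' @export
generate_metabolome <- function(spec, frequencies) {
  samples <- rownames(frequencies)
  n <- length(samples)
  e <- spec$metabolome_effect
  ld <- spec$confounder_loadings
  std <- standardize
  with_seed(spec$seed + 3L, {
    # BMI is negatively coupled to the community's total auxotrophy load,
    # giving the screen a genuine confounding path to remove
    load <- std(rowSums(frequencies))
    conf <- data.frame(age = rnorm(n, 47, 8),
                       sex = rbinom(n, 1, 0.45),
                       bmi = 24.5 + 2.5 * (-0.5 * load +
                                             sqrt(0.75) * rnorm(n)),
                       row.names = samples)
    conf_part <- ld["age"] * std(conf$age) + ld["sex"] * std(conf$sex) +
      ld["bmi"] * std(conf$bmi)
    noise <- function() rnorm(n, 0, spec$noise_sd)
    metab <- data.frame(
      indole_like = e * std(frequencies[, "trp"]) + conf_part + noise(),
      cresol_like = e * std(frequencies[, "tyr"]) + conf_part + noise(),
      bileacid_like = -e * std(frequencies[, "thr"]) + conf_part + noise(),
      bmi_driven = std(conf$bmi) + noise(),
      inert = noise(),
      row.names = samples)
    planted <- data.frame(
      metabolite = c("indole_like", "cresol_like", "bileacid_like"),
      amino_acid = c("trp", "tyr", "thr"),
      direction = c(1, 1, -1), stringsAsFactors = FALSE)
    list(metabolome = metab, confounders = conf, planted = planted)
  })
}
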