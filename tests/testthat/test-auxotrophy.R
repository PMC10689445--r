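med <- full_medium()

test_that("planted knockouts are called exactly, prototrophs all-zero", {
  proto <- predict_auxotrophies(make_chassis_model(chassis_spec()), med)
  expect_equal(proto$n_auxotrophies, 0)
  expect_true(all(proto$calls == 0))

  trp <- predict_auxotrophies(
    make_chassis_model(chassis_spec(knockout_set = "trp"), id = "k1"), med)
  expect_equal(unname(trp$calls["trp"]), 1L)
  expect_equal(trp$n_auxotrophies, 1)

  bcaa_set <- c("ile", "leu", "val")
  bcaa <- predict_auxotrophies(
    make_chassis_model(chassis_spec(knockout_set = bcaa_set), id = "k3"),
    med)
  # independent reachability argument: biomass requires every amino acid;
  # a knocked-out amino acid is reachable only through its transporter,
  # so the drop-out of exactly the knocked-out set must fail
  expect_identical(names(bcaa$calls)[bcaa$calls == 1L], bcaa_set)
  expect_equal(bcaa$n_auxotrophies, 3)
})

test_that("a genome without growth on the full medium is unevaluable", {
  # knockout without transporter: cannot grow even on the full medium
  spec <- chassis_spec(knockout_set = "trp",
                       transporter_set = setdiff(amino_acids()$amino_acid,
                                                 "trp"))
  m <- make_chassis_model(spec, id = "dead")
  expect_warning(res <- predict_auxotrophies(m, med), "unevaluable")
  expect_null(res)
})

test_that("a medium lacking an amino acid is a configuration error", {
  short_med <- medium(med[names(med) != "trp_e"])
  expect_error(predict_auxotrophies(make_chassis_model(chassis_spec()),
                                    short_med),
               "trp_e")
})

test_that("calls are invariant to other amino acids' exchange bounds", {
  m <- make_chassis_model(chassis_spec(knockout_set = "his"), id = "k")
  p1 <- predict_auxotrophies(m, med)
  rich <- medium(ifelse(names(med) == "glc_e", med, med * 50) |>
                   setNames(names(med)))
  p2 <- predict_auxotrophies(m, rich)
  expect_identical(p1$calls, p2$calls)
})

test_that("genome quality filter keeps inclusive boundaries", {
  meta <- data.frame(
    genome_id = sprintf("g%02d", 1:10),
    completeness = c(85, 84.9, 100, 90, 85.01, 60, 99, 85, 92, 88),
    contamination = c(2, 0, 2.01, 0.5, 2, 0, 1.99, 0, 3, 2))
  got <- filter_genomes(meta)
  want <- meta$genome_id[meta$completeness >= 85 & meta$contamination <= 2]
  expect_identical(got, want)
  expect_true("g01" %in% got)   # (85.0, 2.0) retained
  expect_false("g02" %in% got)  # (84.9, 0.0) excluded
  expect_length(filter_genomes(meta, min_completeness = 101), 0)
})

test_that("completeness bias check recovers planted dependence and nulls", {
  # perfect anti-monotone
  meta <- data.frame(genome_id = c("a", "b", "c", "d"),
                     completeness = c(99, 98, 97, 96), contamination = 0)
  prof <- data.frame(genome_id = c("a", "b", "c", "d"),
                     n_auxotrophies = c(1, 2, 5, 9))
  expect_equal(completeness_bias_check(meta, prof)$estimate, -1)

  # generative coupling: each % completeness lost adds knockout risk
  spec <- cohort_spec(n_genomes = 150, completeness_coupling = 0.04,
                      seed = 91)
  coll <- generate_genome_collection(spec)
  bias <- completeness_bias_check(coll$metadata, coll$truth)
  expect_lt(bias$estimate, -0.2)
  expect_lt(bias$p_raw, 0.01)

  # independent completeness and auxotrophy count: mostly non-significant
  set.seed(92)
  hits <- replicate(100, {
    meta <- data.frame(genome_id = 1:200,
                       completeness = runif(200, 80, 100),
                       contamination = 0)
    prof <- data.frame(genome_id = 1:200,
                       n_auxotrophies = rbinom(200, 20, 0.3))
    completeness_bias_check(meta, prof)$p_raw < 0.05
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("validation metrics reproduce confusion-table arithmetic", {
  pred <- profiles_table(list(
    predict_auxotrophies(
      make_chassis_model(chassis_spec(knockout_set = c("trp", "his")),
                         id = "s1"), med),
    predict_auxotrophies(
      make_chassis_model(chassis_spec(knockout_set = "lys"), id = "s2"),
      med)))
  # craft labels giving TP=3, FN=1, TN=5, FP=1
  expl <- data.frame(
    genome_id = c("s1", "s1", "s1", "s2", "s2", "s1", "s2", "s2", "s2",
                  "s2"),
    amino_acid = c("trp", "his", "ala", "lys", "gly", "gln", "ala", "arg",
                   "asp", "met"),
    status = c("auxotroph", "auxotroph", "auxotroph", "auxotroph",
               "prototroph", "prototroph", "prototroph", "prototroph",
               "prototroph", "auxotroph"))
  vm <- validation_metrics(pred, expl)
  expect_equal(c(vm$TP, vm$FN, vm$TN, vm$FP), c(3, 2, 5, 0))
  expect_equal(vm$sensitivity, 100 * 3 / 5)
  expect_equal(vm$specificity, 100)
  expect_equal(vm$accuracy, 100 * 8 / 10)

  # planted flips at known rates are recovered as realized counts
  set.seed(93)
  coll <- generate_genome_collection(cohort_spec(n_genomes = 30, seed = 94))
  truthB <- as.matrix(coll$truth[, amino_acids()$amino_acid])
  flip <- matrix(runif(length(truthB)) < 0.1, nrow = nrow(truthB))
  lab <- abs(truthB - flip)
  expl2 <- data.frame(
    genome_id = rep(coll$truth$genome_id, times = 20),
    amino_acid = rep(amino_acids()$amino_acid, each = 30),
    status = ifelse(as.vector(lab) == 1, "auxotroph", "prototroph"))
  vm3 <- validation_metrics(coll$truth, expl2)
  # flipped auxotrophs become FN, flipped prototrophs FP, rest agree
  expect_equal(vm3$FN + vm3$FP, sum(flip))
  expect_equal(vm3$TP + vm3$TN, sum(!flip))

  expect_warning(validation_metrics(pred, data.frame(
    genome_id = "ghost", amino_acid = "trp", status = "auxotroph")),
    "ghost")
})

test_that("perfect agreement gives 100/100/100", {
  coll <- generate_genome_collection(cohort_spec(n_genomes = 10, seed = 95))
  expl <- data.frame(
    genome_id = rep(coll$truth$genome_id, times = 20),
    amino_acid = rep(amino_acids()$amino_acid, each = 10),
    status = ifelse(as.vector(as.matrix(
      coll$truth[, amino_acids()$amino_acid])) == 1,
      "auxotroph", "prototroph"))
  vm <- validation_metrics(coll$truth, expl)
  expect_equal(c(vm$sensitivity, vm$specificity, vm$accuracy),
               c(100, 100, 100))
})

test_that("relaxing a drop-out never converts growth into no-growth", {
  # monotonicity of LP feasibility under bound relaxation, checked on a
  # genotype that is auxotrophic for several amino acids
  m <- make_chassis_model(chassis_spec(knockout_set = c("trp", "ile",
                                                        "met")), id = "mono")
  m <- apply_medium(m, med)
  prob <- fba_problem(m)
  ex <- exchange_metabolites(m)
  drop <- function(mets) {
    lb <- prob$lb
    lb[match(names(ex)[ex %in% mets], prob$rxn_ids)] <- 0
    r <- lp_solve(prob$obj, prob$S, rep(0, nrow(prob$S)), lb, prob$ub)
    r$objective
  }
  g_both <- drop(c("trp_e", "ile_e"))
  g_one <- drop("trp_e")
  expect_gte(g_one, g_both - 1e-9)
})
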