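med <- full_medium()

test_that("chassis growth follows the planted dependency structure", {
  proto <- make_chassis_model(chassis_spec())
  expect_gt(solve_fba(apply_medium(proto, minimal_medium()))$growth_rate,
            1)

  ko <- make_chassis_model(chassis_spec(knockout_set = "trp"), id = "ko")
  expect_lt(solve_fba(apply_medium(ko, minimal_medium()))$growth_rate,
            1e-9)
  rescued <- apply_medium(ko, medium(c(glc_e = 10, trp_e = 10)))
  expect_gt(solve_fba(rescued)$growth_rate, 1)

  # a model grows on the full medium iff knockouts are covered by
  # transporters
  dead <- make_chassis_model(
    chassis_spec(knockout_set = "his", transporter_set = character()),
    id = "dead")
  expect_lt(solve_fba(apply_medium(dead, med))$growth_rate, 1e-9)
})

test_that("generated models validate and respect edge-case probabilities", {
  coll0 <- generate_genome_collection(
    cohort_spec(n_genomes = 12, auxotrophy_prob = 0, seed = 81))
  expect_true(all(coll0$truth$n_auxotrophies == 0))

  prob1 <- setNames(rep(0, 20), amino_acids()$amino_acid)
  prob1["trp"] <- 1
  coll1 <- generate_genome_collection(
    cohort_spec(n_genomes = 12, auxotrophy_prob = prob1, seed = 81))
  expect_true(all(coll1$truth$trp == 1))
  expect_true(all(coll1$truth$n_auxotrophies == 1))
  for (m in coll1$models) expect_silent(validate_model(m))
})

test_that("fixed seeds give byte-identical generated bundles", {
  spec <- cohort_spec(n_genomes = 10, n_samples = 12, n_subjects = 6,
                      seed = 82)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_inputs(spec, d1)
  simulate_inputs(spec, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("screen recovers the planted truth on a generated collection", {
  coll <- generate_genome_collection(cohort_spec(n_genomes = 40, seed = 83))
  prof <- profiles_table(lapply(coll$models, predict_auxotrophies,
                                full_medium = med))
  aa <- amino_acids()$amino_acid
  expect_equal(as.matrix(prof[, aa]),
               as.matrix(coll$truth[match(prof$genome_id,
                                          coll$truth$genome_id), aa]),
               ignore_attr = TRUE)
})

test_that("community generator honors degenerate and null settings", {
  spec <- cohort_spec(n_genomes = 1, n_samples = 8, seed = 84)
  coll <- generate_genome_collection(spec)
  com <- generate_communities(spec, coll$truth)
  expect_true(all(abs(shannon_index(com$abundance)) < 1e-12))

  # zero diversity effect: correlation centered at zero over replicates
  rhos <- sapply(1:40, function(r) {
    spec0 <- cohort_spec(n_genomes = 60, n_samples = 50,
                         diversity_effect = 0, seed = 8400 + r)
    coll0 <- generate_genome_collection(spec0)
    com0 <- generate_communities(spec0, coll0$truth)
    cs <- community_summary(com0$abundance, coll0$truth)
    cor(cs$weighted_auxotrophy_count, cs$shannon, method = "spearman")
  })
  expect_lt(abs(mean(rhos)), 0.08)
  expect_gt(mean(abs(rhos) < 0.35), 0.85)
})

test_that("longitudinal limits: zero turnover reproduces t1, full turnover diverges", {
  spec <- cohort_spec(n_genomes = 30, n_samples = 15, n_subjects = 10,
                      seed = 85, stability_slope = 0)
  coll <- generate_genome_collection(spec)
  com <- generate_communities(spec, coll$truth)
  lon <- generate_longitudinal(spec, com, coll$truth)

  # reconstruct t2 with f = 0 by mixing manually: stability must be 1
  p <- com$abundance
  rec <- stability_records(com$tree,
                           abundance_matrix(cbind(unclass(p),
                                                  t2 = p[, 1])),
                           data.frame(subject_id = "u", sample_t1 =
                                        colnames(p)[1],
                                      sample_t2 = "t2"))
  expect_equal(rec$stability, 1)

  # disjoint support: stability near zero under both variants
  tree <- read_newick("(A:1,B:1);")
  pd <- abundance_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                                dimnames = list(c("A", "B"),
                                                c("x1", "x2"))))
  man <- data.frame(subject_id = "u", sample_t1 = "x1", sample_t2 = "x2")
  expect_equal(stability_records(tree, pd, man)$stability, 0)

  # realized turnover fractions respect the logistic link bounds
  expect_true(all(lon$turnover > 0 & lon$turnover < 1))
})

test_that("metabolome generator plants recoverable and confounded effects", {
  spec <- cohort_spec(n_genomes = 80, n_samples = 150, seed = 86)
  coll <- generate_genome_collection(spec)
  com <- generate_communities(spec, coll$truth)
  freq <- auxotrophy_frequency(com$abundance, coll$truth)
  mb <- generate_metabolome(spec, freq)

  scr <- association_screen(freq, mb$metabolome, mb$confounders)
  planted <- merge(scr, mb$planted,
                   by.x = c("amino_acid", "target"),
                   by.y = c("amino_acid", "metabolite"))
  expect_equal(nrow(planted), 3)
  expect_true(all(sign(planted$estimate) == planted$direction))
  expect_true(all(planted$p_adjusted < 0.05))

  # the purely BMI-driven target correlates only through the planted
  # confounding path, which adjustment removes
  bmi_unadj <- partial_spearman(freq[, "trp"],
                                mb$metabolome$bmi_driven)
  bmi_adj <- partial_spearman(freq[, "trp"], mb$metabolome$bmi_driven,
                              confounders = mb$confounders)
  expect_lt(bmi_unadj$rho, -0.08)
  expect_lt(abs(bmi_adj$rho), abs(bmi_unadj$rho))

  # all-zero effects: the planted columns become pure confounder+noise
  spec0 <- cohort_spec(n_genomes = 80, n_samples = 150, seed = 86,
                       metabolome_effect = 0)
  mb0 <- generate_metabolome(spec0, freq)
  scr0 <- association_screen(freq, mb0$metabolome[c("indole_like",
                                                    "cresol_like",
                                                    "bileacid_like")],
                             mb0$confounders)
  expect_lte(mean(scr0$p_adjusted < 0.05), 0.05)
})
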