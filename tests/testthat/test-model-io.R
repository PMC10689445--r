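test_that("smallest valid JSON document parses and invariant violations error", {
  doc <- list(
    id = "mini",
    metabolites = list(list(id = "x_e", name = "x", compartment = "e"),
                       list(id = "x_c", name = "x", compartment = "c")),
    reactions = list(
      list(id = "EX_x_e", stoichiometry = list(x_e = -1),
           lower_bound = -10, upper_bound = 1000),
      list(id = "BIOMASS", stoichiometry = list(x_e = 1, x_c = -1),
           lower_bound = 0, upper_bound = 1000)),
    biomass_reaction_id = "BIOMASS")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  m <- read_model_json(f)
  expect_s3_class(m, "metabolic_model")
  expect_length(m$reactions, 2)
  expect_identical(m$biomass_reaction_id, "BIOMASS")

  doc$biomass_reaction_id <- "GROWTH"
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(read_model_json(f), "not among reactions")

  doc$biomass_reaction_id <- "BIOMASS"
  doc$reactions[[2]]$stoichiometry <- list(ghost_c = -1)
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(read_model_json(f), "undeclared metabolite")

  doc$reactions[[2]] <- list(id = "BIOMASS")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(read_model_json(f), "missing field")
})

test_that("JSON serialization round-trips chassis models bit-identically", {
  m <- make_chassis_model(chassis_spec(knockout_set = c("trp", "lys")))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f1)
  m2 <- read_model_json(f1)
  expect_identical(m$metabolites, m2$metabolites)
  expect_equal(m$reactions, m2$reactions)
  expect_identical(m$biomass_reaction_id, m2$biomass_reaction_id)
  write_model_json(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("SBML round trip preserves the model and contract violations error", {
  m <- make_chassis_model(chassis_spec(knockout_set = "his"), id = "sb")
  f <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, f)
  m2 <- read_model_sbml(f)
  expect_identical(m$metabolites, m2$metabolites)
  expect_equal(m$reactions, m2$reactions)
  expect_identical(m$biomass_reaction_id, m2$biomass_reaction_id)

  # screen output is invariant to the serialization format
  med <- full_medium()
  p1 <- predict_auxotrophies(m, med)
  p2 <- predict_auxotrophies(m2, med)
  expect_identical(p1$calls, p2$calls)

  sbml_doc <- function(objectives) {
    c('<?xml version="1.0" encoding="UTF-8"?>',
      paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
             'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
             'level="3" version="1" fbc:required="false">'),
      '<model id="t">',
      '<listOfSpecies><species id="M_x_e" compartment="e"/></listOfSpecies>',
      '<listOfReactions><reaction id="R_BM" reversible="false">',
      '<listOfReactants><speciesReference species="M_x_e" stoichiometry="1"/></listOfReactants>',
      '</reaction></listOfReactions>',
      objectives,
      '</model></sbml>')
  }
  obj_block <- function(id) {
    c(sprintf('<fbc:objective fbc:id="%s" fbc:type="maximize">', id),
      '<fbc:listOfFluxObjectives>',
      '<fbc:fluxObjective fbc:reaction="R_BM" fbc:coefficient="1"/>',
      '</fbc:listOfFluxObjectives></fbc:objective>')
  }
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_doc(c('<fbc:listOfObjectives fbc:activeObjective="a">',
                        obj_block("a"), obj_block("b"),
                        '</fbc:listOfObjectives>')), f2)
  expect_error(read_model_sbml(f2), "multiple objectives")

  writeLines(sbml_doc(character()), f2)
  expect_error(read_model_sbml(f2), "no biomass objective")

  writeLines(c(sbml_doc(c('<fbc:listOfObjectives fbc:activeObjective="a">',
                          obj_block("a"),
                          '</fbc:listOfObjectives>'))[1:4],
               '<listOfRules/>', '</model></sbml>'), f2)
  expect_error(read_model_sbml(f2), "listOfRules")
})

test_that("SBML without bound annotations gets reversibility defaults", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            "http://www.sbml.org/sbml/level3/version1/core",
            "http://www.sbml.org/sbml/level3/version1/fbc/version2"),
    '<model id="d">',
    '<listOfSpecies><species id="M_x_e" compartment="e"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R_EX_x_e" reversible="true">',
    '<listOfReactants><speciesReference species="M_x_e" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '<reaction id="R_BM" reversible="false">',
    '<listOfReactants><speciesReference species="M_x_e" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="o"><fbc:objective fbc:id="o" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="R_BM" fbc:coefficient="1"/></fbc:listOfFluxObjectives>',
    '</fbc:objective></fbc:listOfObjectives>',
    '</model></sbml>'), f)
  m <- read_model_sbml(f)
  expect_equal(m$reactions$EX_x_e$lower_bound, -1000)
  expect_equal(m$reactions$EX_x_e$upper_bound, 1000)
  expect_equal(m$reactions$BM$lower_bound, 0)
  expect_equal(m$reactions$BM$upper_bound, 1000)
})

test_that("our SBML is readable by an independent SBML+fbc implementation", {
  m <- make_chassis_model(chassis_spec(knockout_set = "trp"), id = "xchk")
  f <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, f)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, cobra, json",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "rx = m.reactions.get_by_id('EX_glc_e')",
    "print(json.dumps({'n_rxn': len(m.reactions),",
    "  'n_met': len(m.metabolites),",
    "  'glc_lb': rx.lower_bound,",
    "  'objective': [r.id for r in m.reactions if r.objective_coefficient != 0]}))"),
    script)
  out <- suppressWarnings(
    system2("python", c(script, f), stdout = TRUE, stderr = FALSE))
  info <- jsonlite::fromJSON(out[length(out)])
  expect_equal(info$n_rxn, length(m$reactions))
  expect_equal(info$n_met, nrow(m$metabolites))
  expect_equal(info$glc_lb, -10)
  expect_equal(info$objective, "BIOMASS")
})

test_that("apply_medium only touches exchange lower bounds and is idempotent", {
  m <- make_chassis_model(chassis_spec())
  med <- full_medium()
  m1 <- apply_medium(m, med)
  m2 <- apply_medium(m1, med)
  expect_identical(m1, m2)
  expect_identical(stoichiometric_matrix(m1), stoichiometric_matrix(m))

  ex <- is_exchange(m)
  for (rid in names(which(!ex)))
    expect_identical(m1$reactions[[rid]], m$reactions[[rid]])

  expect_equal(m1$reactions$EX_glc_e$lower_bound, -10)
  expect_equal(m1$reactions$EX_trp_e$lower_bound, -10)
  expect_equal(m1$reactions$EX_lac__D_e$lower_bound, 0)

  # dropping one amino acid changes exactly that exchange bound
  med2 <- medium(med[names(med) != "trp_e"])
  m3 <- apply_medium(m1, med2)
  diffs <- vapply(names(m1$reactions), function(r)
    !identical(m1$reactions[[r]], m3$reactions[[r]]), TRUE)
  expect_identical(names(which(diffs)), "EX_trp_e")

  expect_warning(apply_medium(m, medium(c(unobtainium_e = 5))),
                 "unobtainium_e")
})

test_that("media read from TSV and JSON agree", {
  med <- medium(c(glc_e = 10, trp_e = 2.5))
  f_tsv <- withr::local_tempfile(fileext = ".tsv")
  f_json <- withr::local_tempfile(fileext = ".json")
  write_medium(med, f_tsv)
  jsonlite::write_json(as.list(med), f_json, auto_unbox = TRUE)
  expect_equal(read_medium(f_tsv), med)
  expect_equal(read_medium(f_json), med)
  expect_error(medium(c(glc_e = -1)), "nonnegative")
})
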