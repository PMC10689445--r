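#' Default fermentation by-product panel
#'
#' Maps each by-product to the extracellular metabolite id(s) whose
#' secretion counts towards it.  Lactate covers both enantiomers, whose
#' production rates are interchangeable in degenerate FBA optima and are
#' therefore combined before thresholding.
#'
#' @return named list: by-product -> character vector of metabolite ids.
#' @export
byproduct_panel <- function() {
  list(lactate = c("lac__D_e", "lac__L_e"),
       acetate = "ac_e",
       propionate = "ppa_e",
       succinate = "succ_e",
       butyrate = "but_e",
       formate = "for_e",
       ethanol = "etoh_e",
       co2 = "co2_e",
       h2 = "h2_e")
}

#' Predict growth-normalized fermentation by-products
#'
#' Maximizes biomass on the given medium, disambiguates the optimal flux
#' distribution with parsimonious FBA, reads the positive (secreting)
#' exchange fluxes (mmol/gDW/hr) and divides them by the growth rate
#' (1/hr), yielding growth-normalized secretion in mmol/gDW.  A by-product
#' is called produced when its normalized secretion strictly exceeds
#' `production_cutoff`; D- and L-lactate are summed before thresholding.
#'
#' @param model a `metabolic_model`.
#' @param med a `medium`; the model must grow on it (zero growth leaves
#'   the normalization undefined and is an error).
#' @param production_cutoff producer-call cutoff in mmol/gDW; default 1.
#' @param panel by-product to metabolite-id mapping, see
#'   [byproduct_panel()].
#' @param growth_threshold minimal growth rate treated as growth.
#' @return a `byproduct_profile`: `genome_id`, `normalized_secretion`
#'   (mmol/gDW per panel entry), 0/1 `producer_calls`.
#' @export
predict_byproducts <- function(model, med, production_cutoff = 1.0,
                               panel = byproduct_panel(),
                               growth_threshold = 1e-6) {
  model <- apply_medium(model, med)
  base <- solve_fba(model)
  if (base$status != "optimal")
    stop("FBA failed for genome ", model$id, ": status ", base$status)
  if (base$growth_rate < growth_threshold)
    stop("genome ", model$id,
         " has zero growth on the medium; normalization undefined")
  sol <- solve_pfba(model, optimum_fraction = 1)
  if (sol$status != "optimal")
    stop("FBA failed for genome ", model$id, ": status ", sol$status)
  g <- sol$growth_rate

  ex_met <- exchange_metabolites(model)
  secretion <- sol$fluxes[names(ex_met)]
  secretion[secretion < 1e-9] <- 0
  by_met <- setNames(as.numeric(secretion) / g, ex_met)

  normalized <- vapply(panel, function(mets)
    sum(by_met[intersect(mets, names(by_met))]), 0.0)
  producer <- as.integer(normalized > production_cutoff)
  structure(list(genome_id = model$id,
                 normalized_secretion = normalized,
                 producer_calls = setNames(producer, names(normalized))),
            class = "byproduct_profile")
}

#' @export
print.byproduct_profile <- function(x, ...) {
  prod <- names(x$producer_calls)[x$producer_calls == 1L]
  cat("<byproduct_profile>", x$genome_id, "- produces:",
      if (length(prod)) paste(prod, collapse = " ") else "(none)", "\n")
  invisible(x)
}

#' Bind by-product profiles into a long table
#' @param byproducts list of `byproduct_profile`.
#' @return data.frame: `genome_id`, `metabolite`, `normalized_rate`,
#'   `producer_call`.
#' @export
byproducts_table <- function(byproducts) {
  do.call(rbind, lapply(byproducts, function(b)
    data.frame(genome_id = b$genome_id,
               metabolite = names(b$normalized_secretion),
               normalized_rate = as.numeric(b$normalized_secretion),
               producer_call = as.integer(b$producer_calls),
               stringsAsFactors = FALSE)))
}

#' Association between auxotrophies and by-product production
#'
#' For every (amino acid, by-product) pair, builds the 2x2 table of
#' auxotroph/prototroph versus producer/non-producer over the shared
#' genome set and evaluates it with the Fisher exact test, reporting the
#' (Haldane-corrected) log2 odds ratio.  P values are Benjamini-Hochberg
#' corrected across all testable pairs of the screen.  Pairs with an empty
#' margin (e.g. an amino acid with zero auxotrophs) are flagged untestable
#' and excluded from the correction family.
#'
#' @param profiles profile table from [profiles_table()].
#' @param byproducts list of `byproduct_profile` (same genomes).
#' @return data.frame: `family`, `amino_acid`, `byproduct`, `estimate`
#'   (log2 OR), `p_raw`, `p_adjusted`, `n`, `testable`.
#' @export
byproduct_auxotrophy_association <- function(profiles, byproducts) {
  btab <- byproducts_table(byproducts)
  shared <- intersect(profiles$genome_id, unique(btab$genome_id))
  if (!length(shared)) stop("no shared genomes between inputs")
  B <- profile_matrix(profiles[match(shared, profiles$genome_id), ])
  prod_mat <- do.call(cbind, lapply(split(btab, btab$metabolite), function(d)
    d$producer_call[match(shared, d$genome_id)]))

  rows <- list()
  for (aa in colnames(B)) {
    for (bp in colnames(prod_mat)) {
      aux <- B[, aa] == 1
      prd <- prod_mat[, bp] == 1
      tab <- matrix(c(sum(aux & prd), sum(aux & !prd),
                      sum(!aux & prd), sum(!aux & !prd)),
                    nrow = 2, byrow = TRUE)
      ft <- fisher_exact_2x2(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        family = "byproduct_screen", amino_acid = aa, byproduct = bp,
        estimate = ft$log2_odds_ratio, p_raw = ft$p, n = length(shared),
        testable = ft$testable, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- NA_real_
  res$p_adjusted[res$testable] <- p.adjust(res$p_raw[res$testable],
                                           method = "BH")
  res
}
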