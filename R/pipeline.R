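#' Assemble a pipeline configuration
#'
#' Bundles input paths and parameters for [run_pipeline()].  Either
#' `models_dir` (a directory of JSON models, one per genome, screened
#' with drop-out FBA) or `profiles` (a precomputed auxotrophy profile
#' TSV, so the screen stage is reused from persisted output) must be
#' given.  `metabolome`/`confounders` and `tree`/`manifest` switch the
#' respective downstream stages on.
#'
#' @param out_dir output directory (created if needed).
#' @param metadata genome metadata TSV (genome_id, completeness,
#'   contamination).
#' @param abundance genome x sample abundance TSV.
#' @param medium growth-medium TSV/JSON (required with `models_dir`).
#' @param models_dir directory of `<genome_id>.json` models.
#' @param profiles auxotrophy-profile TSV from a previous run.
#' @param tree Newick phylogeny (stability stage).
#' @param manifest paired-sample manifest TSV (subject_id, sample_t1,
#'   sample_t2).
#' @param metabolome sample x metabolite TSV (association stage).
#' @param confounders sample x covariate TSV (age, sex, bmi).
#' @param growth_threshold,production_cutoff,min_completeness,
#'   max_contamination,presence_threshold,unifrac_variant analysis
#'   parameters (see the stage functions).
#' @param seed recorded in the run manifest (the analysis itself is
#'   deterministic given its inputs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, metadata, abundance,
                            medium = NULL, models_dir = NULL,
                            profiles = NULL, tree = NULL, manifest = NULL,
                            metabolome = NULL, confounders = NULL,
                            growth_threshold = 1e-6,
                            production_cutoff = 1.0,
                            min_completeness = 85,
                            max_contamination = 2,
                            presence_threshold = 0,
                            unifrac_variant = "weighted_normalized",
                            seed = NA_integer_) {
  if (is.null(models_dir) && is.null(profiles))
    stop("either models_dir or profiles is required")
  if (!is.null(models_dir) && is.null(medium))
    stop("medium is required when screening models")
  structure(list(out_dir = out_dir, metadata = metadata,
                 abundance = abundance, medium = medium,
                 models_dir = models_dir, profiles = profiles,
                 tree = tree, manifest = manifest,
                 metabolome = metabolome, confounders = confounders,
                 growth_threshold = growth_threshold,
                 production_cutoff = production_cutoff,
                 min_completeness = min_completeness,
                 max_contamination = max_contamination,
                 presence_threshold = presence_threshold,
                 unifrac_variant = unifrac_variant,
                 seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full auxotrophy analysis pipeline
#'
#' Executes: genome quality filter, drop-out auxotrophy screen (or reuse
#' of persisted profiles), completeness-bias QC, by-product prediction
#' and Fisher association, community statistics (auxotrophy frequencies,
#' weighted counts, Hamming, Shannon) with the diversity correlations and
#' a host-essentiality summary, the longitudinal stability analysis when
#' a phylogeny and paired-sample manifest are configured, and the
#' confounder-adjusted metabolome screen when a metabolite table is
#' configured.  Every stage writes its table under `out_dir`, and a YAML
#' run manifest records parameters, seed, versions and retained counts.
#' Any stage failure aborts with the stage name.
#'
#' @param config a `pipeline_config` (or path to a YAML file with the
#'   same fields).
#' @return invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(...)
    message("[auxoflux] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  meta <- stage("filter", {
    read.table(config$metadata, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  })
  retained <- stage("filter", filter_genomes(meta, config$min_completeness,
                                             config$max_contamination))
  note(length(retained), " of ", nrow(meta),
       " genomes pass completeness >= ", config$min_completeness,
       "% and contamination <= ", config$max_contamination, "%")
  write_tsv(data.frame(genome_id = retained), out("retained_genomes.tsv"))

  byprod <- NULL
  byprod_assoc <- NULL
  if (!is.null(config$profiles)) {
    prof_tab <- stage("screen", read_profiles(config$profiles))
    prof_tab <- prof_tab[prof_tab$genome_id %in% retained, , drop = FALSE]
    note("reusing ", nrow(prof_tab), " persisted auxotrophy profiles")
  } else {
    med <- stage("screen", read_medium(config$medium))
    model_files <- file.path(config$models_dir, paste0(retained, ".json"))
    missing <- retained[!file.exists(model_files)]
    if (length(missing))
      note("no model file for ", length(missing), " retained genome(s)")
    keep <- file.exists(model_files)
    profiles <- stage("screen", {
      lapply(model_files[keep], function(f) {
        m <- read_model_json(f)
        withCallingHandlers(
          predict_auxotrophies(m, med,
                               growth_threshold = config$growth_threshold),
          warning = function(w) {
            note(conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      })
    })
    unevaluable <- sum(vapply(profiles, is.null, TRUE))
    if (unevaluable)
      note(unevaluable, " genome(s) unevaluable (no growth on full medium)")
    prof_tab <- profiles_table(profiles)

    byprod <- stage("byproducts", {
      models_ok <- model_files[keep][!vapply(profiles, is.null, TRUE)]
      lapply(models_ok, function(f)
        predict_byproducts(read_model_json(f), med,
                           production_cutoff = config$production_cutoff))
    })
    write_tsv(byproducts_table(byprod), out("byproducts.tsv"))
    byprod_assoc <- stage("byproducts",
                          byproduct_auxotrophy_association(prof_tab, byprod))
    write_tsv(byprod_assoc, out("byproduct_associations.tsv"))
  }
  write_profiles(prof_tab, out("auxotrophy_profiles.tsv"))

  bias <- stage("screen", completeness_bias_check(meta, prof_tab))
  write_tsv(bias, out("completeness_bias.tsv"))

  pair_manifest <- NULL
  if (!is.null(config$manifest))
    pair_manifest <- read.table(config$manifest, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)

  comm <- stage("community", {
    p <- read_abundance(config$abundance)
    # follow-up samples enter only the stability stage; the
    # cross-sectional statistics use first-time-point samples
    if (!is.null(pair_manifest)) {
      cross <- setdiff(colnames(p), pair_manifest$sample_t2)
      p_all <- p
      p <- p[, cross, drop = FALSE]
    } else {
      p_all <- p
    }
    keep <- intersect(rownames(p), prof_tab$genome_id)
    dropped <- setdiff(rownames(p), keep)
    if (length(dropped))
      note(length(dropped),
           " genome(s) in the abundance matrix lack profiles and are ",
           "dropped before renormalization")
    p <- abundance_matrix(unclass(p)[keep, , drop = FALSE])
    p_all <- abundance_matrix(unclass(p_all)[keep, , drop = FALSE])
    freq <- auxotrophy_frequency(p, prof_tab)
    summ <- community_summary(p, prof_tab, config$presence_threshold)
    list(p = p, p_all = p_all, freq = freq, summary = summ)
  })
  write_tsv(data.frame(sample_id = rownames(comm$freq), comm$freq,
                       check.names = FALSE),
            out("auxotrophy_frequencies.tsv"))
  write_tsv(comm$summary, out("community_summary.tsv"))

  aa_tab <- amino_acids()
  ess <- stage("community", {
    med_freq <- apply(comm$freq, 2, stats::median)
    data.frame(amino_acid = aa_tab$amino_acid,
               host_essential = aa_tab$host_essential,
               median_frequency = med_freq[aa_tab$amino_acid],
               row.names = NULL)
  })
  write_tsv(ess, out("essentiality_summary.tsv"))

  diversity <- stage("community", {
    safe <- function(x, y) {
      tryCatch(suppressWarnings(partial_spearman(x, y)),
               error = function(e) list(rho = NA_real_, p = NA_real_,
                                        n = sum(complete.cases(x, y))))
    }
    ok <- is.finite(comm$summary$mean_hamming)
    r1 <- safe(comm$summary$weighted_auxotrophy_count,
               comm$summary$shannon)
    r2 <- safe(comm$summary$mean_hamming[ok], comm$summary$shannon[ok])
    data.frame(family = "diversity",
               label_x = c("weighted_auxotrophy_count", "mean_hamming"),
               label_y = "shannon",
               estimate = c(r1$rho, r2$rho), p_raw = c(r1$p, r2$p),
               p_adjusted = c(r1$p, r2$p), n = c(r1$n, r2$n),
               stringsAsFactors = FALSE)
  })
  write_tsv(diversity, out("diversity_associations.tsv"))

  stability <- NULL
  if (!is.null(config$tree) && !is.null(config$manifest)) {
    stability <- stage("stability", {
      tree <- read_newick(config$tree)
      stability_analysis(tree, comm$p_all, pair_manifest, prof_tab,
                         variant = config$unifrac_variant,
                         presence_threshold = config$presence_threshold)
    })
    write_tsv(stability$records, out("stability_records.tsv"))
    write_tsv(stability$associations, out("stability_associations.tsv"))
  }

  metabolome <- NULL
  if (!is.null(config$metabolome)) {
    metabolome <- stage("associate", {
      targ <- read.table(config$metabolome, header = TRUE, sep = "\t",
                         row.names = 1, check.names = FALSE)
      conf <- if (is.null(config$confounders)) NULL
              else read.table(config$confounders, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE)
      association_screen(comm$freq, targ, conf)
    })
    write_tsv(metabolome, out("metabolome_associations.tsv"))
  }

  manifest <- list(
    package = "auxoflux",
    version = as.character(utils::packageVersion("auxoflux")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[c("growth_threshold", "production_cutoff",
                          "min_completeness", "max_contamination",
                          "presence_threshold", "unifrac_variant")],
    inputs = Filter(Negate(is.null),
                    config[c("metadata", "abundance", "medium",
                             "models_dir", "profiles", "tree", "manifest",
                             "metabolome", "confounders")]),
    counts = list(genomes_total = nrow(meta),
                  genomes_retained = length(retained),
                  genomes_profiled = nrow(prof_tab),
                  samples = ncol(comm$p)),
    log = as.list(log_lines))
  yaml::write_yaml(manifest, out("run_manifest.yaml"))

  invisible(list(retained = retained, profiles = prof_tab, bias = bias,
                 byproducts = byprod, byproduct_associations = byprod_assoc,
                 community = comm, essentiality = ess,
                 diversity = diversity, stability = stability,
                 metabolome = metabolome, out_dir = config$out_dir))
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates a genome collection, communities, longitudinal pairs and a
#' metabolome from one [cohort_spec()] and writes every file the pipeline
#' consumes (JSON models, medium TSV, metadata TSV, abundance TSV, Newick
#' tree, manifest TSV, metabolome and confounder TSVs, plus the planted
#' truth table), returning a ready [pipeline_config()].
#'
#' @param spec a `cohort_spec`.
#' @param dir target directory.
#' @param out_dir pipeline output directory (defaults to
#'   `file.path(dir, "results")`).
#' @return list: `config` (a `pipeline_config`), `truth`, `planted`.
#' @export
simulate_inputs <- function(spec, dir, out_dir = file.path(dir, "results")) {
  dir.create(file.path(dir, "models"), showWarnings = FALSE,
             recursive = TRUE)
  coll <- generate_genome_collection(spec)
  for (g in names(coll$models))
    write_model_json(coll$models[[g]],
                     file.path(dir, "models", paste0(g, ".json")))
  write_tsv(coll$metadata, file.path(dir, "genome_metadata.tsv"))
  write_tsv(coll$truth, file.path(dir, "truth_profiles.tsv"))
  write_medium(full_medium(), file.path(dir, "medium.tsv"))

  com <- generate_communities(spec, coll$truth)
  lon <- generate_longitudinal(spec, com, coll$truth)
  write_abundance(lon$abundance, file.path(dir, "abundance.tsv"))
  ape::write.tree(com$tree, file.path(dir, "tree.nwk"))
  write_tsv(lon$manifest, file.path(dir, "paired_samples.tsv"))

  freq <- auxotrophy_frequency(com$abundance, coll$truth)
  mb <- generate_metabolome(spec, freq)
  write_tsv(data.frame(sample_id = rownames(mb$metabolome), mb$metabolome),
            file.path(dir, "metabolome.tsv"))
  write_tsv(data.frame(sample_id = rownames(mb$confounders),
                       mb$confounders),
            file.path(dir, "confounders.tsv"))

  config <- pipeline_config(
    out_dir = out_dir,
    metadata = file.path(dir, "genome_metadata.tsv"),
    abundance = file.path(dir, "abundance.tsv"),
    medium = file.path(dir, "medium.tsv"),
    models_dir = file.path(dir, "models"),
    tree = file.path(dir, "tree.nwk"),
    manifest = file.path(dir, "paired_samples.tsv"),
    metabolome = file.path(dir, "metabolome.tsv"),
    confounders = file.path(dir, "confounders.tsv"),
    seed = spec$seed)
  list(config = config, truth = coll$truth, planted = mb$planted)
}
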