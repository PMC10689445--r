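#' The 20 proteinogenic amino acids
#'
#' Reference table used throughout the screen: three-letter codes, the
#' human-host essentiality tag (His, Ile, Leu, Lys, Met, Phe, Thr, Trp,
#' Val are essential to the host) and the extracellular metabolite id each
#' amino acid exchanges through.
#'
#' @return data.frame with columns `amino_acid`, `host_essential`,
#'   `exchange_met` (20 rows, 9 host-essential).
#' @export
amino_acids <- function() {
  aa <- c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his",
          "ile", "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp",
          "tyr", "val")
  essential <- c("his", "ile", "leu", "lys", "met", "phe", "thr", "trp",
                 "val")
  data.frame(amino_acid = aa,
             host_essential = aa %in% essential,
             exchange_met = paste0(aa, "_e"),
             stringsAsFactors = FALSE)
}

#' Predict amino-acid auxotrophies by medium drop-out FBA
#'
#' For each amino acid the model is asked to grow twice: on the full
#' medium and on the same medium with that single amino acid removed.  An
#' organism is called auxotrophic for an amino acid when it grows on the
#' full medium but not without the amino acid (growth below
#' `growth_threshold`).  Exactly 1 + 20 FBA solves are performed; the
#' result is deterministic for a fixed model.
#'
#' A genome that does not grow on the full medium is unevaluable: the
#' function warns and returns `NULL` rather than assigning a profile,
#' because the auxotrophy definition conditions on growth in the original
#' medium.
#'
#' @param model a `metabolic_model`.
#' @param full_medium a `medium` containing an uptake limit for all 20
#'   amino-acid exchange metabolites (configuration error otherwise).
#' @param aa_table amino-acid reference table, see [amino_acids()].
#' @param growth_threshold growth rate (1/hr) below which the model is
#'   considered unable to grow; default 1e-6, well above the solver's
#'   feasibility tolerance and below any biologically meaningful rate.
#' @return an `auxotrophy_profile`: `genome_id`, named 0/1 `calls` over
#'   the 20 amino acids, and `n_auxotrophies = sum(calls)`; or `NULL` for
#'   an unevaluable genome.
#' @export
predict_auxotrophies <- function(model, full_medium,
                                 aa_table = amino_acids(),
                                 growth_threshold = 1e-6) {
  missing_aa <- setdiff(aa_table$exchange_met, names(full_medium))
  if (length(missing_aa))
    stop("full medium lacks amino-acid exchange metabolite(s): ",
         paste(missing_aa, collapse = ", "))

  model <- apply_medium(model, full_medium)
  prob <- fba_problem(model)
  ex_met <- exchange_metabolites(model)

  g_full <- solve_problem(prob)
  if (g_full$status != "optimal" || g_full$objective < growth_threshold) {
    warning("genome ", model$id,
            " does not grow on the full medium; unevaluable")
    return(NULL)
  }

  calls <- setNames(integer(nrow(aa_table)), aa_table$amino_acid)
  for (i in seq_len(nrow(aa_table))) {
    met <- aa_table$exchange_met[i]
    rid <- names(ex_met)[match(met, ex_met)]
    if (is.na(rid)) {
      # amino acid has no exchange in this model: it cannot be taken up,
      # so the drop-out changes nothing relative to the full medium
      calls[i] <- 0L
      next
    }
    j <- match(rid, prob$rxn_ids)
    saved <- prob$lb[j]
    prob$lb[j] <- 0
    g <- solve_problem(prob)
    prob$lb[j] <- saved
    grows <- g$status == "optimal" && g$objective >= growth_threshold
    calls[i] <- as.integer(!grows)
  }

  structure(list(genome_id = model$id, calls = calls,
                 n_auxotrophies = sum(calls)),
            class = "auxotrophy_profile")
}

#' @export
print.auxotrophy_profile <- function(x, ...) {
  cat("<auxotrophy_profile>", x$genome_id, "-", x$n_auxotrophies,
      "auxotrophies:", paste(names(x$calls)[x$calls == 1L], collapse = " "),
      "\n")
  invisible(x)
}

#' Bind auxotrophy profiles into a genome x amino-acid table
#'
#' @param profiles list of `auxotrophy_profile` (NULL entries dropped).
#' @return data.frame: `genome_id`, one 0/1 column per amino acid,
#'   `n_auxotrophies`.
#' @export
profiles_table <- function(profiles) {
  profiles <- Filter(Negate(is.null), profiles)
  if (!length(profiles)) stop("no evaluable profiles")
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(genome_id = p$genome_id, t(p$calls),
               n_auxotrophies = p$n_auxotrophies,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  tab
}

#' Write / read an auxotrophy profile table as TSV
#' @param tab table from [profiles_table()].
#' @param path file path.
#' @return `path` invisibly / the table.
#' @export
write_profiles <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

profile_matrix <- function(tab, aa_table = amino_acids()) {
  B <- as.matrix(tab[, aa_table$amino_acid, drop = FALSE])
  rownames(B) <- tab$genome_id
  storage.mode(B) <- "double"
  B
}

#' Filter genomes on assembly quality
#'
#' Retains genomes with completeness at or above and contamination at or
#' below the cutoffs (both boundaries inclusive).  Used to exclude
#' incomplete genomes whose missing biosynthesis genes would inflate the
#' auxotrophy count.
#'
#' @param meta data.frame with columns `genome_id`, `completeness` (%),
#'   `contamination` (%).
#' @param min_completeness,max_contamination cutoffs in percent;
#'   defaults 85 and 2.
#' @return character vector of retained genome ids (possibly empty).
#' @export
filter_genomes <- function(meta, min_completeness = 85,
                           max_contamination = 2) {
  stopifnot(all(c("genome_id", "completeness", "contamination") %in%
                  names(meta)))
  if (any(meta$completeness < 0 | meta$completeness > 100))
    stop("completeness must be within [0, 100]")
  if (any(meta$contamination < 0))
    stop("contamination must be nonnegative")
  meta$genome_id[meta$completeness >= min_completeness &
                   meta$contamination <= max_contamination]
}

#' Completeness-vs-auxotrophy bias check
#'
#' Spearman correlation between genome completeness and the number of
#' predicted auxotrophies.  A strong negative correlation indicates that
#' incomplete genomes inflate auxotrophy calls; this is a QC report, not a
#' filter.
#'
#' @param meta genome metadata (see [filter_genomes()]).
#' @param profiles profile table from [profiles_table()].
#' @return one-row data.frame: `estimate` (rho), `p_raw`, `n`, `note`.
#' @export
completeness_bias_check <- function(meta, profiles) {
  shared <- intersect(meta$genome_id, profiles$genome_id)
  if (length(shared) < 3)
    stop("need at least 3 genomes with both metadata and profiles")
  x <- meta$completeness[match(shared, meta$genome_id)]
  y <- profiles$n_auxotrophies[match(shared, profiles$genome_id)]
  res <- partial_spearman(x, y)
  data.frame(family = "qc", label_x = "completeness",
             label_y = "n_auxotrophies", estimate = res$rho,
             p_raw = res$p, n = res$n,
             note = if (is.na(res$rho)) "undefined (constant input)" else "",
             stringsAsFactors = FALSE)
}

#' Validation against experimentally determined auxotrophies
#'
#' Confusion matrix over all labeled (strain, amino acid) pairs, with
#' auxotrophy as the positive class: sensitivity = 100 TP / (TP + FN),
#' specificity = 100 TN / (TN + FP), accuracy = 100 (TP + TN) / total.
#' Strains without a predicted profile are skipped with a warning.
#'
#' @param predicted profile table from [profiles_table()].
#' @param experimental data.frame with columns `genome_id`, `amino_acid`,
#'   `status` (`"auxotroph"` or `"prototroph"`); typically a sparse subset
#'   of strains and amino acids with in vitro evidence.
#' @return object of class `validation_metrics`: TP, FP, TN, FN,
#'   sensitivity, specificity, accuracy (percent).
#' @export
validation_metrics <- function(predicted, experimental) {
  stopifnot(all(c("genome_id", "amino_acid", "status") %in%
                  names(experimental)))
  if (!all(experimental$status %in% c("auxotroph", "prototroph")))
    stop("experimental status must be 'auxotroph' or 'prototroph'")
  missing <- setdiff(unique(experimental$genome_id), predicted$genome_id)
  if (length(missing))
    warning("no predicted profile for strain(s), skipped: ",
            paste(missing, collapse = ", "))
  exp_use <- experimental[experimental$genome_id %in% predicted$genome_id, ]
  B <- profile_matrix(predicted)
  pred <- B[cbind(match(exp_use$genome_id, rownames(B)),
                  match(exp_use$amino_acid, colnames(B)))]
  truth <- exp_use$status == "auxotroph"
  TP <- sum(pred == 1 & truth); FN <- sum(pred == 0 & truth)
  TN <- sum(pred == 0 & !truth); FP <- sum(pred == 1 & !truth)
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN,
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP),
    accuracy = 100 * (TP + TN) / (TP + TN + FP + FN)),
    class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf(paste0("<validation_metrics> TP %d FP %d TN %d FN %d | ",
                     "sensitivity %.1f%% specificity %.1f%% accuracy %.1f%%\n"),
              x$TP, x$FP, x$TN, x$FN,
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}
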