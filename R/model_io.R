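#' Construct a metabolic model
#'
#' A metabolic model is a stoichiometric network: metabolites partitioned
#' into compartments (cytosol `"c"`, extracellular `"e"`), reactions with
#' flux bounds in mmol/gDW/hr, and a designated biomass reaction whose flux
#' is the growth rate (1/hr).  Exchange reactions connect an extracellular
#' metabolite to the environment; by convention negative exchange flux is
#' uptake and positive flux secretion.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions named list; each element a list with `stoichiometry`
#'   (named numeric, metabolite id -> signed coefficient), `lower_bound`,
#'   `upper_bound`.
#' @param biomass_reaction_id id of the biomass reaction.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, biomass_reaction_id) {
  mod <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         biomass_reaction_id = biomass_reaction_id),
    class = "metabolic_model")
  validate_model(mod)
  mod
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique metabolite ids, non-empty
#' compartments, non-empty stoichiometries resolving to declared
#' metabolites, `lower_bound <= upper_bound`, and an existing biomass
#' reaction.  Called by all constructors and readers.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending field.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  if (!all(c("id", "name", "compartment") %in% names(met)))
    stop("metabolites table must have columns id, name, compartment")
  if (anyDuplicated(met$id))
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (any(!nzchar(met$compartment)))
    stop("empty compartment for metabolite(s): ",
         paste(met$id[!nzchar(met$compartment)], collapse = ", "))
  if (length(model$reactions) == 0) stop("model has no reactions")
  rids <- names(model$reactions)
  if (is.null(rids) || anyDuplicated(rids))
    stop("reactions must be uniquely named by reaction id")
  for (rid in rids) {
    rx <- model$reactions[[rid]]
    if (length(rx$stoichiometry) == 0)
      stop("reaction ", rid, " has empty stoichiometry")
    dangling <- setdiff(names(rx$stoichiometry), met$id)
    if (length(dangling))
      stop("reaction ", rid, " references undeclared metabolite(s): ",
           paste(dangling, collapse = ", "))
    if (!is.numeric(rx$lower_bound) || !is.numeric(rx$upper_bound))
      stop("reaction ", rid, " has non-numeric bounds")
    if (rx$lower_bound > rx$upper_bound)
      stop("reaction ", rid, " has lower_bound > upper_bound")
  }
  if (!model$biomass_reaction_id %in% rids)
    stop("biomass_reaction_id '", model$biomass_reaction_id,
         "' not among reactions")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n",
      " metabolites:", nrow(x$metabolites),
      " reactions:", length(x$reactions),
      " exchanges:", sum(is_exchange(x)), "\n",
      " biomass:", x$biomass_reaction_id, "\n")
  invisible(x)
}

#' Identify exchange reactions
#'
#' An exchange reaction touches exactly one metabolite, with coefficient
#' -1, in the extracellular compartment.  This structural rule makes
#' detection independent of id conventions and serialization format.
#'
#' @param model a `metabolic_model`.
#' @param extracellular compartment id treated as extracellular.
#' @return named logical vector over reactions.
#' @export
is_exchange <- function(model, extracellular = "e") {
  comp <- setNames(model$metabolites$compartment, model$metabolites$id)
  vapply(model$reactions, function(rx) {
    s <- rx$stoichiometry
    length(s) == 1L && s[[1]] == -1 &&
      identical(unname(comp[names(s)]), extracellular)
  }, logical(1))
}

#' Exchanged metabolite of each exchange reaction
#' @param model a `metabolic_model`.
#' @return named character: reaction id -> extracellular metabolite id,
#'   for exchange reactions only.
#' @export
exchange_metabolites <- function(model) {
  ex <- names(which(is_exchange(model)))
  vapply(model$reactions[ex], function(rx) names(rx$stoichiometry), "")
}

#' Stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return dense matrix S, one row per metabolite, one column per reaction.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (rid in rids) {
    s <- model$reactions[[rid]]$stoichiometry
    S[names(s), rid] <- as.numeric(s)
  }
  S
}

reaction_bounds <- function(model) {
  lb <- vapply(model$reactions, function(r) r$lower_bound, 0.0)
  ub <- vapply(model$reactions, function(r) r$upper_bound, 0.0)
  list(lb = lb, ub = ub)
}

#' Read a metabolic model from the package's JSON dialect
#'
#' The dialect is a single JSON object with fields `id`, `metabolites`
#' (array of `{id, name, compartment}`), `reactions` (array of
#' `{id, stoichiometry: {met: coef}, lower_bound, upper_bound}`) and
#' `biomass_reaction_id`.
#'
#' @param path file path.
#' @return a validated `metabolic_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  for (field in c("id", "metabolites", "reactions", "biomass_reaction_id"))
    if (is.null(doc[[field]]))
      stop("malformed model document: missing field '", field, "'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    for (f in c("id", "compartment"))
      if (is.null(m[[f]]))
        stop("malformed metabolite entry: missing field '", f, "'")
    data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment, stringsAsFactors = FALSE)
  }))
  rxns <- list()
  for (r in doc$reactions) {
    for (f in c("id", "stoichiometry", "lower_bound", "upper_bound"))
      if (is.null(r[[f]]))
        stop("malformed reaction entry: missing field '", f, "'")
    rxns[[r$id]] <- list(
      stoichiometry = unlist(r$stoichiometry),
      lower_bound = as.numeric(r$lower_bound),
      upper_bound = as.numeric(r$upper_bound))
  }
  metabolic_model(doc$id, mets, rxns, doc$biomass_reaction_id)
}

#' Write a metabolic model to the package's JSON dialect
#'
#' `read_model_json(write_model_json(m, f))` reproduces `m` field by field.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(names(model$reactions), function(rid) {
      rx <- model$reactions[[rid]]
      list(id = rid,
           stoichiometry = as.list(rx$stoichiometry),
           lower_bound = rx$lower_bound,
           upper_bound = rx$upper_bound)
    }),
    biomass_reaction_id = model$biomass_reaction_id)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a growth medium
#'
#' A medium maps extracellular metabolite ids to maximal uptake rates
#' (mmol/gDW/hr, nonnegative).  Accepts a two-column TSV
#' (`metabolite_id`, `max_uptake`) or a JSON object `{met: limit}`.
#'
#' @param path file path (`.json` or TSV).
#' @return named numeric vector of class `medium`.
#' @export
read_medium <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- unlist(jsonlite::read_json(path))
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (!all(c("metabolite_id", "max_uptake") %in% names(tab)))
      stop("medium TSV needs columns metabolite_id, max_uptake")
    x <- setNames(as.numeric(tab$max_uptake), tab$metabolite_id)
  }
  medium(x)
}

#' Construct a growth medium
#' @param uptake_limits named nonnegative numeric; names are extracellular
#'   metabolite ids.
#' @return named numeric vector of class `medium`.
#' @export
medium <- function(uptake_limits) {
  x <- unlist(uptake_limits)
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("medium entries must be named by metabolite id")
  if (any(x < 0)) stop("medium uptake limits must be nonnegative")
  structure(as.numeric(x), names = names(x), class = "medium")
}

#' Write a medium as TSV
#' @param med a `medium`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(med, path) {
  write.table(data.frame(metabolite_id = names(med),
                         max_uptake = as.numeric(med)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a growth medium to a model
#'
#' Sets each exchange reaction's lower bound to minus the medium's uptake
#' limit for its metabolite, and to zero for every exchange whose
#' metabolite is absent from the medium (a closed environment for that
#' nutrient).  Upper bounds are untouched, so secretion is always allowed;
#' non-exchange reactions are untouched.  Medium entries without a matching
#' exchange reaction are skipped with a warning, which allows one community
#' medium to be applied to many genomes.
#'
#' @param model a `metabolic_model`.
#' @param med a `medium`.
#' @return the model with updated exchange bounds.
#' @export
apply_medium <- function(model, med) {
  ex_met <- exchange_metabolites(model)
  unmatched <- setdiff(names(med), ex_met)
  if (length(unmatched))
    warning("medium metabolite(s) without exchange reaction skipped: ",
            paste(unmatched, collapse = ", "))
  for (rid in names(ex_met)) {
    m <- ex_met[[rid]]
    model$reactions[[rid]]$lower_bound <-
      if (m %in% names(med)) -as.numeric(med[[m]]) else 0
  }
  model
}
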