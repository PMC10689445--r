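#' Assemble the linear-programming view of a model
#'
#' Internal-but-exported helper: the stoichiometric matrix, bounds and
#' biomass objective index in one list, so that repeated solves (e.g. the
#' 21 solves of a drop-out screen) do not rebuild the matrix.
#'
#' @param model a `metabolic_model`.
#' @return list with `S`, `lb`, `ub`, `obj` (0/1 vector), `rxn_ids`,
#'   `biomass`.
#' @export
fba_problem <- function(model) {
  S <- stoichiometric_matrix(model)
  bnd <- reaction_bounds(model)
  obj <- as.numeric(colnames(S) == model$biomass_reaction_id)
  list(S = S, lb = bnd$lb, ub = bnd$ub, obj = obj,
       rxn_ids = colnames(S), biomass = model$biomass_reaction_id)
}

solve_problem <- function(prob) {
  lp_solve(prob$obj, prob$S, rep(0, nrow(prob$S)), prob$lb, prob$ub,
           maximize = TRUE)
}

flux_solution <- function(status, growth_rate, fluxes) {
  structure(list(status = status, growth_rate = growth_rate,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution>", x$status,
      if (x$status == "optimal") sprintf(" growth %.6g /hr", x$growth_rate),
      "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes flux through the biomass reaction subject to steady state
#' (`S v = 0`) and the reaction bounds.  The optimal objective value is the
#' predicted growth rate (1/hr).  A failed or non-optimal solve is reported
#' in `status` (`"infeasible"`, `"unbounded"`, `"maxit"`, `"numerical"`),
#' never as a silent zero.
#'
#' @param model a `metabolic_model`.
#' @return a `flux_solution`: `status`, `growth_rate`, named `fluxes`.
#' @export
solve_fba <- function(model) {
  prob <- fba_problem(model)
  res <- solve_problem(prob)
  if (res$status != "optimal")
    return(flux_solution(res$status, NA_real_, NULL))
  flux_solution("optimal", res$objective,
                setNames(res$x, prob$rxn_ids))
}

#' Parsimonious flux balance analysis
#'
#' Fixes growth at (a fraction of) the FBA optimum and minimizes the total
#' absolute flux `sum(|v|)`.  Reversible fluxes are split into nonnegative
#' forward/backward pairs, keeping the problem a pure LP; the result is a
#' deterministic representative of the optimal face, suitable for reading
#' exchange fluxes when the FBA optimum is degenerate.
#'
#' @param model a `metabolic_model`; each reaction's bounds must straddle
#'   zero (`lb <= 0 <= ub`), which holds for all conventional
#'   constraint-based models.
#' @param optimum_fraction growth retained, in (0, 1]; default 1.
#' @return a `flux_solution`; `growth_rate >= optimum_fraction * g*`.
#' @export
solve_pfba <- function(model, optimum_fraction = 1) {
  stopifnot(optimum_fraction > 0, optimum_fraction <= 1)
  prob <- fba_problem(model)
  base <- solve_problem(prob)
  if (base$status != "optimal")
    return(flux_solution(base$status, NA_real_, NULL))
  gstar <- base$objective
  if (gstar <= 0)
    stop("solve_pfba requires positive FBA growth")
  if (any(prob$lb > 0) || any(prob$ub < 0))
    stop("solve_pfba requires reaction bounds straddling zero")

  n <- ncol(prob$S); m <- nrow(prob$S)
  # v = p - q, p,q >= 0; minimize sum(p + q)
  # rows: S p - S q = 0;  biomass row: v_b - slack = fraction * g*
  A <- cbind(prob$S, -prob$S, 0)
  brow <- c(prob$obj, -prob$obj, -1)
  A <- rbind(A, brow)
  b <- c(rep(0, m), optimum_fraction * gstar)
  lb <- rep(0, 2 * n + 1)
  ub <- c(pmax(prob$ub, 0), pmax(-prob$lb, 0), Inf)
  objc <- c(rep(1, 2 * n), 0)

  res <- lp_solve(objc, A, b, lb, ub, maximize = FALSE)
  if (res$status != "optimal")
    return(flux_solution(res$status, NA_real_, NULL))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  fluxes <- setNames(v, prob$rxn_ids)
  flux_solution("optimal", unname(fluxes[prob$biomass]), fluxes)
}

#' Write a flux solution as TSV
#' @param solution a `flux_solution` with status `"optimal"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(solution, path) {
  stopifnot(solution$status == "optimal")
  write.table(data.frame(reaction_id = names(solution$fluxes),
                         flux = as.numeric(solution$fluxes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
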