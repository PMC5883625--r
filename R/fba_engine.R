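# Flux balance analysis: maximise a linear objective over S v = 0 with box
# flux bounds. The LP kernel (lp.R) sits behind this module's contract;
# only the optimal objective value is guaranteed reproducible, since flux
# vectors at degenerate optima are not unique.

#' Construct an FBA problem
#'
#' @param model a `"metabolic_model"`.
#' @param objective_id reaction whose flux is optimised; defaults to the
#'   model's objective.
#' @param sense `"max"` or `"min"`.
#' @return An object of class `"fba_problem"` carrying the model and a set
#'   of bound overrides (initially empty).
#' @export
#' @examples
#' m <- build_reduced_model()
#' sol <- solve_fba(fba_problem(m))
#' sol$objective_value
fba_problem <- function(model, objective_id = model$objective_id,
                        sense = c("max", "min")) {
  sense <- match.arg(sense)
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (length(model$reactions) > 0L && !objective_id %in% rxn_ids)
    stop(sprintf("objective reaction '%s' not in model", objective_id))
  structure(list(model = model, objective_id = objective_id, sense = sense,
                 overrides = list()),
            class = "fba_problem")
}

#' Fix a reaction flux
#'
#' Returns a new problem in which the reaction's lower and upper bound are
#' both set to `value`, replacing the model's declared bounds. The input
#' problem is unchanged.
#'
#' @param problem an `"fba_problem"`.
#' @param reaction_id reaction to fix.
#' @param value flux value in mmol/gDW/h.
#' @return A new `"fba_problem"`.
#' @export
fix_flux <- function(problem, reaction_id, value) {
  set_flux_bounds(problem, reaction_id, value, value)
}

#' Override the bounds of a reaction
#'
#' The override replaces the model's declared bounds for this problem
#' (it may lie outside them); this replacement semantics is deliberate so
#' scans can both restrict and open up reactions.
#'
#' @param problem an `"fba_problem"`.
#' @param reaction_id reaction to bound.
#' @param lower,upper new finite bounds, `lower <= upper`.
#' @return A new `"fba_problem"`.
#' @export
set_flux_bounds <- function(problem, reaction_id, lower, upper) {
  stopifnot(inherits(problem, "fba_problem"))
  rxn_ids <- vapply(problem$model$reactions, `[[`, "", "id")
  if (!reaction_id %in% rxn_ids)
    stop(sprintf("unknown reaction id '%s'", reaction_id))
  if (lower > upper)
    stop(sprintf("override for '%s': lower (%g) exceeds upper (%g)",
                 reaction_id, lower, upper))
  problem$overrides[[reaction_id]] <- c(lower = lower, upper = upper)
  problem
}

#' Solve an FBA problem
#'
#' @param problem an `"fba_problem"`.
#' @param tol feasibility tolerance on S v = 0 and the bounds.
#' @return An object of class `"flux_solution"`: a list with `status`
#'   (`"optimal"` or `"infeasible"`), `objective_value` (flux of the
#'   objective reaction; `NA` if infeasible) and `fluxes` (named vector).
#'   With finite box bounds throughout, the feasible set is a polytope and
#'   an unbounded status cannot arise.
#' @export
solve_fba <- function(problem, tol = 1e-9) {
  stopifnot(inherits(problem, "fba_problem"))
  model <- problem$model
  if (length(model$reactions) == 0L)
    return(structure(list(status = "optimal", objective_value = 0,
                          fluxes = numeric(0)), class = "flux_solution"))
  S <- stoichiometry_matrix(model)
  bounds <- flux_bounds(model)
  lower <- bounds$lower
  upper <- bounds$upper
  names(lower) <- names(upper) <- bounds$reaction_id
  for (id in names(problem$overrides)) {
    lower[id] <- problem$overrides[[id]]["lower"]
    upper[id] <- problem$overrides[[id]]["upper"]
  }
  obj <- setNames(numeric(ncol(S)), colnames(S))
  obj[problem$objective_id] <- 1
  res <- lp_solve(obj, S, rep(0, nrow(S)), lower, upper,
                  sense = problem$sense, tol = tol)
  if (res$status != "optimal")
    return(structure(list(status = res$status,
                          objective_value = NA_real_, fluxes = NULL),
                     class = "flux_solution"))
  fluxes <- setNames(res$x, colnames(S))
  structure(list(status = "optimal",
                 objective_value = unname(fluxes[problem$objective_id]),
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: status %s, objective %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}
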