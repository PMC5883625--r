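# Robustness scan of the three malate synthesis routes. For each route the
# scan fixes the route's reactions to a common imposed flux, zeroes the
# other two routes, fixes the biomass flux to an imposed growth value and
# maximises PMA synthesis — producing one optimal-PMA surface per route
# over (route flux x growth).

#' Packaged malate-route definitions
#'
#' The three malate synthesis routes of the reduced model:
#' \describe{
#'   \item{oxidative_tca}{oxoglutarate dehydrogenase (`AKGDH`), aconitate
#'     hydratase (`ACONT`), fumarase (`FUM`), succinate dehydrogenase
#'     (`SDH`), succinate-CoA ligase (`SUCOAS`).}
#'   \item{reductive_tca}{cytosolic malate dehydrogenase (`MDH_c`).}
#'   \item{glyoxylate_shunt}{fumarase (`FUM`), isocitrate lyase (`ICL`),
#'     malate synthase (`MAS`, the glyoxylate-consuming, malate-producing
#'     step).}
#' }
#' Fumarase appears in both the oxidative and glyoxylate lists; during a
#' scan the scanned route's constraint takes precedence over the zeroing
#' of the other routes (see [apply_route_constraints()]).
#'
#' @return Named list of `"route_definition"` objects with fields `name`
#'   and `reaction_ids`.
#' @export
route_definitions <- function() {
  def <- function(name, ids)
    structure(list(name = name, reaction_ids = ids),
              class = "route_definition")
  list(
    oxidative_tca = def("oxidative_tca",
                        c("AKGDH", "ACONT", "FUM", "SDH", "SUCOAS")),
    reductive_tca = def("reductive_tca", "MDH_c"),
    glyoxylate_shunt = def("glyoxylate_shunt", c("FUM", "ICL", "MAS")))
}

resolve_route <- function(route) {
  if (inherits(route, "route_definition")) return(route)
  defs <- route_definitions()
  if (is.character(route) && length(route) == 1L && route %in% names(defs))
    return(defs[[route]])
  stop(sprintf("unknown route '%s'", paste(route, collapse = ",")))
}

carbon_source_exchange <- c(glucose = "EX_glc", sucrose = "EX_suc")

#' Constrain a model for one cell of a route scan
#'
#' Fixes every reaction of the scanned route to `route_flux` and every
#' reaction of the other two routes to 0 — except reactions shared with
#' the scanned route, for which the scanned constraint wins. The
#' mitochondrial malate dehydrogenase (`MDH_m`) is fixed to 0 in all three
#' scans, biomass is fixed to `growth`, and substrate uptake is bounded at
#' `uptake_rate` on the chosen carbon source (the other source is closed).
#'
#' @param model a `"metabolic_model"` (typically [build_reduced_model()]).
#' @param route a `"route_definition"` or one of `"oxidative_tca"`,
#'   `"reductive_tca"`, `"glyoxylate_shunt"`.
#' @param route_flux imposed route flux, mmol/gDW/h (>= 0).
#' @param growth imposed biomass flux, gDW/h (>= 0).
#' @param carbon_source `"glucose"` or `"sucrose"`.
#' @param uptake_rate maximum substrate uptake, mmol/gDW/h; default 10 for
#'   glucose and its hexose equivalent 5 for sucrose.
#' @return An `"fba_problem"` maximising PMA synthesis.
#' @export
apply_route_constraints <- function(model, route, route_flux, growth,
                                    carbon_source = c("glucose", "sucrose"),
                                    uptake_rate = NULL) {
  carbon_source <- match.arg(carbon_source)
  route <- resolve_route(route)
  stopifnot(route_flux >= 0, growth >= 0)
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  missing_rxn <- setdiff(route$reaction_ids, rxn_ids)
  if (length(missing_rxn))
    stop(sprintf("route '%s': reaction(s) missing from model: %s",
                 route$name, paste(missing_rxn, collapse = ", ")))
  if (is.null(uptake_rate))
    uptake_rate <- if (carbon_source == "glucose") 10 else 5
  prob <- fba_problem(model, objective_id = model$objective_id,
                      sense = "max")
  # carbon entry: open the chosen source, close the other
  for (src in names(carbon_source_exchange)) {
    ex <- carbon_source_exchange[[src]]
    if (!ex %in% rxn_ids) {
      if (src == carbon_source)
        stop(sprintf("carbon source exchange '%s' missing from model", ex))
      next
    }
    if (src == carbon_source)
      prob <- set_flux_bounds(prob, ex, -uptake_rate, 0)
    else
      prob <- set_flux_bounds(prob, ex, 0, 0)
  }
  # other routes to zero, scanned route wins on shared reactions
  defs <- route_definitions()
  for (other in defs) {
    if (other$name == route$name) next
    for (id in setdiff(other$reaction_ids, route$reaction_ids))
      if (id %in% rxn_ids) prob <- fix_flux(prob, id, 0)
  }
  for (id in route$reaction_ids)
    prob <- fix_flux(prob, id, route_flux)
  if ("MDH_m" %in% rxn_ids) prob <- fix_flux(prob, "MDH_m", 0)
  if ("BIOMASS" %in% rxn_ids) prob <- fix_flux(prob, "BIOMASS", growth)
  prob
}

#' Scan the optimal-PMA surface for one route
#'
#' Evaluates [solve_fba()] on [apply_route_constraints()] over a regular
#' grid of imposed route flux (default 0 to 140 mmol/gDW/h in 71 steps)
#' and imposed growth (default 0 to 1 gDW/h in 21 steps). Infeasible cells
#' are recorded as `NA` with status `"infeasible"` — deliberately distinct
#' from a feasible optimum of 0.
#'
#' @param model a `"metabolic_model"`.
#' @param route route name or `"route_definition"`.
#' @param flux_max,flux_steps route-flux grid: `flux_steps` equally spaced
#'   values on `[0, flux_max]`.
#' @param growth_max,growth_steps growth grid on `[0, growth_max]`.
#' @param carbon_source `"glucose"` or `"sucrose"`.
#' @param uptake_rate passed to [apply_route_constraints()].
#' @return An object of class `"scan_grid"`: list with `route`,
#'   `carbon_source`, `route_flux_values`, `growth_values` and matrices
#'   `pma_optimum` (flux x growth, `NA` = infeasible) and `status`.
#' @export
scan_surface <- function(model, route, flux_max = 140, flux_steps = 71,
                         growth_max = 1, growth_steps = 21,
                         carbon_source = c("glucose", "sucrose"),
                         uptake_rate = NULL) {
  carbon_source <- match.arg(carbon_source)
  route <- resolve_route(route)
  stopifnot(flux_steps >= 2, growth_steps >= 2)
  fvals <- seq(0, flux_max, length.out = flux_steps)
  gvals <- seq(0, growth_max, length.out = growth_steps)
  pma <- matrix(NA_real_, flux_steps, growth_steps,
                dimnames = list(signif(fvals, 10), signif(gvals, 10)))
  status <- matrix("infeasible", flux_steps, growth_steps,
                   dimnames = dimnames(pma))
  for (i in seq_along(fvals)) {
    for (j in seq_along(gvals)) {
      prob <- apply_route_constraints(model, route, fvals[i], gvals[j],
                                      carbon_source, uptake_rate)
      sol <- tryCatch(solve_fba(prob), error = function(e)
        stop(sprintf("scan cell (route_flux=%g, growth=%g) failed: %s",
                     fvals[i], gvals[j], conditionMessage(e))))
      status[i, j] <- sol$status
      if (sol$status == "optimal") pma[i, j] <- sol$objective_value
    }
  }
  structure(list(route = route, carbon_source = carbon_source,
                 route_flux_values = fvals, growth_values = gvals,
                 pma_optimum = pma, status = status),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf(
    "scan_grid: route %s (%s), %d x %d grid, max PMA %s mmol/gDW/h\n",
    x$route$name, x$carbon_source, length(x$route_flux_values),
    length(x$growth_values),
    format(suppressWarnings(max(x$pma_optimum, na.rm = TRUE)))))
  invisible(x)
}

#' Long-format view of a scan grid
#'
#' @param x a `"scan_grid"`.
#' @param ... unused.
#' @return data.frame with columns `route`, `carbon_source`, `route_flux`,
#'   `growth`, `pma_optimum`, `status`.
#' @export
as.data.frame.scan_grid <- function(x, ...) {
  grid <- expand.grid(route_flux = x$route_flux_values,
                      growth = x$growth_values)
  data.frame(route = x$route$name, carbon_source = x$carbon_source,
             grid, pma_optimum = as.vector(x$pma_optimum),
             status = as.vector(x$status), stringsAsFactors = FALSE)
}

#' Summarise route-scan grids
#'
#' Per grid: the optimal PMA rate over the whole surface, the route flux
#' attaining it (smallest such flux on ties), the optimum restricted to
#' the zero-growth column, and the cutoff flux — the smallest scanned
#' route flux beyond the arg-max at which the optimum is 0 or the cell is
#' infeasible at every growth value (`NA` if the scan never reaches it).
#'
#' @param grids a `"scan_grid"` or list of them.
#' @return data.frame with one row per grid: `route`, `carbon_source`,
#'   `pma_optimum`, `argmax_route_flux`, `optimum_at_zero_growth`,
#'   `cutoff_flux`.
#' @export
summarize_scans <- function(grids) {
  if (inherits(grids, "scan_grid")) grids <- list(grids)
  if (length(grids) == 0L) stop("no scan grids supplied")
  rows <- lapply(grids, function(g) {
    stopifnot(inherits(g, "scan_grid"))
    best_per_flux <- apply(g$pma_optimum, 1, function(row)
      if (all(is.na(row))) NA_real_ else max(row, na.rm = TRUE))
    finite <- which(!is.na(best_per_flux))
    if (!length(finite)) stop(sprintf("route '%s': empty feasible grid",
                                      g$route$name))
    opt <- max(best_per_flux[finite])
    argmax_i <- finite[which.max(best_per_flux[finite])]  # smallest on ties
    dead <- which(is.na(best_per_flux) | abs(best_per_flux) < 1e-9)
    dead <- dead[dead >= argmax_i]   # the arg-max itself counts when opt = 0
    cutoff <- if (length(dead)) g$route_flux_values[min(dead)] else NA_real_
    zero_g <- g$pma_optimum[, 1]
    data.frame(route = g$route$name, carbon_source = g$carbon_source,
               pma_optimum = opt,
               argmax_route_flux = g$route_flux_values[argmax_i],
               optimum_at_zero_growth =
                 if (all(is.na(zero_g))) NA_real_ else max(zero_g, na.rm = TRUE),
               cutoff_flux = cutoff, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
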