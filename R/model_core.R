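# Data model for constraint-based metabolic models: metabolites, reactions,
# the model container with its stoichiometric matrix, JSON (de)serialisation
# and elemental (carbon) bookkeeping.

COMPARTMENTS <- c("cytosol", "mitochondrion", "extracellular")
ELEMENTS <- c("C", "H", "O", "N", "P", "S")
REACTION_KINDS <- c("internal", "exchange", "biomass")

#' Create a metabolite
#'
#' @param id short unique token, e.g. `"mal_c"`.
#' @param name free-text name.
#' @param compartment one of `"cytosol"`, `"mitochondrion"`,
#'   `"extracellular"`.
#' @param formula named list or vector of non-negative integer element
#'   counts; only the elements C, H, O, N, P, S are allowed.
#' @param bookkeeping logical; `TRUE` marks free water/proton-like species
#'   whose hydrogen and oxygen are not tracked exactly in lumped reactions.
#' @return An object of class `"metabolite"`.
#' @export
#' @examples
#' metabolite("mal_c", "L-malate", "cytosol", c(C = 4, H = 6, O = 5))
metabolite <- function(id, name = id, compartment = "cytosol",
                       formula = NULL, bookkeeping = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!compartment %in% COMPARTMENTS)
    stop(sprintf("metabolite '%s': unknown compartment '%s'", id, compartment))
  if (!is.null(formula)) {
    formula <- unlist(formula)
    bad <- setdiff(names(formula), ELEMENTS)
    if (length(bad))
      stop(sprintf("metabolite '%s': formula contains unknown element(s) %s",
                   id, paste(bad, collapse = ", ")))
    if (any(formula < 0) || any(formula != round(formula)))
      stop(sprintf("metabolite '%s': element counts must be non-negative integers", id))
    formula <- as.list(formula)
  }
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula, bookkeeping = isTRUE(bookkeeping)),
            class = "metabolite")
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed: negative values are consumed,
#' positive values produced. Bounds are fluxes in mmol/gDW/h.
#'
#' @param id short unique token.
#' @param stoichiometry named numeric vector or list, metabolite id ->
#'   signed coefficient.
#' @param name free-text name.
#' @param lower_bound,upper_bound flux bounds, `lower_bound <= upper_bound`.
#' @param kind `"internal"`, `"exchange"` or `"biomass"`. Exchange and
#'   biomass reactions are exempt from elemental balancing.
#' @return An object of class `"reaction"`.
#' @export
reaction <- function(id, stoichiometry, name = id,
                     lower_bound = 0, upper_bound = 1000,
                     kind = "internal") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  st <- unlist(stoichiometry)
  if (is.null(names(st)) || any(!nzchar(names(st))))
    stop(sprintf("reaction '%s': stoichiometry must be a named vector", id))
  if (anyDuplicated(names(st)))
    stop(sprintf("reaction '%s': duplicate metabolite in stoichiometry", id))
  if (!kind %in% REACTION_KINDS)
    stop(sprintf("reaction '%s': unknown kind '%s'", id, kind))
  if (!is.finite(lower_bound) || !is.finite(upper_bound))
    stop(sprintf("reaction '%s': bounds must be finite", id))
  if (lower_bound > upper_bound)
    stop(sprintf("reaction '%s': lower_bound (%g) exceeds upper_bound (%g)",
                 id, lower_bound, upper_bound))
  structure(list(id = id, name = name, stoichiometry = as.list(st),
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 kind = kind),
            class = "reaction")
}

#' Assemble and validate a metabolic model
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the default objective reaction (by convention
#'   the PMA synthesis reaction).
#' @param notes optional character notes stored with the model.
#' @return An object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, objective_id,
                            notes = character()) {
  model <- structure(list(metabolites = metabolites, reactions = reactions,
                          objective_id = objective_id, notes = notes),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, dangling stoichiometry references, bound ordering
#' and the presence of the objective reaction; each violation raises a
#' targeted error.
#'
#' @param model a `"metabolic_model"`.
#' @return The model, invisibly, if valid.
#' @export
validate_model <- function(model) {
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  dup <- met_ids[duplicated(met_ids)]
  if (length(dup))
    stop(sprintf("duplicate metabolite id(s): %s",
                 paste(unique(dup), collapse = ", ")))
  dup <- rxn_ids[duplicated(rxn_ids)]
  if (length(dup))
    stop(sprintf("duplicate reaction id(s): %s",
                 paste(unique(dup), collapse = ", ")))
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown))
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   r$id, paste(unknown, collapse = ", ")))
    if (r$lower_bound > r$upper_bound)
      stop(sprintf("reaction '%s': lower_bound exceeds upper_bound", r$id))
  }
  if (length(model$reactions) > 0 &&
      !model$objective_id %in% rxn_ids)
    stop(sprintf("objective_id '%s' is not a reaction id", model$objective_id))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions, objective '%s'\n",
              length(x$metabolites), length(x$reactions), x$objective_id))
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `"metabolic_model"`.
#' @return Dense numeric matrix S (metabolites x reactions), with
#'   dimnames set to metabolite and reaction ids.
#' @export
stoichiometry_matrix <- function(model) {
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- unlist(r$stoichiometry)
  S
}

#' Flux bounds of a model
#'
#' @param model a `"metabolic_model"`.
#' @return A data.frame with columns `reaction_id`, `lower`, `upper`.
#' @export
flux_bounds <- function(model) {
  data.frame(
    reaction_id = vapply(model$reactions, `[[`, "", "id"),
    lower = vapply(model$reactions, `[[`, 0, "lower_bound"),
    upper = vapply(model$reactions, `[[`, 0, "upper_bound"),
    stringsAsFactors = FALSE)
}

#' Load a metabolic model from JSON
#'
#' The schema has top-level keys `metabolites`, `reactions`, `objective_id`
#' and `notes`; see the packaged reduced model under
#' `system.file("extdata", "apullulans_core_synthetic.json",
#' package = "pmaflux")` for a documented instance.
#'
#' @param path path to a model JSON file.
#' @return A validated `"metabolic_model"`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  raw <- jsonlite::read_json(path)
  for (key in c("metabolites", "reactions", "objective_id"))
    if (is.null(raw[[key]]))
      stop(sprintf("model JSON is missing required field '%s'", key))
  mets <- lapply(raw$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite entry without 'id' field")
    metabolite(m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "cytosol",
               formula = m$formula,
               bookkeeping = isTRUE(m$bookkeeping))
  })
  rxns <- lapply(raw$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry without 'id' field")
    if (is.null(r$stoichiometry))
      stop(sprintf("reaction '%s' without 'stoichiometry' field", r$id))
    reaction(r$id, stoichiometry = r$stoichiometry, name = r$name %||% r$id,
             lower_bound = r$lower_bound %||% 0,
             upper_bound = r$upper_bound %||% 1000,
             kind = r$kind %||% "internal")
  })
  metabolic_model(mets, rxns, objective_id = raw$objective_id,
                  notes = unlist(raw$notes) %||% character())
}

#' Save a metabolic model to JSON
#'
#' Inverse of [load_model()]; `load_model(save_model(m, f))` reproduces an
#' equivalent model (same ids, stoichiometries, bounds) up to key ordering.
#'
#' @param model a `"metabolic_model"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  validate_model(model)
  out <- list(
    metabolites = lapply(model$metabolites, function(m) {
      e <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.null(m$formula)) e$formula <- m$formula
      if (isTRUE(m$bookkeeping)) e$bookkeeping <- TRUE
      e
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name, stoichiometry = r$stoichiometry,
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           kind = r$kind)
    }),
    objective_id = model$objective_id,
    notes = as.list(model$notes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Per-reaction carbon balance report
#'
#' For every internal reaction, reports the net carbon imbalance in atoms
#' (carbon consumed minus carbon produced, i.e. a reaction missing a CO2
#' substrate scores -1); exchange and biomass reactions are flagged exempt
#' and not scored. A non-zero imbalance signals a mis-specified reaction.
#'
#' @param model a `"metabolic_model"`.
#' @return A data.frame with columns `reaction_id`, `kind`,
#'   `carbon_imbalance` (atoms; `NA` for exempt reactions) and `exempt`.
#' @export
carbon_balance_report <- function(model) {
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  carbons <- vapply(model$metabolites, function(m) {
    if (is.null(m$formula)) NA_real_ else as.numeric(m$formula$C %||% 0)
  }, 0)
  names(carbons) <- met_ids
  rows <- lapply(model$reactions, function(r) {
    exempt <- r$kind %in% c("exchange", "biomass")
    imb <- NA_real_
    if (!exempt) {
      cc <- carbons[names(r$stoichiometry)]
      if (anyNA(cc))
        stop(sprintf("reaction '%s': metabolite '%s' has no formula",
                     r$id, names(r$stoichiometry)[which(is.na(cc))[1L]]))
      imb <- -sum(unlist(r$stoichiometry) * cc)
    }
    data.frame(reaction_id = r$id, kind = r$kind, carbon_imbalance = imb,
               exempt = exempt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
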