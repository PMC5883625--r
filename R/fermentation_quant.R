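# Deterministic quantitation arithmetic for fermentation outcomes:
# PMA <-> malic acid hydrolysis conversion, titer / yield / productivity,
# percent change and qPCR relative expression (2^-ddCt).

# standard atomic masses (IUPAC 2021 abridged)
ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999)

#' Mass ratio of a malate residue to free malic acid
#'
#' Polymalic acid is a polyester of L-malic acid: each ester bond releases
#' one water on hydrolysis, so one gram of polymer yields more than one
#' gram of free acid. The ratio is
#' `(MW(C4H6O5) - MW(H2O)) / MW(C4H6O5) = 0.86565...`, conventionally
#' rounded to 0.87.
#'
#' @return The exact residue-to-acid mass ratio (dimensionless).
#' @export
#' @examples
#' residue_mass_ratio()                  # 0.8656...
#' round_half_up(residue_mass_ratio(), 2)  # 0.87
residue_mass_ratio <- function() {
  mw_malic <- 4 * ATOMIC_MASS["C"] + 6 * ATOMIC_MASS["H"] +
    5 * ATOMIC_MASS["O"]
  mw_water <- 2 * ATOMIC_MASS["H"] + ATOMIC_MASS["O"]
  unname((mw_malic - mw_water) / mw_malic)
}

#' Round half away from zero
#'
#' Reported fermentation quantities are conventionally rounded half-up at
#' the printed precision (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

check_factor <- function(factor) {
  if (!is.finite(factor) || factor <= 0 || factor >= 1)
    stop("conversion factor must lie strictly between 0 and 1")
}

#' Convert between PMA and malic-acid concentrations
#'
#' `pma_from_ma()` multiplies by the residue mass ratio;
#' `ma_from_pma()` divides. The factor is always explicit — the exact
#' ratio from [residue_mass_ratio()] or the conventional rounded 0.87 —
#' because published PMA/MA pairs are not mutually consistent under a
#' single factor.
#'
#' @param ma_g_L,pma_g_L concentrations in g/L (>= 0).
#' @param factor residue-to-acid mass ratio in (0, 1).
#' @return Converted concentration in g/L.
#' @export
#' @examples
#' pma_from_ma(94.2, residue_mass_ratio())  # ~81.5
#' ma_from_pma(33.91, 0.87)                 # ~38.98
pma_from_ma <- function(ma_g_L, factor = residue_mass_ratio()) {
  check_factor(factor)
  if (any(ma_g_L < 0)) stop("concentration must be non-negative")
  ma_g_L * factor
}

#' @rdname pma_from_ma
#' @export
ma_from_pma <- function(pma_g_L, factor = residue_mass_ratio()) {
  check_factor(factor)
  if (any(pma_g_L < 0)) stop("concentration must be non-negative")
  pma_g_L / factor
}

#' Volumetric productivity
#'
#' @param titer_g_L final product titer, g/L.
#' @param elapsed_h elapsed fermentation time, h (> 0).
#' @return Productivity in g/L/h.
#' @export
#' @examples
#' productivity(94.2, 140)  # 0.672... -> 0.67 at 2 dp
productivity <- function(titer_g_L, elapsed_h) {
  if (any(elapsed_h <= 0)) stop("elapsed time must be positive")
  titer_g_L / elapsed_h
}

#' Product yield on substrate
#'
#' @param product_g_L product formed, g/L.
#' @param substrate_consumed_g_L substrate consumed, g/L (> 0).
#' @return Yield in g product per g substrate.
#' @export
yield_g_g <- function(product_g_L, substrate_consumed_g_L) {
  if (any(substrate_consumed_g_L <= 0))
    stop("substrate consumed must be positive")
  product_g_L / substrate_consumed_g_L
}

#' Percent change relative to a reference
#'
#' `(new - reference) / reference * 100`. Note the asymmetry:
#' `percent_change(a, b)` and `percent_change(b, a)` are not negatives of
#' each other — both are reported relative to their own reference.
#'
#' @param new_value new quantity.
#' @param reference_value reference quantity (> 0).
#' @return Percent change.
#' @export
#' @examples
#' percent_change(33.91, 24.10)  # 40.7
percent_change <- function(new_value, reference_value) {
  if (any(reference_value <= 0)) stop("reference must be positive")
  (new_value - reference_value) / reference_value * 100
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_reference,treated) -
#' (Ct_target,control - Ct_reference,control)`; relative expression is
#' `2^-ddCt`.
#'
#' @param ct_target_treated,ct_reference_treated,ct_target_control,ct_reference_control
#'   cycle-threshold values; the reference is the housekeeping gene.
#' @return Fold change of the target in treated vs control.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  cts <- c(ct_target_treated, ct_reference_treated,
           ct_target_control, ct_reference_control)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Read a fermentation time course from CSV
#'
#' Expected columns: `time_h`, `biomass_g_L`, `pma_g_L`, `ma_g_L` and any
#' of `sucrose_g_L`, `glucose_g_L`, `fructose_g_L`. Time must be
#' non-decreasing and all concentrations non-negative.
#'
#' @param path CSV file path.
#' @return data.frame of fermentation records.
#' @export
read_timecourse <- function(path) {
  rec <- utils::read.csv(path)
  validate_timecourse(rec)
  rec
}

validate_timecourse <- function(rec) {
  req <- c("time_h", "biomass_g_L", "pma_g_L", "ma_g_L")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stop(sprintf("time course lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  if (is.unsorted(rec$time_h))
    stop("time_h must be non-decreasing")
  conc <- rec[, setdiff(names(rec), "time_h"), drop = FALSE]
  if (any(unlist(conc) < 0)) stop("concentrations must be non-negative")
  invisible(rec)
}

sugar_columns <- function(rec)
  intersect(c("sucrose_g_L", "glucose_g_L", "fructose_g_L"), names(rec))

#' Summarise a fermentation run
#'
#' Final titer, elapsed time, productivity, yield on consumed sugars
#' (initial minus final total across sugar columns) and the PMA/MA
#' conversion factor in use. The yield basis follows the reporting
#' convention of quoting malic-acid equivalents: when `basis = "ma"` the
#' product is `ma_g_L` (or PMA converted through `factor` when the MA
#' column is all zero).
#'
#' @param rec data.frame from [read_timecourse()] (or equivalent).
#' @param factor PMA/MA conversion factor in (0, 1).
#' @param basis `"pma"` or `"ma"`: which product the titer refers to.
#' @return A `"quant_summary"` list: `final_titer_g_L`, `elapsed_h`,
#'   `productivity_g_L_h`, `yield_g_g`, `conversion_factor`, `basis`.
#' @export
quant_summary <- function(rec, factor = residue_mass_ratio(),
                          basis = c("pma", "ma")) {
  basis <- match.arg(basis)
  validate_timecourse(rec)
  check_factor(factor)
  last <- nrow(rec)
  titer <- if (basis == "pma") rec$pma_g_L[last] else {
    if (any(rec$ma_g_L > 0)) rec$ma_g_L[last]
    else ma_from_pma(rec$pma_g_L[last], factor)
  }
  elapsed <- rec$time_h[last] - rec$time_h[1]
  if (elapsed <= 0) stop("run has no elapsed time")
  sug <- sugar_columns(rec)
  if (!length(sug)) stop("time course has no sugar columns")
  consumed <- sum(rec[1, sug]) - sum(rec[last, sug])
  structure(list(final_titer_g_L = titer, elapsed_h = elapsed,
                 productivity_g_L_h = productivity(titer, elapsed),
                 yield_g_g = yield_g_g(titer, consumed),
                 conversion_factor = factor, basis = basis),
            class = "quant_summary")
}

#' @export
print.quant_summary <- function(x, ...) {
  cat(sprintf(
    "quant_summary (%s): titer %.2f g/L in %.0f h, productivity %.2f g/L/h, yield %.2f g/g\n",
    x$basis, x$final_titer_g_L, x$elapsed_h, x$productivity_g_L_h,
    x$yield_g_g))
  invisible(x)
}
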