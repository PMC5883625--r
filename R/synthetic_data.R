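# Seeded generators for synthetic inputs with the statistical structure
# the analyses assume: a two-carbon-source x two-timepoint metabolome with
# lognormal noise and planted fold changes, logistic-growth fermentation
# time courses, and small random carbon-balanced networks for exercising
# the LP engine.
#
# Each generator draws from its own stream, derived from the user seed as
# seed * 8 + <generator offset> (offsets: metabolome 1, timecourse 2,
# networks 3), so adding generators never perturbs existing fixtures. The
# caller's RNG state is saved and restored around every draw.

derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (as.integer(seed) %% 268435455L) * 8L + offset
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Specification for a synthetic metabolome experiment
#'
#' Defaults emulate the study design the pipeline targets: 81 identified
#' metabolites plus 2 internal standards, two carbon sources (glucose,
#' sucrose) sampled at 48 and 72 h, six biological replicates, lognormal
#' multiplicative noise on peak areas and per-sample injection factors.
#'
#' @param n_metabolites number of assayed metabolites (standards excluded).
#' @param groups data.frame with columns `carbon_source` and `timepoint_h`.
#' @param n_replicates biological replicates per group (>= 2).
#' @param baseline_log_mean,baseline_log_sd log-scale distribution of
#'   per-metabolite baseline intensities (arbitrary units).
#' @param sigma standard deviation of the replicate noise on the natural
#'   log scale (> 0).
#' @param planted_effects data.frame with columns `metabolite`, `group`,
#'   `log2_effect`: metabolite `metabolite` is shifted by
#'   `log2_effect * log(2)` on the log scale in group `group`
#'   (`"<carbon_source>_<timepoint_h>"`). `NULL` plants nothing.
#' @param injection_sd log-scale spread of per-sample injection factors
#'   (0 disables them).
#' @param n_standards number of spiked internal standards.
#' @param seed integer seed; the generator is fully deterministic given
#'   the spec.
#' @return A `"metabolome_spec"` list.
#' @export
metabolome_spec <- function(n_metabolites = 81,
                            groups = expand.grid(
                              carbon_source = c("glucose", "sucrose"),
                              timepoint_h = c(48, 72),
                              stringsAsFactors = FALSE),
                            n_replicates = 6,
                            baseline_log_mean = 12, baseline_log_sd = 1,
                            sigma = 0.5,
                            planted_effects = NULL,
                            injection_sd = 0.2,
                            n_standards = 2,
                            seed = 1) {
  stopifnot(n_metabolites >= 1, n_replicates >= 2, sigma >= 0,
            injection_sd >= 0, n_standards >= 0)   # sigma 0 = noise-free limit
  if (!is.null(planted_effects)) {
    req <- c("metabolite", "group", "log2_effect")
    if (!all(req %in% names(planted_effects)))
      stop("planted_effects needs columns metabolite, group, log2_effect")
    if (any(!is.finite(planted_effects$log2_effect)))
      stop("planted effects must be finite")
  }
  structure(list(n_metabolites = n_metabolites, groups = groups,
                 n_replicates = n_replicates,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, sigma = sigma,
                 planted_effects = planted_effects,
                 injection_sd = injection_sd, n_standards = n_standards,
                 seed = seed),
            class = "metabolome_spec")
}

#' Generate a synthetic metabolome table
#'
#' Intensities are
#' `exp(Normal(baseline + effect * log(2), sigma)) * injection_factor`;
#' internal-standard rows are exactly constant up to the injection factor,
#' so [normalize_by_internal_standard()] recovers the planted factors.
#'
#' @param spec a [metabolome_spec()].
#' @return List with `table` (an `"intensity_table"`), `truth`
#'   (data.frame of planted effects, empty when none) and
#'   `injection_factors` (named per-sample vector).
#' @export
gen_metabolome <- function(spec) {
  stopifnot(inherits(spec, "metabolome_spec"))
  with_seed(derive_seed(spec$seed, 1L), {
    glabels <- paste(spec$groups$carbon_source, spec$groups$timepoint_h,
                     sep = "_")
    design <- do.call(rbind, lapply(seq_len(nrow(spec$groups)), function(g)
      data.frame(sample_id = sprintf("%s_r%d", glabels[g],
                                     seq_len(spec$n_replicates)),
                 carbon_source = spec$groups$carbon_source[g],
                 timepoint_h = spec$groups$timepoint_h[g],
                 replicate = seq_len(spec$n_replicates),
                 group = glabels[g], stringsAsFactors = FALSE)))
    n_samp <- nrow(design)
    met_ids <- sprintf("met_%02d", seq_len(spec$n_metabolites))
    std_ids <- if (spec$n_standards > 0)
      sprintf("IS_%d", seq_len(spec$n_standards)) else character()
    baseline <- stats::rnorm(spec$n_metabolites, spec$baseline_log_mean,
                             spec$baseline_log_sd)
    names(baseline) <- met_ids
    shift <- matrix(0, spec$n_metabolites, n_samp,
                    dimnames = list(met_ids, design$sample_id))
    if (!is.null(spec$planted_effects)) {
      for (k in seq_len(nrow(spec$planted_effects))) {
        pe <- spec$planted_effects[k, ]
        if (!pe$metabolite %in% met_ids)
          stop(sprintf("planted effect on unknown metabolite '%s'",
                       pe$metabolite))
        if (!pe$group %in% glabels)
          stop(sprintf("planted effect on unknown group '%s'", pe$group))
        shift[pe$metabolite, design$group == pe$group] <-
          shift[pe$metabolite, design$group == pe$group] +
          pe$log2_effect * log(2)
      }
    }
    noise <- matrix(stats::rnorm(spec$n_metabolites * n_samp, 0, spec$sigma),
                    spec$n_metabolites, n_samp)
    vals <- exp(baseline + shift + noise)
    if (length(std_ids)) {
      std_base <- exp(stats::rnorm(spec$n_standards,
                                   spec$baseline_log_mean, 0.25))
      vals <- rbind(vals,
                    matrix(std_base, spec$n_standards, n_samp,
                           dimnames = list(std_ids, design$sample_id)))
    }
    inj <- if (spec$injection_sd > 0)
      exp(stats::rnorm(n_samp, 0, spec$injection_sd)) else rep(1, n_samp)
    names(inj) <- design$sample_id
    vals <- sweep(vals, 2, inj, "*")
    truth <- if (is.null(spec$planted_effects))
      data.frame(metabolite = character(), group = character(),
                 log2_effect = numeric(), stringsAsFactors = FALSE)
    else spec$planted_effects
    list(table = intensity_table(vals,
                                 design[, setdiff(names(design), "group")],
                                 internal_standard_ids = std_ids),
         truth = truth, injection_factors = inj)
  })
}

#' Specification for a synthetic fermentation time course
#'
#' Biomass follows the logistic solution
#' `X(t) = Xmax X0 e^(mu t) / (Xmax - X0 + X0 e^(mu t))`; product follows
#' the Luedeking-Piret form `dP/dt = alpha dX/dt + beta X` (integrated in
#' closed form); substrate decreases as `P / yield_ps + (X - X0) /
#' yield_xs`. Yields may be `Inf` to disable the corresponding drain.
#'
#' @param x0,xmax,mu logistic parameters: inoculum and capacity (g/L,
#'   `xmax > x0 > 0`) and specific growth rate (1/h, > 0).
#' @param alpha growth-associated product coefficient (g product / g
#'   biomass).
#' @param beta non-growth-associated rate (g product / g biomass / h).
#' @param yield_ps product yield on substrate (g/g, > 0, may be `Inf`).
#' @param yield_xs biomass yield on substrate (g/g, > 0, may be `Inf`).
#' @param s0 initial substrate (g/L).
#' @param substrate sugar column to drain (`"sucrose_g_L"`,
#'   `"glucose_g_L"` or `"fructose_g_L"`).
#' @param times strictly increasing sampling times, h.
#' @param noise_sd observation noise sd (g/L; 0 for noise-free curves).
#' @param seed integer seed.
#' @return A `"timecourse_spec"` list.
#' @export
timecourse_spec <- function(x0 = 0.5, xmax = 25, mu = 0.12,
                            alpha = 1.2, beta = 0.02,
                            yield_ps = 0.62, yield_xs = 0.5,
                            s0 = 200, substrate = "sucrose_g_L",
                            times = seq(0, 140, by = 10),
                            noise_sd = 0, seed = 1) {
  stopifnot(xmax > x0, x0 > 0, mu > 0, yield_ps > 0, yield_xs > 0,
            noise_sd >= 0)
  if (any(diff(times) <= 0)) stop("sampling times must be increasing")
  if (!substrate %in% c("sucrose_g_L", "glucose_g_L", "fructose_g_L"))
    stop("unknown substrate column")
  structure(list(x0 = x0, xmax = xmax, mu = mu, alpha = alpha, beta = beta,
                 yield_ps = yield_ps, yield_xs = yield_xs, s0 = s0,
                 substrate = substrate, times = times, noise_sd = noise_sd,
                 seed = seed),
            class = "timecourse_spec")
}

#' Generate a synthetic fermentation time course
#'
#' @param spec a [timecourse_spec()].
#' @return data.frame of fermentation records (`time_h`, `biomass_g_L`,
#'   `pma_g_L`, `ma_g_L`, sugar columns), truncated at zero where noise
#'   would take a concentration negative. The `pma_g_L` column carries the
#'   product; `ma_g_L` is left at 0 (the product is quoted on the PMA
#'   basis).
#' @export
gen_timecourse <- function(spec) {
  stopifnot(inherits(spec, "timecourse_spec"))
  with_seed(derive_seed(spec$seed, 2L), {
    t <- spec$times
    egt <- exp(spec$mu * t)
    denom <- spec$xmax - spec$x0 + spec$x0 * egt
    X <- spec$xmax * spec$x0 * egt / denom
    intX <- (spec$xmax / spec$mu) * log(denom / spec$xmax)  # integral of X dt
    P <- spec$alpha * (X - spec$x0) + spec$beta * intX
    S <- spec$s0 - P / spec$yield_ps - (X - spec$x0) / spec$yield_xs
    rec <- data.frame(time_h = t, biomass_g_L = X, pma_g_L = P,
                      ma_g_L = 0)
    rec[[spec$substrate]] <- S
    for (col in setdiff(names(rec), "time_h")) {
      if (spec$noise_sd > 0)
        rec[[col]] <- rec[[col]] + stats::rnorm(length(t), 0, spec$noise_sd)
      rec[[col]] <- pmax(rec[[col]], 0)
    }
    validate_timecourse(rec)
    rec
  })
}

#' Generate random small carbon-balanced test networks
#'
#' Produces toy metabolic models for exercising the LP engine: a single
#' uptake exchange, a chain of unimolecular single-carbon conversions with
#' random extra edges and random bounds, and a single secretion exchange.
#' Every internal reaction is carbon-balanced by construction and every
#' network has a feasible non-zero optimum through its backbone chain.
#'
#' @param seed integer seed.
#' @param n_networks number of models to generate.
#' @param max_reactions cap on total reactions per model (>= 3, <= 8).
#' @return List of `"metabolic_model"` objects (objective: the secretion
#'   exchange).
#' @export
gen_toy_networks <- function(seed = 1, n_networks = 10, max_reactions = 8) {
  stopifnot(max_reactions >= 3, max_reactions <= 8)
  with_seed(derive_seed(seed, 3L), {
    lapply(seq_len(n_networks), function(i) {
      n_int <- sample(2:4, 1)                       # internal metabolites
      mets <- c(list(metabolite("M_ext_in", "substrate", "extracellular",
                                formula = c(C = 1, H = 2, O = 1)),
                     metabolite("M_ext_out", "product", "extracellular",
                                formula = c(C = 1, H = 2, O = 1))),
                lapply(seq_len(n_int), function(k)
                  metabolite(sprintf("M%d", k), sprintf("M%d", k), "cytosol",
                             formula = c(C = 1, H = 2, O = 1))))
      uptake <- round(stats::runif(1, 2, 10), 2)
      rxns <- list(
        reaction("EX_in", c(M_ext_in = -1), lower_bound = -uptake,
                 upper_bound = 0, kind = "exchange"),
        reaction("T_in", c(M_ext_in = -1, M1 = 1),
                 upper_bound = round(stats::runif(1, uptake / 2, 12), 2)))
      # backbone chain M1 -> ... -> Mn
      for (k in seq_len(n_int - 1))
        rxns <- c(rxns, list(reaction(
          sprintf("R%d", k), stats::setNames(c(-1, 1),
                                             sprintf("M%d", c(k, k + 1))),
          lower_bound = if (stats::runif(1) < 0.3)
            -round(stats::runif(1, 0, 5), 2) else 0,
          upper_bound = round(stats::runif(1, 0.5, 12), 2))))
      rxns <- c(rxns, list(
        reaction("T_out", stats::setNames(c(-1, 1),
                                          c(sprintf("M%d", n_int), "M_ext_out")),
                 upper_bound = round(stats::runif(1, 0.5, 12), 2)),
        reaction("EX_out", c(M_ext_out = -1), upper_bound = 1000,
                 kind = "exchange")))
      # random shortcut edges while the budget allows
      while (length(rxns) < max_reactions && stats::runif(1) < 0.6 &&
             n_int >= 2) {
        pair <- sample(n_int, 2)
        rxns <- c(rxns, list(reaction(
          sprintf("S%d", length(rxns)),
          stats::setNames(c(-1, 1), sprintf("M%d", pair)),
          upper_bound = round(stats::runif(1, 0, 8), 2))))
      }
      metabolic_model(mets, rxns, objective_id = "EX_out",
                      notes = sprintf("toy network %d", i))
    })
  })
}
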