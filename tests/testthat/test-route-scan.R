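# Route-scan tests run on a reduced grid covering the structurally
# informative region of the packaged model (all three cutoffs lie below a
# route flux of 20 mmol/gDW/h).

scan_all <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(names(route_definitions()), function(rt)
        scan_surface(reduced_model_fixture, rt, flux_max = 20,
                     flux_steps = 11, growth_max = 1, growth_steps = 5))
    cache
  }
})

test_that("packaged route definitions carry the named enzyme sets", {
  defs <- route_definitions()
  expect_setequal(defs$oxidative_tca$reaction_ids,
                  c("AKGDH", "ACONT", "FUM", "SDH", "SUCOAS"))
  expect_identical(defs$reductive_tca$reaction_ids, "MDH_c")
  expect_setequal(defs$glyoxylate_shunt$reaction_ids,
                  c("FUM", "ICL", "MAS"))
  rxn_ids <- vapply(reduced_model_fixture$reactions, `[[`, "", "id")
  for (d in defs) expect_true(all(d$reaction_ids %in% rxn_ids))
})

test_that("route constraints pin the scanned route and zero the others", {
  prob <- apply_route_constraints(reduced_model_fixture, "glyoxylate_shunt",
                                  route_flux = 3, growth = 0.2)
  ov <- prob$overrides
  # fumarase is shared with the oxidative list: the scanned value wins
  expect_equal(unname(ov$FUM), c(3, 3))
  expect_equal(unname(ov$ICL), c(3, 3))
  expect_equal(unname(ov$AKGDH), c(0, 0))
  expect_equal(unname(ov$MDH_c), c(0, 0))
  expect_equal(unname(ov$MDH_m), c(0, 0))
  expect_equal(unname(ov$BIOMASS), c(0.2, 0.2))
  expect_equal(unname(ov$EX_glc), c(-10, 0))
  expect_equal(unname(ov$EX_suc), c(0, 0))
  expect_error(apply_route_constraints(chain_model(), "reductive_tca", 1, 0),
               "missing from model")
})

test_that("reductive route with zero flux and growth makes no PMA", {
  prob <- apply_route_constraints(reduced_model_fixture, "reductive_tca",
                                  route_flux = 0, growth = 0)
  sol <- solve_fba(prob)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("growth demanded above the model maximum is infeasible", {
  gmax <- solve_fba(fba_problem(reduced_model_fixture,
                                objective_id = "BIOMASS"))$objective_value
  prob <- apply_route_constraints(reduced_model_fixture, "reductive_tca",
                                  route_flux = 0, growth = gmax + 1)
  expect_identical(solve_fba(prob)$status, "infeasible")
})

test_that("optimal PMA is non-increasing in imposed growth at every route flux", {
  for (g in scan_all()) {
    pm <- g$pma_optimum
    for (i in seq_len(nrow(pm))) {
      vals <- pm[i, ]
      finite <- which(!is.na(vals))
      if (length(finite) > 1)
        expect_true(all(diff(vals[finite]) <= 1e-6),
                    info = sprintf("%s at flux %s", g$route$name,
                                   rownames(pm)[i]))
      # infeasibility only appears after feasibility is lost for good
      if (length(finite))
        expect_true(all(diff(finite) == 1),
                    info = sprintf("feasible growth range not contiguous (%s)",
                                   g$route$name))
    }
  }
})

test_that("route optima are ordered reductive >= glyoxylate >= oxidative", {
  summ <- summarize_scans(scan_all())
  opt <- setNames(summ$pma_optimum, summ$route)
  expect_gte(opt["reductive_tca"], opt["glyoxylate_shunt"])
  expect_gte(opt["glyoxylate_shunt"], opt["oxidative_tca"])
  # and every route eventually hits a cutoff on this model
  expect_true(all(is.finite(summ$cutoff_flux)))
  expect_true(all(summ$cutoff_flux >= summ$argmax_route_flux))
  cut <- setNames(summ$cutoff_flux, summ$route)
  expect_gte(cut["reductive_tca"], cut["oxidative_tca"])
})

test_that("optimal PMA is concave in route flux at fixed growth", {
  for (g in scan_all()) {
    pm <- g$pma_optimum
    for (j in seq_len(ncol(pm))) {
      v <- pm[, j]
      for (i in 2:(length(v) - 1)) {
        if (anyNA(v[(i - 1):(i + 1)])) next
        expect_gte(v[i], (v[i - 1] + v[i + 1]) / 2 - 1e-6)
      }
    }
  }
})

test_that("sucrose at hexose-equivalent uptake reproduces the glucose optima", {
  for (rt in names(route_definitions())) {
    for (f in c(0, 4, 8)) {
      for (gr in c(0, 0.5)) {
        pg <- solve_fba(apply_route_constraints(
          reduced_model_fixture, rt, f, gr, carbon_source = "glucose"))
        ps <- solve_fba(apply_route_constraints(
          reduced_model_fixture, rt, f, gr, carbon_source = "sucrose"))
        expect_identical(pg$status, ps$status)
        if (pg$status == "optimal")
          expect_equal(pg$objective_value, ps$objective_value,
                       tolerance = 1e-6)
      }
    }
  }
})

test_that("a scanned chain reproduces the closed-form min(flux, uptake)", {
  m <- chain_model(uptake = 6)
  route <- structure(list(name = "chain_mid", reaction_ids = "MID"),
                     class = "route_definition")
  g <- scan_surface(m, route, flux_max = 6, flux_steps = 3,
                    growth_max = 1, growth_steps = 3, uptake_rate = 6)
  for (i in seq_along(g$route_flux_values)) {
    f <- g$route_flux_values[i]
    expect_equal(unname(g$pma_optimum[i, 1]), min(f, 6), tolerance = 1e-9)
  }
})

test_that("scan summaries handle degenerate grids", {
  mk_grid <- function(vals, fvals) {
    structure(list(route = route_definitions()$reductive_tca,
                   carbon_source = "glucose", route_flux_values = fvals,
                   growth_values = 0,
                   pma_optimum = matrix(vals, ncol = 1),
                   status = matrix("optimal", length(vals), 1)),
              class = "scan_grid")
  }
  allzero <- summarize_scans(mk_grid(c(0, 0, 0), c(0, 5, 10)))
  expect_equal(allzero$pma_optimum, 0)
  expect_equal(allzero$cutoff_flux, 0)  # first grid point
  single <- summarize_scans(mk_grid(7, 3))
  expect_equal(single$pma_optimum, 7)
  expect_error(summarize_scans(list()), "no scan grids")
})

test_that("long-format export matches the grid", {
  g <- scan_all()[[1]]
  df <- as.data.frame(g)
  expect_equal(nrow(df), length(g$route_flux_values) * length(g$growth_values))
  cell <- df[df$route_flux == 4 & df$growth == 0, ]
  expect_equal(cell$pma_optimum, g$pma_optimum["4", "0"])
})
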