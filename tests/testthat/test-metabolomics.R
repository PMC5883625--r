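mat <- function(..., nrow, ids = NULL, samples = NULL) {
  m <- matrix(c(...), nrow = nrow, byrow = TRUE)
  rownames(m) <- ids %||% sprintf("m%d", seq_len(nrow))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("internal-standard normalisation removes injection factors", {
  v <- mat(10, 20, 30,
           5, 5, 5,
           2, 2, 2, nrow = 3, ids = c("m1", "IS_1", "IS_2"))
  tab <- toy_table(v, c("glucose_48", "glucose_48", "glucose_48"),
                   standards = c("IS_1", "IS_2"))
  # identical standards: values unchanged up to one global constant
  norm <- normalize_by_internal_standard(tab)
  expect_equal(norm$values["m1", ] / tab$values["m1", ],
               rep(norm$values["m1", 1] / tab$values["m1", 1], 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # scaling one whole column (standards included) is a no-op after normalisation
  v2 <- v
  v2[, 2] <- v2[, 2] * 3
  tab2 <- toy_table(v2, rep("glucose_48", 3), standards = c("IS_1", "IS_2"))
  norm2 <- normalize_by_internal_standard(tab2)
  expect_equal(norm2$values, norm$values, tolerance = 1e-12)
  expect_error(normalize_by_internal_standard(
    toy_table(v, rep("glucose_48", 3))), "no internal standards")
})

test_that("planted per-sample injection factors are recovered exactly", {
  spec_inj <- metabolome_spec(seed = 5, injection_sd = 0.3)
  spec_flat <- metabolome_spec(seed = 5, injection_sd = 0)
  with_inj <- gen_metabolome(spec_inj)
  flat <- gen_metabolome(spec_flat)
  # standards track the planted factors: their geometric mean recovers them
  std <- with_inj$table$values[with_inj$table$internal_standard_ids, ]
  est <- exp(colMeans(log(std)))
  expect_equal(est / with_inj$injection_factors,
               rep(est[1] / with_inj$injection_factors[1], ncol(std)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # and normalisation maps both tables onto the same values
  expect_equal(normalize_by_internal_standard(with_inj$table)$values,
               normalize_by_internal_standard(flat$table)$values,
               tolerance = 1e-12)
})

test_that("unit-variance scaling centres and scales every row", {
  expect_equal(unname(uv_scale(mat(1, 2, 3, nrow = 1),
                               log_transform = FALSE)[1, ]),
               c(-1, 0, 1))
  x <- mat(stats::rnorm(50, 8, 2), stats::runif(50, 1, 9), nrow = 2)
  sc <- uv_scale(x, log_transform = FALSE)
  expect_equal(unname(rowMeans(sc)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(sc, 1, stats::var)), c(1, 1), tolerance = 1e-12)
  expect_warning(
    dropped <- uv_scale(mat(1, 1, 1, 4, 5, 6, nrow = 2),
                        log_transform = FALSE),
    "zero-variance")
  expect_identical(rownames(dropped), "m2")
  expect_error(uv_scale(mat(1, nrow = 1), log_transform = FALSE),
               "at least 2 samples")
})

test_that("PCA concentrates correlated variance and reconstructs the input", {
  # two perfectly correlated profiles: one component carries everything
  base <- c(1, 3, 2, 5, 4)
  sc <- uv_scale(mat(base, 2 * base + 1, nrow = 2), log_transform = FALSE)
  p <- pca(sc)
  expect_equal(p$explained_variance[1] / p$total_variance, 1,
               tolerance = 1e-12)
  # full-rank reconstruction: scores %*% t(loadings) = t(scaled)
  set.seed(31)
  sc2 <- uv_scale(matrix(stats::rnorm(60), 6, 10,
                         dimnames = list(sprintf("m%d", 1:6),
                                         sprintf("s%d", 1:10))),
                  log_transform = FALSE)
  p2 <- pca(sc2)
  expect_lt(max(abs(p2$scores %*% t(p2$loadings) - t(sc2))), 1e-8)
  expect_lt(max(abs(crossprod(p2$loadings) - diag(ncol(p2$loadings)))), 1e-8)
  expect_true(all(diff(p2$explained_variance) <= 1e-12))
  expect_equal(sum(p2$explained_variance), p2$total_variance,
               tolerance = 1e-8)
  # near-uncorrelated data spreads variance roughly evenly
  set.seed(7)
  big <- matrix(stats::rnorm(400 * 4), 4, 400,
                dimnames = list(sprintf("m%d", 1:4), NULL))
  colnames(big) <- sprintf("s%d", 1:400)
  p3 <- pca(uv_scale(big, log_transform = FALSE), n_components = 4)
  share <- p3$explained_variance / p3$total_variance
  expect_true(all(share > 0.15 & share < 0.35))
  expect_error(pca(sc2, n_components = 99), "n_components")
})

test_that("VIP scores satisfy their normalisation and symmetry properties", {
  groups <- rep(c("glucose_48", "sucrose_48"), each = 4)
  # p = 1: the single VIP is exactly 1
  one <- uv_scale(mat(c(1, 2, 1, 2, 5, 6, 5, 7), nrow = 1),
                  log_transform = FALSE)
  expect_equal(unname(plsda_vip(one, groups, n_components = 1)), 1,
               tolerance = 1e-12)
  # duplicated profiles score identically; sum VIP^2 = p
  set.seed(12)
  x <- matrix(stats::rnorm(40), 5, 8,
              dimnames = list(sprintf("m%d", 1:5), sprintf("s%d", 1:8)))
  x[1, groups == "sucrose_48"] <- x[1, groups == "sucrose_48"] + 3
  x <- rbind(x, m6 = x[1, ])
  sc <- uv_scale(x, log_transform = FALSE)
  vip <- plsda_vip(sc, groups, n_components = 2)
  expect_equal(unname(vip["m1"]), unname(vip["m6"]), tolerance = 1e-9)
  expect_equal(sum(vip^2), nrow(sc), tolerance = 1e-6)
  expect_error(plsda_vip(sc, rep("a", 8)), "two groups")
  expect_error(plsda_vip(sc, c(rep("a", 7), "b")), "at least 2")
})

test_that("single-component VIP matches the direct projection oracle", {
  groups <- rep(c("glucose_48", "sucrose_48"), each = 5)
  set.seed(40)
  x <- matrix(stats::rnorm(20, sd = 0.3), 2, 10,
              dimnames = list(c("hit", "null"), sprintf("s%d", 1:10)))
  x["hit", groups == "sucrose_48"] <- x["hit", groups == "sucrose_48"] + 4
  sc <- uv_scale(x, log_transform = FALSE)
  vip <- plsda_vip(sc, groups, n_components = 1)
  oracle <- vip_single_component_oracle(sc, groups)
  expect_equal(unname(vip), oracle, tolerance = 1e-9)
  expect_gt(vip["hit"], 1)
  expect_lt(vip["null"], 1)
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  suppressMessages(requireNamespace("mixOmics"))
  groups <- rep(c("glucose_48", "sucrose_48"), each = 6)
  set.seed(9)
  x <- matrix(stats::rnorm(120), 10, 12,
              dimnames = list(sprintf("m%d", 1:10), sprintf("s%d", 1:12)))
  x[1:2, groups == "sucrose_48"] <- x[1:2, groups == "sucrose_48"] + 2
  sc <- uv_scale(x, log_transform = FALSE)
  vip <- plsda_vip(sc, groups, n_components = 2)
  fit <- mixOmics::plsda(t(sc), factor(groups), ncomp = 2, scale = FALSE)
  ref <- mixOmics::vip(fit)[, 2]
  expect_equal(unname(vip), unname(ref[rownames(sc)]), tolerance = 1e-6)
})

test_that("pooled t statistics match the textbook formula", {
  groups <- c(rep("glucose_48", 3), rep("sucrose_48", 3))
  tab <- toy_table(mat(exp(c(1, 2, 3, 2, 3, 4)), nrow = 1), groups)
  res <- two_sample_t(tab, "sucrose_48", "glucose_48", log_transform = TRUE)
  expect_equal(res$t_statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(-sqrt(3 / 2), df = 4),
               tolerance = 1e-9)  # = 0.28786
  # swapping the groups negates t and keeps p
  swapped <- two_sample_t(tab, "glucose_48", "sucrose_48",
                          log_transform = TRUE)
  expect_equal(swapped$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- toy_table(mat(exp(c(1, 2, 3, 1, 2, 3)), nrow = 1), groups)
  ressame <- two_sample_t(same, "glucose_48", "sucrose_48")
  expect_equal(ressame$t_statistic, 0)
  expect_equal(ressame$p_value, 1)
  # zero pooled variance is conservative, with a warning
  flat <- toy_table(mat(rep(2, 6), nrow = 1), groups)
  expect_warning(resflat <- two_sample_t(flat, "glucose_48", "sucrose_48"),
                 "zero pooled variance")
  expect_equal(resflat$p_value, 1)
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- stats::runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
})

test_that("fold changes follow the log2(treated/control) convention", {
  groups <- c(rep("glucose_48", 2), rep("sucrose_48", 2))
  tab <- toy_table(mat(2, 2, 2, 2,
                       2, 2, 8, 8, nrow = 2), groups)
  fc <- fold_change(tab, "glucose_48", "sucrose_48")
  expect_equal(fc$fold_change_log2, c(0, 2))
  expect_equal(fc$mean_A, c(2, 2))
  expect_equal(fc$mean_B, c(2, 8))
  expect_error(fold_change(tab, "glucose_48", "sucrose_72"), "empty group")
})

test_that("a planted 1.84-fold shift is recovered at six replicates", {
  pe <- data.frame(metabolite = "met_01", group = "sucrose_48",
                   log2_effect = log2(1.84))
  fcs <- vapply(1:40, function(s) {
    gm <- gen_metabolome(metabolome_spec(n_metabolites = 20,
                                         planted_effects = pe, seed = s))
    tab <- normalize_by_internal_standard(gm$table)
    fold_change(tab, "glucose_48", "sucrose_48")$fold_change_log2[1]
  }, 0)
  expect_lt(abs(mean(fcs) - log2(1.84)), 0.15)
})

test_that("selection requires all three criteria simultaneously", {
  base <- data.frame(metabolite = c("a", "b", "c", "d"),
                     p_value = c(0.04, 0.04, 0.10, 0.04),
                     q_value = c(0.03, 0.03, 0.03, 0.10),
                     vip = c(1.2, 0.9, 1.2, 1.2))
  sel <- select_differential(base)
  expect_identical(sel$selected, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(select_differential(base[, -2]), "missing column")
})

test_that("the pipeline is invariant to rescaling a raw metabolite row", {
  pe <- data.frame(metabolite = "met_03", group = "sucrose_48",
                   log2_effect = 2)
  gm <- gen_metabolome(metabolome_spec(n_metabolites = 12,
                                       planted_effects = pe, seed = 21))
  scaled_up <- gm$table
  scaled_up$values["met_05", ] <- scaled_up$values["met_05", ] * 50
  r1 <- differential_analysis(gm$table, "glucose_48", "sucrose_48")
  r2 <- differential_analysis(scaled_up, "glucose_48", "sucrose_48")
  for (col in c("fold_change_log2", "t_statistic", "p_value", "q_value",
                "vip", "selected"))
    expect_equal(r1[[col]], r2[[col]], tolerance = 1e-9, info = col)
})

test_that("Ward clustering matches a naive agglomeration oracle", {
  # two identical profiles merge first, at height zero
  x <- mat(1, 2, 3,
           1, 2, 3,
           9, 9, 9, nrow = 3)
  hc <- hierarchical_clustering(x)
  expect_equal(hc$height[1], 0)
  expect_setequal(-hc$merge[1, ], c(1, 2))
  # coincident pair in a triangle merges before the distant point
  y <- mat(0, 0, 0, 0, 5, 5, nrow = 3)
  hc2 <- hierarchical_clustering(y)
  expect_setequal(-hc2$merge[1, ], c(1, 2))
  # five-point configuration: heights and merge composition match the oracle
  set.seed(17)
  z <- matrix(stats::rnorm(20), 5, 4,
              dimnames = list(sprintf("m%d", 1:5), sprintf("s%d", 1:4)))
  hc3 <- hierarchical_clustering(z)
  oracle <- ward_oracle(z)
  expect_equal(hc3$height, oracle$heights, tolerance = 1e-9)
  merge_members <- function(hc) {
    sets <- vector("list", nrow(hc$merge))
    for (k in seq_len(nrow(hc$merge))) {
      grab <- function(v) if (v < 0) -v else sets[[v]]
      sets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
    }
    sets
  }
  expect_identical(merge_members(hc3), oracle$merge_sets)
  expect_error(hierarchical_clustering(z[1, , drop = FALSE]), "at least 2")
})

test_that("intensity tables round-trip through TSV", {
  gm <- gen_metabolome(metabolome_spec(n_metabolites = 8, seed = 3))
  tf <- tempfile(fileext = ".tsv")
  df <- tempfile(fileext = ".tsv")
  write_intensity_table(gm$table, tf, df)
  back <- read_intensity_table(tf, df,
                               internal_standard_ids =
                                 gm$table$internal_standard_ids)
  expect_equal(back$values, gm$table$values, tolerance = 1e-12)
  expect_equal(back$sample_design$carbon_source,
               gm$table$sample_design$carbon_source)
})

test_that("malformed tables are rejected with targeted errors", {
  v <- mat(1, 2, 3, 4, nrow = 2)
  expect_error(toy_table(mat(-1, 2, 1, 1, nrow = 2),
                         c("glucose_48", "glucose_48")),
               "strictly positive")
  design <- data.frame(sample_id = c("s1", "sX"), carbon_source = "glucose",
                       timepoint_h = 48, replicate = 1:2)
  expect_error(intensity_table(v, design), "do not match")
  expect_error(intensity_table(v, design[, -2]), "carbon_source")
})
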