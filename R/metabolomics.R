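# GC-MS metabolome differential-analysis pipeline: internal-standard
# normalisation, unit-variance scaling, PCA, PLS-DA with VIP scores,
# pooled two-sample t tests with Benjamini-Hochberg FDR, log2 fold
# changes, the multi-criteria selection rule, and Ward clustering.
#
# Group labels throughout are "<carbon_source>_<timepoint_h>", e.g.
# "glucose_48". Tests and fold changes operate on normalised intensities
# (t tests on their logs); unit-variance scaling is applied only for the
# multivariate steps (PCA, PLS-DA, clustering), since scaling each
# metabolite to unit variance would destroy the mean differences the
# univariate tests measure.

#' Assemble an intensity table
#'
#' @param values numeric matrix of strictly positive intensities,
#'   metabolites x samples, with rownames (metabolite ids) and colnames
#'   (sample ids).
#' @param sample_design data.frame with columns `sample_id`,
#'   `carbon_source`, `timepoint_h`, `replicate`; one row per column of
#'   `values`, matched by `sample_id`.
#' @param internal_standard_ids metabolite ids of spiked internal
#'   standards (rows of `values`); excluded from downstream statistics
#'   after normalisation.
#' @return An object of class `"intensity_table"`.
#' @export
intensity_table <- function(values, sample_design,
                            internal_standard_ids = character()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("intensity matrix must carry metabolite rownames and sample colnames")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("intensities must be strictly positive and finite")
  req <- c("sample_id", "carbon_source", "timepoint_h", "replicate")
  miss <- setdiff(req, names(sample_design))
  if (length(miss))
    stop(sprintf("sample design lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  if (!setequal(sample_design$sample_id, colnames(values)) ||
      nrow(sample_design) != ncol(values))
    stop("sample design rows do not match intensity columns")
  sample_design <- sample_design[match(colnames(values),
                                       sample_design$sample_id), ]
  rownames(sample_design) <- NULL
  unknown_std <- setdiff(internal_standard_ids, rownames(values))
  if (length(unknown_std))
    stop(sprintf("internal standard(s) not in table: %s",
                 paste(unknown_std, collapse = ", ")))
  structure(list(values = values, sample_design = sample_design,
                 internal_standard_ids = internal_standard_ids,
                 normalized = FALSE),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d metabolites (%d internal standards) x %d samples%s\n",
              nrow(x$values), length(x$internal_standard_ids),
              ncol(x$values),
              if (x$normalized) ", normalised" else ""))
  invisible(x)
}

#' Group labels of an intensity table
#'
#' @param table an `"intensity_table"`.
#' @return Character vector `"<carbon_source>_<timepoint_h>"` per sample.
#' @export
group_labels <- function(table) {
  paste(table$sample_design$carbon_source, table$sample_design$timepoint_h,
        sep = "_")
}

assay_rows <- function(table) {
  setdiff(rownames(table$values), table$internal_standard_ids)
}

#' Normalise samples by their internal standards
#'
#' Divides each sample column by the geometric mean of its
#' internal-standard intensities, removing per-sample injection and
#' recovery differences. Internal-standard rows are retained (they become
#' constant up to measurement noise) but stay flagged for exclusion from
#' downstream statistics.
#'
#' @param table an `"intensity_table"` with at least one internal standard.
#' @return The normalised `"intensity_table"`.
#' @export
normalize_by_internal_standard <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  ids <- table$internal_standard_ids
  if (!length(ids)) stop("no internal standards defined")
  std <- table$values[ids, , drop = FALSE]
  bad <- colnames(std)[apply(std, 2, function(v) any(v <= 0))]
  if (length(bad))
    stop(sprintf("non-positive internal-standard intensity in sample(s): %s",
                 paste(bad, collapse = ", ")))
  gm <- exp(colMeans(log(std)))
  table$values <- sweep(table$values, 2, gm, "/")
  table$normalized <- TRUE
  table
}

#' Unit-variance scale a matrix of metabolite profiles
#'
#' Mean-centres each metabolite row and divides by its sample standard
#' deviation (n-1 denominator). Rows with zero variance are dropped with
#' a warning. Internal-standard rows are dropped first when an
#' `"intensity_table"` is supplied.
#'
#' @param x an `"intensity_table"` or a numeric matrix
#'   (metabolites x samples).
#' @param log_transform take logs before scaling (default `TRUE` for
#'   intensity tables, matching the multiplicative error structure of
#'   GC-MS peak areas).
#' @return Numeric matrix with every row at mean 0, variance 1.
#' @export
uv_scale <- function(x, log_transform = inherits(x, "intensity_table")) {
  if (inherits(x, "intensity_table")) x <- x$values[assay_rows(x), , drop = FALSE]
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("unit-variance scaling needs at least 2 samples")
  if (log_transform) x <- log(x)
  sds <- apply(x, 1, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance row(s): %s", sum(zero),
                    paste(rownames(x)[zero], collapse = ", ")))
    x <- x[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  if (!nrow(x)) stop("no rows left after dropping zero-variance rows")
  sweep(sweep(x, 1, rowMeans(x)), 1, sds, "/")
}

#' Principal component analysis of a scaled matrix
#'
#' Computed by singular value decomposition of the transposed
#' (samples x variables) matrix. Component signs are fixed by the
#' convention that the largest-magnitude loading of each component is
#' positive, making results deterministic.
#'
#' @param scaled matrix from [uv_scale()], metabolites x samples.
#' @param n_components number of components (default all).
#' @return An object of class `"pca_result"`: `scores`
#'   (samples x components), `loadings` (metabolites x components,
#'   orthonormal), `explained_variance` per component (sums to the total
#'   variance across all `min(dim)` components).
#' @export
pca <- function(scaled, n_components = NULL) {
  X <- t(as.matrix(scaled))            # samples x metabolites
  X <- sweep(X, 2, colMeans(X))        # column-centred (rows of input were
                                       # already centred across samples)
  k_full <- min(dim(X))
  if (is.null(n_components)) n_components <- k_full
  if (n_components < 1 || n_components > k_full)
    stop(sprintf("n_components must be in 1..%d", k_full))
  sv <- svd(X, nu = n_components, nv = n_components)
  if (max(sv$d) < .Machine$double.eps^0.5) stop("degenerate matrix: no variance")
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)],
                                n_components), 2, flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  dimnames(loadings) <- list(rownames(scaled),
                             paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(colnames(scaled),
                           paste0("PC", seq_len(n_components)))
  ev <- sv$d^2 / (nrow(X) - 1)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(n_components)],
                 total_variance = sum(ev)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  pct <- 100 * x$explained_variance / x$total_variance
  cat(sprintf("pca_result: %d components (%s%% of variance)\n",
              ncol(x$scores), paste(sprintf("%.1f", pct), collapse = ", ")))
  invisible(x)
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a single-response PLS regression of the binary group indicator on
#' the scaled profiles by the iterative NIPALS algorithm, then scores each
#' metabolite as
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{aj}^2 / \sum_a SSY_a}}
#' where `p` is the number of metabolites, `SSY_a` the response variance
#' explained by component `a` and `w_a` the normalised weight vectors.
#' The scores satisfy `sum(VIP^2) == p`.
#'
#' @param scaled matrix from [uv_scale()], metabolites x samples.
#' @param group_labels vector with exactly two distinct values, one per
#'   sample; each group needs >= 2 samples.
#' @param n_components number of PLS components (default 2); silently
#'   truncated, with a warning, if it exceeds the achievable rank.
#' @return Named numeric vector of VIP scores per metabolite.
#' @export
plsda_vip <- function(scaled, group_labels, n_components = 2) {
  X <- t(as.matrix(scaled))            # samples x metabolites
  groups <- as.factor(group_labels)
  if (nlevels(groups) != 2L)
    stop("plsda_vip requires exactly two groups")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  if (length(groups) != nrow(X))
    stop("group_labels length does not match number of samples")
  y <- as.numeric(groups == levels(groups)[2L])
  y <- y - mean(y)
  X <- sweep(X, 2, colMeans(X))
  p <- ncol(X)
  W <- NULL; ssy <- numeric(0)
  Xa <- X; ya <- y
  for (a in seq_len(n_components)) {
    w <- as.numeric(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning(sprintf("PLS rank exhausted at %d component(s)", a - 1L))
      break
    }
    w <- w / nw
    t_a <- as.numeric(Xa %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) {
      warning(sprintf("PLS rank exhausted at %d component(s)", a - 1L))
      break
    }
    p_a <- as.numeric(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    ssy <- c(ssy, q_a^2 * tt)           # response sum of squares explained
    W <- cbind(W, w)
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
  }
  if (is.null(W)) stop("no usable PLS component (degenerate input)")
  vip <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  setNames(vip, colnames(X))
}

#' Pooled two-sample t tests per metabolite
#'
#' Two-sided Student's t with pooled (equal) variance on log-transformed
#' normalised intensities, df = nA + nB - 2. A metabolite with zero pooled
#' variance gets t = 0, p = 1 (conservative) with a warning.
#'
#' @param table a normalised `"intensity_table"`.
#' @param group_a,group_b group labels as in [group_labels()]; the t
#'   statistic is for `group_b - group_a`.
#' @param log_transform test log intensities (default `TRUE`).
#' @return data.frame with columns `metabolite`, `t_statistic`, `df`,
#'   `p_value`.
#' @export
two_sample_t <- function(table, group_a, group_b, log_transform = TRUE) {
  stopifnot(inherits(table, "intensity_table"))
  labs <- group_labels(table)
  ia <- which(labs == group_a)
  ib <- which(labs == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs at least 2 replicates")
  vals <- table$values[assay_rows(table), , drop = FALSE]
  if (log_transform) vals <- log(vals)
  na <- length(ia); nb <- length(ib)
  res <- t(apply(vals, 1, function(row) {
    xa <- row[ia]; xb <- row[ib]
    sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) /
      (na + nb - 2)
    if (sp2 < .Machine$double.eps) return(c(0, 1, 1))
    tval <- (mean(xb) - mean(xa)) / sqrt(sp2 * (1 / na + 1 / nb))
    c(tval, 2 * stats::pt(-abs(tval), df = na + nb - 2), 0)
  }))
  degenerate <- rownames(vals)[res[, 3] == 1]
  if (length(degenerate))
    warning(sprintf("zero pooled variance, p set to 1: %s",
                    paste(degenerate, collapse = ", ")))
  out <- data.frame(metabolite = rownames(vals), t_statistic = res[, 1],
                    df = na + nb - 2, p_value = res[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment via [stats::p.adjust()], order-preserving with the
#' input, monotone in p-rank and never below the raw p-value.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 fold change between two groups
#'
#' `log2(mean_B / mean_A)` per metabolite on normalised (not unit-variance
#' scaled) intensities, with `group_a` the control — so the control level
#' is defined as 1.00 and a doubling in the treated group reads as +1.
#'
#' @param table a normalised `"intensity_table"`.
#' @param group_a control group label; `group_b` treated group label.
#' @param group_b see `group_a`.
#' @return data.frame with `metabolite`, `mean_A`, `mean_B`,
#'   `fold_change_log2`.
#' @export
fold_change <- function(table, group_a, group_b) {
  stopifnot(inherits(table, "intensity_table"))
  labs <- group_labels(table)
  ia <- which(labs == group_a)
  ib <- which(labs == group_b)
  if (!length(ia) || !length(ib))
    stop(sprintf("empty group: %s", if (!length(ia)) group_a else group_b))
  vals <- table$values[assay_rows(table), , drop = FALSE]
  ma <- rowMeans(vals[, ia, drop = FALSE])
  mb <- rowMeans(vals[, ib, drop = FALSE])
  data.frame(metabolite = rownames(vals), mean_A = unname(ma),
             mean_B = unname(mb), fold_change_log2 = unname(log2(mb / ma)),
             stringsAsFactors = FALSE)
}

#' Apply the differential-selection rule
#'
#' A metabolite is selected when p < `alpha`, VIP > `vip_min` and
#' q <= `fdr_max` simultaneously.
#'
#' @param stats data.frame containing columns `metabolite`, `p_value`,
#'   `q_value`, `vip`.
#' @param alpha t-test significance level (default 0.05).
#' @param vip_min VIP threshold (default 1).
#' @param fdr_max BH-FDR limit (default 0.05).
#' @return The input with a logical `selected` column appended.
#' @export
select_differential <- function(stats, alpha = 0.05, vip_min = 1,
                                fdr_max = 0.05) {
  req <- c("metabolite", "p_value", "q_value", "vip")
  miss <- setdiff(req, names(stats))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  stats$selected <- stats$p_value < alpha & stats$vip > vip_min &
    stats$q_value <= fdr_max
  stats
}

#' Full differential analysis for one contrast
#'
#' Runs internal-standard normalisation (unless already applied), pooled t
#' tests on log intensities, BH-FDR, log2 fold changes on normalised
#' intensities, PLS-DA VIP scores on the unit-variance-scaled profiles of
#' the two groups, and the selection rule.
#'
#' @param table an `"intensity_table"`.
#' @param control,treated group labels (see [group_labels()]); fold
#'   changes are `log2(treated / control)`.
#' @param alpha,vip_min,fdr_max selection thresholds, see
#'   [select_differential()].
#' @param n_components PLS components for the VIP scores.
#' @return A `"differential_result"` data.frame: `metabolite`, `mean_A`,
#'   `mean_B`, `fold_change_log2`, `t_statistic`, `p_value`, `q_value`,
#'   `vip`, `selected`.
#' @export
differential_analysis <- function(table, control, treated, alpha = 0.05,
                                  vip_min = 1, fdr_max = 0.05,
                                  n_components = 2) {
  stopifnot(inherits(table, "intensity_table"))
  if (!table$normalized && length(table$internal_standard_ids))
    table <- normalize_by_internal_standard(table)
  labs <- group_labels(table)
  keep <- labs %in% c(control, treated)
  sub <- intensity_table(table$values[, keep, drop = FALSE],
                         table$sample_design[keep, , drop = FALSE],
                         table$internal_standard_ids)
  sub$normalized <- TRUE
  tt <- two_sample_t(sub, control, treated)
  fc <- fold_change(sub, control, treated)
  scaled <- uv_scale(sub)
  vip <- plsda_vip(scaled, group_labels(sub), n_components = n_components)
  res <- merge(fc, tt, by = "metabolite", sort = FALSE)
  res$q_value <- bh_fdr(res$p_value)
  res$vip <- unname(vip[res$metabolite])
  res$vip[is.na(res$vip)] <- 0         # zero-variance rows dropped by scaling
  res <- select_differential(res, alpha, vip_min, fdr_max)
  res$df <- NULL
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Ward hierarchical clustering of metabolite profiles
#'
#' Agglomerative clustering with Ward's criterion (`ward.D2`) on Euclidean
#' distances between unit-variance-scaled profiles. Ties are resolved
#' deterministically (lowest-index pair first, the [stats::hclust()]
#' convention).
#'
#' @param scaled matrix from [uv_scale()], metabolites x samples (>= 2
#'   rows).
#' @return An [stats::hclust()] dendrogram (`merge`, `height`, `order`,
#'   `labels`).
#' @export
hierarchical_clustering <- function(scaled) {
  scaled <- as.matrix(scaled)
  if (nrow(scaled) < 2L) stop("clustering needs at least 2 profiles")
  stats::hclust(stats::dist(scaled, method = "euclidean"),
                method = "ward.D2")
}

#' Read an intensity table and its design from TSV files
#'
#' The intensity TSV has metabolite ids in the first column and one column
#' per sample; the design TSV has columns `sample_id`, `carbon_source`,
#' `timepoint_h`, `replicate`.
#'
#' @param table_path,design_path input file paths.
#' @param internal_standard_ids metabolite ids of the spiked standards.
#' @return An `"intensity_table"`.
#' @export
read_intensity_table <- function(table_path, design_path,
                                 internal_standard_ids = character()) {
  tab <- utils::read.delim(table_path, check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  design <- utils::read.delim(design_path)
  intensity_table(vals, design, internal_standard_ids)
}

#' Write an intensity table and its design to TSV files
#'
#' @param table an `"intensity_table"`.
#' @param table_path,design_path output file paths.
#' @return `table_path`, invisibly.
#' @export
write_intensity_table <- function(table, table_path, design_path) {
  stopifnot(inherits(table, "intensity_table"))
  out <- data.frame(metabolite = rownames(table$values),
                    table$values, check.names = FALSE)
  utils::write.table(out, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$sample_design, design_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(table_path)
}
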