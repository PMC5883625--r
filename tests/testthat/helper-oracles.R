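# Independent oracles, implemented without reference to the package's own
# algorithms.

# LP oracle by brute-force vertex enumeration. The feasible set
# {v : S v = 0, lb <= v <= ub} is a bounded polytope, so when non-empty it
# has a vertex and the optimum is attained at one. A vertex has at least
# n - rank(S) variables at a bound; enumerate every choice of that many
# variables, every lower/upper assignment for them, solve the equality
# system for the rest and keep feasible points.
lp_vertex_oracle <- function(obj, S, lb, ub, tol = 1e-7) {
  n <- ncol(S)
  r <- qr(S)$rank
  nfix <- n - r
  best <- -Inf
  feasible <- FALSE
  consider <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (max(abs(S %*% v)) > tol) return()
    feasible <<- TRUE
    val <- sum(obj * v)
    if (val > best) best <<- val
  }
  if (nfix == 0) {
    sol <- qr.solve(S, rep(0, nrow(S)))
    consider(sol)
  } else {
    fix_sets <- utils::combn(n, nfix, simplify = FALSE)
    for (fs in fix_sets) {
      free <- setdiff(seq_len(n), fs)
      Sf <- S[, free, drop = FALSE]
      qrSf <- qr(Sf)
      if (qrSf$rank < length(free)) next  # not a vertex-defining basis
      n_assign <- 2^nfix
      for (mask in 0:(n_assign - 1)) {
        bits <- as.integer(intToBits(mask))[seq_len(nfix)]
        vfix <- ifelse(bits == 1, ub[fs], lb[fs])
        rhs <- -S[, fs, drop = FALSE] %*% vfix
        vfree <- tryCatch(qr.coef(qrSf, rhs), error = function(e) NULL)
        if (is.null(vfree) || anyNA(vfree)) next
        v <- numeric(n)
        v[fs] <- vfix
        v[free] <- vfree
        consider(v)
      }
    }
  }
  if (!feasible) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best)
}

solve_fba_vs_oracle <- function(model) {
  S <- stoichiometry_matrix(model)
  b <- flux_bounds(model)
  obj <- as.numeric(b$reaction_id == model$objective_id)
  oracle <- lp_vertex_oracle(obj, S, b$lower, b$upper)
  sol <- solve_fba(fba_problem(model))
  list(oracle = oracle, solution = sol)
}

# Naive O(n^3) agglomerative clustering with the Ward criterion in its
# "ward.D2" form: squared cluster distances updated by the Lance-Williams
# recurrence on squared Euclidean input. Returns merge heights and the
# member sets of each merge.
ward_oracle <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  merge_sets <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (d2[i, j] < best[1] - 1e-12) best <- c(d2[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights[step] <- sqrt(best[1])
    merge_sets[[step]] <- sort(c(members[[i]], members[[j]]))
    # Lance-Williams update (Ward) for every other active cluster
    for (k in setdiff(active, c(i, j))) {
      ai <- (sizes[i] + sizes[k]) / (sizes[i] + sizes[j] + sizes[k])
      aj <- (sizes[j] + sizes[k]) / (sizes[i] + sizes[j] + sizes[k])
      bk <- -sizes[k] / (sizes[i] + sizes[j] + sizes[k])
      d2[i, k] <- d2[k, i] <- ai * d2[i, k] + aj * d2[j, k] + bk * d2[i, j]
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  list(heights = heights, merge_sets = merge_sets)
}

# Single-component PLS projection oracle for the two-group, small-p case:
# weights proportional to the covariance of each variable with the centred
# group indicator; VIP from the single component reduces to
# sqrt(p) * |w_j| / ||w||.
vip_single_component_oracle <- function(scaled, labels) {
  X <- t(scaled)
  y <- as.numeric(as.factor(labels)) - 1
  y <- y - mean(y)
  X <- sweep(X, 2, colMeans(X))
  w <- as.numeric(crossprod(X, y))
  sqrt(ncol(X)) * abs(w) / sqrt(sum(w^2))
}
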