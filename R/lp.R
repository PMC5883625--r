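# Dense bounded-variable primal simplex. This is the linear-programming
# kernel behind solve_fba(); it is written for the small, fully dense,
# box-bounded problems that arise from reduced metabolic models (tens of
# reactions), not as a general sparse LP code.
#
# Problem form:  max/min c'x  s.t.  A x = b,  l <= x <= u,  all bounds finite.
#
# Phase 1 runs with one artificial variable per equality row; Bland's
# smallest-index rule is used throughout, which guarantees termination in
# the presence of degeneracy at the cost of a few extra pivots (irrelevant
# at this scale).

#' Solve a box-bounded linear program
#'
#' Maximises (or minimises) `obj %*% x` subject to `A %*% x == b` and
#' `lower <= x <= upper`. All bounds must be finite: flux bounds in
#' constraint-based models are box bounds by construction, so a bounded
#' feasible polytope is guaranteed and an "unbounded" outcome cannot occur.
#'
#' @param obj numeric objective coefficient vector (length `ncol(A)`).
#' @param A dense constraint matrix of the equality system.
#' @param b right-hand side vector (length `nrow(A)`).
#' @param lower,upper finite variable bounds.
#' @param sense `"max"` or `"min"`.
#' @param tol pivot tolerance.
#' @return A list with `status` (`"optimal"` or `"infeasible"`), `x`
#'   (primal solution when optimal) and `objective` (its objective value).
#' @keywords internal
lp_solve <- function(obj, A, b, lower, upper, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lower) == n, length(upper) == n)
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("lp_solve requires finite variable bounds")
  if (any(lower > upper + tol))
    stop("lp_solve: lower bound exceeds upper bound")
  if (sense == "min") obj <- -obj

  if (n == 0L || m == 0L) {
    # no equality rows: each variable sits at whichever bound favours obj
    x <- ifelse(obj >= 0, upper, lower)
    if (m > 0L) x <- numeric(0)
    val <- if (n > 0L) sum(obj * x) else 0
    if (sense == "min") val <- -val
    return(list(status = "optimal", x = x, objective = val))
  }

  # Phase 1 setup: structurals at lower bound, artificials absorb residual.
  x0 <- lower
  resid <- b - as.numeric(A %*% x0)
  sgn <- ifelse(resid >= 0, 1, -1)
  big <- sum(abs(resid)) + 1
  Aall <- cbind(A, diag(sgn, m))
  lall <- c(lower, rep(0, m))
  uall <- c(upper, rep(big, m))
  xall <- c(x0, abs(resid))
  basis <- n + seq_len(m)
  stat <- rep("L", n + m)

  run <- function(cc, basis, xall, stat, lock_artificials) {
    max_iter <- 500L * (n + m)
    for (it in seq_len(max_iter)) {
      AB <- Aall[, basis, drop = FALSE]
      y <- tryCatch(solve(t(AB), cc[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(ok = FALSE))
      nonbasic <- setdiff(seq_len(n + m), basis)
      if (lock_artificials) nonbasic <- nonbasic[nonbasic <= n]
      dj <- cc[nonbasic] - as.numeric(crossprod(Aall[, nonbasic, drop = FALSE], y))
      eligible <- (stat[nonbasic] == "L" & dj > tol) |
                  (stat[nonbasic] == "U" & dj < -tol)
      if (!any(eligible))
        return(list(ok = TRUE, basis = basis, x = xall, stat = stat))
      j <- nonbasic[eligible][1L]  # Bland's rule
      dir <- if (stat[j] == "L") 1 else -1
      w <- as.numeric(solve(AB, Aall[, j]))
      tmax <- uall[j] - lall[j]
      leave <- 0L
      for (k in seq_len(m)) {
        wk <- dir * w[k]
        if (wk > tol) {
          lim <- (xall[basis[k]] - lall[basis[k]]) / wk
        } else if (wk < -tol) {
          lim <- (uall[basis[k]] - xall[basis[k]]) / (-wk)
        } else next
        if (lim < tmax - 1e-12 ||
            (lim < tmax + 1e-12 && leave != 0L && basis[k] < basis[leave])) {
          tmax <- lim
          leave <- k
        }
      }
      tmax <- max(tmax, 0)
      xall[basis] <- xall[basis] - tmax * dir * w
      xall[j] <- xall[j] + dir * tmax
      if (leave == 0L) {
        stat[j] <- if (stat[j] == "L") "U" else "L"
        xall[j] <- if (stat[j] == "L") lall[j] else uall[j]
      } else {
        lv <- basis[leave]
        stat[lv] <- if (dir * w[leave] > 0) "L" else "U"
        xall[lv] <- if (stat[lv] == "L") lall[lv] else uall[lv]
        basis[leave] <- j
        stat[j] <- "B"
      }
    }
    list(ok = FALSE)
  }

  phase1 <- run(c(rep(0, n), rep(-1, m)), basis, xall, stat,
                lock_artificials = FALSE)
  if (!phase1$ok) stop("lp_solve: simplex failed to converge in phase 1")
  art_sum <- sum(phase1$x[n + seq_len(m)])
  if (art_sum > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))

  uall[n + seq_len(m)] <- 0
  phase2 <- run(c(obj, rep(0, m)), phase1$basis, phase1$x, phase1$stat,
                lock_artificials = TRUE)
  if (!phase2$ok) stop("lp_solve: simplex failed to converge in phase 2")
  x <- phase2$x[seq_len(n)]
  val <- sum(obj * x)
  if (sense == "min") val <- -val
  list(status = "optimal", x = x, objective = val)
}
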