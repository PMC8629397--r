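#' Ratio bounds on consecutive spectrum entries
#'
#' Lower and upper bounds `L_j <= r_j / r_{j+1} <= U_j` for `j = 1..n-1`,
#' typically the empirical support of the ratios over a training corpus
#' (see [fit_ratio_bounds()]).
#'
#' @param lower,upper Numeric vectors of equal length with
#'   `0 < lower <= upper`.
#' @return A `ratio_bounds` object (tibble with columns `j`, `lower`,
#'   `upper`).
#' @export
ratio_bounds <- function(lower, upper) {
  stopifnot(length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(lower > upper)) {
    abort("ratio bounds must satisfy 0 < lower <= upper < Inf",
          class = "skimspect_domain_error")
  }
  out <- tibble(j = seq_along(lower), lower = as.numeric(lower),
                upper = as.numeric(upper))
  class(out) <- c("ratio_bounds", class(out))
  out
}

# Recycle or truncate bounds to n-1 ratios; beyond the trained range the last
# bound is carried forward (sparsely populated high-j ratio pools).
bounds_for_n <- function(bounds, n) {
  if (n < 2) return(ratio_bounds(numeric(0), numeric(0)))
  need <- n - 1
  lo <- bounds$lower
  up <- bounds$upper
  if (length(lo) < need) {
    lo <- c(lo, rep(lo[length(lo)], need - length(lo)))
    up <- c(up, rep(up[length(up)], need - length(up)))
  }
  ratio_bounds(lo[seq_len(need)], up[seq_len(need)])
}

#' Non-negative least-squares spectrum estimate
#'
#' The unconstrained baseline: `argmin_{r >= 0} || o - P r ||_2` via
#' Lawson–Hanson NNLS. Accurate for `r_1` but unstable for higher
#' multiplicities because the mixture matrix is severely ill-conditioned;
#' kept as the reference the constrained estimators are compared against.
#'
#' @param o Observed histogram counts, length `nrow(P)`.
#' @param P Mixture matrix.
#' @return A list with elements `r` (non-negative spectrum estimate) and
#'   `residual` (Euclidean residual norm).
#' @export
estimate_ls <- function(o, P) {
  o <- hist_vector(o)
  stopifnot(length(o) == nrow(P))
  if (all(o == 0)) {
    return(list(r = numeric(ncol(P)), residual = 0))
  }
  fit <- pracma::lsqnonneg(P, o)
  list(r = as.numeric(fit$x), residual = sqrt(max(fit$resid.norm, 0)))
}

#' Ratio-constrained linear-programming spectrum estimate
#'
#' Minimises the L1 error over bins `h >= 2`,
#' `sum_{h=2}^m | o_h - sum_j P_hj r_j |`, subject to the linearised ratio
#' constraints `lower_j * r_{j+1} <= r_j <= upper_j * r_{j+1}` and `r >= 0`.
#' The singleton bin is excluded because it is dominated by erroneous k-mers.
#' The absolute values are handled with one auxiliary variable per bin, and
#' the residual rows are scaled by `max(o)` for numerical stability.
#'
#' @param o Observed histogram counts, length `nrow(P)`.
#' @param P Mixture matrix (m x n).
#' @param bounds A [ratio_bounds()] object (extended to `n - 1` ratios by
#'   carrying the last bound forward if shorter).
#' @param drop_tol Entries of `P` below this value are zeroed before the
#'   solve; deep Poisson tails (down to 1e-70 and beyond) otherwise destroy
#'   the solver's arithmetic while contributing nothing to the fit.
#' @return A list with `r` (spectrum estimate), `objective` (L1 error over
#'   `h >= 2`), and `status` (solver status string).
#' @export
estimate_lp <- function(o, P, bounds, drop_tol = 1e-14) {
  o <- hist_vector(o)
  m <- nrow(P)
  n <- ncol(P)
  stopifnot(length(o) == m)
  if (!inherits(bounds, "ratio_bounds")) {
    abort("bounds must be a ratio_bounds object",
          class = "skimspect_domain_error")
  }
  bnd <- bounds_for_n(bounds, n)
  if (all(o == 0)) {
    return(list(r = numeric(n), objective = 0, status = "optimal"))
  }
  if (m < 2) {
    abort("need at least two histogram bins for the L1 fit",
          class = "skimspect_domain_error")
  }

  Pm <- P[2:m, , drop = FALSE]
  Pm[Pm < drop_tol] <- 0
  om <- o[2:m]
  sc <- max(om, 1)
  Ps <- Pm / sc
  os <- om / sc
  na <- m - 1 # auxiliary |residual| variables
  nv <- n + na

  # residual envelope:  P r / sc - e <= o/sc  and  -P r / sc - e <= -o/sc
  A_up <- cbind(Ps, -diag(na))
  A_lo <- cbind(-Ps, -diag(na))
  # ratio chain: lower_j r_{j+1} - r_j <= 0 ; r_j - upper_j r_{j+1} <= 0
  n_ratio <- n - 1
  R <- matrix(0, 2 * n_ratio, nv)
  for (j in seq_len(n_ratio)) {
    R[j, j] <- -1
    R[j, j + 1] <- bnd$lower[j]
    R[n_ratio + j, j] <- 1
    R[n_ratio + j, j + 1] <- -bnd$upper[j]
  }
  A <- rbind(A_up, A_lo, R)
  b <- c(os, -os, numeric(2 * n_ratio))
  cc <- c(numeric(n), rep(1, na))

  # no single simplex configuration is reliable on every mixture system;
  # cascade scaled/unscaled primal, then the dual simplex
  configs <- list(c(scale = 1, meth = 1), c(scale = 0, meth = 1),
                  c(scale = 1, meth = 3), c(scale = 0, meth = 3))
  sol <- NULL
  status <- "unsolved"
  for (cfg in configs) {
    sol <- cpp_lp_solve(cc, A, b, scale = cfg[["scale"]],
                        meth = cfg[["meth"]])
    status <- lp_status_string(sol$status, sol$ret)
    if (status == "optimal") break
  }
  if (status != "optimal") {
    abort(paste0("LP solver failed: ", status),
          class = "skimspect_solver_error")
  }
  r <- pmax(sol$x[seq_len(n)], 0)
  list(r = r, objective = sol$objective * sc, status = status)
}

lp_status_string <- function(status, ret) {
  if (ret != 0) return(sprintf("solver error (ret=%d)", ret))
  switch(as.character(status),
         "5" = "optimal",
         "2" = "feasible (not proven optimal)",
         "3" = "infeasible",
         "4" = "no feasible solution",
         "6" = "unbounded",
         sprintf("undefined (status=%d)", status))
}

#' Spline-corrected spectrum estimate
#'
#' Takes the LP estimate and rewrites the low-multiplicity entries using
#' spectral-ratio splines learned from assemblies: with
#' `u_j = r_j^LP / sum_{i >= j} r_i^LP` and predicted ratio
#' `y_j = s_j(u_j)`, the corrected spectrum is defined recursively as
#' `r_1 = r_1^LP`, `r_j = r_{j-1} / y_{j-1}` for `j = 2..6`, and the LP value
#' for `j > 6`. The first entry — which the LP already estimates well — thus
#' anchors the corrected head of the spectrum.
#'
#' @inheritParams estimate_lp
#' @param splines A `ratio_splines` model from [fit_ratio_splines()].
#' @return A list with `r` (corrected spectrum), `r_lp` (the LP estimate),
#'   `objective` (L1 error of the corrected spectrum over `h >= 2`),
#'   `lp_objective`, and `status`.
#' @export
estimate_slp <- function(o, P, bounds, splines, drop_tol = 1e-14) {
  lp <- estimate_lp(o, P, bounds, drop_tol = drop_tol)
  r <- slp_correct(lp$r, splines)
  o <- hist_vector(o)
  obj <- spectrum_objective(o[seq_len(nrow(P))], as.vector(P %*% r), p = 1)
  list(r = r, r_lp = lp$r, objective = obj, lp_objective = lp$objective,
       status = lp$status)
}

slp_correct <- function(r_lp, splines) {
  j_max <- min(length(splines$models), 5L)
  n <- length(r_lp)
  r <- r_lp
  if (n < 2 || sum(r_lp) <= 0) return(r)
  tails <- rev(cumsum(rev(r_lp)))
  for (j in seq_len(min(j_max, n - 1))) {
    if (tails[j] <= 0 || r_lp[j] <= 0) break
    u <- r_lp[j] / tails[j]
    y <- predict_ratio(splines, j, u)
    r[j + 1] <- r[j] / y
  }
  r
}
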