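test_that("NNLS recovers forward-constructed spectra on noiseless data", {
  n <- 3
  P <- mixture_matrix(2, m = 30, n = n)
  r_true <- c(1000, 100, 10)
  o <- as.vector(P %*% r_true)
  fit <- estimate_ls(o, P)
  expect_equal(fit$r, r_true, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-6 * sqrt(sum(o^2)))

  expect_equal(estimate_ls(numeric(30), P)$r, numeric(3))
})

test_that("unconstrained least squares is unstable under tiny perturbations", {
  # the ill-conditioning demonstration: a 1% data perturbation at n = 30
  # produces relative errors in r far beyond 1%
  n <- 30
  P <- mixture_matrix(1, m = n, n = n)
  r_true <- 1e6 * 0.8^(0:(n - 1))
  o <- as.vector(P %*% r_true)
  set.seed(7)
  o_pert <- o * (1 + 0.01 * rnorm(n))
  r_hat <- estimate_ls(o_pert, P)$r
  rel <- abs(r_hat - r_true) / r_true
  expect_gt(max(rel[3:10]), 1) # some r_j off by more than 100%
})

test_that("ratio bounds validate their invariants", {
  expect_s3_class(ratio_bounds(c(1, 2), c(4, 2)), "ratio_bounds")
  expect_error(ratio_bounds(c(2), c(1)), class = "skimspect_domain_error")
  expect_error(ratio_bounds(c(0), c(1)), class = "skimspect_domain_error")
  expect_error(ratio_bounds(c(1), c(Inf)), class = "skimspect_domain_error")
})

grid_search_lp <- function(o, P, lower, upper, r1_grid, ratio_grid) {
  # brute-force oracle: minimize the L1 objective over a dense grid of
  # (r1, consecutive ratios), honouring the ratio box constraints
  n <- ncol(P)
  ratio_sets <- lapply(seq_len(n - 1), function(j) {
    ratio_grid[ratio_grid >= lower[j] & ratio_grid <= upper[j]]
  })
  combos <- as.matrix(expand.grid(c(list(r1 = r1_grid), ratio_sets)))
  R <- matrix(0, nrow(combos), n)
  R[, 1] <- combos[, 1]
  for (j in 2:n) R[, j] <- R[, j - 1] / combos[, j]
  resid <- abs(matrix(o[-1], nrow(combos), nrow(P) - 1, byrow = TRUE) -
                 R %*% t(P[-1, , drop = FALSE]))
  objs <- rowSums(resid)
  best <- which.min(objs)
  list(r = R[best, ], objective = objs[best])
}

test_that("LP matches a brute-force grid oracle on small noiseless systems", {
  # 2-component case from first principles
  P <- mixture_matrix(1, m = 12, n = 2)
  r_true <- c(100, 50)
  o <- as.vector(P %*% r_true)
  fit <- estimate_lp(o, P, ratio_bounds(1, 4))
  expect_equal(fit$r, r_true, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-6 * sum(o))

  # n = 3 with a deliberately binding constraint: compare objectives with
  # the exhaustive oracle
  P3 <- mixture_matrix(1.5, m = 15, n = 3)
  r3 <- c(500, 100, 40)
  o3 <- as.vector(P3 %*% r3)
  lower <- c(2, 4); upper <- c(8, 9) # true ratios 5 and 2.5: lower[2] binds
  fit3 <- estimate_lp(o3, P3, ratio_bounds(lower, upper))
  oracle <- grid_search_lp(o3, P3, lower, upper,
                           r1_grid = seq(480, 520, by = 0.5),
                           ratio_grid = seq(2, 9, by = 0.02))
  # the LP optimum can only undercut the gridded oracle by its resolution
  expect_lte(fit3$objective, oracle$objective * (1 + 1e-4) + 1e-8)
  expect_gte(fit3$objective, oracle$objective * 0.9 - 1e-8)
  # constraints hold in linearized form
  r <- fit3$r
  expect_true(all(lower * r[2:3] <= r[1:2] + 1e-8))
  expect_true(all(r[1:2] <= upper * r[2:3] + 1e-8))
})

test_that("LP zero data and invalid bounds behave as specified", {
  P <- mixture_matrix(1, 10, 4)
  fit <- estimate_lp(numeric(10), P, ratio_bounds(rep(1, 3), rep(4, 3)))
  expect_equal(fit$r, numeric(4))
  expect_error(estimate_lp(numeric(10), P, list(lower = 1, upper = 2)),
               class = "skimspect_domain_error")
})

test_that("SLP is a fixed point when splines reproduce the LP ratios", {
  P <- mixture_matrix(1, m = 20, n = 6)
  r_true <- c(2000, 400, 100, 40, 20, 12)
  o <- as.vector(P %*% r_true)
  bounds <- ratio_bounds(rep(0.5, 5), rep(100, 5))
  lp <- estimate_lp(o, P, bounds)
  # build splines that predict exactly the LP's own consecutive ratios
  tails <- rev(cumsum(rev(lp$r)))
  grids <- lapply(1:5, function(j) {
    u <- lp$r[j] / tails[j]
    list(j = j, link = "identity", u = c(u - 1e-9, u + 1e-9),
         y = rep(lp$r[j] / lp$r[j + 1], 2), u_range = c(u - 1e-9, u + 1e-9),
         n_train = 2L)
  })
  spl <- structure(list(models = grids, j_max = 5), class = "ratio_splines")
  slp <- estimate_slp(o, P, bounds, spl)
  expect_equal(slp$r, lp$r, tolerance = 1e-6)
})

test_that("SLP rewrites the head by recursive division and passes the tail", {
  toy <- toy_models(y = c(8, 4, 2, 2, 2))
  n <- 8
  P <- mixture_matrix(1, m = 20, n = n)
  r_true <- c(1000, 125, 100, 80, 40, 20, 10, 5)
  o <- as.vector(P %*% r_true)
  slp <- estimate_slp(o, P, toy$bounds, toy$splines)
  # r2 = r1 / y1 = r1 / 8
  expect_equal(slp$r[2], slp$r[1] / 8, tolerance = 1e-9)
  expect_equal(slp$r[3], slp$r[2] / 4, tolerance = 1e-9)
  # beyond j = 6 the LP solution passes through untouched
  expect_equal(slp$r[7:8], slp$r_lp[7:8])
  expect_true(all(slp$r >= 0))
  expect_true(is.finite(slp$objective))
})
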