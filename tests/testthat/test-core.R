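# exact expected error-free histogram at lambda_ef for a repeat-free genome
poisson_histogram <- function(L, lambda_ef, hmax = 25, ...) {
  o <- L * dpois(seq_len(hmax), lambda_ef)
  skimspect:::new_kmer_histogram(o, k = 31, ...)
}

test_that("initialization identities hold on the exact Poisson histogram", {
  h <- poisson_histogram(1e6, 1)
  init <- initialize_skim(h)
  # h* = 2; lambda_ef = 3 o3/o2 = 1; lambda = e^-1/2 * (o1/o2) + 1 - e^-1 = 1
  expect_equal(init$h_star, 2L)
  expect_equal(init$lambda_ef, 1, tolerance = 1e-6)
  expect_equal(init$lambda, 1, tolerance = 1e-6)
  expect_equal(init$eps, 0, tolerance = 1e-6)
})

test_that("argmax ties resolve to the smallest h", {
  o <- c(100, 40, 40, 5)
  init <- initialize_skim(skimspect:::new_kmer_histogram(o, k = 31))
  expect_equal(init$h_star, 2L)
})

test_that("singleton excess from sequencing errors raises the error estimate", {
  # inflate o1 by the expected erroneous-k-mer mass at eps = 0.01
  L <- 1e6
  lam <- 0.7
  ef <- lam * (1 - 0.01)^31
  o <- L * dpois(1:25, ef)
  o[1] <- o[1] + expected_erroneous_kmers(L, lam, 0.01, 31)
  init <- initialize_skim(skimspect:::new_kmer_histogram(o, k = 31))
  expect_gt(init$lambda, init$lambda_ef)
  expect_gt(init$eps, 0)
  expect_equal(init$eps, 0.01, tolerance = 0.1) # recovered to ~10%
})

test_that("degenerate histograms signal insufficient coverage", {
  expect_error(initialize_skim(skimspect:::new_kmer_histogram(c(5, 1), k = 31)),
               class = "skimspect_data_error")
  expect_error(initialize_skim(skimspect:::new_kmer_histogram(numeric(0),
                                                              k = 31)),
               class = "skimspect_data_error")
})

test_that("coverage proposals are uniform on [lambda/2, 3 lambda]", {
  set.seed(99)
  draws <- replicate(1e4, propose_lambda(0.8))
  expect_true(all(draws >= 0.4 & draws <= 2.4))
  ks <- ks.test(draws, "punif", 0.4, 2.4)
  expect_gt(ks$p.value, 1e-4)
  # determinism under a fixed seed
  set.seed(123); a <- replicate(5, propose_lambda(1))
  set.seed(123); b <- replicate(5, propose_lambda(1))
  expect_identical(a, b)
})

test_that("acceptance probability follows both cooling schedules", {
  expect_equal(accept_probability(10, 5, 1, 100), 1) # improvement
  expect_equal(accept_probability(10, 10, 50, 100), 1) # boundary
  # algorithm1 algebra: Delta = (N - t + 1) ln 2 gives probability 1/2
  N <- 40; t <- 12
  expect_equal(accept_probability(0, (N - t + 1) * log(2), t, N), 0.5)
  # overview variant: Delta * t / N = ln 2 gives 1/2
  expect_equal(accept_probability(0, log(2) * N / t, t, N,
                                  variant = "overview"), 0.5)
  p <- accept_probability(0, 1000, 99, 100)
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("annealing is deterministic and carries a full trace", {
  h <- poisson_histogram(2e5, 0.7, read_length = 100, total_bases = 2e5,
                         n_reads = 2000)
  toy <- toy_models()
  s1 <- anneal(h, toy, iterations = 40, seed = 42, n = 12)
  s2 <- anneal(h, toy, iterations = 40, seed = 42, n = 12)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$lambda, s2$lambda)
  expect_equal(nrow(s1$trace), 40)
  expect_true(all(c("t", "lambda", "objective", "accepted") %in%
                    names(s1$trace)))

  # dry run returns the initialized state without iterating
  s0 <- anneal(h, toy, iterations = 40, seed = 42, n = 12, dry_run = TRUE)
  expect_equal(nrow(s0$trace), 0)
  expect_equal(s0$lambda, initialize_skim(h)$lambda)
})

test_that("finalization enforces the exact output identities", {
  h <- poisson_histogram(1e6, 0.7, read_length = 100, total_bases = 1e6,
                         n_reads = 10000)
  toy <- toy_models()
  state <- anneal(h, toy, iterations = 10, seed = 1, n = 12)
  # force a known lambda to check the closed-form conversions
  state$lambda <- 0.7
  state$eps <- 0
  fit <- finalize_estimate(state, toy, h)
  expect_equal(fit$coverage, 1.0, tolerance = 1e-12)
  expect_equal(fit$length, 1e6, tolerance = 1e-6)
  # L * c = B exactly
  expect_equal(fit$length * fit$coverage, 1e6, tolerance = 1e-9)
})

test_that("epsilon correction respects the cap and the coverage gate", {
  h <- poisson_histogram(1e6, 0.7, read_length = 100, total_bases = 1e6,
                         n_reads = 10000)
  toy <- toy_models()
  state <- anneal(h, toy, iterations = 5, seed = 2, n = 12)
  state$eps <- 0.02

  # a wildly negative prediction is applied as the -20% cap
  ec_neg <- structure(list(intercept = -5, slope = 0, cap = 0.2,
                           coverage_threshold = 1.5),
                      class = "eps_correction")
  toy_ec <- toy
  toy_ec$eps_correction <- ec_neg
  state$lambda <- 0.7 # coverage 1.0 < 1.5: gate open
  fit <- finalize_estimate(state, toy_ec, h)
  expect_true(fit$correction_applied)
  expect_equal(fit$eps, 0.02 / (1 - 0.2), tolerance = 1e-12)

  # estimated coverage 2.0: no correction even with a huge prediction
  state$lambda <- 1.4
  fit2 <- finalize_estimate(state, toy_ec, h)
  expect_false(fit2$correction_applied)
  expect_equal(fit2$eps, fit2$eps_initial)

  # histograms without metadata cannot be finalized
  h_bare <- poisson_histogram(1e6, 0.7)
  expect_error(finalize_estimate(state, toy_ec, h_bare),
               class = "skimspect_data_error")
})

test_that("tidy, glance and autoplot views expose the fit", {
  h <- poisson_histogram(2e5, 0.7, read_length = 100, total_bases = 2e5,
                         n_reads = 2000)
  fit <- estimate_genome(h, models = toy_models(), iterations = 20,
                         seed = 3, n = 12)
  td <- tidy(fit)
  expect_equal(names(td), c("j", "r"))
  expect_equal(nrow(td), 12)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("length", "coverage", "eps", "uniqueness",
                    "iterations") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
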