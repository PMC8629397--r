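test_that("assembly spectra come from exact canonical counting", {
  sp <- repeat_spectrum("AAAAA", k = 3)
  expect_equal(sp$r[1:3], c(0, 0, 1)) # AAA occurs three times
  expect_equal(sp$L, 5) # k - 1 + sum j r_j = 2 + 3

  # manual canonical enumeration: ACGT x2 (self-canonical), CGTA -> CGTA? no:
  # windows ACGT,CGTA,GTAC,TACG,ACGT; canonical collapse gives counts 2,2,1
  sp2 <- repeat_spectrum("ACGTACGT", k = 4)
  expect_equal(sp2$r[1:2], c(1, 2))
  expect_equal(sp2$L, 8)

  expect_error(repeat_spectrum("ACG", k = 5),
               class = "skimspect_domain_error")
})

test_that("copy numbers beyond n land in the overflow, keeping L exact", {
  seqs <- paste(rep("ACGTTTGAC", 7), collapse = "") # short tandem-ish repeat
  sp <- repeat_spectrum(seqs, k = 5, n = 3)
  expect_true(nrow(sp$overflow) > 0)
  full_total <- sum(seq_len(3) * sp$r[1:3]) +
    sum(sp$overflow$j * sp$overflow$count)
  expect_equal(sp$L, 5 - 1 + full_total)
})

test_that("whole-genome duplication doubles copy numbers up to junctions", {
  set.seed(11)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  one <- repeat_spectrum(g, k = 21, n = 10)
  two <- repeat_spectrum(paste0(g, g), k = 21, n = 10)
  # every interior k-mer moves from multiplicity 1 to 2; only the 20
  # junction windows (and chance collisions) can deviate
  expect_lt(abs(two$r[2] - one$r[1]), 25)
  expect_lt(two$r[1], 25)
  expect_lt(two$uniqueness, 0.01)
})

test_that("ratio bounds are the empirical support with exclusion rules", {
  mk <- function(r) new_repeat_spectrum(r, k = 31, n = length(r))
  b <- fit_ratio_bounds(list(mk(c(1000, 500)), mk(c(1200, 300))), n = 2,
                        min_count = 100)
  expect_equal(b$lower, 2)
  expect_equal(b$upper, 4)

  # toy counts below min_count still produce bounds via the fallback
  b_toy <- fit_ratio_bounds(list(mk(c(10, 5)), mk(c(12, 3))), n = 2)
  expect_equal(b_toy$lower, 2)
  expect_equal(b_toy$upper, 4)

  # a genome with r2 = 0 contributes nothing to the j = 1 pool
  b2 <- fit_ratio_bounds(list(mk(c(1000, 500)), mk(c(800, 0)),
                              mk(c(1200, 300))), n = 2, min_count = 100)
  expect_equal(unlist(b2[1, c("lower", "upper")], use.names = FALSE),
               c(2, 4))

  expect_warning(fit_ratio_bounds(list(mk(c(1000, 500))), n = 2),
                 "degenerate")

  # bounds always bracket the contributing training ratios
  set.seed(3)
  spectra <- lapply(1:8, function(i) {
    mk(round(5000 * runif(1, 0.5, 2) * 0.6^(0:5)))
  })
  b3 <- fit_ratio_bounds(spectra, n = 6, min_count = 10)
  for (s in spectra) {
    y <- s$r[1:5] / s$r[2:6]
    ok <- s$r[1:5] >= 10 & s$r[2:6] >= 10
    expect_true(all(y[ok] >= b3$lower[ok] - 1e-9))
    expect_true(all(y[ok] <= b3$upper[ok] + 1e-9))
  }
})

test_that("ratio splines recover a smooth synthetic relation", {
  # pairs lying exactly on y = exp(1.2 + 2 u): the fitted curve must
  # reproduce it within 1% across the training domain
  set.seed(5)
  u <- seq(0.05, 0.95, length.out = 60)
  pairs <- lapply(1:5, function(j) data.frame(u = u, y = exp(1.2 + 2 * u)))
  spl <- suppressWarnings(fit_ratio_splines(pairs = pairs)) # exact data: step warnings
  u_test <- seq(0.1, 0.9, length.out = 21)
  pred <- predict_ratio(spl, 1, u_test)
  expect_equal(pred, exp(1.2 + 2 * u_test), tolerance = 0.01)

  # a constant relation stays constant (slope penalised away)
  pairs_c <- lapply(1:5, function(j) data.frame(u = u, y = rep(3, 60)))
  spl_c <- suppressWarnings(fit_ratio_splines(pairs = pairs_c))
  expect_equal(predict_ratio(spl_c, 3, u_test), rep(3, 21),
               tolerance = 1e-6)

  # predictions stay within the envelope of noisy training responses
  y_noisy <- exp(1.2 + 2 * u) * rgamma(60, shape = 200, rate = 200)
  pairs_n <- lapply(1:5, function(j) data.frame(u = u, y = y_noisy))
  spl_n <- fit_ratio_splines(pairs = pairs_n)
  pred_n <- predict_ratio(spl_n, 2, u_test)
  expect_true(all(pred_n <= max(y_noisy) & pred_n >= min(y_noisy)))

  # out-of-domain inputs are clamped, keeping predictions positive/finite
  expect_equal(predict_ratio(spl, 1, -1), predict_ratio(spl, 1, 0.05))
  expect_equal(predict_ratio(spl, 1, 2), predict_ratio(spl, 1, 0.95))

  expect_error(fit_ratio_splines(pairs = lapply(1:5, function(j) {
    data.frame(u = u, y = c(-1, rep(2, 59)))
  })), class = "skimspect_domain_error")
})

test_that("epsilon correction regression recovers known relations", {
  # null signal: zero error everywhere gives a zero correction
  p0 <- data.frame(true_eps = rep(0.01, 5), est_eps = rep(0.01, 5),
                   uniqueness = seq(0.3, 0.9, length.out = 5))
  c0 <- fit_epsilon_correction(p0)
  expect_equal(predict_eps_rel_error <- skimspect:::predict_eps_rel_error(
    c0, c(0.4, 0.8)), c(0, 0), tolerance = 1e-12)

  # exact linear relation: coefficients recovered to least-squares precision
  u <- seq(0.3, 0.95, length.out = 10)
  rel <- 0.62 - 0.55 * u
  p1 <- data.frame(true_eps = 0.01, est_eps = 0.01 * (1 + rel),
                   uniqueness = u)
  c1 <- fit_epsilon_correction(p1)
  expect_equal(c1$intercept, 0.62, tolerance = 1e-6)
  expect_equal(c1$slope, -0.55, tolerance = 1e-6)

  # predictions clamp at the +/- 20% cap
  big <- fit_epsilon_correction(data.frame(
    true_eps = 0.01, est_eps = 0.01 * (1 + c(0.9, 0.5, 0.1)),
    uniqueness = c(0.3, 0.6, 0.9)))
  expect_equal(skimspect:::predict_eps_rel_error(big, 0.3), 0.2)
  expect_equal(skimspect:::predict_eps_rel_error(big, 2), -0.2)

  expect_error(fit_epsilon_correction(p1[1:2, ]),
               class = "skimspect_domain_error")
})

test_that("trained models serialize to JSON and back losslessly", {
  mk <- function(r) new_repeat_spectrum(r, k = 31, n = length(r))
  set.seed(9)
  spectra <- lapply(1:12, function(i) {
    mk(round(1e5 * runif(1, 0.5, 2) * 0.55^(0:9)))
  })
  spl <- fit_ratio_splines(spectra)
  b <- fit_ratio_bounds(spectra, n = 10, min_count = 10)
  ec <- fit_epsilon_correction(data.frame(
    true_eps = 0.01, est_eps = c(0.013, 0.012, 0.011, 0.0105),
    uniqueness = c(0.4, 0.6, 0.8, 0.9)))
  tm <- trained_models(b, spl, ec, provenance = list(note = "test", k = 31))

  path <- tempfile(fileext = ".json")
  write_trained_models(tm, path)
  tm2 <- read_trained_models(path)

  expect_equal(tm2$bounds$lower, tm$bounds$lower)
  expect_equal(tm2$bounds$upper, tm$bounds$upper)
  expect_equal(tm2$eps_correction$intercept, ec$intercept)
  expect_equal(tm2$eps_correction$slope, ec$slope)
  expect_equal(tm2$eps_correction$cap, 0.20)
  u <- seq(0.05, 0.95, length.out = 33)
  for (j in 1:5) {
    expect_equal(predict_ratio(tm2$splines, j, u),
                 predict_ratio(tm$splines, j, u), tolerance = 1e-10)
  }
})

test_that("shipped default models load and carry all components", {
  m <- default_trained_models()
  expect_s3_class(m, "trained_models")
  expect_equal(nrow(m$bounds), 49)
  expect_equal(m$splines$j_max, 5)
  expect_false(is.null(m$eps_correction))
  expect_equal(m$eps_correction$cap, 0.20)
  expect_equal(m$eps_correction$coverage_threshold, 1.5)
  expect_lt(m$eps_correction$slope, 0) # error shrinks with uniqueness
})
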