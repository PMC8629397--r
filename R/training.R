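#' Exact repeat spectrum of an assembly
#'
#' Counts canonical k-mers of an assembly and tallies them into the repeat
#' spectrum `r`, where `r_j` is the number of distinct k-mers occurring
#' exactly `j` times in the genome. Copy numbers above `n` are kept in an
#' overflow table (not folded into `r_n`) so the implied genome length
#' `L = k - 1 + sum_j j r_j` stays exact.
#'
#' @param x Assembly sequences (path to FASTA, character vector, or tibble
#'   with a `seq` column).
#' @param k k-mer length (default 31).
#' @param n Number of spectrum entries retained (default 50).
#' @param label Optional species/sample label.
#' @return A `repeat_spectrum` object: list with `r` (length `n`), `k`, `n`,
#'   `overflow` (tibble of `j`, `count` beyond `n`), `L` (exact implied
#'   length, including overflow mass), `uniqueness` (`r_1 / L`), `label`.
#' @examples
#' sp <- repeat_spectrum("AAAAA", k = 3)
#' sp$r[3] # the single 3-mer AAA occurs 3 times
#' sp$L    # 2 + 3 = 5
#' @export
repeat_spectrum <- function(x, k = 31, n = 50, label = NA_character_) {
  seqs <- as_sequence_vector(x)
  o <- cpp_kmer_histogram(seqs, as.integer(k), TRUE)
  if (length(o) == 0L) {
    abort("assembly contains no k-mer of length k",
          class = "skimspect_domain_error")
  }
  new_repeat_spectrum(o, k = k, n = n, label = label)
}

new_repeat_spectrum <- function(full, k, n, label = NA_character_) {
  r <- numeric(n)
  upto <- min(n, length(full))
  r[seq_len(upto)] <- full[seq_len(upto)]
  overflow <- tibble(j = integer(0), count = numeric(0))
  if (length(full) > n) {
    jj <- seq(n + 1L, length(full))
    keep <- full[jj] > 0
    overflow <- tibble(j = jj[keep], count = full[jj][keep])
  }
  L <- k - 1 + sum(seq_along(full) * full)
  structure(
    list(r = r, k = as.integer(k), n = as.integer(n), overflow = overflow,
         L = L, uniqueness = r[1] / L, label = label),
    class = "repeat_spectrum")
}

#' @export
print.repeat_spectrum <- function(x, ...) {
  cat(sprintf("<repeat_spectrum> k=%d n=%d L=%s r1/L=%.3f%s\n",
              x$k, x$n, format(x$L, big.mark = ","), x$uniqueness,
              if (is.na(x$label)) "" else paste0("  [", x$label, "]")))
  invisible(x)
}

#' @export
tidy.repeat_spectrum <- function(x, ...) {
  tibble(j = seq_along(x$r), r = x$r)
}

#' Empirical support of consecutive spectral ratios
#'
#' For each `j`, the lower/upper bound is the smallest/largest observed
#' `r_j / r_{j+1}` over the training spectra. A genome contributes to pool
#' `j` only when both `r_j` and `r_{j+1}` are at least `min_count`: ratios
#' of small counts are sampling noise, and a support estimated from them
#' both misplaces and over-tightens the constraint. Beyond the last
#' well-populated `j` (a pool with at least half the genomes, with a floor
#' of 5), and for any unreliable pool, the widest observed bound across the
#' well-populated pools is used instead, so the poorly observed tail of the
#' spectrum is only loosely constrained.
#'
#' @param spectra List of [repeat_spectrum()] objects.
#' @param n Number of spectrum entries (bounds cover `j = 1..n-1`).
#' @param min_count Minimum `r_j` and `r_{j+1}` for a genome to contribute
#'   a ratio to pool `j` (default 100).
#' @return A [ratio_bounds()] object.
#' @export
fit_ratio_bounds <- function(spectra, n = 50, min_count = 100) {
  stopifnot(length(spectra) >= 1)
  if (length(spectra) == 1L) {
    warn("single training spectrum: degenerate bounds with lower == upper")
  }
  lo <- rep(NA_real_, n - 1)
  up <- rep(NA_real_, n - 1)
  pool_n <- integer(n - 1)
  for (j in seq_len(n - 1)) {
    pool <- unlist(lapply(spectra, function(s) {
      if (length(s$r) > j && s$r[j + 1] >= min_count &&
          s$r[j] >= min_count) {
        s$r[j] / s$r[j + 1]
      } else {
        NULL
      }
    }))
    pool_n[j] <- length(pool)
    if (length(pool) > 0) {
      lo[j] <- min(pool)
      up[j] <- max(pool)
    }
  }
  if (all(pool_n == 0L)) {
    # toy-scale spectra: every count is below min_count; refit on raw pools
    if (min_count > 1) {
      return(fit_ratio_bounds(spectra, n = n, min_count = 1))
    }
    abort("no ratio pool is populated; cannot fit bounds",
          class = "skimspect_domain_error")
  }
  well <- pool_n >= min(max(5, length(spectra) / 2), length(spectra))
  if (!any(well)) {
    well <- pool_n > 0
  }
  wide_lo <- min(lo[well])
  wide_up <- max(up[well])
  last_good <- max(which(well))
  for (j in seq_len(n - 1)) {
    if (!well[j] || j > last_good) {
      lo[j] <- wide_lo
      up[j] <- wide_up
    }
  }
  ratio_bounds(lo, up)
}

#' Gamma-family splines of spectral ratios
#'
#' For each `j = 1..j_max`, models the ratio `y_j = r_j / r_{j+1}` across
#' training genomes as a gamma-distributed response whose mean is a smooth
#' function of `u_j = r_j / sum_{i >= j} r_i`, fitted as a generalized
#' additive model with a penalized spline (smoothness chosen by GCV).
#' A log link absorbs the large dynamic range of the first two ratios; the
#' identity link is used for `j >= 3`. Fitted curves are stored as dense
#' prediction grids over the training domain, so the model serializes to
#' plain JSON and predictions are exactly reproducible after a round trip.
#' At apply time, inputs outside the training domain are clamped to its
#' boundary.
#'
#' The predictor fed to the splines at apply time is the LP-estimated
#' spectral index, which is systematically biased relative to the true index
#' (the LP zeroes much of the spectrum tail). Training therefore pairs the
#' assembly-true ratios with LP-estimated indices from simulated skims when
#' such pairs are supplied (`pairs`, the recommended route used by
#' [train_models()]); with spectra alone, the true indices are used.
#'
#' @param spectra List of [repeat_spectrum()] objects (at least 10
#'   recommended; fewer triggers a warning). Ignored when `pairs` is given.
#' @param pairs Optional list (one element per `j`) of data frames with
#'   columns `u` (predictor index) and `y` (ratio response), overriding the
#'   pairs derived from `spectra`.
#' @param j_max Highest ratio index modelled (default 5).
#' @param grid_n Number of grid points for the stored prediction curve.
#' @param gcv Use GCV to select smoothness (default); otherwise supply `sp`.
#' @param sp Optional fixed smoothing parameter passed to the GAM.
#' @return A `ratio_splines` object.
#' @export
fit_ratio_splines <- function(spectra = NULL, pairs = NULL, j_max = 5,
                              grid_n = 201, gcv = TRUE, sp = NULL) {
  if (is.null(pairs) && length(spectra) < 10) {
    warn("fewer than 10 training spectra; ratio splines may be unreliable")
  }
  models <- vector("list", j_max)
  for (j in seq_len(j_max)) {
    dat <- if (!is.null(pairs)) {
      stopifnot(length(pairs) >= j)
      as.data.frame(pairs[[j]])
    } else {
      ratio_training_frame(spectra, j)
    }
    if (nrow(dat) < 4) {
      abort(sprintf("too few training ratios for j = %d", j),
            class = "skimspect_domain_error")
    }
    if (any(dat$y <= 0)) {
      abort("non-positive spectral ratios in training data",
            class = "skimspect_domain_error")
    }
    link <- if (j <= 2) "log" else "identity"
    kk <- max(4, min(10, nrow(dat) - 1))
    fit <- mgcv::gam(
      y ~ s(u, k = kk), data = dat,
      family = stats::Gamma(link = link),
      method = if (gcv) "GCV.Cp" else "GCV.Cp", sp = sp)
    u_grid <- seq(min(dat$u), max(dat$u), length.out = grid_n)
    y_grid <- as.numeric(predict(fit, newdata = data.frame(u = u_grid),
                                 type = "response"))
    y_floor <- min(dat$y) * 1e-3
    y_grid <- pmax(y_grid, y_floor)
    models[[j]] <- list(j = j, link = link, u = u_grid, y = y_grid,
                        u_range = range(dat$u), n_train = nrow(dat))
  }
  structure(list(models = models, j_max = j_max), class = "ratio_splines")
}

ratio_training_frame <- function(spectra, j) {
  rows <- lapply(spectra, function(s) {
    r <- s$r
    if (length(r) <= j || r[j] <= 0 || r[j + 1] <= 0) return(NULL)
    tail_sum <- sum(r[j:length(r)])
    if (tail_sum <= 0) return(NULL)
    data.frame(u = r[j] / tail_sum, y = r[j] / r[j + 1])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(u = numeric(0), y = numeric(0))
  out
}

#' Predict a spectral ratio from the fitted splines
#'
#' @param splines A `ratio_splines` object.
#' @param j Ratio index.
#' @param u Value of `r_j / sum_{i >= j} r_i`; clamped to the training
#'   domain.
#' @return Predicted `r_j / r_{j+1}`, strictly positive.
#' @export
predict_ratio <- function(splines, j, u) {
  mod <- splines$models[[j]]
  if (is.null(mod)) {
    abort(sprintf("no spline trained for j = %d", j),
          class = "skimspect_domain_error")
  }
  u_cl <- pmin(pmax(u, mod$u_range[1]), mod$u_range[2])
  approx(mod$u, mod$y, xout = u_cl, rule = 2)$y
}

#' @export
print.ratio_splines <- function(x, ...) {
  cat(sprintf("<ratio_splines> j = 1..%d (links: %s)\n", x$j_max,
              paste(vapply(x$models, function(m) m$link, ""), collapse = ", ")))
  invisible(x)
}

#' Error-rate correction regression
#'
#' The initial sequencing-error estimate is made under a no-repeat
#' assumption, so it is biased for repetitive genomes; the relative error of
#' that estimate is strongly (negatively) correlated with the uniqueness
#' ratio `r_1 / L`. This fits a linear regression of the relative error on
#' the estimated uniqueness ratio from calibration runs at known error rate.
#' At apply time the predicted relative error is capped at +/- 20% and the
#' correction is only applied when the estimated coverage is below 1.5.
#'
#' @param pairs A data frame with columns `true_eps`, `est_eps` and
#'   `uniqueness` (the estimated `r_1 / L`), one row per calibration skim.
#' @param cap Cap on the absolute relative correction (default 0.20).
#' @param coverage_threshold Apply the correction only below this estimated
#'   sequence coverage (default 1.5).
#' @return An `eps_correction` object with fields `intercept`, `slope`,
#'   `cap`, `coverage_threshold`.
#' @export
fit_epsilon_correction <- function(pairs, cap = 0.20,
                                   coverage_threshold = 1.5) {
  stopifnot(is.data.frame(pairs),
            all(c("true_eps", "est_eps", "uniqueness") %in% names(pairs)))
  if (nrow(pairs) < 3) {
    abort("need at least 3 calibration pairs",
          class = "skimspect_domain_error")
  }
  rel_err <- (pairs$est_eps - pairs$true_eps) / pairs$true_eps
  fit <- lm(rel_err ~ uniqueness, data = data.frame(
    rel_err = rel_err, uniqueness = pairs$uniqueness))
  cf <- coef(fit)
  structure(
    list(intercept = unname(cf[1]), slope = unname(cf[2]),
         cap = cap, coverage_threshold = coverage_threshold),
    class = "eps_correction")
}

# Predicted relative error of the initial eps estimate, capped.
predict_eps_rel_error <- function(corr, uniqueness) {
  rho <- corr$intercept + corr$slope * uniqueness
  pmin(pmax(rho, -corr$cap), corr$cap)
}

#' Bundle of trained models
#'
#' @param bounds A [ratio_bounds()] object.
#' @param splines A `ratio_splines` object.
#' @param eps_correction An `eps_correction` object, or `NULL` to skip
#'   error-rate correction.
#' @param provenance Optional named list describing the training set
#'   (corpus description, k, seed, ...).
#' @return A `trained_models` object.
#' @export
trained_models <- function(bounds, splines, eps_correction = NULL,
                           provenance = list()) {
  stopifnot(inherits(bounds, "ratio_bounds"),
            inherits(splines, "ratio_splines"))
  if (!is.null(eps_correction)) {
    stopifnot(inherits(eps_correction, "eps_correction"))
  }
  structure(
    list(bounds = bounds, splines = splines,
         eps_correction = eps_correction, provenance = provenance),
    class = "trained_models")
}

#' @export
print.trained_models <- function(x, ...) {
  cat(sprintf("<trained_models> %d ratio bounds; splines j = 1..%d; %s\n",
              nrow(x$bounds), x$splines$j_max,
              if (is.null(x$eps_correction)) "no eps correction"
              else "with eps correction"))
  invisible(x)
}

#' Serialize / restore trained models as JSON
#'
#' All components (bounds, spline prediction grids, regression coefficients,
#' provenance) are stored at full double precision, so the round trip is
#' lossless.
#'
#' @param models A [trained_models()] object.
#' @param path Output (input) JSON path.
#' @return `path` invisibly (writer); a `trained_models` object (reader).
#' @export
write_trained_models <- function(models, path) {
  payload <- list(
    format = "skimspect_trained_models",
    version = 1L,
    bounds = list(lower = models$bounds$lower, upper = models$bounds$upper),
    splines = lapply(models$splines$models, function(m) {
      list(j = m$j, link = m$link, u = m$u, y = m$y,
           u_range = m$u_range, n_train = m$n_train)
    }),
    eps_correction = if (is.null(models$eps_correction)) NULL else {
      unclass(models$eps_correction)
    },
    provenance = models$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_trained_models
#' @export
read_trained_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "skimspect_trained_models")) {
    abort("not a skimspect trained-models file",
          class = "skimspect_parse_error")
  }
  bounds <- ratio_bounds(payload$bounds$lower, payload$bounds$upper)
  models <- lapply(payload$splines, function(m) {
    list(j = as.integer(m$j), link = m$link, u = as.numeric(m$u),
         y = as.numeric(m$y), u_range = as.numeric(m$u_range),
         n_train = as.integer(m$n_train))
  })
  splines <- structure(list(models = models, j_max = length(models)),
                       class = "ratio_splines")
  eps <- payload$eps_correction
  eps_correction <- if (is.null(eps)) NULL else {
    structure(list(intercept = eps$intercept, slope = eps$slope,
                   cap = eps$cap,
                   coverage_threshold = eps$coverage_threshold),
              class = "eps_correction")
  }
  trained_models(bounds, splines, eps_correction,
                 provenance = payload$provenance %||% list())
}

#' Default trained models shipped with the package
#'
#' Deterministically trained on the synthetic assembly corpus produced by
#' [make_training_corpus()] with a fixed seed (see the tools/ script in the
#' package sources). Suitable for skims whose repeat structure resembles the
#' synthetic corpus; retrain with [train_models()] on real assemblies for
#' production use.
#'
#' @return A `trained_models` object.
#' @export
default_trained_models <- function() {
  path <- system.file("extdata", "trained_models_synthetic.json",
                      package = "skimspect", mustWork = TRUE)
  read_trained_models(path)
}

#' Train all models from a corpus of assemblies
#'
#' Convenience wrapper: computes exact spectra (if not already given),
#' fits ratio bounds and splines, and optionally calibrates the error-rate
#' correction by simulating skims at a known error rate and running the
#' full estimation pipeline on them.
#'
#' @param assemblies Either a list of [repeat_spectrum()] objects, or a
#'   character vector of FASTA paths, or a list of sequence sets.
#' @param k,n k-mer length and spectrum dimension.
#' @param eps_calibration `NULL` to skip, or a list of genome sequences
#'   (character) on which calibration skims are simulated.
#' @param calibration_eps,calibration_coverage Error rate and coverage of
#'   the calibration skims.
#' @param read_length Calibration read length.
#' @param iterations Annealing iterations for calibration runs.
#' @param seed RNG seed for the calibration skims.
#' @param spline_skims `NULL` to train splines on true spectral indices, or
#'   a list of genome sequences (character, same order as `assemblies`) from
#'   which error-free skims are simulated so the splines are trained on
#'   LP-estimated indices (see [spline_training_pairs()]; recommended).
#' @return A [trained_models()] object.
#' @export
train_models <- function(assemblies, k = 31, n = 50,
                         eps_calibration = NULL,
                         calibration_eps = 0.01,
                         calibration_coverage = 1,
                         read_length = 100,
                         iterations = 300,
                         seed = 1,
                         spline_skims = NULL) {
  spectra <- lapply(assemblies, function(a) {
    if (inherits(a, "repeat_spectrum")) a else repeat_spectrum(a, k = k, n = n)
  })
  bounds <- fit_ratio_bounds(spectra, n = n)
  splines <- if (is.null(spline_skims)) {
    fit_ratio_splines(spectra)
  } else {
    pairs <- spline_training_pairs(spline_skims, spectra, bounds, k = k,
                                   n = n, read_length = read_length,
                                   seed = seed)
    fit_ratio_splines(pairs = pairs)
  }
  eps_corr <- NULL
  if (!is.null(eps_calibration)) {
    partial <- trained_models(bounds, splines, NULL)
    pairs <- calibrate_epsilon(eps_calibration, partial, k = k, n = n,
                               eps = calibration_eps,
                               coverage = calibration_coverage,
                               read_length = read_length,
                               iterations = iterations, seed = seed)
    eps_corr <- fit_epsilon_correction(pairs)
  }
  trained_models(bounds, splines, eps_corr,
                 provenance = list(n_genomes = length(spectra), k = k, n = n,
                                   seed = seed))
}

#' LP-estimated spline training pairs from simulated skims
#'
#' For each training genome, simulates an error-free skim at the given
#' coverage, runs the ratio-constrained LP at the (known) k-mer coverage,
#' and pairs the LP-estimated spectral indices
#' `u_j = r_j^LP / sum_{i >= j} r_i^LP` with the assembly-true ratios
#' `y_j = r_j / r_{j+1}`. Training the splines on these pairs matches what
#' they see at apply time, absorbing the LP's systematic bias in `u`.
#'
#' @param genomes List of genome sequences (character strings).
#' @param spectra Their exact [repeat_spectrum()]s, same order.
#' @param bounds [ratio_bounds()] used by the LP.
#' @param k,n Spectrum parameters.
#' @param coverage,read_length Skim parameters (defaults 1X, 100 bp).
#' @param j_max Highest ratio index.
#' @param seed Seed for the skims.
#' @return A list of `j_max` data frames with columns `u` and `y`.
#' @export
spline_training_pairs <- function(genomes, spectra, bounds, k = 31, n = 50,
                                  coverage = 1, read_length = 100,
                                  j_max = 5, seed = 1) {
  stopifnot(length(genomes) == length(spectra))
  lambda_ef <- kmer_coverage(coverage, read_length, k)
  m <- max(n, round(n * max(1, lambda_ef)))
  P <- mixture_matrix(lambda_ef, m, n)
  pairs <- lapply(seq_len(j_max), function(j) data.frame(u = numeric(0),
                                                         y = numeric(0)))
  for (i in seq_along(genomes)) {
    reads <- simulate_reads(genomes[[i]], coverage = coverage,
                            read_length = read_length, error_rate = 0,
                            seed = derive_seed(seed, 5000L + i))
    o_full <- cpp_kmer_histogram(reads$seq, as.integer(k), TRUE)
    o <- c(o_full, numeric(max(0, m - length(o_full))))[seq_len(m)]
    r_lp <- tryCatch(estimate_lp(o, P, bounds)$r, error = function(e) NULL)
    if (is.null(r_lp)) next
    tails <- rev(cumsum(rev(r_lp)))
    r_true <- spectra[[i]]$r
    for (j in seq_len(j_max)) {
      if (tails[j] <= 0 || r_lp[j] <= 0) next
      if (length(r_true) <= j || r_true[j] <= 0 || r_true[j + 1] <= 0) next
      pairs[[j]] <- rbind(pairs[[j]],
                          data.frame(u = r_lp[j] / tails[j],
                                     y = r_true[j] / r_true[j + 1]))
    }
  }
  pairs
}

calibrate_epsilon <- function(genomes, models, k, n, eps, coverage,
                              read_length, iterations, seed) {
  rows <- lapply(seq_along(genomes), function(i) {
    gseq <- genomes[[i]]
    reads <- simulate_reads(gseq, coverage = coverage,
                            read_length = read_length, error_rate = eps,
                            seed = derive_seed(seed, i))
    hist <- kmer_histogram(reads, k = k,
                           read_length = read_length,
                           total_bases = sum(nchar(reads$seq)),
                           n_reads = nrow(reads))
    est <- tryCatch(
      estimate_genome(hist, models = models, iterations = iterations,
                      seed = derive_seed(seed, 1000L + i), n = n),
      error = function(e) NULL)
    if (is.null(est)) return(NULL)
    tibble(true_eps = eps, est_eps = est$eps_initial,
           uniqueness = est$uniqueness)
  })
  bind_rows(rows)
}
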