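#' Initialize coverage and error-rate estimates from a histogram
#'
#' Under a no-repeat assumption the error-free k-mer counts are Poisson, so
#' consecutive histogram bins around the mode identify the error-free k-mer
#' coverage: with `h* = argmax_{h>1} o_h` (smallest h on ties),
#' `lambda_ef = (h*+1) o_{h*+1} / o_{h*}`. The singleton excess then fixes
#' the total k-mer coverage
#' `lambda = exp(-lambda_ef) lambda_ef^{h*} / h*! * o_1/o_{h*}
#'  + lambda_ef (1 - exp(-lambda_ef))`,
#' and the error rate follows from `eps = 1 - (lambda_ef / lambda)^{1/k}`.
#'
#' @param hist A [kmer_histogram()] (or plain numeric count vector).
#' @param k k-mer length (taken from the histogram attribute if present).
#' @return A list with `lambda_ef`, `lambda`, `eps`, `h_star`, and — when
#'   the histogram carries read-length/total-base metadata — the implied
#'   initial sequence coverage `c0` and no-repeat genome length `L0`.
#' @export
initialize_skim <- function(hist, k = NULL) {
  o <- hist_vector(hist)
  k <- k %||% attr(hist, "k") %||% 31L
  if (sum(o > 0) < 3 || length(o) < 3 || all(o[-1] == 0)) {
    abort("insufficient coverage signal: need at least three populated bins with some h > 1",
          class = "skimspect_data_error")
  }
  h_star <- which.max(o[-1]) + 1L # ties resolved to the smallest h
  if (h_star + 1L > length(o) || o[h_star] == 0) {
    abort("insufficient coverage signal: histogram mode at its boundary",
          class = "skimspect_data_error")
  }
  lambda_ef <- (h_star + 1) * o[h_star + 1] / o[h_star]
  if (!is.finite(lambda_ef) || lambda_ef <= 0) {
    abort("insufficient coverage signal: degenerate bin ratio",
          class = "skimspect_data_error")
  }
  lambda <- exp(-lambda_ef) * lambda_ef^h_star / factorial(h_star) *
    o[1] / o[h_star] + lambda_ef * (1 - exp(-lambda_ef))
  # sampling noise can push lambda below lambda_ef; error-free then
  if (lambda < lambda_ef) lambda <- lambda_ef
  eps <- 1 - (lambda_ef / lambda)^(1 / k)
  out <- list(lambda_ef = lambda_ef, lambda = lambda, eps = eps,
              h_star = h_star, k = k)
  rl <- attr(hist, "read_length")
  B <- attr(hist, "total_bases")
  if (!is.null(rl) && !is.null(B) && !is.na(rl) && !is.na(B)) {
    c0 <- sequence_coverage(lambda, rl, k)
    out$c0 <- c0
    out$L0 <- B / c0
  }
  out
}

#' Propose a candidate k-mer coverage
#'
#' Uniform draw on `[lambda/2, 3 lambda]`, floored at `1e-3` to keep the
#' mixture matrix well defined.
#'
#' @param lambda Current k-mer coverage.
#' @return The proposed value.
#' @export
propose_lambda <- function(lambda) {
  stopifnot(lambda > 0)
  max(runif(1, lambda / 2, 3 * lambda), 1e-3)
}

#' Annealing acceptance probability
#'
#' Improving moves are always accepted. Worsening moves are accepted with a
#' probability that shrinks as the run progresses; two published cooling
#' variants are supported: `"algorithm1"` uses
#' `exp((E_current - E_next) / (N - t + 1))` and `"overview"` uses
#' `exp(-(E_next - E_current) * t / N)`.
#'
#' @param e_current,e_next Objective values of the current and candidate
#'   state.
#' @param t Iteration index, `1 <= t <= N`.
#' @param N Total iterations.
#' @param variant `"algorithm1"` (default) or `"overview"`.
#' @return Acceptance probability in `(0, 1]`.
#' @export
accept_probability <- function(e_current, e_next, t, N,
                               variant = c("algorithm1", "overview")) {
  variant <- match.arg(variant)
  stopifnot(t >= 1, t <= N)
  if (e_next <= e_current) return(1)
  logp <- switch(variant,
                 algorithm1 = (e_current - e_next) / (N - t + 1),
                 overview = -(e_next - e_current) * t / N)
  min(1, exp(logp))
}

#' Simulated-annealing search over k-mer coverage
#'
#' The outer loop of the estimator: starting from [initialize_skim()]'s
#' state, proposes a new coverage each iteration, rebuilds the mixture
#' matrix, solves the inner spline-corrected LP for the spectrum, and
#' accepts/rejects by [accept_probability()]. The error rate is held fixed
#' throughout (it is corrected once, at finalization). An LP failure at some
#' iteration counts as a rejected move, never an abort.
#'
#' @param hist A [kmer_histogram()] with read-length and total-base
#'   metadata.
#' @param models A [trained_models()] object.
#' @param iterations Number of annealing iterations `N`.
#' @param seed RNG seed for the proposal/acceptance draws.
#' @param n Spectrum dimension (default 50).
#' @param variant Cooling schedule variant, see [accept_probability()].
#' @param dry_run If `TRUE`, skip the loop and return the initialized state
#'   (with the inner solve at the initial coverage).
#' @return A list with the final accepted `lambda`, `lambda_ef`, `eps`
#'   (initial estimate), `r`, `objective`, `m`, `n`, `k`, and a `trace`
#'   tibble with one row per iteration
#'   (`t`, `lambda`, `objective`, `accepted`).
#' @export
anneal <- function(hist, models, iterations = 1000, seed = 1, n = 50,
                   variant = c("algorithm1", "overview"), dry_run = FALSE) {
  variant <- match.arg(variant)
  stopifnot(iterations >= 1)
  init <- initialize_skim(hist)
  o_full <- hist_vector(hist)
  k <- init$k
  # bin truncation is fixed for the whole run from the initial estimate
  m <- max(n, round(n * max(1, init$lambda_ef)))
  o <- c(o_full, numeric(max(0, m - length(o_full))))[seq_len(m)]
  excluded_mass <- if (length(o_full) > m) {
    sum(o_full[(m + 1):length(o_full)])
  } else {
    0
  }
  eps <- init$eps
  ef_factor <- (1 - eps)^k

  solve_inner <- function(lambda) {
    P <- mixture_matrix(lambda * ef_factor, m, n)
    fit <- estimate_slp(o, P, models$bounds, models$splines)
    list(r = fit$r, objective = fit$objective)
  }

  withr_seed(seed, {
    lambda <- init$lambda
    cur <- solve_inner(lambda)
    if (dry_run) {
      empty_trace <- tibble(t = integer(0), lambda = numeric(0),
                            objective = numeric(0), accepted = logical(0))
      return_state <- anneal_state(init, lambda, eps, cur, empty_trace,
                                   m, n, k, excluded_mass, seed, variant)
      iterations <- 0L
    }
    tr_lambda <- numeric(iterations)
    tr_obj <- numeric(iterations)
    tr_acc <- logical(iterations)
    for (t in seq_len(iterations)) {
      lambda_next <- propose_lambda(lambda)
      cand <- tryCatch(solve_inner(lambda_next), error = function(e) NULL)
      if (is.null(cand)) {
        # solver failure: treat as a rejected move
        runif(1) # keep the draw stream aligned with the accept step
        tr_lambda[t] <- lambda_next
        tr_obj[t] <- NA_real_
        tr_acc[t] <- FALSE
        next
      }
      p_acc <- accept_probability(cur$objective, cand$objective, t,
                                  iterations, variant)
      accepted <- runif(1) <= p_acc
      if (accepted) {
        lambda <- lambda_next
        cur <- cand
      }
      tr_lambda[t] <- lambda_next
      tr_obj[t] <- cand$objective
      tr_acc[t] <- accepted
    }
    if (dry_run) {
      return_state
    } else {
      trace <- tibble(t = seq_len(iterations), lambda = tr_lambda,
                      objective = tr_obj, accepted = tr_acc)
      anneal_state(init, lambda, eps, cur, trace, m, n, k, excluded_mass,
                   seed, variant)
    }
  })
}

anneal_state <- function(init, lambda, eps, cur, trace, m, n, k,
                         excluded_mass, seed, variant) {
  list(lambda = lambda, lambda_ef = lambda * (1 - eps)^k, eps = eps,
       r = cur$r, objective = cur$objective, trace = trace,
       m = m, n = n, k = k, init = init, excluded_mass = excluded_mass,
       seed = seed, variant = variant)
}

#' Finalize a skim estimate
#'
#' Applies the trained error-rate correction (only when the estimated
#' sequence coverage is below the trained threshold, 1.5 by default; the
#' relative correction is capped at 20%), recomputes the coverage as
#' `lambda_final = lambda (1-eps)^k / (1-eps_corrected)^k`, and converts to
#' sequence coverage and genome length via `c = lambda l/(l-k+1)`,
#' `L = B / c`.
#'
#' @param state Result of [anneal()].
#' @param models A [trained_models()] object.
#' @param hist The histogram the state was estimated from (supplies read
#'   length and total bases).
#' @return A `skim_fit` object.
#' @export
finalize_estimate <- function(state, models, hist) {
  rl <- attr(hist, "read_length")
  B <- attr(hist, "total_bases")
  if (is.null(rl) || is.null(B) || is.na(rl) || is.na(B)) {
    abort("histogram lacks read_length/total_bases metadata needed for c and L",
          class = "skimspect_data_error")
  }
  k <- state$k
  eps <- state$eps
  lambda <- state$lambda
  c_uncorr <- sequence_coverage(lambda, rl, k)
  L_spec <- k - 1 + sum(seq_along(state$r) * state$r)
  uniqueness <- if (L_spec > 0) state$r[1] / L_spec else NA_real_

  eps_corrected <- eps
  correction_applied <- FALSE
  corr <- models$eps_correction
  if (!is.null(corr) && is.finite(uniqueness) &&
      c_uncorr < corr$coverage_threshold && eps > 0) {
    rho <- predict_eps_rel_error(corr, uniqueness)
    eps_corrected <- eps / (1 + rho)
    eps_corrected <- min(max(eps_corrected, 0), 1 - 1e-12)
    correction_applied <- TRUE
  }
  lambda_final <- lambda * (1 - eps)^k / (1 - eps_corrected)^k
  c_final <- sequence_coverage(lambda_final, rl, k)
  L_final <- B / c_final

  structure(
    list(coverage = c_final, length = L_final, eps = eps_corrected,
         eps_initial = eps, lambda = lambda_final,
         lambda_pre_correction = lambda, r = state$r,
         uniqueness = uniqueness, objective = state$objective,
         trace = state$trace, k = k, n = state$n, m = state$m,
         read_length = rl, total_bases = B,
         correction_applied = correction_applied, seed = state$seed,
         variant = state$variant, init = state$init),
    class = "skim_fit")
}

#' Estimate genome parameters from a skim histogram
#'
#' The full pipeline: initialization, simulated-annealing search over the
#' k-mer coverage with spline-corrected LP inner solves, and finalization
#' with the trained error-rate correction. Returns coverage `c`, genome
#' length `L = B/c`, sequencing error rate, and the repeat spectrum.
#'
#' @inheritParams anneal
#' @param models Trained constraint models; defaults to the synthetic-corpus
#'   models shipped with the package.
#' @return A `skim_fit` object; see [tidy.skim_fit()] and
#'   [glance.skim_fit()] for tabular views.
#' @examples
#' \donttest{
#' g <- simulate_genome(2e5, seed = 3)
#' reads <- simulate_reads(g, coverage = 1, read_length = 100, seed = 4)
#' h <- kmer_histogram(reads, k = 31, read_length = 100,
#'                     total_bases = attr(reads, "total_bases"),
#'                     n_reads = attr(reads, "n_reads"))
#' fit <- estimate_genome(h, iterations = 100, seed = 5)
#' glance(fit)
#' }
#' @export
estimate_genome <- function(hist, models = default_trained_models(),
                            iterations = 1000, seed = 1, n = 50,
                            variant = c("algorithm1", "overview")) {
  variant <- match.arg(variant)
  state <- anneal(hist, models, iterations = iterations, seed = seed,
                  n = n, variant = variant)
  finalize_estimate(state, models, hist)
}

#' @export
print.skim_fit <- function(x, ...) {
  cat("<skim_fit>\n")
  cat(sprintf("  genome length L : %s bp\n",
              format(round(x$length), big.mark = ",")))
  cat(sprintf("  coverage c      : %.3f\n", x$coverage))
  cat(sprintf("  error rate eps  : %.4g%s\n", x$eps,
              if (x$correction_applied) " (corrected)" else ""))
  cat(sprintf("  k-mer coverage  : %.3f\n", x$lambda))
  cat(sprintf("  uniqueness r1/L : %.3f\n", x$uniqueness))
  cat(sprintf("  objective       : %.6g after %d iterations\n",
              x$objective, nrow(x$trace)))
  invisible(x)
}
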