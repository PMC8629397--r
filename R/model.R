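#' Convert between sequence coverage and k-mer coverage
#'
#' A read of length `l` contains `l - k + 1` k-mers, so a genome sequenced at
#' depth `c` has each position covered by `lambda = (1 - (k-1)/l) c` read
#' k-mers on average.
#'
#' @param c Sequence coverage (mean sequenced depth per position).
#' @param lambda k-mer coverage.
#' @param read_length Read length `l` in bp; must exceed `k - 1`.
#' @param k k-mer length.
#' @return The converted coverage.
#' @examples
#' kmer_coverage(1, read_length = 100, k = 31) # 0.7
#' sequence_coverage(0.7, read_length = 100, k = 31) # 1
#' @export
kmer_coverage <- function(c, read_length, k = 31) {
  check_read_length(read_length, k)
  (1 - (k - 1) / read_length) * c
}

#' @rdname kmer_coverage
#' @export
sequence_coverage <- function(lambda, read_length, k = 31) {
  check_read_length(read_length, k)
  lambda * read_length / (read_length - k + 1)
}

check_read_length <- function(read_length, k) {
  if (any(read_length <= k - 1)) {
    abort(sprintf("read_length (%g) must exceed k - 1 (%g)",
                  read_length[1], k - 1),
          class = "skimspect_domain_error")
  }
  invisible(TRUE)
}

#' Expected number of erroneous k-mers in a skim
#'
#' Under the substitution error model, a sequenced k-mer is error-free with
#' probability `(1 - eps)^k`; erroneous k-mers are assumed novel (each is seen
#' once). With `L * lambda` k-mer instances expected in the skim, the expected
#' number of erroneous k-mers is `E = L * lambda * (1 - (1 - eps)^k)`.
#'
#' @param L Genome length in bp.
#' @param lambda k-mer coverage.
#' @param eps Per-base error probability in `[0, 1)`.
#' @param k k-mer length.
#' @export
expected_erroneous_kmers <- function(L, lambda, eps, k = 31) {
  stopifnot(L >= 0, lambda >= 0, eps >= 0, eps < 1)
  # expm1 keeps precision for small eps: 1-(1-eps)^k = -expm1(k*log1p(-eps))
  L * lambda * (-expm1(k * log1p(-eps)))
}

#' Poisson mixture matrix over copy-number classes
#'
#' Entry `P[h, j]` is the probability that a k-mer with genomic copy number
#' `j` is observed exactly `h` times in the skim, i.e. the Poisson pmf at `h`
#' with rate `j * lambda_ef` where `lambda_ef` is the error-free k-mer
#' coverage. The pmf is evaluated in log space (log-gamma) and exponentiated
#' last, so large `j * lambda_ef` cannot overflow.
#'
#' @param lambda_ef Error-free k-mer coverage, `> 0`.
#' @param m Number of observed-count rows (h = 1..m).
#' @param n Number of copy-number columns (j = 1..n).
#' @return An `m` x `n` numeric matrix.
#' @export
mixture_matrix <- function(lambda_ef, m, n) {
  if (!is.finite(lambda_ef) || lambda_ef <= 0) {
    abort("lambda_ef must be positive", class = "skimspect_domain_error")
  }
  stopifnot(m >= 1, n >= 1)
  h <- seq_len(m)
  j <- seq_len(n)
  rate <- j * lambda_ef
  logP <- outer(h, rate, function(h, r) h * log(r) - r - lgamma(h + 1))
  P <- exp(logP)
  dimnames(P) <- NULL
  P
}

#' Expected observed-count histogram
#'
#' The mean of the observed histogram under the mixture model:
#' `m_h = sum_j P[h, j] r_j + [h == 1] * E`, with `E` the expected number of
#' erroneous k-mers (all of which land in the singleton bin).
#'
#' @param r Repeat spectrum, length `ncol(P)`.
#' @param P Mixture matrix from [mixture_matrix()].
#' @param E Expected erroneous k-mers (added to bin `h = 1`).
#' @return Numeric vector of length `nrow(P)`.
#' @export
expected_counts <- function(r, P, E = 0) {
  if (length(r) != ncol(P)) {
    abort(sprintf("length(r) = %d but ncol(P) = %d", length(r), ncol(P)),
          class = "skimspect_domain_error")
  }
  m <- as.vector(P %*% r)
  if (length(m) >= 1) m[1] <- m[1] + E
  m
}

#' Weighted p-norm objective between observed and expected histograms
#'
#' `(sum_h w_h |m_h - o_h|^p)^(1/p)`. The default weights `w = [0, 1, 1, ...]`
#' with `p = 1` exclude the singleton bin (dominated by sequencing errors)
#' and reduce to the plain L1 distance over bins `h >= 2`. Vectors of unequal
#' length are zero-padded.
#'
#' @param o Observed histogram counts.
#' @param m Expected counts.
#' @param w Weight vector, recycled/padded to the common length. `NULL`
#'   (default) means `[0, 1, 1, ...]`.
#' @param p Norm order, 1 or 2.
#' @export
spectrum_objective <- function(o, m, w = NULL, p = 1) {
  if (!p %in% c(1, 2)) {
    abort("p must be 1 or 2", class = "skimspect_domain_error")
  }
  len <- max(length(o), length(m))
  o <- c(o, numeric(len - length(o)))
  m <- c(m, numeric(len - length(m)))
  if (is.null(w)) {
    w <- rep(1, len)
    if (len >= 1) w[1] <- 0
  } else {
    stopifnot(all(w >= 0))
    w <- c(w, numeric(max(0, len - length(w))))[seq_len(len)]
  }
  sum(w * abs(m - o)^p)^(1 / p)
}

#' Condition number of the mixture matrix
#'
#' The 2-norm condition number (ratio of extreme singular values). For the
#' square error-free mixture matrix at `lambda_ef = 1` the condition number
#' grows at least like `2^n / n`, which is why unconstrained inversion of the
#' mixture is hopeless beyond very small `n`.
#'
#' @param P A square mixture matrix.
#' @return The condition number `sigma_max / sigma_min`.
#' @export
condition_number <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  d <- svd(P, nu = 0, nv = 0)$d
  if (min(d) <= max(d) * .Machine$double.eps * nrow(P)) {
    abort("matrix is singular to machine precision",
          class = "skimspect_rank_error")
  }
  max(d) / min(d)
}
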