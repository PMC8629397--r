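#' Uniqueness ratio of a repeat spectrum
#'
#' The fraction of the genome's k-mers that are unique: `r_1 / L` with
#' `L = k - 1 + sum_j j r_j`. Near 1 for non-repetitive genomes; a genome
#' that duplicated very recently has `r_1` close to 0.
#'
#' @param r A [repeat_spectrum()] object or a numeric spectrum vector.
#' @param k k-mer length (needed when `r` is a plain vector).
#' @export
uniqueness_ratio <- function(r, k = 31) {
  if (inherits(r, "repeat_spectrum")) return(r$uniqueness)
  r <- as.numeric(r)
  if (all(r == 0)) {
    abort("zero spectrum has no uniqueness ratio",
          class = "skimspect_domain_error")
  }
  r[1] / (k - 1 + sum(seq_along(r) * r))
}

#' High Copy Repeats per Million (HCRM)
#'
#' The mean multiplicity of the 10 most abundant k-mers, per Mbp of genome:
#' a summary of high-copy (transposon-like) repeat content that is nearly
#' invariant under whole-genome duplication, unlike the uniqueness ratio.
#'
#' @param counts A k-mer count table from [count_kmers()], a numeric vector
#'   of multiplicities, or sequences (counted internally at `k`).
#' @param genome_length Genome length in bp used for the per-Mbp scaling.
#' @param k k-mer length when counting from sequences.
#' @param top Number of top multiplicities averaged (default 10).
#' @return The HCRM value.
#' @export
hcrm <- function(counts, genome_length, k = 31, top = 10) {
  stopifnot(genome_length > 0)
  if (is.data.frame(counts) && "count" %in% names(counts)) {
    mult <- sort(counts$count, decreasing = TRUE)
  } else if (is.numeric(counts)) {
    mult <- sort(counts, decreasing = TRUE)
  } else {
    seqs <- as_sequence_vector(counts)
    mult <- cpp_kmer_top_counts(seqs, as.integer(k), TRUE, as.integer(top))
  }
  if (length(mult) == 0) {
    abort("empty k-mer table", class = "skimspect_domain_error")
  }
  if (length(mult) < top) {
    warn(sprintf("only %d distinct k-mers; HCRM averaged over all of them",
                 length(mult)))
  }
  mean(head(mult, top)) / (genome_length / 1e6)
}

#' Null bound on HCRM in a random genome
#'
#' For a genome of `L` i.i.d. uniform bases, each of the `4^k` possible
#' k-mers has Poisson(`L / 4^k`) copy number; by the union bound,
#' `Prob[HCRM >= H] < 4^k * P(X >= x0)` with threshold copy number
#' `x0 = H * L / 1e6` (H is per-Mbp). Computed entirely in log space; even a
#' modest HCRM is astronomically unlikely by chance, so observed high-copy
#' repeats are real repeat elements, not sampling artefacts.
#'
#' @param H HCRM threshold (per-Mbp units).
#' @param L Genome length in bp.
#' @param k k-mer length.
#' @return `log10` of the probability bound, capped above at 0.
#' @examples
#' hcrm_null_bound(200, 1e8) # far below -100
#' @export
hcrm_null_bound <- function(H, L, k = 31) {
  stopifnot(H > 0, L > 0)
  x0 <- ceiling(H * L / 1e6)
  if (x0 <= 1) return(0) # every genome has a k-mer with >= 1 copy
  log_rate <- log(L) - k * log(4)
  rate <- exp(log_rate)
  # log Poisson upper tail sum_{x >= x0} via log-sum-exp; terms decay by a
  # factor rate/x < 1, so a short run of terms reaches full precision
  x <- x0 + 0:60
  log_terms <- -rate + x * log_rate - lgamma(x + 1)
  log_tail <- log_sum_exp(log_terms)
  # bound the truncation: remaining terms are a geometric series with
  # ratio rate/(x0+61) << 1, negligible at the scales used here
  log_bound <- k * log(4) + log_tail
  min(log_bound / log(10), 0)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Classify the decay of a repeat spectrum
#'
#' Genomes dominated by unique sequence show a rapid drop from `r_1` to
#' `r_5` (`log10(r_1/r_5) >= 4.5`); repeat-rich genomes decay smoothly
#' (`log10(r_1/r_5) <= 2.5`); anything between is `"intermediate"`.
#'
#' @param r A repeat spectrum (vector or [repeat_spectrum()]).
#' @return `"rapid"`, `"intermediate"` or `"smooth"`.
#' @export
classify_decay <- function(r) {
  if (inherits(r, "repeat_spectrum")) r <- r$r
  r <- as.numeric(r)
  if (length(r) < 5 || r[5] <= 0) {
    warn("r5 is zero; classifying as 'rapid' by convention")
    return("rapid")
  }
  if (r[1] <= 0) {
    warn("r1 is zero (duplication-dominated); classifying as 'smooth'")
    return("smooth")
  }
  ratio <- log10(r[1] / r[5])
  if (ratio >= 4.5) "rapid" else if (ratio <= 2.5) "smooth" else "intermediate"
}

#' Repeat profile of an assembly or skim
#'
#' One-stop summary: uniqueness ratio, HCRM, decay class and the head of the
#' repeat spectrum, computed from assembly sequences by exact counting.
#'
#' @param x Sequences (FASTA path, character vector, or tibble with `seq`).
#' @param k k-mer length.
#' @param n Spectrum entries to retain.
#' @return A one-row tibble with columns `uniqueness`, `hcrm`, `decay`,
#'   `L`, and `r1`..`r10`.
#' @export
repeat_profile <- function(x, k = 31, n = 50) {
  seqs <- as_sequence_vector(x)
  sp <- repeat_spectrum(seqs, k = k, n = n)
  top <- cpp_kmer_top_counts(seqs, as.integer(k), TRUE, 10L)
  out <- tibble(
    uniqueness = sp$uniqueness,
    hcrm = mean(top) / (sp$L / 1e6),
    decay = classify_decay(sp),
    L = sp$L)
  rhead <- setNames(as.list(sp$r[1:10]), paste0("r", 1:10))
  bind_cols_safe(out, rhead)
}

bind_cols_safe <- function(df, lst) {
  for (nm in names(lst)) df[[nm]] <- lst[[nm]]
  df
}

#' Association test between recent duplication signatures and repeat metrics
#'
#' Convenience wrapper around Fisher's exact test on a 2x2 table of genomes
#' split by (uniqueness below a threshold AND HCRM below a threshold) versus
#' a known-duplication annotation.
#'
#' @param profile A data frame with columns `uniqueness`, `hcrm`, and a
#'   logical `wgd` annotation column.
#' @param uniqueness_cut,hcrm_cut Thresholds (defaults 0.8 and 200).
#' @return The `htest` object from [stats::fisher.test()].
#' @export
wgd_association_test <- function(profile, uniqueness_cut = 0.8,
                                 hcrm_cut = 200) {
  stopifnot(all(c("uniqueness", "hcrm", "wgd") %in% names(profile)))
  low <- profile$uniqueness < uniqueness_cut & profile$hcrm < hcrm_cut
  stats::fisher.test(table(low, profile$wgd))
}
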