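#' Simulate a genome with planted repeat families
#'
#' Builds a synthetic linear genome: an i.i.d. uniform background with
#' repeat families spliced in at random positions. Each family is defined by
#' a unit length, a copy number, and a per-copy divergence rate (i.i.d.
#' substitutions applied independently to every copy), which smoothly moves
#' k-mer mass from the family's nominal copy number down towards lower
#' multiplicities. The true repeat spectrum is computed by exact counting of
#' the emitted sequence rather than inferred from the family layout, so
#' junction and divergence effects are always reflected in the truth.
#'
#' @param length Target genome length in bp.
#' @param families A data frame with columns `unit_length`, `copies`,
#'   `divergence` (one row per repeat family), or `NULL` for a repeat-free
#'   genome.
#' @param k k-mer length used for the truth spectrum.
#' @param n Spectrum dimension for the truth spectrum.
#' @param seed RNG seed; the same seed yields byte-identical output.
#' @param label Optional label stored in the truth spectrum.
#' @return A list with `sequence` (single character string), `truth`
#'   (a [repeat_spectrum()] of the emitted sequence), `families`, and `seed`.
#' @examples
#' g <- simulate_genome(1e4, seed = 7)
#' g$truth$uniqueness > 0.95
#' @export
simulate_genome <- function(length, families = NULL, k = 31, n = 50,
                            seed = 1, label = NA_character_) {
  stopifnot(length >= 1)
  if (!is.null(families) && nrow(families) > 0) {
    stopifnot(all(c("unit_length", "copies", "divergence") %in%
                    names(families)))
    stopifnot(all(families$divergence >= 0), all(families$divergence < 1),
              all(families$copies >= 1), all(families$unit_length >= 1))
  }
  withr_seed(seed, {
    bases <- c("A", "C", "G", "T")
    footprint <- if (is.null(families) || nrow(families) == 0) 0 else {
      sum(families$unit_length * families$copies)
    }
    if (footprint > length) {
      abort("repeat family footprint exceeds the genome length",
            class = "skimspect_domain_error")
    }
    bg_len <- length - footprint
    segments <- list(paste(sample(bases, bg_len, replace = TRUE),
                           collapse = ""))
    if (footprint > 0) {
      copies <- list()
      for (f in seq_len(nrow(families))) {
        unit <- sample(bases, families$unit_length[f], replace = TRUE)
        for (cp in seq_len(families$copies[f])) {
          cpy <- unit
          div <- families$divergence[f]
          if (div > 0) {
            nmut <- rbinom(1, length(cpy), div)
            if (nmut > 0) {
              pos <- sample.int(length(cpy), nmut)
              cpy[pos] <- vapply(cpy[pos], function(b) {
                sample(setdiff(bases, b), 1)
              }, "")
            }
          }
          copies[[length(copies) + 1L]] <- paste(cpy, collapse = "")
        }
      }
      # splice copies into the background at random breakpoints
      bg <- segments[[1]]
      cuts <- sort(sample.int(nchar(bg) + 1L, length(copies),
                              replace = TRUE)) - 1L
      pieces <- character(0)
      prev <- 0L
      ord <- sample.int(length(copies)) # shuffle family copy order
      for (i in seq_along(cuts)) {
        pieces <- c(pieces, substr(bg, prev + 1L, cuts[i]), copies[[ord[i]]])
        prev <- cuts[i]
      }
      pieces <- c(pieces, substr(bg, prev + 1L, nchar(bg)))
      segments <- list(paste(pieces, collapse = ""))
    }
    genome <- segments[[1]]
    truth <- repeat_spectrum(genome, k = k, n = n, label = label)
    list(sequence = genome, truth = truth, families = families, seed = seed)
  })
}

# fold (seed, salt) into a valid 32-bit seed, Lehmer-style
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 16807) %%
               2147483647)
}

# evaluate expr with a locally-scoped RNG seed, restoring global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a shotgun genome skim
#'
#' Draws a Poisson number of reads with mean `coverage * L / read_length`,
#' uniform start positions on the forward strand (optionally sampling the
#' reverse complement with probability 1/2), and i.i.d. substitution errors
#' at the given per-base rate (to one of the three alternative bases,
#' uniformly). Read ids embed the true 0-based start coordinate.
#'
#' @param genome A genome sequence (single character string) or the list
#'   returned by [simulate_genome()].
#' @param coverage Target mean sequence coverage `c`.
#' @param read_length Read length in bp; must not exceed the genome length.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param revcomp Sample reverse-complement reads with probability 1/2
#'   (default `FALSE`).
#' @return A tibble with columns `id` and `seq`, plus attributes
#'   `read_length`, `total_bases`, `n_reads`, `coverage`, `error_rate`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 100,
                           error_rate = 0, seed = 1, revcomp = FALSE) {
  if (is.list(genome)) genome <- genome$sequence
  L <- nchar(genome)
  if (read_length > L) {
    abort("read_length exceeds genome length",
          class = "skimspect_domain_error")
  }
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1)
  withr_seed(seed, {
    n_reads <- rpois(1, coverage * L / read_length)
    if (n_reads == 0L) {
      out <- tibble(id = character(0), seq = character(0))
    } else {
      starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
      seqs <- substring(genome, starts, starts + read_length - 1L)
      if (error_rate > 0) {
        seqs <- apply_substitutions(seqs, error_rate)
      }
      strand <- rep("+", n_reads)
      if (isTRUE(revcomp)) {
        flip <- runif(n_reads) < 0.5
        if (any(flip)) {
          seqs[flip] <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[flip])))
          strand[flip] <- "-"
        }
      }
      out <- tibble(
        id = sprintf("read_%d_start=%d_strand=%s",
                     seq_len(n_reads), starts - 1L, strand),
        seq = seqs)
    }
    attr(out, "read_length") <- read_length
    attr(out, "total_bases") <- as.numeric(n_reads) * read_length
    attr(out, "n_reads") <- n_reads
    attr(out, "coverage") <- coverage
    attr(out, "error_rate") <- error_rate
    out
  })
}

apply_substitutions <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  # flatten to one character vector, mutate all error positions at once,
  # and re-split; orders of magnitude faster than per-read loops
  lens <- nchar(seqs)
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  total <- length(chars)
  n_err <- rbinom(1, total, rate)
  if (n_err > 0) {
    pos <- sample.int(total, n_err)
    # substitute with a uniformly chosen different base: offset 1..3 in the
    # cyclic base order never maps a base to itself
    cur <- match(chars[pos], bases)
    chars[pos] <- bases[((cur - 1L + sample.int(3, n_err, replace = TRUE))
                        %% 4L) + 1L]
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  flat <- paste(chars, collapse = "")
  substring(flat, starts, ends)
}

#' Write simulated reads to FASTQ
#'
#' @param reads Tibble from [simulate_reads()].
#' @param path Output path (plain text).
#' @param quality_char Constant quality character (default `"I"`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  qual <- strrep(quality_char, nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param x A genome list from [simulate_genome()], a character vector, or a
#'   tibble with `id`/`seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$sequence)) {
    ids <- "genome"
    seqs <- x$sequence
  } else if (is.data.frame(x)) {
    ids <- x$id
    seqs <- x$seq
  } else {
    seqs <- as.character(x)
    ids <- if (!is.null(names(seqs))) names(seqs) else {
      paste0("seq", seq_along(seqs))
    }
  }
  # wrap at 80 columns
  chunks <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = 80L)
    c(paste0(">", ids[i]), substring(s, starts, pmin(starts + 79L, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' Generate a synthetic training corpus of genomes
#'
#' Emits `n_genomes` synthetic genomes whose uniqueness ratios span the
#' range observed across real eukaryotic assemblies (roughly 0.3 to 0.99).
#' Genome `i` targets a uniqueness ratio on a regular grid; its repeated
#' fraction is spread over copy-number classes with a power-law footprint
#' profile (random decay exponent per genome), mild per-copy divergence, and
#' an occasional small high-copy family emulating transposon-like elements.
#' Truth spectra are computed by exact counting of each emitted genome.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param genome_length Length of each genome in bp.
#' @param k,n Spectrum parameters for the truth spectra.
#' @param uniqueness_range Range of target uniqueness ratios; the default
#'   mirrors the span observed across real eukaryotic assemblies
#'   (about 0.29 to 0.995).
#' @param seed Corpus seed; everything is deterministic given it.
#' @return A list with `genomes` (list of [simulate_genome()] results),
#'   `spectra` (their truth spectra) and `summary` (a tibble with one row
#'   per genome: label, target and realised uniqueness, genome length).
#' @export
make_training_corpus <- function(n_genomes = 30, genome_length = 4e6,
                                 k = 31, n = 50,
                                 uniqueness_range = c(0.29, 0.995),
                                 seed = 1) {
  stopifnot(n_genomes >= 2)
  targets <- seq(uniqueness_range[1], uniqueness_range[2],
                 length.out = n_genomes)
  genomes <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    fam <- withr_seed(derive_seed(seed, i * 2L), {
      corpus_families(targets[i], genome_length)
    })
    genomes[[i]] <- simulate_genome(
      genome_length, families = fam, k = k, n = n,
      seed = derive_seed(seed, i * 2L + 1L), label = sprintf("synth_%02d", i))
  }
  spectra <- lapply(genomes, function(g) g$truth)
  summary <- tibble(
    label = vapply(spectra, function(s) s$label, ""),
    target_uniqueness = targets,
    uniqueness = vapply(spectra, function(s) s$uniqueness, 0),
    L = vapply(spectra, function(s) s$L, 0))
  list(genomes = genomes, spectra = spectra, summary = summary)
}

# Repeat-family layout for a target uniqueness ratio. Repeat elements are
# drawn one by one until the repeated footprint (1 - u) of the genome is
# spent: unit lengths uniform in 100-600 bp and copy numbers from a power
# law with minimum 2, giving the smooth power-law spectral decay seen in
# real assemblies (no artificial cliff at any copy number). The power-law
# exponent shifts with the target uniqueness -- repeat-rich genomes carry
# heavier high-copy tails -- with only slight jitter, so the cross-genome
# spectral-ratio relation stays tight, as observed across real assemblies.
# An occasional very-high-copy short element emulates mobile elements.
corpus_families <- function(u_target, genome_length) {
  # per-copy divergence and junction k-mers put some repeat footprint back
  # into the unique class, so overshoot the repeated fraction slightly to
  # realise the requested uniqueness
  f_rep <- min(0.98, 1.45 * (1 - u_target))
  if (f_rep <= 0.005) return(NULL)
  budget <- f_rep * genome_length
  # spectral decay exponent: repeat-rich genomes carry heavier tails
  b <- 3.2 - 1.2 * f_rep + runif(1, -0.02, 0.02)
  jj <- 2:300
  pj <- jj^(-b)
  rows <- list()
  spent <- 0
  # transposon-like element first, so the budget check is conservative
  if (runif(1) < 0.4 && f_rep > 0.05) {
    copies <- sample(200:500, 1)
    unit <- sample(60:120, 1)
    if (unit * copies < 0.3 * budget) {
      rows[[length(rows) + 1L]] <- tibble(
        unit_length = unit, copies = copies,
        divergence = runif(1, 0, 0.002))
      spent <- spent + unit * copies
    }
  }
  # many short elements rather than few long ones: per-genome spectral
  # ratios then concentrate tightly around the copy-number law
  max_unit <- max(80L, min(150L, as.integer(budget / 50)))
  while (spent < budget) {
    unit <- sample(60:max_unit, 1)
    copies <- sample(jj, 1, prob = pj)
    if (spent + unit * copies > budget) {
      # shrink the last element to fit; drop it if it gets too short
      unit <- floor((budget - spent) / copies)
      if (unit < 40) break
    }
    rows[[length(rows) + 1L]] <- tibble(
      unit_length = unit, copies = copies,
      divergence = 0.002)
    spent <- spent + unit * copies
  }
  if (length(rows) == 0) return(NULL)
  bind_rows(rows)
}
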