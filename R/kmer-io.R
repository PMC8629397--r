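#' Read sequences from a FASTA or FASTQ file
#'
#' Reads plain or gzip-compressed FASTA/FASTQ into a tibble with one row per
#' record. Qualities are discarded; sequences are folded to upper case.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @param format `"auto"` (default, detected from the file extension, falling
#'   back to sniffing the first character), `"fasta"` or `"fastq"`.
#' @return A tibble with columns `id` (character) and `seq` (character).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGTACGT", ">s2", "GGGGCCCC"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "skimspect_io_error")
  }
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE)) {
      "fastq"
    } else if (grepl("\\.(fasta|fa|fna|ffn)$", base, ignore.case = TRUE)) {
      "fasta"
    } else {
      con <- gzfile(path, "rt")
      first <- readLines(con, n = 1L)
      close(con)
      if (length(first) == 0L) {
        abort("empty input file", class = "skimspect_io_error")
      }
      if (startsWith(first, "@")) "fastq" else "fasta"
    }
  }
  if (format == "fastq") {
    con <- gzfile(path, "rt")
    n_lines <- length(readLines(con))
    close(con)
    if (n_lines %% 4L != 0L) {
      abort(sprintf(
        "truncated FASTQ: %d lines is not a multiple of 4 (near line %d)",
        n_lines, n_lines + 1L),
        class = "skimspect_io_error")
    }
  }
  recs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)),
            class = "skimspect_io_error")
    }
  )
  tibble(
    id = unname(sub("\\s.*$", "", names(recs))),
    seq = unname(toupper(as.character(recs)))
  )
}

#' Count canonical k-mers exactly
#'
#' Exact (hash-based) counting of k-mers over \{A,C,G,T\}. Windows containing
#' any other character contribute nothing. In canonical mode each k-mer is
#' keyed by the lexicographic minimum of itself and its reverse complement, so
#' counting is strand-symmetric.
#'
#' @param x Sequences: a character vector, a tibble with a `seq` column (as
#'   returned by [read_sequences()]), or a path to a FASTA/FASTQ file.
#' @param k k-mer length, between 1 and 32. Default 31.
#' @param canonical Collapse each k-mer with its reverse complement
#'   (default `TRUE`).
#' @return A tibble with columns `kmer` and `count`, with attribute `k`.
#'   Sequences shorter than `k` contribute nothing; if no window is valid the
#'   table is empty (with a warning).
#' @examples
#' count_kmers("ACGT", k = 3, canonical = FALSE)
#' count_kmers("ACGT", k = 3) # revcomp(CGT) == ACG, so one canonical 3-mer
#' @export
count_kmers <- function(x, k = 31, canonical = TRUE) {
  seqs <- as_sequence_vector(x)
  res <- cpp_kmer_table(seqs, as.integer(k), isTRUE(canonical))
  out <- tibble(kmer = res$kmer, count = res$count)
  out <- arrange(out, .data$kmer)
  if (nrow(out) == 0L) {
    warn("no k-mer window of length k found; empty count table")
  }
  attr(out, "k") <- as.integer(k)
  out
}

as_sequence_vector <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    x <- read_sequences(x)
  }
  if (is.data.frame(x)) {
    stopifnot("seq" %in% names(x))
    x <- x$seq
  }
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x)) abort("cannot interpret input as sequences")
  x
}

#' Build a k-mer count histogram
#'
#' Tallies a k-mer count table (or counts k-mers directly from sequences) into
#' the observed-count histogram `o`, where `o[h]` is the number of distinct
#' k-mers seen exactly `h` times. The histogram carries the skim metadata
#' needed downstream: read length and the total number of sequenced bases.
#'
#' @param x A count table from [count_kmers()], a numeric vector of
#'   multiplicities, or sequences (anything [count_kmers()] accepts, in which
#'   case counting happens internally without materialising the table).
#' @param k k-mer length; taken from the table attribute when available.
#' @param canonical Passed to the counter when `x` is sequences.
#' @param read_length Read length in bp (`NA` if unknown).
#' @param total_bases Total sequenced bases B (`NA` if unknown).
#' @param n_reads Number of reads (`NA` if unknown).
#' @return A `kmer_histogram`: a tibble with columns `h` (1..H_max) and
#'   `count`, plus attributes `k`, `read_length`, `total_bases`, `n_reads`.
#' @export
kmer_histogram <- function(x, k = 31, canonical = TRUE,
                           read_length = NA_real_, total_bases = NA_real_,
                           n_reads = NA_real_) {
  if (is.data.frame(x) && all(c("kmer", "count") %in% names(x))) {
    k <- attr(x, "k") %||% k
    o <- tabulate_counts(x$count)
  } else if (is.numeric(x) && !is.null(names(x))) {
    o <- tabulate_counts(as.integer(x))
  } else if (is.numeric(x)) {
    o <- tabulate_counts(as.integer(x))
  } else {
    seqs <- as_sequence_vector(x)
    o <- cpp_kmer_histogram(seqs, as.integer(k), isTRUE(canonical))
  }
  new_kmer_histogram(o, k = k, read_length = read_length,
                     total_bases = total_bases, n_reads = n_reads)
}

tabulate_counts <- function(counts) {
  if (length(counts) == 0L) return(numeric(0))
  stopifnot(all(counts >= 1))
  as.numeric(tabulate(counts))
}

new_kmer_histogram <- function(o, k, read_length = NA_real_,
                               total_bases = NA_real_, n_reads = NA_real_) {
  o <- as.numeric(o)
  stopifnot(all(o >= 0), all(is.finite(o) | length(o) == 0L))
  out <- tibble(h = seq_along(o), count = o)
  class(out) <- c("kmer_histogram", class(out))
  attr(out, "k") <- as.integer(k)
  attr(out, "read_length") <- as.numeric(read_length)
  attr(out, "total_bases") <- as.numeric(total_bases)
  attr(out, "n_reads") <- as.numeric(n_reads)
  out
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf(
    "<kmer_histogram> k=%d  bins=%d  distinct=%s  instances=%s\n",
    attr(x, "k"), nrow(x),
    format(sum(x$count), big.mark = ","),
    format(sum(x$h * x$count), big.mark = ",")))
  if (!is.na(attr(x, "total_bases"))) {
    cat(sprintf("  read_length=%g  total_bases=%g  n_reads=%g\n",
                attr(x, "read_length"), attr(x, "total_bases"),
                attr(x, "n_reads")))
  }
  NextMethod()
}

hist_vector <- function(hist) {
  if (is.data.frame(hist)) hist$count else as.numeric(hist)
}

#' Read a two-column k-mer histogram file
#'
#' Parses the whitespace-separated `h count` text dialect written by standard
#' k-mer counters. Rows may appear in any order; absent multiplicities are
#' filled with zero counts.
#'
#' @param path Path to the histogram text file.
#' @inheritParams kmer_histogram
#' @return A `kmer_histogram`.
#' @export
read_histo <- function(path, k = 31, read_length = NA_real_,
                       total_bases = NA_real_, n_reads = NA_real_) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "skimspect_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_kmer_histogram(numeric(0), k = k, read_length = read_length,
                              total_bases = total_bases, n_reads = n_reads))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed histogram line %d: '%s'", bad[1], lines[bad[1]]),
          class = "skimspect_parse_error")
  }
  h <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  cnt <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  ok <- is.finite(h) & is.finite(cnt) & h == round(h) & cnt == round(cnt) &
    h >= 1 & cnt >= 0
  if (!all(ok)) {
    abort(sprintf("non-integer fields on histogram line %d: '%s'",
                  which(!ok)[1], lines[which(!ok)[1]]),
          class = "skimspect_parse_error")
  }
  if (anyDuplicated(h)) {
    abort(sprintf("duplicate multiplicity h=%g in histogram", h[duplicated(h)][1]),
          class = "skimspect_parse_error")
  }
  o <- numeric(max(h))
  o[h] <- cnt
  new_kmer_histogram(o, k = k, read_length = read_length,
                     total_bases = total_bases, n_reads = n_reads)
}

#' Write a k-mer histogram to the two-column text format
#'
#' Zero-count bins are omitted; [read_histo()] restores them, so the
#' write/read round trip is exact on the dense count vector.
#'
#' @param hist A `kmer_histogram` (or plain numeric vector of counts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histo <- function(hist, path) {
  o <- hist_vector(hist)
  keep <- which(o != 0)
  writeLines(sprintf("%d %s", keep, format(o[keep], scientific = FALSE,
                                           trim = TRUE)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
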