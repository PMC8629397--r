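# Small fixtures shared across test files; everything is generated in code.

write_tmp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_tmp_fastq <- function(seqs, ids = paste0("r", seq_along(seqs))) {
  path <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

# Exhaustive reference k-mer counter (string-based, no hashing tricks):
# the oracle against which the compiled counter is checked.
ref_count_kmers <- function(seqs, k, canonical = TRUE) {
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                      collapse = ""))
  out <- character(0)
  for (s in toupper(seqs)) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      if (canonical) {
        rc <- revcomp(w)
        if (rc < w) w <- rc
      }
      out <- c(out, w)
    }
  }
  if (length(out) == 0) return(integer(0))
  tab <- table(out)
  setNames(as.integer(tab), names(tab))
}

# tiny trained models for fast pipeline tests (loose bounds, flat splines)
toy_models <- function(y = c(8, 4, 2.5, 2, 1.8)) {
  b <- ratio_bounds(rep(0.5, 49), rep(1000, 49))
  grids <- lapply(seq_along(y), function(j) {
    list(j = j, link = if (j <= 2) "log" else "identity",
         u = seq(0.001, 1, length.out = 11), y = rep(y[j], 11),
         u_range = c(0.001, 1), n_train = 11L)
  })
  spl <- structure(list(models = grids, j_max = length(y)),
                   class = "ratio_splines")
  trained_models(b, spl)
}
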