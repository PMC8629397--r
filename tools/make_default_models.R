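#!/usr/bin/env Rscript
# Rebuilds the default trained models shipped in inst/extdata.
# Deterministic: everything derives from the fixed seed below.
# Run from the package root: Rscript tools/make_default_models.R
suppressPackageStartupMessages(library(skimspect))

seed <- 20260101L
corpus <- make_training_corpus(n_genomes = 40, genome_length = 4e6,
                               k = 31, n = 50, seed = seed)
message("corpus uniqueness range: ",
        paste(round(range(corpus$summary$uniqueness), 3), collapse = " - "))

genome_seqs <- lapply(corpus$genomes, function(g) g$sequence)
models <- train_models(
  corpus$spectra,
  k = 31, n = 50,
  spline_skims = genome_seqs,
  eps_calibration = genome_seqs,
  calibration_eps = 0.01,
  calibration_coverage = 1,
  read_length = 100,
  iterations = 400,
  seed = seed)

models$provenance <- list(
  corpus = "synthetic corpus: 40 genomes of 4 Mbp, uniqueness 0.29-0.995",
  k = 31, n = 50, seed = seed,
  calibration = "40 skims at 1X, read length 100, eps 0.01")

out <- file.path("inst", "extdata", "trained_models_synthetic.json")
write_trained_models(models, out)
message("wrote ", out, " (", file.size(out), " bytes)")
print(models$eps_correction)
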