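# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default-design synthetic study, seed fixed for the whole suite.
cached_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_study(simulation_design(seed = 42))
  }
  .fixtures$sim
}

# Full pipeline on the cached study.
cached_pipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    .fixtures$pipe <- run_linctype_pipeline(simulation_design(seed = 42),
                                            sim = cached_sim())
  }
  .fixtures$pipe
}

# Coding-potential scorers trained on a modest labelled set.
cached_scorers <- function() {
  if (is.null(.fixtures$scorers)) {
    tr <- simulate_codepot_sequences(n_per_class = 150, seed = 99)
    .fixtures$scorers <- train_scorers(tr$seqs, tr$labels)
  }
  .fixtures$scorers
}

# Tiny catalog builder: one single-exon transcript per row of `spec`,
# spec = data.frame(id, chrom, start, end, strand, biotype).
toy_catalog <- function(id, chrom, start, end, strand = "+",
                        biotype = "candidate", gene = id) {
  transcript_catalog(data.frame(
    transcript_id = id, gene_id = gene, chrom = chrom,
    start = start, end = end, strand = strand,
    biotype = biotype, source = "toy", stringsAsFactors = FALSE
  ))
}

random_dna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
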