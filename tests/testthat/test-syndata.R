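# The synthetic-data generator: planted constraints, determinism, effect
# sizes, sequence models, methylation coupling, survival and PPI.

test_that("design validation rejects inconsistent configurations", {
  expect_error(simulation_design(n_novel_lincrna = 10), "too small")
  expect_error(simulation_design(hazard_ratio_range = c(2, 1)),
               "increasing")
  expect_error(simulation_design(censor_rate = 1.2), "censor_rate")
  d <- simulation_design(seed = 5)
  expect_equal(length(d$groups) * d$samples_per_group, 33L)
  expect_length(d$groups, 11)
})

test_that("planted truth echoes the design counts and ids exist in catalogs", {
  sim <- cached_sim()
  d <- sim$design
  tr <- sim$truth
  expect_length(tr$novel_lincrna_ids, d$n_novel_lincrna)
  expect_length(tr$decoy_near_ids, d$n_decoy_near)
  expect_length(tr$decoy_short_ids, d$n_decoy_short)
  expect_length(tr$decoy_coding_ids, d$n_decoy_coding)
  expect_equal(lengths(tr$ms_lincrna_map),
               setNames(rep(d$ms_lincrna_per_subtype, 5),
                        group_vocabulary()$subtypes))
  # MS marker sets are disjoint across subtypes
  ms <- unlist(tr$ms_lincrna_map)
  expect_false(any(duplicated(ms)))
  # every truth id exists in an emitted catalog
  all_ids <- c(transcripts(sim$known)$transcript_id,
               transcripts(sim$novel)$transcript_id)
  expect_true(all(c(tr$novel_lincrna_ids, tr$decoy_near_ids,
                    tr$decoy_short_ids, tr$decoy_coding_ids,
                    tr$planted_class$id, tr$cis_pairs$lincrna_id,
                    tr$cis_pairs$transcript_id,
                    tr$meth_regulated$transcript_id) %in% all_ids))
})

test_that("planted features respect the discovery-filter geometry", {
  sim <- cached_sim()
  tr <- sim$truth
  d_true <- distance_to_nearest_known(
    subset_catalog(sim$novel, tr$novel_lincrna_ids), sim$known)
  expect_true(all(d_true >= 2000))
  d_near <- distance_to_nearest_known(
    subset_catalog(sim$novel, tr$decoy_near_ids), sim$known)
  expect_true(all(d_near < 2000))
  expect_true(all(mature_length(sim$novel, tr$decoy_short_ids) < 200))
  expect_true(all(mature_length(sim$novel, tr$novel_lincrna_ids) >= 200))
  # ~96% of true novels are single-exon
  tx <- transcripts(subset_catalog(sim$novel, tr$novel_lincrna_ids))
  expect_equal(mean(tx$n_exons == 1), 0.96, tolerance = 0.01)
})

test_that("generators are pure functions of the design seed", {
  d <- simulation_design(seed = 77)
  a1 <- generate_annotation(d)
  a2 <- generate_annotation(d)
  expect_identical(a1, a2)
  s1 <- generate_sequences(a1$known, d, a1$truth)
  s2 <- generate_sequences(a2$known, d, a2$truth)
  expect_identical(s1, s2)
  p1 <- generate_ppi(a1$known, d, a1$truth)
  expect_identical(p1, generate_ppi(a1$known, d, a1$truth))
  # different seeds give different layouts
  a3 <- generate_annotation(simulation_design(seed = 78))
  expect_false(identical(a1$known$exons, a3$known$exons))
})

test_that("coding sequences carry long ORFs and noncoding ones do not", {
  sim <- cached_sim()
  tx <- transcripts(transcript_catalog(rbind(sim$known$exons,
                                             sim$novel$exons)))
  coding_ids <- c(tx$transcript_id[tx$biotype == "coding"],
                  sim$truth$decoy_coding_ids)
  expect_equal(unname(nchar(sim$sequences)),
               unname(mature_length(transcript_catalog(
                 rbind(sim$known$exons, sim$novel$exons)))[
                   names(sim$sequences)]))
  covs <- vapply(sim$sequences[coding_ids],
                 function(s) longest_orf(s)$orf_cov, numeric(1))
  expect_true(all(covs >= 0.6))
  # noncoding model: long ORFs are rare (the consensus scorers depend on
  # this separation)
  held <- simulate_codepot_sequences(n_per_class = 300, seed = 137)
  nc <- held$seqs[held$labels == "noncoding"]
  orf_len <- vapply(nc, function(s) longest_orf(s)$orf_len, numeric(1))
  expect_gte(mean(orf_len < 300), 0.95)
})

test_that("planted subtype effects land at the designed magnitude", {
  sim <- cached_sim()
  lm2 <- log2(sim$expression$m)
  meta <- sim$expression$meta
  diffs <- c()
  for (st in names(sim$truth$ms_lincrna_map)) {
    for (id in sim$truth$ms_lincrna_map[[st]]) {
      inx <- meta$group == st
      diffs <- c(diffs, mean(lm2[id, inx]) - mean(lm2[id, !inx]))
    }
  }
  expect_equal(mean(diffs), sim$design$effect_log2fc, tolerance = 0.25)
  expect_true(all(abs(diffs - sim$design$effect_log2fc) < 1.5))
})

test_that("cis pairs correlate near the planted latent strength", {
  sim <- cached_sim()
  lm2 <- log2(sim$expression$m + 1)
  r <- vapply(seq_len(nrow(sim$truth$cis_pairs)), function(i) {
    cor(lm2[sim$truth$cis_pairs$lincrna_id[i], ],
        lm2[sim$truth$cis_pairs$transcript_id[i], ])
  }, numeric(1))
  expect_true(all(r > 0.4 & r < 0.97))
  expect_equal(mean(r), sim$design$cis_latent_r, tolerance = 0.12)
  # degenerate case: no noise, no effects -> identical samples per row
  d0 <- simulation_design(noise_sd_log2 = 0, effect_log2fc = 0, seed = 3)
  ann0 <- generate_annotation(d0)
  e0 <- generate_expression(d0, ann0$truth,
                            transcript_catalog(rbind(ann0$known$exons,
                                                     ann0$novel$exons)))
  expect_true(all(apply(e0$m, 1, function(x) max(x) - min(x)) < 1e-9))
})

test_that("methylation couples to expression with the planted sign", {
  sim <- cached_sim()
  beta <- sim$methylation$beta
  expect_true(all(beta > 0 & beta < 1))
  reg <- sim$truth$meth_regulated
  lm2 <- log2(sim$expression$m + 1)
  r <- vapply(seq_len(nrow(reg)), function(i) {
    cor(beta[reg$cpg_id[i], ], lm2[reg$transcript_id[i], ])
  }, numeric(1))
  expect_true(all(r[reg$sign == "negative"] < 0))
  expect_true(all(r[reg$sign == "positive"] > 0))
  # regulated CpGs sit inside the promoter window of their transcript
  combined <- transcript_catalog(rbind(sim$known$exons, sim$novel$exons))
  win <- promoter_cpg_sites(combined, sim$methylation$sites)
  key <- paste(win$transcript_id, win$cpg_id)
  expect_true(all(paste(reg$transcript_id, reg$cpg_id) %in% key))
})

test_that("survival generator honours censoring and hazard settings", {
  d0 <- simulation_design(censor_rate = 0, seed = 9)
  s0 <- generate_survival(d0, rep(c("k1", "k2"), each = 30))
  expect_true(all(s0$event == 1))
  expect_true(all(s0$time >= 0))
  d1 <- simulation_design(censor_rate = 0.3, seed = 9)
  s1 <- generate_survival(d1, rep(c("k1", "k2"), each = 300))
  expect_lt(abs(mean(s1$event == 0) - 0.3), 0.06)  # ~3 SE at n = 600
  hz <- attr(s1, "hazards")
  expect_equal(unname(hz["k2"] / hz["k1"]), 4, tolerance = 1e-12)
  # higher-hazard groups die sooner on average
  expect_lt(median(s1$time[s1$label == "k2"]),
            median(s1$time[s1$label == "k1"]))
})

test_that("the PPI network is simple and honours the planted pairs", {
  sim <- cached_sim()
  ppi <- sim$ppi
  expect_false(any(ppi$gene_a == ppi$gene_b))
  expect_false(any(duplicated(paste(ppi$gene_a, ppi$gene_b))))
  cp <- sim$truth$coding_pairs
  keys <- paste(pmin(ppi$gene_a, ppi$gene_b), pmax(ppi$gene_a, ppi$gene_b))
  want <- paste(pmin(cp$gene_a, cp$gene_b), pmax(cp$gene_a, cp$gene_b))
  expect_true(all(want[cp$ppi] %in% keys))
  expect_false(any(want[!cp$ppi] %in% keys))
})

test_that("a written study round-trips through the standard formats", {
  outdir <- file.path(tempdir(), "study_out")
  d <- simulation_design(seed = 31)
  sim <- simulate_study(d, outdir = outdir)
  expect_setequal(list.files(outdir),
                  c("known.gtf", "novel_candidates.gtf", "transcripts.fa",
                    "fpkm.tsv", "samples.tsv", "meth_beta.tsv", "cpg.bed",
                    "ppi.tsv", "survival.tsv", "truth.json"))
  fa <- Biostrings::readDNAStringSet(file.path(outdir, "transcripts.fa"))
  expect_equal(as.character(fa), sim$sequences)
  m <- as.matrix(utils::read.table(file.path(outdir, "fpkm.tsv"),
                                   sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  expect_equal(m, sim$expression$m, tolerance = 1e-12)
  truth_back <- jsonlite::read_json(file.path(outdir, "truth.json"),
                                    simplifyVector = TRUE)
  expect_equal(truth_back$novel_lincrna_ids, sim$truth$novel_lincrna_ids)
  bed <- utils::read.table(file.path(outdir, "cpg.bed"), sep = "\t")
  expect_equal(bed$V3 - bed$V2, rep(2L, nrow(bed)))  # 0-based half-open
})
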