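# Catalog construction, GTF I/O, interval distances and the discovery
# filter cascade.

test_that("GTF parsing converts 1-based inclusive to 0-based half-open", {
  gtf <- file.path(tempdir(), "toy.gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\texon\t301\t350\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr2\tsrc\texon\t1\t80\t.\t-\t.\ttranscript_id "t2"; gene_id "g2";'
  ), gtf)
  cat <- parse_gtf(gtf)
  tx <- transcripts(cat)
  t1 <- tx[tx$transcript_id == "t1", ]
  expect_equal(t1$n_exons, 2L)
  expect_equal(t1$mature_length, 150L)
  expect_equal(cat$exons$start[cat$exons$transcript_id == "t1"], c(100L, 300L))
  expect_equal(cat$exons$end[cat$exons$transcript_id == "t1"], c(200L, 350L))
  expect_equal(tx$strand[tx$transcript_id == "t2"], "-")
  expect_equal(tx$span_start[tx$transcript_id == "t2"], 0L)
})

test_that("write -> parse round trip preserves exon coordinates", {
  sim <- cached_sim()
  path <- file.path(tempdir(), "roundtrip.gtf")
  write_gtf(sim$novel, path)
  back <- parse_gtf(path)
  cols <- c("transcript_id", "chrom", "start", "end", "strand", "biotype")
  expect_equal(back$exons[cols], sim$novel$exons[cols])
})

test_that("catalog invariants are enforced", {
  expect_error(toy_catalog("t1", "chr1", 100, 100), "end <= start")
  expect_error(transcript_catalog(data.frame()), "missing exon columns")
  expect_error(
    transcript_catalog(data.frame(
      transcript_id = "t1", gene_id = "g", chrom = "chr1",
      start = c(0, 50), end = c(100, 150), strand = "+",
      biotype = "candidate", source = "s")),
    "overlapping exons")
})

test_that("mature length sums exon lengths", {
  expect_equal(unname(mature_length(toy_catalog("t", "chr1", 0, 1673))),
               1673L)
  two_ex <- transcript_catalog(data.frame(
    transcript_id = "t", gene_id = "t", chrom = "chr1",
    start = c(0, 200), end = c(100, 300), strand = "+",
    biotype = "candidate", source = "s"))
  expect_equal(unname(mature_length(two_ex)), 200L)
  expect_error(mature_length(two_ex, "missing"), "unknown transcript")
})

test_that("distance to nearest known gene: gaps, overlap, empty chromosome", {
  known <- toy_catalog(c("g1", "g2"), c("chr1", "chr1"),
                       c(0, 20000), c(1000, 21000), biotype = "coding")
  cand <- toy_catalog(c("c1", "c2", "c3"), c("chr1", "chr1", "chr9"),
                      c(5000, 500, 100), c(6000, 1500, 300))
  d <- distance_to_nearest_known(cand, known)
  expect_equal(unname(d["c1"]), 4000)   # [5000,6000) vs [0,1000)
  expect_equal(unname(d["c2"]), 0)      # overlap
  expect_equal(unname(d["c3"]), Inf)    # no known gene on chr9
})

test_that("indexed distance equals the brute-force oracle on random instances", {
  set.seed(7)
  for (rep in 1:5) {
    n_known <- 200
    chroms <- paste0("chr", sample(1:3, n_known, replace = TRUE))
    s <- sample(1:500000, n_known)
    known <- toy_catalog(sprintf("g%03d", 1:n_known), chroms, s,
                         s + sample(100:5000, n_known, replace = TRUE),
                         biotype = "coding")
    qs <- sample(1:500000, 40)
    cand <- toy_catalog(sprintf("c%02d", 1:40),
                        paste0("chr", sample(1:3, 40, replace = TRUE)),
                        qs, qs + sample(100:3000, 40, replace = TRUE))
    d <- distance_to_nearest_known(cand, known)
    ktx <- transcripts(known)
    ctx <- transcripts(cand)
    for (i in seq_len(nrow(ctx))) {
      expect_equal(unname(d[ctx$transcript_id[i]]),
                   oracle_min_gap(ctx$chrom[i], ctx$span_start[i],
                                  ctx$span_end[i], ktx$chrom,
                                  ktx$span_start, ktx$span_end))
    }
  }
})

test_that("nearest gene assignment picks minimal gap with deterministic ties", {
  known <- toy_catalog(c("gA", "gB"), "chr1", c(20000, 70000),
                       c(21000, 71000), biotype = "coding")
  cand <- toy_catalog("c1", "chr1", 9000, 10000)
  res <- nearest_gene_assignment(cand, known, max_dist = 1e6)
  expect_equal(res$gene_id, "gA")
  expect_equal(res$gap_bp, 10000)
  res2 <- nearest_gene_assignment(cand, known, max_dist = 5000)
  expect_true(is.na(res2$gene_id))
  # tie at equal gap: smaller start wins
  tied <- toy_catalog(c("gZ", "gY"), "chr1", c(0, 2000), c(500, 2500),
                      biotype = "coding")
  mid <- toy_catalog("c", "chr1", 1000, 1500)
  expect_equal(nearest_gene_assignment(mid, tied)$gene_id, "gZ")
})

test_that("nearest gene assignment equals the brute-force scan on random instances", {
  set.seed(11)
  hits <- 0
  for (rep in 1:100) {
    n <- 15
    s <- sample(1:200000, n)
    known <- toy_catalog(sprintf("g%02d", 1:n),
                         paste0("chr", sample(1:2, n, replace = TRUE)),
                         s, s + sample(100:2000, n, replace = TRUE),
                         biotype = "coding")
    q <- sample(1:200000, 1)
    cand <- toy_catalog("c", paste0("chr", sample(1:2, 1)), q, q + 500)
    res <- nearest_gene_assignment(cand, known, max_dist = 50000)
    ktx <- transcripts(known)
    ctx <- transcripts(cand)
    gaps <- vapply(seq_len(n), function(i) {
      oracle_min_gap(ctx$chrom, ctx$span_start, ctx$span_end,
                     ktx$chrom[i], ktx$span_start[i], ktx$span_end[i])
    }, numeric(1))
    ok <- which(gaps <= 50000)
    if (length(ok) == 0) {
      expect_true(is.na(res$gene_id))
    } else {
      best <- ok[order(gaps[ok], ktx$span_start[ok], ktx$transcript_id[ok])][1]
      expect_equal(res$gene_id, ktx$gene_id[best])
      hits <- hits + 1
    }
  }
  expect_gt(hits, 30)  # the random layout must actually exercise matches
})

test_that("filter cascade rejects at the distance and length boundaries", {
  known <- toy_catalog("g1", "chr1", 0, 1000, biotype = "coding")
  cand <- toy_catalog(c("near", "far", "short"), "chr1",
                      c(2999, 13000, 50000),
                      c(2999 + 500, 13500, 50199))
  set.seed(1)
  seqs <- c(near = random_dna(500, c(A = .33, C = .17, G = .17, T = .33)),
            far = random_dna(500, c(A = .33, C = .17, G = .17, T = .33)),
            short = random_dna(199, c(A = .33, C = .17, G = .17, T = .33)))
  res <- filter_novel_lincrnas(cand, known, seqs, cached_scorers())
  aud <- res$audit
  expect_equal(aud$reason[aud$transcript_id == "near"], "distance")
  expect_equal(aud$gap_bp[aud$transcript_id == "near"], 1999)
  expect_equal(aud$reason[aud$transcript_id == "short"], "length")
  expect_equal(aud$verdict[aud$transcript_id == "far"], "accepted")
  expect_error(filter_novel_lincrnas(cand, known, seqs[1:2],
                                     cached_scorers()),
               "without sequence: short")
})

test_that("filter is monotone in its thresholds and consensus-contained", {
  pipe <- cached_pipeline()
  sim <- cached_sim()
  seqs <- sim$sequences[transcripts(sim$novel)$transcript_id]
  base <- filter_novel_lincrnas(sim$novel, sim$known, seqs, pipe$scorers)
  stricter_d <- filter_novel_lincrnas(sim$novel, sim$known, seqs,
                                      pipe$scorers, min_dist = 50000)
  stricter_l <- filter_novel_lincrnas(sim$novel, sim$known, seqs,
                                      pipe$scorers, min_len = 1000)
  expect_true(all(stricter_d$accepted$transcript_id %in%
                    base$accepted$transcript_id))
  expect_true(all(stricter_l$accepted$transcript_id %in%
                    base$accepted$transcript_id))
  # accepted set is contained in each single-filter pass set
  aud <- base$audit
  pass_dist <- aud$transcript_id[aud$gap_bp >= 2000]
  pass_len <- aud$transcript_id[aud$mature_len >= 200]
  acc <- base$accepted$transcript_id
  expect_true(all(acc %in% pass_dist) && all(acc %in% pass_len))
  # accepted transcripts split exactly into SE/ME classes
  expect_true(all(base$accepted$exon_class %in% c("SElincRNA", "MElincRNA")))
  expect_equal(base$accepted$exon_class == "SElincRNA",
               base$accepted$n_exons == 1)
})
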