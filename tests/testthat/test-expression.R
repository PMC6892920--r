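# FPKM filtering, differential expression, class assignment, qPCR
# quantification and descriptive statistics.

make_matrix <- function(v, samples = paste0("s", seq_len(ncol(v)))) {
  m <- as.matrix(v)
  colnames(m) <- samples
  m
}

test_that("low-expression filter drops only strictly-above-threshold rows", {
  m <- rbind(all_low = rep(0.001, 4),
             three_low = c(0.001, 0.001, 0.001, 5),
             high = rep(5, 4))
  m <- make_matrix(m)
  kept <- low_expression_filter(m)
  expect_false("all_low" %in% rownames(kept))          # 4/4 low
  expect_true("three_low" %in% rownames(kept))         # 3/4 = 75%, not >75%
  expect_true("high" %in% rownames(kept))
  zero <- make_matrix(matrix(0, 3, 4,
                             dimnames = list(paste0("t", 1:3), NULL)))
  expect_equal(nrow(low_expression_filter(zero)), 0)
  expect_equal(ncol(kept), ncol(m))  # samples unchanged
})

test_that("filter is monotone in both thresholds", {
  set.seed(41)
  m <- make_matrix(matrix(rexp(600, 10), 60, 10,
                          dimnames = list(sprintf("t%02d", 1:60), NULL)))
  for (fm in c(0.05, 0.2, 0.5)) {
    a <- rownames(low_expression_filter(m, fpkm_min = fm, frac = 0.5))
    b <- rownames(low_expression_filter(m, fpkm_min = fm * 2, frac = 0.5))
    expect_true(all(b %in% a))  # higher fpkm_min never keeps more
    c1 <- rownames(low_expression_filter(m, fpkm_min = fm, frac = 0.3))
    expect_true(all(c1 %in% rownames(low_expression_filter(m, fpkm_min = fm,
                                                           frac = 0.7))))
  }
})

test_that("differential expression matches t.test and hand BH per transcript", {
  set.seed(43)
  n_t <- 50
  m <- make_matrix(matrix(2^rnorm(n_t * 8, 3, 1), n_t, 8,
                          dimnames = list(sprintf("t%02d", 1:n_t), NULL)))
  meta <- data.frame(sample_id = colnames(m),
                     group = rep(c("her2", "normal"), each = 4))
  de <- differential_expression(m, meta, "normal", "her2")
  la <- log2(m[, 5:8] + 1); lb <- log2(m[, 1:4] + 1)
  for (i in seq_len(n_t)) {
    tt <- t.test(lb[i, ], la[i, ])
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[i], unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-12)
  }
  expect_equal(de$q, oracle_bh(de$p), tolerance = 1e-12)
})

test_that("degenerate groups give null results, tiny groups error", {
  m <- make_matrix(matrix(4, 3, 6, dimnames = list(paste0("t", 1:3), NULL)))
  meta <- data.frame(sample_id = colnames(m),
                     group = rep(c("tn", "normal"), each = 3))
  de <- differential_expression(m, meta, "normal", "tn")
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p, rep(1, 3))
  expect_false(any(de$significant))
  meta$group[1:5] <- "tn"
  expect_error(differential_expression(m, meta, "normal", "tn"),
               "at least 2 samples")
})

test_that("a planted 3-log2 shift at n=3/group is detected in most replicates", {
  set.seed(47)
  n_rep <- 500  # one planted transcript per row; 500 replicates
  base <- rnorm(n_rep, 3, 1)
  la <- matrix(rnorm(3 * n_rep, base, 0.5), n_rep, 3)
  lb <- matrix(rnorm(3 * n_rep, base + 3, 0.5), n_rep, 3)
  m <- make_matrix(cbind(2^la, 2^lb), samples = paste0("s", 1:6))
  rownames(m) <- sprintf("t%03d", seq_len(n_rep))
  meta <- data.frame(sample_id = colnames(m),
                     group = rep(c("normal", "her2"), each = 3))
  de <- differential_expression(m, meta, "normal", "her2")
  expect_gte(mean(de$significant), 0.9)
})

test_that("expression classes follow the comparison-pattern semantics", {
  voc <- group_vocabulary()
  grid <- expand.grid(subtype = voc$subtypes,
                      control = c("adjacent", "normal"),
                      stringsAsFactors = FALSE)
  build <- function(id, up_in, down_all = FALSE) {
    data.frame(transcript_id = id, subtype = grid$subtype,
               control = grid$control,
               log2fc = ifelse(down_all, -2,
                               ifelse(grid$subtype %in% up_in, 2, 0)),
               significant = down_all | grid$subtype %in% up_in,
               stringsAsFactors = FALSE)
  }
  de <- rbind(build("up_all", voc$subtypes),
              build("down_all", character(0), down_all = TRUE),
              build("lum_only", voc$luminal),
              build("mixed", c("lumA", "her2")))
  cls <- assign_expression_class(de)
  lab <- setNames(cls$class, cls$transcript_id)
  expect_equal(unname(lab["up_all"]), "II")
  expect_equal(unname(lab["down_all"]), "I")
  expect_equal(unname(lab["lum_only"]), "III")
  expect_equal(unname(lab["mixed"]), "unclassified")
  # partition: every transcript gets exactly one label
  expect_equal(sort(cls$transcript_id), sort(unique(de$transcript_id)))
})

test_that("planted expression classes are never mislabelled on synthetic data", {
  pipe <- cached_pipeline()
  truth <- cached_sim()$truth$planted_class
  got <- merge(pipe$classes, truth, by.x = "transcript_id", by.y = "id")
  called <- got[got$class.x != "unclassified", ]
  # every confident call must match the planted class (recall is limited
  # by the all-ten-comparisons rule at n = 3/group)
  expect_true(all(called$class.x == called$class.y))
  # transcripts with no planted class are never assigned I/II/III
  unplanted <- setdiff(pipe$classes$transcript_id, truth$id)
  expect_true(all(pipe$classes$class[pipe$classes$transcript_id %in%
                                       unplanted] == "unclassified"))
})

test_that("2^-dCT quantification has its closed forms and monotonicity", {
  expect_equal(relative_expression_ddct(25, 25), 1.0)
  expect_equal(relative_expression_ddct(24, 25), 2.0)
  expect_equal(relative_expression_ddct(28, 25), 0.125)
  ct <- seq(20, 30, by = 0.5)
  expect_true(all(diff(relative_expression_ddct(ct, 25)) < 0))
  expect_true(all(diff(relative_expression_ddct(25, ct)) > 0))
  expect_true(all(relative_expression_ddct(ct, rev(ct)) > 0))
})

test_that("descriptive statistics summarise per class and tolerate empties", {
  cat2 <- transcript_catalog(data.frame(
    transcript_id = c("t1", "t1"), gene_id = "t1", chrom = "chr1",
    start = c(0, 200), end = c(100, 300), strand = "+",
    biotype = "candidate", source = "s"))
  st <- descriptive_stats(cat2)
  me <- st[st$class == "MElincRNA", ]
  expect_equal(me$n, 1L)
  expect_equal(me$mean_exons, 2)
  expect_equal(me$median_exon_length, 100)
  expect_equal(me$median_mature_length, 200)
  expect_equal(me$median_span_length, 300)
  expect_equal(st$n[st$class == "coding"], 0L)  # empty class, no crash
  # median over three mature lengths
  cat3 <- toy_catalog(c("a", "b", "c"), "chr1", c(0, 1000, 3000),
                      c(100, 1200, 3300))
  st3 <- descriptive_stats(cat3)
  expect_equal(st3$median_mature_length[st3$class == "SElincRNA"], 200)
})
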