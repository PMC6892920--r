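# Synthetic study generator. Every downstream stage of the pipeline is
# exercised on data produced here, with all planted signals recorded in a
# ground-truth table: novel intergenic lincRNAs and the decoys that
# violate each discovery filter, subtype-specific expression effects,
# expression classes, cis-correlated lincRNA-gene pairs, promoter
# CpG-methylation-repressed transcripts, PPI-constrained coding pairs,
# and cluster-specific survival hazards.
#
# All generators are pure functions of (design, seed): each uses a fixed
# offset from the design seed so the components are independently
# reproducible.

#' Study simulation design
#'
#' Captures the design of the emulated study: 11 groups (five tumor
#' subtypes, five matched adjacent-tissue groups, normal breast) with
#' `samples_per_group` samples each (33 by default), plus the feature
#' counts and effect sizes of every planted signal.
#'
#' @param samples_per_group Samples per group (default 3; 11 groups).
#' @param n_known_genes Known coding genes.
#' @param n_known_noncoding Known noncoding transcripts.
#' @param n_novel_lincrna True novel intergenic lincRNAs (>= 2 kb from
#'   any known gene, >= 200 nt, noncoding sequence).
#' @param n_decoy_near Decoys violating the 2 kb distance rule.
#' @param n_decoy_short Decoys with mature length < 200 nt.
#' @param n_decoy_coding Intergenic decoys with protein-coding-like
#'   sequence.
#' @param ms_lincrna_per_subtype Planted subtype-specific lincRNAs per
#'   subtype.
#' @param effect_log2fc Planted log2 fold change of subtype and class
#'   effects (default 3).
#' @param cis_pair_fraction Fraction of novel lincRNAs given a correlated
#'   cis coding partner.
#' @param cis_latent_r Expected Pearson correlation of planted cis pairs.
#' @param meth_regulated_fraction Fraction of novel lincRNAs (and a
#'   proportional number of coding genes) with a promoter CpG coupled to
#'   expression.
#' @param noise_sd_log2 Within-group SD on the log2 FPKM scale.
#' @param hazard_ratio_range Range (min, max) of cluster hazard ratios
#'   for the survival generator.
#' @param censor_rate Expected censoring fraction (0 disables censoring).
#' @param validation_per_subtype Samples per subtype in the tumor-only
#'   validation cohort used for survival evaluation.
#' @param seed Integer seed; every generator derives its RNG stream from
#'   it.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(samples_per_group = 3,
                              n_known_genes = 60,
                              n_known_noncoding = 20,
                              n_novel_lincrna = 50,
                              n_decoy_near = 10,
                              n_decoy_short = 5,
                              n_decoy_coding = 20,
                              ms_lincrna_per_subtype = 5,
                              effect_log2fc = 3.0,
                              cis_pair_fraction = 0.2,
                              cis_latent_r = 0.8,
                              meth_regulated_fraction = 0.3,
                              noise_sd_log2 = 0.5,
                              hazard_ratio_range = c(1, 4),
                              censor_rate = 0.2,
                              validation_per_subtype = 40,
                              seed = 1) {
  voc <- group_vocabulary()
  d <- list(n_subtypes = 5L,
            samples_per_group = as.integer(samples_per_group),
            groups = voc$all,
            n_known_genes = as.integer(n_known_genes),
            n_known_noncoding = as.integer(n_known_noncoding),
            n_novel_lincrna = as.integer(n_novel_lincrna),
            n_decoy_near = as.integer(n_decoy_near),
            n_decoy_short = as.integer(n_decoy_short),
            n_decoy_coding = as.integer(n_decoy_coding),
            ms_lincrna_per_subtype = as.integer(ms_lincrna_per_subtype),
            effect_log2fc = effect_log2fc,
            cis_pair_fraction = cis_pair_fraction,
            cis_latent_r = cis_latent_r,
            meth_regulated_fraction = meth_regulated_fraction,
            noise_sd_log2 = noise_sd_log2,
            hazard_ratio_range = hazard_ratio_range,
            censor_rate = censor_rate,
            validation_per_subtype = as.integer(validation_per_subtype),
            seed = as.integer(seed))
  counts <- unlist(d[grep("^n_|samples_per_group|ms_lincrna", names(d))])
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (d$samples_per_group < 1) stop("need at least one sample per group")
  if (length(hazard_ratio_range) != 2 ||
      hazard_ratio_range[1] > hazard_ratio_range[2] ||
      hazard_ratio_range[1] <= 0) {
    stop("hazard_ratio_range must be an increasing positive pair")
  }
  if (cis_latent_r < 0 || cis_latent_r >= 1) stop("cis_latent_r in [0, 1)")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate in [0, 1)")
  n_special <- 5 * d$ms_lincrna_per_subtype + 8 +
    round(d$cis_pair_fraction * d$n_novel_lincrna)
  if (n_special > d$n_novel_lincrna) {
    stop("n_novel_lincrna too small for the requested planted signals (",
         n_special, " needed)")
  }
  n_cis <- round(d$cis_pair_fraction * d$n_novel_lincrna)
  if (d$n_decoy_near > 25) {
    stop("at most 25 near-decoys can be hosted by the gene layout")
  }
  if (d$n_known_genes < 40 + n_cis || d$n_known_genes < 60) {
    stop("need at least max(60, 40 + cis pairs) known genes to host the ",
         "planted gene roles")
  }
  structure(d, class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("simulation_design:", length(x$groups) * x$samples_per_group,
      "samples in", length(x$groups), "groups; seed", x$seed, "\n")
  cat("  features:", x$n_known_genes, "coding,", x$n_known_noncoding,
      "known noncoding,", x$n_novel_lincrna, "novel lincRNA,",
      x$n_decoy_near + x$n_decoy_short + x$n_decoy_coding, "decoys\n")
  invisible(x)
}

#' Sample metadata for the discovery cohort
#'
#' @param design A [simulation_design()].
#' @return A data.frame with `sample_id`, `group`, `subtype` (NA for
#'   control tissues).
#' @export
design_samples <- function(design) {
  voc <- group_vocabulary()
  groups <- rep(design$groups, each = design$samples_per_group)
  n <- length(groups)
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = groups,
    subtype = ifelse(groups %in% voc$subtypes, groups,
                     sub("^adjacent_", "", ifelse(groups == "normal",
                                                  NA, groups))),
    stringsAsFactors = FALSE
  )
}

# ---- genome layout -------------------------------------------------------

#' @noRd
make_exon_rows <- function(id, gene, chrom, strand, start, exon_lens,
                           intron_lens, biotype, source) {
  starts <- integer(length(exon_lens))
  ends <- integer(length(exon_lens))
  cur <- start
  for (i in seq_along(exon_lens)) {
    starts[i] <- cur
    ends[i] <- cur + exon_lens[i]
    cur <- ends[i] + if (i < length(exon_lens)) intron_lens[i] else 0L
  }
  data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
             start = starts, end = ends, strand = strand,
             biotype = biotype, source = source, stringsAsFactors = FALSE)
}

#' Generate the known and candidate annotation catalogs
#'
#' Lays out known coding genes, known noncoding transcripts, true novel
#' intergenic lincRNAs (genomic gap >= 2000 bp to every known gene,
#' mature length >= 200 nt, ~96% single-exon) and the three decoy
#' classes: near-decoys (< 2000 bp from a gene), short-decoys (< 200 nt)
#' and coding-like decoys (intergenic, long, but with a protein-coding
#' sequence). Chromosome coordinates guarantee every constraint by
#' construction; all planted roles are recorded in the ground truth.
#'
#' @param design A [simulation_design()].
#' @return A list with `known` and `novel` ([transcript_catalog()]s) and
#'   `truth` (ground-truth list).
#' @export
generate_annotation <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_rng(design$seed + 101L, {
    voc <- group_vocabulary()
    gene_ids <- sprintf("G%03d", seq_len(design$n_known_genes))
    nc_ids <- sprintf("NC%03d", seq_len(design$n_known_noncoding))
    novel_ids <- sprintf("L%03d", seq_len(design$n_novel_lincrna))
    near_ids <- sprintf("DN%02d", seq_len(design$n_decoy_near))
    short_ids <- sprintf("DS%02d", seq_len(design$n_decoy_short))
    cdecoy_ids <- sprintf("DC%02d", seq_len(design$n_decoy_coding))

    # fixed role assignment over the id space (randomness lives in
    # coordinates, lengths, strands and expression)
    n_ms <- 5 * design$ms_lincrna_per_subtype
    ms_map <- split(novel_ids[seq_len(n_ms)],
                    rep(voc$subtypes, each = design$ms_lincrna_per_subtype))
    ms_map <- ms_map[voc$subtypes]
    n_cis <- round(design$cis_pair_fraction * design$n_novel_lincrna)
    cis_linc <- novel_ids[n_ms + seq_len(n_cis)]
    class1_linc <- novel_ids[n_ms + n_cis + 1:5]
    class3_linc <- novel_ids[n_ms + n_cis + 6:8]
    class2_gene <- gene_ids[1:5]
    class3_gene <- gene_ids[6:7]
    pair_genes <- gene_ids[8:15]
    near_host <- gene_ids[16:(15 + design$n_decoy_near)]
    cis_gene <- gene_ids[40 + seq_len(n_cis)]
    coding_pairs <- data.frame(
      gene_a = pair_genes[c(1, 3, 5, 7)],
      gene_b = pair_genes[c(2, 4, 6, 8)],
      ppi = c(TRUE, TRUE, FALSE, FALSE),
      latent_r = design$cis_latent_r,
      stringsAsFactors = FALSE
    )
    # multi-exon novels: ~4% of true novels, never fewer than 1
    n_me <- max(1L, round(0.04 * design$n_novel_lincrna))
    me_ids <- utils::tail(novel_ids, n_me)

    rows <- list()
    cursor <- c(chr1 = 10000L, chr2 = 10000L)
    place <- function(chrom, gap, id, gene, exon_lens, intron_lens,
                      biotype, source) {
      start <- cursor[[chrom]] + as.integer(gap)
      strand <- sample(c("+", "-"), 1)
      r <- make_exon_rows(id, gene, chrom, strand, start,
                          as.integer(exon_lens), as.integer(intron_lens),
                          biotype, source)
      cursor[[chrom]] <<- max(r$end)
      rows[[length(rows) + 1]] <<- r
      invisible(r)
    }
    big_gap <- function() sample(120000:160000, 1)

    chrom_of <- function(i) if (i %% 2 == 1) "chr1" else "chr2"

    for (i in seq_along(gene_ids)) {
      g <- gene_ids[i]
      chrom <- chrom_of(i)
      n_ex <- sample(6:12, 1)
      place(chrom, big_gap(), paste0(g, ".1"), g,
            pmax(60, round(stats::rlnorm(n_ex, log(150), 0.4))),
            sample(500:3000, n_ex - 1, replace = TRUE),
            "coding", "sim_known")
      j <- match(g, near_host)
      if (!is.na(j)) {
        place(chrom, sample(100:1900, 1), near_ids[j], near_ids[j],
              pmax(250, round(stats::rlnorm(1, log(1200), 0.4))),
              integer(0), "candidate", "sim_candidate")
      }
      j <- match(g, cis_gene)
      if (!is.na(j)) {
        id <- cis_linc[j]
        place(chrom, sample(5000:80000, 1), id, id,
              pmax(250, round(stats::rlnorm(1, log(1600), 0.45))),
              integer(0), "candidate", "sim_candidate")
      }
    }
    for (i in seq_along(nc_ids)) {
      n_ex <- sample(1:3, 1)
      place(chrom_of(i), big_gap(), paste0(nc_ids[i], ".1"), nc_ids[i],
            pmax(200, round(stats::rlnorm(n_ex, log(700), 0.5))),
            if (n_ex > 1) sample(1000:5000, n_ex - 1, replace = TRUE)
            else integer(0),
            "known_noncoding", "sim_known")
    }
    standalone <- setdiff(novel_ids, cis_linc)
    for (i in seq_along(standalone)) {
      id <- standalone[i]
      if (id %in% me_ids) {
        n_ex <- sample(2:4, 1)
        place(chrom_of(i), big_gap(), id, id,
              pmax(150, round(stats::rlnorm(n_ex, log(400), 0.5))),
              sample(2000:8000, n_ex - 1, replace = TRUE),
              "candidate", "sim_candidate")
      } else {
        place(chrom_of(i), big_gap(), id, id,
              pmax(250, round(stats::rlnorm(1, log(1600), 0.45))),
              integer(0), "candidate", "sim_candidate")
      }
    }
    for (i in seq_along(short_ids)) {
      place(chrom_of(i), big_gap(), short_ids[i], short_ids[i],
            sample(80:199, 1), integer(0), "candidate", "sim_candidate")
    }
    for (i in seq_along(cdecoy_ids)) {
      place(chrom_of(i), big_gap(), cdecoy_ids[i], cdecoy_ids[i],
            pmax(600, round(stats::rlnorm(1, log(1500), 0.3))),
            integer(0), "candidate", "sim_candidate")
    }

    exons <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    known <- transcript_catalog(
      exons[exons$source == "sim_known", , drop = FALSE])
    novel <- transcript_catalog(
      exons[exons$source == "sim_candidate", , drop = FALSE])

    n_meth_linc <- round(design$meth_regulated_fraction *
                           design$n_novel_lincrna)
    n_meth_gene <- round(design$meth_regulated_fraction *
                           design$n_known_genes / 3)
    meth_targets <- c(sample(novel_ids, n_meth_linc),
                      paste0(sample(gene_ids, n_meth_gene), ".1"))
    meth_sign <- ifelse(stats::runif(length(meth_targets)) < 0.8,
                        "negative", "positive")

    truth <- list(
      novel_lincrna_ids = novel_ids,
      decoy_near_ids = near_ids,
      decoy_short_ids = short_ids,
      decoy_coding_ids = cdecoy_ids,
      multi_exon_novel_ids = me_ids,
      ms_lincrna_map = ms_map,
      cis_pairs = data.frame(lincrna_id = cis_linc,
                             gene_id = cis_gene,
                             transcript_id = paste0(cis_gene, ".1"),
                             latent_r = design$cis_latent_r,
                             stringsAsFactors = FALSE),
      planted_class = data.frame(
        id = c(class1_linc, paste0(class2_gene, ".1"),
               class3_linc, paste0(class3_gene, ".1")),
        class = c(rep("I", length(class1_linc)),
                  rep("II", length(class2_gene)),
                  rep("III", length(class3_linc) + length(class3_gene))),
        stringsAsFactors = FALSE),
      coding_pairs = cbind(coding_pairs,
                           id_a = paste0(coding_pairs$gene_a, ".1"),
                           id_b = paste0(coding_pairs$gene_b, ".1")),
      meth_regulated = data.frame(transcript_id = meth_targets,
                                  sign = meth_sign,
                                  stringsAsFactors = FALSE),
      silent_ids = paste0(utils::tail(nc_ids, 4), ".1")
    )
    list(known = known, novel = novel, truth = truth)
  })
}

# ---- sequence models -----------------------------------------------------

# First-order Markov chain for noncoding sequence: AT-rich with CpG
# depletion, which keeps spurious long ORFs rare and separates the
# hexamer statistics from the coding model.
#' @noRd
.nc_trans <- rbind(
  A = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33),
  C = c(A = 0.36, C = 0.18, G = 0.06, T = 0.40),
  G = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33),
  T = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)
)

# Batch first-order Markov sampling: one vectorised step per position
# across all sequences.
#' @noRd
rmarkov_batch <- function(lengths, trans = .nc_trans) {
  n <- length(lengths)
  if (n == 0) return(character(0))
  maxlen <- max(lengths)
  bases <- colnames(trans)
  cum <- t(apply(trans, 1, cumsum))
  cum[, ncol(cum)] <- 1  # guard against floating-point undershoot
  out <- matrix("", nrow = n, ncol = maxlen)
  state <- sample.int(4, n, replace = TRUE,
                      prob = colSums(trans) / sum(trans))
  out[, 1] <- bases[state]
  if (maxlen > 1) {
    for (j in 2:maxlen) {
      u <- stats::runif(n)
      # first column where u <= cumulative probability = inverse-cdf draw
      state <- max.col(u <= cum[state, , drop = FALSE],
                       ties.method = "first")
      out[, j] <- bases[state]
    }
  }
  vapply(seq_len(n), function(i) {
    paste(out[i, seq_len(lengths[i])], collapse = "")
  }, character(1))
}

# 3-periodic coding model: position-specific base preferences define a
# distribution over the 61 sense codons.
#' @noRd
.codon_probs <- local({
  b <- c("A", "C", "G", "T")
  p1 <- c(A = 0.28, C = 0.20, G = 0.33, T = 0.19)
  p2 <- c(A = 0.32, C = 0.22, G = 0.18, T = 0.28)
  p3 <- c(A = 0.16, C = 0.32, G = 0.30, T = 0.22)
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  codons <- paste0(g$b1, g$b2, g$b3)
  pr <- p1[g$b1] * p2[g$b2] * p3[g$b3]
  keep <- !(codons %in% c("TAA", "TAG", "TGA"))
  stats::setNames(pr[keep] / sum(pr[keep]), codons[keep])
})

#' @noRd
rcoding_seq <- function(len) {
  # ORF (ATG + biased sense codons + stop) covering ~70% of the length,
  # flanked by noncoding-model UTRs
  orf_codons <- max(4L, floor(0.7 * len / 3))
  orf_nt <- orf_codons * 3L
  interior <- sample(names(.codon_probs), orf_codons - 2L, replace = TRUE,
                     prob = .codon_probs)
  orf <- paste0("ATG", paste(interior, collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  rest <- len - orf_nt
  utr5 <- rest %/% 2
  utr3 <- rest - utr5
  flanks <- rmarkov_batch(c(max(utr5, 1), max(utr3, 1)))
  paste0(if (utr5 > 0) flanks[1] else "", orf,
         if (utr3 > 0) flanks[2] else "")
}

#' Generate transcript sequences
#'
#' Coding transcripts (known coding genes and coding-like decoys) are
#' drawn from a 3-periodic codon model with an ORF covering ~70% of the
#' mature length; all other transcripts come from a first-order AT-rich
#' noncoding Markov model. Sequence length equals mature length.
#'
#' @param catalog A [transcript_catalog()] (known, novel, or combined).
#' @param design A [simulation_design()].
#' @param truth Ground truth from [generate_annotation()] (identifies the
#'   coding-like decoys).
#' @return A named character vector of sequences.
#' @export
generate_sequences <- function(catalog, design, truth) {
  tx <- transcripts(catalog)
  with_rng(design$seed + 202L, {
    coding <- tx$biotype == "coding" |
      tx$transcript_id %in% truth$decoy_coding_ids
    out <- character(nrow(tx))
    names(out) <- tx$transcript_id
    nc_idx <- which(!coding)
    if (length(nc_idx) > 0) {
      out[nc_idx] <- rmarkov_batch(tx$mature_length[nc_idx])
    }
    for (i in which(coding)) {
      out[i] <- rcoding_seq(tx$mature_length[i])
    }
    out
  })
}

#' Labelled sequences for coding-potential scorer training/evaluation
#'
#' Draws `n_per_class` sequences from each sequence model (lengths
#' log-normal, clipped to `length_range`).
#'
#' @param n_per_class Sequences per class.
#' @param length_range Length clip range in nt.
#' @param seed RNG seed.
#' @return A list with `seqs` (named character vector) and `labels`
#'   (`"coding"`/`"noncoding"`).
#' @export
simulate_codepot_sequences <- function(n_per_class = 300,
                                       length_range = c(300, 3000),
                                       seed = 1) {
  with_rng(seed, {
    lens <- function(n) {
      pmin(length_range[2],
           pmax(length_range[1], round(stats::rlnorm(n, log(900), 0.4))))
    }
    nc <- rmarkov_batch(lens(n_per_class))
    cod <- vapply(lens(n_per_class), rcoding_seq, character(1))
    seqs <- c(cod, nc)
    names(seqs) <- c(sprintf("cod%04d", seq_len(n_per_class)),
                     sprintf("nc%04d", seq_len(n_per_class)))
    list(seqs = seqs,
         labels = rep(c("coding", "noncoding"), each = n_per_class))
  })
}

# ---- expression ----------------------------------------------------------

#' Generate the FPKM expression matrix
#'
#' Baseline log2 FPKM is normal per transcript (coding genes higher than
#' noncoding); subtype-specific markers get `+effect_log2fc` in their
#' tumor subtype only; Class I/II transcripts are shifted down/up in all
#' five tumor groups; Class III up in the luminal tumor groups only; cis
#' pairs (and the planted coding-coding pairs) share a latent factor
#' giving expected Pearson correlation `cis_latent_r`; planted silent
#' transcripts sit far below the low-expression threshold. FPKM is
#' `2^log2`, so strictly positive.
#'
#' @param design A [simulation_design()].
#' @param truth Ground truth from [generate_annotation()].
#' @param catalog Combined [transcript_catalog()] (known + candidates).
#' @param samples Optional metadata data.frame (`sample_id`, `group`);
#'   defaults to the 33-sample discovery cohort of [design_samples()].
#' @param seed_offset Offset added to the design seed (use a different
#'   offset per cohort).
#' @return A list with `m` (FPKM matrix) and `meta`.
#' @export
generate_expression <- function(design, truth, catalog, samples = NULL,
                                seed_offset = 303L) {
  tx <- transcripts(catalog)
  meta <- samples %||% design_samples(design)
  voc <- group_vocabulary()
  with_rng(design$seed + seed_offset, {
    n_t <- nrow(tx); n_s <- nrow(meta)
    ids <- tx$transcript_id
    mu <- ifelse(tx$biotype == "coding",
                 stats::rnorm(n_t, 4, 1.2),
                 stats::rnorm(n_t, 2, 1.2))
    mu[ids %in% truth$silent_ids] <- -9
    eff <- matrix(0, n_t, n_s)
    grp <- meta$group
    add_effect <- function(eff, t_ids, g_sel, delta) {
      ti <- match(t_ids, ids)
      eff[ti, g_sel] <- eff[ti, g_sel] + delta
      eff
    }
    for (st in names(truth$ms_lincrna_map)) {
      eff <- add_effect(eff, truth$ms_lincrna_map[[st]], grp == st,
                        design$effect_log2fc)
    }
    pc <- truth$planted_class
    tumor <- grp %in% voc$subtypes
    luminal <- grp %in% voc$luminal
    eff <- add_effect(eff, pc$id[pc$class == "I"], tumor,
                      -design$effect_log2fc)
    eff <- add_effect(eff, pc$id[pc$class == "II"], tumor,
                      design$effect_log2fc)
    eff <- add_effect(eff, pc$id[pc$class == "III"], luminal,
                      design$effect_log2fc)

    noise <- matrix(stats::rnorm(n_t * n_s), n_t, n_s)
    latent_pairs <- rbind(
      data.frame(a = truth$cis_pairs$lincrna_id,
                 b = truth$cis_pairs$transcript_id,
                 r = truth$cis_pairs$latent_r),
      data.frame(a = truth$coding_pairs$id_a,
                 b = truth$coding_pairs$id_b,
                 r = truth$coding_pairs$latent_r)
    )
    for (i in seq_len(nrow(latent_pairs))) {
      z <- stats::rnorm(n_s)
      rho <- latent_pairs$r[i]
      for (id in c(latent_pairs$a[i], latent_pairs$b[i])) {
        ti <- match(id, ids)
        noise[ti, ] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n_s)
      }
    }
    log2x <- mu + eff + design$noise_sd_log2 * noise
    m <- 2^log2x
    dimnames(m) <- list(ids, meta$sample_id)
    list(m = m, meta = meta)
  })
}

#' Tumor-only validation cohort metadata
#'
#' @param design A [simulation_design()].
#' @return Metadata data.frame with `validation_per_subtype` samples per
#'   tumor subtype.
#' @export
validation_samples <- function(design) {
  voc <- group_vocabulary()
  groups <- rep(voc$subtypes, each = design$validation_per_subtype)
  data.frame(sample_id = sprintf("V%03d", seq_along(groups)),
             group = groups, subtype = groups, stringsAsFactors = FALSE)
}

# ---- methylation ---------------------------------------------------------

#' Generate promoter CpG methylation
#'
#' Each methylation-regulated transcript receives one CpG placed 500-2000
#' bp upstream of its strand-aware TSS whose beta value is a logistic
#' transform of the transcript's standardized log2 expression
#' (`beta = logistic(a -/+ b z + eps)`, `b = 2`), giving the planted
#' negative (or positive) correlation. Null CpGs inside other promoter
#' windows are independent logistic noise, and decoy CpGs are placed
#' outside the window entirely.
#'
#' @param design A [simulation_design()].
#' @param truth Ground truth (from [generate_annotation()]).
#' @param catalog Combined [transcript_catalog()].
#' @param m FPKM matrix from [generate_expression()].
#' @param n_null_cpgs Null in-window CpGs to plant.
#' @param n_decoy_cpgs Out-of-window CpGs to plant.
#' @return A list with `beta` (CpG x sample matrix in (0,1)), `sites`
#'   (`cpg_id`, `chrom`, `position`) and `truth` (input truth with
#'   `meth_regulated` completed with CpG ids).
#' @export
generate_methylation <- function(design, truth, catalog, m,
                                 n_null_cpgs = 30, n_decoy_cpgs = 10) {
  tss <- transcript_tss(catalog)
  with_rng(design$seed + 404L, {
    reg <- truth$meth_regulated
    n_s <- ncol(m)
    cpg_rows <- list(); beta_rows <- list()
    k <- 0
    new_cpg <- function(t_id, offset_range) {
      k <<- k + 1
      i <- match(t_id, tss$transcript_id)
      offset <- sample(offset_range[1]:offset_range[2], 1)
      pos <- if (tss$strand[i] == "-") tss$tss[i] + offset
             else tss$tss[i] - offset
      list(cpg_id = sprintf("cg%05d", k), chrom = tss$chrom[i],
           position = max(0L, as.integer(pos)))
    }
    b <- 2
    reg$cpg_id <- NA_character_
    for (i in seq_len(nrow(reg))) {
      site <- new_cpg(reg$transcript_id[i], c(500, 2000))
      reg$cpg_id[i] <- site$cpg_id
      z <- as.numeric(scale(log2(m[reg$transcript_id[i], ] + 1)))
      a <- stats::rnorm(1, 0, 0.7)
      s <- if (reg$sign[i] == "negative") -b else b
      beta_rows[[site$cpg_id]] <- stats::plogis(a + s * z +
                                                  stats::rnorm(n_s, 0, 0.5))
      cpg_rows[[site$cpg_id]] <- site
    }
    unreg <- setdiff(tss$transcript_id, reg$transcript_id)
    null_hosts <- sample(unreg, min(n_null_cpgs, length(unreg)))
    for (t_id in null_hosts) {
      site <- new_cpg(t_id, c(500, 2000))
      beta_rows[[site$cpg_id]] <- stats::plogis(stats::rnorm(n_s, 0, 1))
      cpg_rows[[site$cpg_id]] <- site
    }
    decoy_hosts <- sample(tss$transcript_id,
                          min(n_decoy_cpgs, nrow(tss)))
    for (t_id in decoy_hosts) {
      site <- new_cpg(t_id, c(2500, 6000))
      beta_rows[[site$cpg_id]] <- stats::plogis(stats::rnorm(n_s, 0, 1))
      cpg_rows[[site$cpg_id]] <- site
    }
    sites <- do.call(rbind, lapply(cpg_rows, function(s) {
      data.frame(cpg_id = s$cpg_id, chrom = s$chrom, position = s$position,
                 stringsAsFactors = FALSE)
    }))
    rownames(sites) <- NULL
    beta <- do.call(rbind, beta_rows)
    colnames(beta) <- colnames(m)
    truth$meth_regulated <- reg
    truth$null_cpg_ids <- setdiff(rownames(beta), reg$cpg_id)
    list(beta = beta, sites = sites, truth = truth)
  })
}

# ---- survival ------------------------------------------------------------

#' Generate cluster-keyed exponential survival
#'
#' Event times are exponential with cluster-specific hazards spread
#' geometrically across `hazard_ratio_range`; censoring is a competing
#' exponential calibrated to the design's expected censoring fraction
#' (disabled at `censor_rate = 0`).
#'
#' @param design A [simulation_design()].
#' @param labels Cluster/group label per subject.
#' @param seed RNG seed (default derives from the design seed).
#' @return A data.frame with `label`, `time` (months), `event` (0/1);
#'   the per-label hazard ratios are attached as attribute `hazards`.
#' @export
generate_survival <- function(design, labels, seed = design$seed + 505L) {
  with_rng(seed, {
    labs <- sort(unique(as.character(labels)))
    hr <- exp(seq(log(design$hazard_ratio_range[1]),
                  log(design$hazard_ratio_range[2]),
                  length.out = max(length(labs), 2)))[seq_along(labs)]
    names(hr) <- labs
    lambda0 <- log(2) / 60  # baseline median survival 60 months
    lambda <- lambda0 * hr[as.character(labels)]
    t_event <- stats::rexp(length(labels), rate = lambda)
    if (design$censor_rate > 0) {
      cr <- design$censor_rate
      t_cens <- stats::rexp(length(labels),
                            rate = lambda * cr / (1 - cr))
      out <- data.frame(label = as.character(labels),
                        time = pmin(t_event, t_cens),
                        event = as.integer(t_event <= t_cens),
                        stringsAsFactors = FALSE)
    } else {
      out <- data.frame(label = as.character(labels), time = t_event,
                        event = 1L, stringsAsFactors = FALSE)
    }
    attr(out, "hazards") <- hr
    out
  })
}

# ---- PPI -----------------------------------------------------------------

#' Generate the protein-protein interaction stand-in network
#'
#' An undirected simple random graph over the coding gene ids, with the
#' planted PPI-supported coexpressed coding pairs guaranteed present and
#' the planted unsupported pairs guaranteed absent.
#'
#' @param known Known-gene [transcript_catalog()].
#' @param design A [simulation_design()].
#' @param truth Ground truth (for the planted coding pairs).
#' @return A data.frame of edges (`gene_a`, `gene_b`).
#' @export
generate_ppi <- function(known, design, truth) {
  tx <- transcripts(known)
  genes <- sort(unique(tx$gene_id[tx$biotype == "coding"]))
  with_rng(design$seed + 606L, {
    n_edges <- 3 * length(genes)
    a <- sample(genes, n_edges, replace = TRUE)
    b <- sample(genes, n_edges, replace = TRUE)
    keep <- a != b
    e <- unique(data.frame(gene_a = pmin(a[keep], b[keep]),
                           gene_b = pmax(a[keep], b[keep]),
                           stringsAsFactors = FALSE))
    cp <- truth$coding_pairs
    forced <- data.frame(gene_a = pmin(cp$gene_a[cp$ppi], cp$gene_b[cp$ppi]),
                         gene_b = pmax(cp$gene_a[cp$ppi], cp$gene_b[cp$ppi]),
                         stringsAsFactors = FALSE)
    banned <- ppi_key(cp$gene_a[!cp$ppi], cp$gene_b[!cp$ppi])
    e <- unique(rbind(e, forced))
    e <- e[!(ppi_key(e$gene_a, e$gene_b) %in% banned), , drop = FALSE]
    e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
    rownames(e) <- NULL
    e
  })
}

# ---- orchestration -------------------------------------------------------

#' Simulate a complete study
#'
#' Runs every generator and optionally writes the standard file set:
#' `known.gtf`, `novel_candidates.gtf`, `transcripts.fa`, `fpkm.tsv`,
#' `samples.tsv`, `meth_beta.tsv`, `cpg.bed` (0-based half-open),
#' `ppi.tsv`, `survival.tsv` (validation cohort), `truth.json`.
#'
#' @param design A [simulation_design()].
#' @param outdir Optional output directory (created if needed).
#' @return A list with `design`, `known`, `novel`, `truth`, `sequences`,
#'   `expression` (`m`, `meta`), `validation` (`m`, `meta`, `survival`),
#'   `methylation` (`beta`, `sites`), `ppi`.
#' @export
simulate_study <- function(design, outdir = NULL) {
  ann <- generate_annotation(design)
  combined <- transcript_catalog(rbind(ann$known$exons, ann$novel$exons))
  seqs <- generate_sequences(combined, design, ann$truth)
  expr <- generate_expression(design, ann$truth, combined)
  meth <- generate_methylation(design, ann$truth, combined, expr$m)
  truth <- meth$truth
  ppi <- generate_ppi(ann$known, design, truth)
  vmeta <- validation_samples(design)
  vexpr <- generate_expression(design, truth, combined, samples = vmeta,
                               seed_offset = 707L)
  surv <- generate_survival(design, vmeta$subtype)
  surv$sample_id <- vmeta$sample_id
  truth$cluster_hazards <- attr(surv, "hazards")
  sim <- list(design = design, known = ann$known, novel = ann$novel,
              truth = truth, sequences = seqs, expression = expr,
              validation = list(m = vexpr$m, meta = vmeta, survival = surv),
              methylation = list(beta = meth$beta, sites = meth$sites),
              ppi = ppi)
  if (!is.null(outdir)) write_study(sim, outdir)
  sim
}

#' @noRd
write_study <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_gtf(sim$known, fp("known.gtf"))
  write_gtf(sim$novel, fp("novel_candidates.gtf"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences),
                              fp("transcripts.fa"))
  write_tsv <- function(d, f, rn = FALSE) {
    utils::write.table(d, fp(f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  }
  write_tsv(as.data.frame(sim$expression$m), "fpkm.tsv", rn = TRUE)
  write_tsv(sim$expression$meta, "samples.tsv")
  write_tsv(as.data.frame(sim$methylation$beta), "meth_beta.tsv", rn = TRUE)
  bed <- data.frame(chrom = sim$methylation$sites$chrom,
                    start = sim$methylation$sites$position,
                    end = sim$methylation$sites$position + 2L,
                    name = sim$methylation$sites$cpg_id)
  utils::write.table(bed, fp("cpg.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(sim$ppi, "ppi.tsv")
  write_tsv(sim$validation$survival, "survival.tsv")
  jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
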