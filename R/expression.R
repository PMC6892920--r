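# FPKM matrix handling: low-expression filtering, differential expression,
# expression-class assignment, qPCR relative quantification, descriptive
# statistics by transcript class.

#' Group vocabulary of the study design
#'
#' Five tumor subtypes, their matched adjacent-tissue groups, and normal
#' breast tissue.
#' @return Character vectors in a list: `subtypes`, `luminal`, `adjacent`,
#'   `controls`, `all`.
#' @export
group_vocabulary <- function() {
  subtypes <- c("lumA", "lumB_her2neg", "lumB_her2pos", "her2", "tn")
  adjacent <- paste0("adjacent_", subtypes)
  list(subtypes = subtypes,
       luminal = c("lumA", "lumB_her2neg", "lumB_her2pos"),
       adjacent = adjacent,
       controls = c(adjacent, "normal"),
       all = c(subtypes, adjacent, "normal"))
}

#' @noRd
check_matrix <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs transcript rownames and sample colnames")
  }
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) stop("FPKM values must be nonnegative")
  m
}

#' Low-expression filter
#'
#' Drops transcripts whose FPKM is below `fpkm_min` in strictly more than
#' `frac` of the samples; the sample set is unchanged.
#'
#' @param m FPKM matrix, transcripts x samples.
#' @param fpkm_min FPKM threshold (default 0.01).
#' @param frac Sample fraction threshold; the boundary is strict (a
#'   transcript low in exactly `frac` of samples is retained).
#' @return The filtered matrix.
#' @export
low_expression_filter <- function(m, fpkm_min = 0.01, frac = 0.75) {
  m <- check_matrix(m)
  low_frac <- rowMeans(m < fpkm_min)
  m[low_frac <= frac, , drop = FALSE]
}

#' Differential expression between two sample groups
#'
#' Welch two-sample t-test per transcript on log2(FPKM + 1), with
#' Benjamini-Hochberg adjustment across all transcripts of the
#' comparison. The fold change is the mean difference on the transformed
#' scale (B minus A).
#'
#' @param m FPKM matrix, transcripts x samples.
#' @param meta Sample metadata with columns `sample_id` and `group`.
#' @param group_a,group_b Group labels (vectors allowed; samples from all
#'   listed groups are pooled).
#' @param alpha Significance level on the adjusted value q.
#' @param fc_min Minimum |log2 fold change| for the `significant` flag.
#' @return A data.frame with `transcript_id`, `comparison`, `log2fc`, `p`,
#'   `q`, `significant`.
#' @export
differential_expression <- function(m, meta, group_a, group_b,
                                    alpha = 0.05, fc_min = 1.0) {
  m <- check_matrix(m)
  sa <- meta$sample_id[meta$group %in% group_a]
  sb <- meta$sample_id[meta$group %in% group_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("each group needs at least 2 samples")
  }
  la <- log2(m[, sa, drop = FALSE] + 1)
  lb <- log2(m[, sb, drop = FALSE] + 1)
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  # zero variance in both groups with equal means: no evidence either way
  p[!is.finite(tstat)] <- 1
  lfc <- mb - ma
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    transcript_id = rownames(m),
    comparison = paste0(paste(group_b, collapse = "+"), "_vs_",
                        paste(group_a, collapse = "+")),
    log2fc = lfc,
    p = p,
    q = q,
    significant = q < alpha & abs(lfc) >= fc_min,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' All tumor-versus-control comparisons
#'
#' Runs [differential_expression()] for each tumor subtype against each of
#' the two control tissues (pooled adjacent tissue, and normal breast).
#'
#' @inheritParams differential_expression
#' @return A data.frame stacking the per-comparison tables, with extra
#'   columns `subtype` and `control` (`"adjacent"` or `"normal"`).
#' @export
tumor_control_de <- function(m, meta, alpha = 0.05, fc_min = 1.0) {
  voc <- group_vocabulary()
  out <- list()
  for (st in voc$subtypes) {
    for (ctrl in c("adjacent", "normal")) {
      ctrl_groups <- if (ctrl == "adjacent") voc$adjacent else "normal"
      de <- differential_expression(m, meta, group_a = ctrl_groups,
                                    group_b = st, alpha = alpha,
                                    fc_min = fc_min)
      de$subtype <- st
      de$control <- ctrl
      out[[paste(st, ctrl, sep = "_vs_")]] <- de
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Expression-class assignment
#'
#' Assigns each transcript one of the expression classes observed across
#' tumor-versus-control comparisons: Class I (significantly down in every
#' subtype against both controls), Class II (significantly up in every
#' subtype against both controls), Class III (significantly up in every
#' luminal comparison and in no non-luminal comparison), otherwise
#' unclassified.
#'
#' @param de Stacked comparison table from [tumor_control_de()] (columns
#'   `transcript_id`, `subtype`, `control`, `log2fc`, `significant`).
#' @return A data.frame with `transcript_id` and `class` in
#'   `{"I", "II", "III", "unclassified"}`.
#' @export
assign_expression_class <- function(de) {
  voc <- group_vocabulary()
  ids <- unique(de$transcript_id)
  up <- de$significant & de$log2fc > 0
  down <- de$significant & de$log2fc < 0
  is_luminal <- de$subtype %in% voc$luminal
  all_true <- rep(TRUE, nrow(de))
  tab <- function(flag, subset = all_true) {
    # per-transcript count of comparisons with `flag`, within `subset`
    v <- rowsum(as.numeric(flag & subset), de$transcript_id)
    stats::setNames(v[, 1], rownames(v))[ids]
  }
  n_comp <- tab(all_true)
  n_lum <- tab(all_true, is_luminal)
  cls <- rep("unclassified", length(ids))
  cls[tab(down) == n_comp] <- "I"
  cls[tab(up) == n_comp] <- "II"
  class3 <- tab(up, is_luminal) == n_lum & tab(up, !is_luminal) == 0 &
    n_lum < n_comp
  cls[class3] <- "III"
  data.frame(transcript_id = ids, class = cls, stringsAsFactors = FALSE)
}

#' qPCR relative expression by the 2^-dCT method
#'
#' @param ct_target,ct_ref Cycle-threshold values for the target and the
#'   reference transcript.
#' @return `2^-(ct_target - ct_ref)`.
#' @examples
#' relative_expression_ddct(24, 25)  # one cycle earlier -> 2-fold
#' @export
relative_expression_ddct <- function(ct_target, ct_ref) {
  2^(-(ct_target - ct_ref))
}

#' Descriptive statistics by transcript class
#'
#' Summarises exon counts, exon lengths, mature and genomic-span lengths,
#' and expression per transcript class (SElincRNA, MElincRNA, coding,
#' known noncoding).
#'
#' @param catalog A [transcript_catalog()]; candidate transcripts are
#'   split into SElincRNA/MElincRNA by exon count.
#' @param m Optional FPKM matrix for the expression summary.
#' @return A data.frame with one row per class: `class`, `n`,
#'   `mean_exons`, `median_exon_length`, `median_mature_length`,
#'   `median_span_length`, `median_fpkm` (NA without `m`).
#' @export
descriptive_stats <- function(catalog, m = NULL) {
  tx <- transcripts(catalog)
  cls <- ifelse(tx$biotype == "coding", "coding",
         ifelse(tx$biotype == "known_noncoding", "known_noncoding",
         ifelse(tx$n_exons == 1, "SElincRNA", "MElincRNA")))
  ex <- catalog$exons
  ex_class <- cls[match(ex$transcript_id, tx$transcript_id)]
  classes <- c("SElincRNA", "MElincRNA", "coding", "known_noncoding")
  rows <- lapply(classes, function(k) {
    sel <- cls == k
    if (!any(sel)) {
      return(data.frame(class = k, n = 0L, mean_exons = NA_real_,
                        median_exon_length = NA_real_,
                        median_mature_length = NA_real_,
                        median_span_length = NA_real_,
                        median_fpkm = NA_real_))
    }
    med_fpkm <- NA_real_
    if (!is.null(m)) {
      ids <- intersect(tx$transcript_id[sel], rownames(m))
      if (length(ids) > 0) med_fpkm <- stats::median(m[ids, , drop = FALSE])
    }
    data.frame(
      class = k,
      n = sum(sel),
      mean_exons = mean(tx$n_exons[sel]),
      median_exon_length = stats::median(ex$end[ex_class == k] -
                                           ex$start[ex_class == k]),
      median_mature_length = stats::median(tx$mature_length[sel]),
      median_span_length = stats::median(tx$span_end[sel] -
                                           tx$span_start[sel]),
      median_fpkm = med_fpkm
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
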