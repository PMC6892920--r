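# Promoter CpG methylation <-> expression linkage: windowed CpG selection
# around the TSS and Pearson correlation with the t-transform p-value.

#' Transcription start sites
#'
#' The TSS is the 5' end of the transcript span by strand: the span start
#' for `+` (and unstranded) transcripts, the last spanned base for `-`
#' transcripts. Positions are 0-based.
#'
#' @param catalog A [transcript_catalog()].
#' @return A data.frame with `transcript_id`, `chrom`, `strand`, `tss`.
#' @export
transcript_tss <- function(catalog) {
  tx <- transcripts(catalog)
  data.frame(
    transcript_id = tx$transcript_id,
    chrom = tx$chrom,
    strand = tx$strand,
    tss = ifelse(tx$strand == "-", tx$span_end - 1L, tx$span_start),
    stringsAsFactors = FALSE
  )
}

#' CpG sites in a transcript's promoter window
#'
#' Selects CpG sites whose distance to the strand-aware TSS lies within
#' the inclusive window (default 500-2000 bp). By default both sides of
#' the TSS are searched; `upstream_only = TRUE` restricts to the
#' strand-aware upstream side.
#'
#' @param catalog A [transcript_catalog()].
#' @param sites Data.frame of CpG sites with columns `cpg_id`, `chrom`,
#'   `position` (0-based).
#' @param window Length-2 numeric, inclusive distance band in bp.
#' @param upstream_only Restrict to the upstream side of the TSS.
#' @return A data.frame of (transcript, CpG) pairs with `distance_bp`.
#' @export
promoter_cpg_sites <- function(catalog, sites,
                               window = c(500, 2000),
                               upstream_only = FALSE) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  tss <- transcript_tss(catalog)
  out <- list()
  for (i in seq_len(nrow(tss))) {
    on_chrom <- sites[sites$chrom == tss$chrom[i], , drop = FALSE]
    if (nrow(on_chrom) == 0) next
    delta <- on_chrom$position - tss$tss[i]
    dist <- abs(delta)
    keep <- dist >= window[1] & dist <= window[2]
    if (upstream_only) {
      upstream <- if (tss$strand[i] == "-") delta > 0 else delta < 0
      keep <- keep & upstream
    }
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      transcript_id = tss$transcript_id[i],
      cpg_id = on_chrom$cpg_id[keep],
      distance_bp = dist[keep],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(0), cpg_id = character(0),
                      distance_bp = numeric(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Methylation-expression correlation
#'
#' Pearson correlation between a CpG's beta values and a transcript's
#' FPKM values across matched samples, with the two-sided p-value from
#' the t transform.
#'
#' @param betas Numeric vector of beta values in `[0, 1]`.
#' @param fpkms Numeric vector of expression values, same sample order.
#' @return A list with `r` and `p`.
#' @export
methylation_expression_correlation <- function(betas, fpkms) {
  if (any(betas < 0 | betas > 1)) stop("beta values must lie in [0, 1]")
  pearson_test(betas, fpkms)
}

#' Significant promoter methylation-expression correlations
#'
#' For every (CpG, transcript) pair with the CpG inside the promoter
#' window, computes the Pearson correlation between methylation and
#' expression across all shared samples and reports pairs with
#' `p < p_max`, with the direction of the association.
#'
#' @param catalog A [transcript_catalog()] of the transcripts to test.
#' @param sites CpG site table (`cpg_id`, `chrom`, `position`).
#' @param beta Beta matrix, CpGs x samples (rownames = `cpg_id`).
#' @param m FPKM matrix, transcripts x samples (shared sample columns).
#' @param p_max Significance cutoff on the correlation p-value.
#' @param window,upstream_only Passed to [promoter_cpg_sites()].
#' @return A data.frame with `cpg_id`, `transcript_id`, `distance_bp`,
#'   `r`, `p`, `direction` (`"negative"`/`"positive"`).
#' @export
significant_meth_regulators <- function(catalog, sites, beta, m,
                                        p_max = 0.01,
                                        window = c(500, 2000),
                                        upstream_only = FALSE) {
  pairs <- promoter_cpg_sites(catalog, sites, window = window,
                              upstream_only = upstream_only)
  empty <- data.frame(cpg_id = character(0), transcript_id = character(0),
                      distance_bp = numeric(0), r = numeric(0),
                      p = numeric(0), direction = character(0))
  if (nrow(pairs) == 0) return(empty)
  shared <- intersect(colnames(beta), colnames(m))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  pairs <- pairs[pairs$cpg_id %in% rownames(beta) &
                   pairs$transcript_id %in% rownames(m), , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  b <- beta[pairs$cpg_id, shared, drop = FALSE]
  x <- m[pairs$transcript_id, shared, drop = FALSE]
  r <- rowwise_cor(b, x)
  p <- pearson_p(r, length(shared))
  out <- data.frame(
    cpg_id = pairs$cpg_id,
    transcript_id = pairs$transcript_id,
    distance_bp = pairs$distance_bp,
    r = r,
    p = p,
    direction = ifelse(r < 0, "negative", "positive"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out[!is.na(out$p) & out$p < p_max, , drop = FALSE]
}
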