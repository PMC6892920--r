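# Transcript catalogs, GTF I/O and the intergenic lincRNA filter cascade.
#
# Internal coordinates are 0-based half-open [start, end); GTF I/O converts
# to/from the 1-based inclusive convention at the boundary.

#' Construct a transcript catalog
#'
#' A `transcript_catalog` is an exon-level table describing stranded,
#' exon-structured transcript models. Exons are stored in 0-based half-open
#' coordinates; all exported I/O converts at the boundary.
#'
#' @param exons A data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand` (one of
#'   `"+"`, `"-"`, `"."`), `biotype` (one of `"coding"`,
#'   `"known_noncoding"`, `"candidate"`) and `source`.
#' @return An object of class `transcript_catalog`.
#' @examples
#' ex <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'                  start = c(100, 300), end = c(200, 350), strand = "+",
#'                  biotype = "candidate", source = "example")
#' transcript_catalog(ex)
#' @export
transcript_catalog <- function(exons) {
  required <- c("transcript_id", "gene_id", "chrom", "start", "end",
                "strand", "biotype", "source")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    stop("missing exon columns: ", paste(missing_cols, collapse = ", "))
  }
  exons <- as.data.frame(exons)[required]
  if (nrow(exons) == 0) stop("catalog must contain at least one exon")
  if (any(exons$end <= exons$start)) {
    bad <- which(exons$end <= exons$start)[1]
    stop("exon with end <= start for transcript ", exons$transcript_id[bad])
  }
  if (!all(exons$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  if (!all(exons$biotype %in% c("coding", "known_noncoding", "candidate"))) {
    stop("biotype must be coding, known_noncoding or candidate")
  }
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  # one chromosome and strand per transcript; exons non-overlapping
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(unique(exons$chrom[idx])) != 1 ||
        length(unique(exons$strand[idx])) != 1) {
      stop("transcript ", exons$transcript_id[idx[1]],
           " spans multiple chromosomes or strands")
    }
    if (length(idx) > 1) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1] < e[-length(e)])) {
        stop("overlapping exons in transcript ", exons$transcript_id[idx[1]])
      }
    }
  }
  structure(list(exons = exons), class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  tx <- transcripts(x)
  cat("transcript_catalog:", nrow(tx), "transcripts,",
      nrow(x$exons), "exons\n")
  cat("  biotypes:", paste(sprintf("%s=%d", names(table(tx$biotype)),
                                   table(tx$biotype)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-transcript summary of a catalog
#'
#' @param catalog A [transcript_catalog()].
#' @return A data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `biotype`, `source`, `n_exons`,
#'   `mature_length` (summed exon length), `span_start`, `span_end`
#'   (0-based half-open genomic span).
#' @export
transcripts <- function(catalog) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  ex <- catalog$exons
  first <- !duplicated(ex$transcript_id)
  agg_len <- rowsum(ex$end - ex$start, ex$transcript_id)
  agg_n <- rowsum(rep(1L, nrow(ex)), ex$transcript_id)
  agg_s <- rowsum(ex$start, ex$transcript_id, na.rm = TRUE)  # sorted, min is first
  span_start <- tapply(ex$start, ex$transcript_id, min)
  span_end <- tapply(ex$end, ex$transcript_id, max)
  ids <- ex$transcript_id[first]
  out <- data.frame(
    transcript_id = ids,
    gene_id = ex$gene_id[first],
    chrom = ex$chrom[first],
    strand = ex$strand[first],
    biotype = ex$biotype[first],
    source = ex$source[first],
    n_exons = as.integer(agg_n[ids, 1]),
    mature_length = as.integer(agg_len[ids, 1]),
    span_start = as.integer(span_start[ids]),
    span_end = as.integer(span_end[ids]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Mature (summed-exon) transcript length
#'
#' @param catalog A [transcript_catalog()].
#' @param ids Optional transcript ids; defaults to all transcripts.
#' @return A named integer vector of summed exon lengths in nucleotides.
#' @export
mature_length <- function(catalog, ids = NULL) {
  tx <- transcripts(catalog)
  len <- stats::setNames(tx$mature_length, tx$transcript_id)
  if (is.null(ids)) return(len)
  missing_ids <- setdiff(ids, names(len))
  if (length(missing_ids) > 0) {
    stop("unknown transcript id(s): ", paste(missing_ids, collapse = ", "))
  }
  len[ids]
}

#' Subset a catalog by transcript id
#' @param catalog A [transcript_catalog()].
#' @param ids Transcript ids to keep.
#' @export
subset_catalog <- function(catalog, ids) {
  keep <- catalog$exons$transcript_id %in% ids
  if (!any(keep)) stop("no matching transcripts")
  transcript_catalog(catalog$exons[keep, , drop = FALSE])
}

#' Read a transcript catalog from a GTF file
#'
#' Exon features are grouped by their `transcript_id` attribute; 1-based
#' inclusive GTF coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path Path to a GTF file with `exon` features.
#' @param biotype Biotype assigned to transcripts whose GTF attributes carry
#'   no `biotype` tag (default `"candidate"`).
#' @return A [transcript_catalog()].
#' @export
parse_gtf <- function(path, biotype = "candidate") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid)) {
    bad <- if (is.null(tid)) 1L else which(is.na(tid))[1]
    stop("exon record ", bad, " lacks a transcript_id attribute")
  }
  bt <- gr$biotype %||% rep(NA_character_, length(gr))
  src <- as.character(gr$source %||% rep("gtf", length(gr)))
  exons <- data.frame(
    transcript_id = tid,
    gene_id = gr$gene_id %||% tid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = ifelse(is.na(bt), biotype, bt),
    source = src,
    stringsAsFactors = FALSE
  )
  exons$strand[exons$strand == "*"] <- "."
  transcript_catalog(exons)
}

#' Write a transcript catalog to a GTF file
#'
#' @param catalog A [transcript_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(catalog, path) {
  ex <- catalog$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ifelse(ex$strand == ".", "*", ex$strand)
  )
  gr$source <- ex$source
  gr$type <- "exon"
  gr$transcript_id <- ex$transcript_id
  gr$gene_id <- ex$gene_id
  gr$biotype <- ex$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Genomic spans of transcripts as a GRanges
#'
#' @param catalog A [transcript_catalog()].
#' @return A `GRanges` (1-based inclusive) with one range per transcript,
#'   named by transcript id.
#' @export
transcript_spans <- function(catalog) {
  tx <- transcripts(catalog)
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$span_start + 1L, end = tx$span_end),
    strand = ifelse(tx$strand == ".", "*", tx$strand)
  )
  names(gr) <- tx$transcript_id
  gr$biotype <- tx$biotype
  gr$gene_id <- tx$gene_id
  gr
}

#' Genomic spans of genes (union of their transcripts' spans)
#'
#' @param catalog A [transcript_catalog()].
#' @param biotype Optional biotype filter (e.g. `"coding"`).
#' @return A `GRanges` named by gene id.
#' @export
gene_spans <- function(catalog, biotype = NULL) {
  tx <- transcripts(catalog)
  if (!is.null(biotype)) tx <- tx[tx$biotype %in% biotype, , drop = FALSE]
  if (nrow(tx) == 0) stop("no transcripts of the requested biotype")
  s <- tapply(tx$span_start, tx$gene_id, min)
  e <- tapply(tx$span_end, tx$gene_id, max)
  chrom <- tapply(tx$chrom, tx$gene_id, function(x) x[1])
  gids <- names(s)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom[gids]),
    ranges = IRanges::IRanges(start = as.integer(s[gids]) + 1L,
                              end = as.integer(e[gids]))
  )
  names(gr) <- gids
  gr
}

#' Distance to the nearest known gene
#'
#' Minimum genomic gap (in bp) between each candidate transcript's span and
#' any known gene on the same chromosome, strand-agnostic. Overlapping
#' features have distance 0; candidates on a chromosome with no known gene
#' get `Inf`.
#'
#' @param candidates,known [transcript_catalog()] objects.
#' @return A named numeric vector, one entry per candidate transcript.
#' @export
distance_to_nearest_known <- function(candidates, known) {
  q <- transcript_spans(candidates)
  s <- gene_spans(known)
  # a query chromosome absent from the known set is legitimate (-> Inf)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(q, s, ignore.strand = TRUE))
  d <- rep(Inf, length(q))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  stats::setNames(d, names(q))
}

#' Nearest coding gene assignment
#'
#' Assigns each candidate transcript the coding gene with the minimal
#' genomic gap within `max_dist`. Ties are broken by smaller gene start,
#' then lexicographic gene id.
#'
#' @param candidates A [transcript_catalog()] of transcripts to assign.
#' @param known A [transcript_catalog()] containing coding genes.
#' @param max_dist Maximum gap in bp (default 1 Mb).
#' @return A data.frame with `transcript_id`, `gene_id` (NA when no gene is
#'   within `max_dist`) and `gap_bp`.
#' @export
nearest_gene_assignment <- function(candidates, known, max_dist = 1e6) {
  q <- transcript_spans(candidates)
  genes <- gene_spans(known, biotype = "coding")
  out <- data.frame(transcript_id = names(q),
                    gene_id = NA_character_,
                    gap_bp = NA_real_,
                    stringsAsFactors = FALSE)
  # explicit all-pairs distances keep the tie-break contract exact
  for (i in seq_along(q)) {
    gap <- suppressWarnings(
      GenomicRanges::distance(q[i], genes, ignore.strand = TRUE))
    j <- which(!is.na(gap) & gap <= max_dist)
    if (length(j) == 0) next
    best <- j[order(gap[j], GenomicRanges::start(genes)[j],
                    names(genes)[j])][1]
    out$gene_id[i] <- names(genes)[best]
    out$gap_bp[i] <- gap[best]
  }
  out
}

#' Novel lincRNA filter cascade
#'
#' Applies the three discovery filters to candidate transcripts: genomic
#' distance to any known gene >= `min_dist`, mature length >= `min_len`,
#' and a two-scorer coding-potential consensus calling the sequence
#' noncoding. Accepted transcripts are labelled `SElincRNA` (single exon)
#' or `MElincRNA` (multi exon).
#'
#' @param candidates A [transcript_catalog()] of candidate transcripts.
#' @param known A [transcript_catalog()] of known genes.
#' @param sequences Named character vector or `DNAStringSet` of candidate
#'   transcript sequences; every candidate must be present.
#' @param scorers A fitted [train_scorers()] object.
#' @param min_dist Minimum genomic gap to any known gene in bp.
#' @param min_len Minimum mature length in nt.
#' @return A list with `accepted` (data.frame of accepted transcripts with
#'   an `exon_class` column) and `audit` (per-candidate trail with columns
#'   `transcript_id`, `gap_bp`, `mature_len`, `p_A`, `p_B`, `verdict`,
#'   `reason`).
#' @export
filter_novel_lincrnas <- function(candidates, known, sequences, scorers,
                                  min_dist = 2000, min_len = 200) {
  tx <- transcripts(candidates)
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  missing_seq <- setdiff(tx$transcript_id, names(seqs))
  if (length(missing_seq) > 0) {
    stop("candidate(s) without sequence: ",
         paste(missing_seq, collapse = ", "))
  }
  gap <- distance_to_nearest_known(candidates, known)[tx$transcript_id]
  cp <- score_coding_potential(seqs[tx$transcript_id], scorers)
  audit <- data.frame(
    transcript_id = tx$transcript_id,
    gap_bp = unname(gap),
    mature_len = tx$mature_length,
    p_A = cp$p_A,
    p_B = cp$p_B,
    verdict = NA_character_,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
  fail_dist <- audit$gap_bp < min_dist
  fail_len <- audit$mature_len < min_len
  fail_code <- !cp$consensus_noncoding
  audit$reason <- ifelse(fail_dist, "distance",
                  ifelse(fail_len, "length",
                  ifelse(fail_code, "coding", "accepted")))
  audit$verdict <- ifelse(audit$reason == "accepted", "accepted", "rejected")
  acc <- tx[audit$verdict == "accepted", , drop = FALSE]
  acc$exon_class <- ifelse(acc$n_exons == 1, "SElincRNA", "MElincRNA")
  rownames(acc) <- NULL
  list(accepted = acc, audit = audit)
}
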