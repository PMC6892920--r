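# Coding-potential scoring: Fickett TESTCODE statistic, hexamer usage-bias
# log-likelihood ratio, longest-ORF features, and two logistic combiners
# whose conjunction ("called noncoding by both") is the discovery rule.

# Fickett TESTCODE lookup tables (position-asymmetry and composition
# parameters with their published weights). Thresholds are scanned in
# descending order; a value >= threshold maps to the matching probability.
.fickett <- list(
  position_breaks = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
  content_breaks = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0),
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
  ),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
  ),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
)

#' @noRd
seq_chars <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  if (!all(s %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  s
}

#' Fickett TESTCODE coding-potential score
#'
#' Classic positional-periodicity statistic: for each base, the asymmetry
#' of its counts across the three codon positions (max/(min+1)) and its
#' overall fraction are mapped through published lookup tables and
#' combined with the published weights. Higher values indicate
#' protein-coding-like periodicity. `N` characters are ignored in counts.
#'
#' @param seq A nucleotide string (length >= 6, alphabet ACGTN).
#' @return A single numeric score.
#' @examples
#' fickett_score(paste(rep("ATGGCC", 30), collapse = ""))
#' @export
fickett_score <- function(seq) {
  s <- seq_chars(seq)
  if (length(s) < 6) stop("sequence shorter than 6 nt")
  keep <- s != "N"
  pos <- (seq_along(s) - 1L) %% 3L
  s <- s[keep]; pos <- pos[keep]
  if (length(s) == 0) stop("sequence contains only N")
  total <- length(s)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(pos[s == b] + 1L, nbins = 3L)
    ratio <- max(cnt) / (min(cnt) + 1)
    frac <- sum(cnt) / total
    pi_ <- which(ratio >= .fickett$position_breaks)[1]
    ci_ <- which(frac >= .fickett$content_breaks)[1]
    score <- score +
      .fickett$position_prob[[b]][pi_] * .fickett$position_weight[[b]] +
      .fickett$content_prob[[b]][ci_] * .fickett$content_weight[[b]]
  }
  score
}

#' Longest open reading frame on the sense strand
#'
#' Scans the three forward frames for ATG..stop (TAA/TAG/TGA) open reading
#' frames and returns the longest, measured in nucleotides including the
#' stop codon.
#'
#' @param seq A nucleotide string.
#' @return A list with `orf_len` (nt, 0 when no ORF), `orf_cov`
#'   (`orf_len` / sequence length), `frame` (0, 1 or 2; NA when no ORF)
#'   and `start` (0-based nucleotide offset of the ATG; NA when no ORF).
#' @examples
#' longest_orf("ATGAAATAG")
#' @export
longest_orf <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  best <- list(orf_len = 0L, orf_cov = 0, frame = NA_integer_,
               start = NA_integer_)
  if (n < 6) return(best)
  for (f in 0:2) {
    starts_nt <- seq.int(f + 1L, n - 2L, by = 3L)
    if (length(starts_nt) == 0) next
    codons <- substring(s, starts_nt, starts_nt + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_start <- codons == "ATG"
    prev_stop <- 0L
    pending_start <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(pending_start) && is_start[i]) pending_start <- i
      if (is_stop[i]) {
        if (!is.na(pending_start)) {
          len <- (i - pending_start + 1L) * 3L
          if (len > best$orf_len) {
            best$orf_len <- len
            best$frame <- f
            best$start <- starts_nt[pending_start] - 1L
          }
        }
        pending_start <- NA_integer_
        prev_stop <- i
      }
    }
  }
  best$orf_cov <- best$orf_len / n
  best
}

#' Train hexamer frequency tables
#'
#' Counts in-frame hexamers (step 3, within the longest ORF when one
#' exists, otherwise frame 0 of the full sequence) separately for coding
#' and noncoding training sequences, adds a pseudocount, and normalises
#' each table to sum to 1.
#'
#' @param coding,noncoding Character vectors (or `DNAStringSet`s) of
#'   training sequences.
#' @param pseudocount Added to every hexamer count before normalising.
#' @return An object of class `hexamer_table` with elements `coding` and
#'   `noncoding` (each a named numeric vector over all 4096 hexamers).
#' @export
train_hexamer_tables <- function(coding, noncoding, pseudocount = 1) {
  all_hex <- hexamer_universe()
  count_class <- function(seqs) {
    counts <- stats::setNames(rep(0, length(all_hex)), all_hex)
    for (s in as.character(seqs)) {
      h <- inframe_hexamers(s)
      if (length(h) == 0) next
      tb <- table(h)
      counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    }
    counts <- counts + pseudocount
    counts / sum(counts)
  }
  structure(list(coding = count_class(coding),
                 noncoding = count_class(noncoding)),
            class = "hexamer_table")
}

#' @noRd
hexamer_universe <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  # expand.grid varies the first column fastest; paste in reverse for
  # lexicographic order (cosmetic only)
  sort(apply(g, 1, paste, collapse = ""))
}

# In-frame hexamers of the longest ORF (fallback: frame 0 of the whole
# sequence). Hexamers containing N are dropped.
#' @noRd
inframe_hexamers <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 6) return(character(0))
  orf <- longest_orf(s)
  if (orf$orf_len >= 6) {
    from <- orf$start + 1L
    to <- orf$start + orf$orf_len
  } else {
    from <- 1L
    to <- n
  }
  pos <- seq.int(from, to - 5L, by = 3L)
  if (length(pos) == 0) return(character(0))
  h <- substring(s, pos, pos + 5L)
  h[!grepl("N", h, fixed = TRUE)]
}

#' Hexamer usage-bias score
#'
#' Mean log-likelihood ratio (nats) of in-frame hexamers under the coding
#' versus noncoding frequency tables:
#' \eqn{s = (1/n)\sum_i \log(F_{cod}(h_i)/F_{nc}(h_i))}. Positive values
#' indicate coding-like hexamer composition.
#'
#' @param seq A nucleotide string (length >= 6).
#' @param tables A [train_hexamer_tables()] object.
#' @return A single numeric score (0 for sequences with no scoreable
#'   hexamer).
#' @export
hexamer_score <- function(seq, tables) {
  stopifnot(inherits(tables, "hexamer_table"))
  if (nchar(as.character(seq)) < 6) stop("sequence shorter than 6 nt")
  h <- inframe_hexamers(seq)
  if (length(h) == 0) return(0)
  mean(log(tables$coding[h] / tables$noncoding[h]))
}

#' Sequence feature table for coding-potential scoring
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param tables A [train_hexamer_tables()] object.
#' @return A data.frame with `transcript_id`, `fickett`, `hexamer`,
#'   `orf_len`, `orf_cov`.
#' @export
codepot_features <- function(seqs, tables) {
  seqs <- as.character(seqs)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  feats <- lapply(seqs, function(s) {
    orf <- longest_orf(s)
    data.frame(fickett = fickett_score(s),
               hexamer = hexamer_score(s, tables),
               orf_len = orf$orf_len,
               orf_cov = orf$orf_cov)
  })
  out <- do.call(rbind, feats)
  out <- cbind(data.frame(transcript_id = ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Fit the two logistic coding-potential scorers
#'
#' Scorer A combines the Fickett statistic with ORF coverage; scorer B
#' combines the hexamer bias score with ORF coverage. Both are logistic
#' regressions fitted by maximum likelihood on labelled training
#' sequences. The decision rule downstream is the conjunction: a sequence
#' is called noncoding only when both scorers give a coding probability
#' below `tau`.
#'
#' @param seqs Character vector or `DNAStringSet` of training sequences.
#' @param labels Factor or character vector with values `"coding"` /
#'   `"noncoding"`, one per sequence.
#' @param tables Optional pre-trained [train_hexamer_tables()]; by default
#'   tables are trained on the same labelled sequences.
#' @param tau Probability threshold for the noncoding call (default 0.5).
#' @param pseudocount Passed to [train_hexamer_tables()].
#' @return An object of class `codepot_scorers`.
#' @export
train_scorers <- function(seqs, labels, tables = NULL, tau = 0.5,
                          pseudocount = 1) {
  labels <- as.character(labels)
  if (length(labels) != length(seqs)) stop("one label per sequence required")
  if (!all(labels %in% c("coding", "noncoding"))) {
    stop("labels must be 'coding' or 'noncoding'")
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in the training set")
  }
  if (is.null(tables)) {
    tables <- train_hexamer_tables(as.character(seqs)[labels == "coding"],
                                   as.character(seqs)[labels == "noncoding"],
                                   pseudocount = pseudocount)
  }
  feats <- codepot_features(seqs, tables)
  y <- as.integer(labels == "coding")
  # perfect separation on clean training data is expected; the saturated
  # probabilities are exactly what the conjunction rule consumes
  fit_a <- suppressWarnings(stats::glm(y ~ fickett + orf_cov,
                                       data = feats, family = stats::binomial()))
  fit_b <- suppressWarnings(stats::glm(y ~ hexamer + orf_cov,
                                       data = feats, family = stats::binomial()))
  structure(list(coef_a = stats::coef(fit_a),
                 coef_b = stats::coef(fit_b),
                 tables = tables,
                 tau = tau),
            class = "codepot_scorers")
}

#' @export
print.codepot_scorers <- function(x, ...) {
  cat("codepot_scorers (tau =", x$tau, ")\n")
  cat("  scorer A (Fickett + ORF):",
      paste(sprintf("%s=%.3g", names(x$coef_a), x$coef_a), collapse = ", "), "\n")
  cat("  scorer B (hexamer + ORF):",
      paste(sprintf("%s=%.3g", names(x$coef_b), x$coef_b), collapse = ", "), "\n")
  invisible(x)
}

#' @noRd
logistic <- function(x) 1 / (1 + exp(-x))

#' Score sequences for coding potential
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param scorers A [train_scorers()] object.
#' @return A data.frame with `transcript_id`, `fickett`, `hexamer`,
#'   `orf_len`, `orf_cov`, `p_A`, `p_B` and `consensus_noncoding`
#'   (TRUE iff both probabilities are strictly below `tau`).
#' @export
score_coding_potential <- function(seqs, scorers) {
  stopifnot(inherits(scorers, "codepot_scorers"))
  feats <- codepot_features(seqs, scorers$tables)
  a <- scorers$coef_a
  b <- scorers$coef_b
  feats$p_A <- logistic(a[1] + a["fickett"] * feats$fickett +
                          a["orf_cov"] * feats$orf_cov)
  feats$p_B <- logistic(b[1] + b["hexamer"] * feats$hexamer +
                          b["orf_cov"] * feats$orf_cov)
  feats$consensus_noncoding <- consensus_noncoding(feats$p_A, feats$p_B,
                                                   scorers$tau)
  feats
}

#' Two-scorer noncoding consensus
#'
#' A transcript is called noncoding only when both scorers agree, i.e.
#' both coding probabilities are strictly below `tau`.
#'
#' @param p_A,p_B Coding probabilities from the two scorers.
#' @param tau Threshold (default 0.5).
#' @return Logical vector.
#' @export
consensus_noncoding <- function(p_A, p_B, tau = 0.5) {
  (p_A < tau) & (p_B < tau)
}
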