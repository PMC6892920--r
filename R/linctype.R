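# Staged marker-panel construction: equal-frequency discretization,
# symmetrical uncertainty, CFS subset merit, best-first subset search,
# and the four-stage Linctype panel assembly.

#' Equal-frequency discretization
#'
#' Bins a numeric vector into (up to) `bins` equal-frequency bins using
#' type-1 quantile break points; boundary values (ties) go to the lower
#' bin. Constant vectors collapse to a single bin. Labels are integers
#' 1..bins and are equivariant under sample permutation.
#'
#' @param values Numeric vector.
#' @param bins Number of bins (default 3).
#' @return Integer vector of bin labels.
#' @examples
#' discretize(1:9)  # three bins of three
#' @export
discretize <- function(values, bins = 3) {
  if (anyNA(values)) stop("missing values are not allowed")
  breaks <- unique(stats::quantile(values, probs = seq(0, 1,
                                                       length.out = bins + 1),
                                   type = 1, names = FALSE))
  if (length(breaks) < 2) return(rep(1L, length(values)))
  as.integer(cut(values, breaks = breaks, include.lowest = TRUE,
                 right = TRUE))
}

#' Symmetrical uncertainty between two discrete variables
#'
#' Normalised mutual information \eqn{SU = 2 I(X;Y) / (H(X) + H(Y))}
#' (natural log), in `[0, 1]`: 0 for an exactly product-form contingency
#' table, 1 when each variable determines the other. Two constant
#' variables carry no information and score 0.
#'
#' @param x,y Discrete vectors (factors, integers or characters) of equal
#'   length.
#' @return A single numeric value in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  tab <- table(x, y)
  n <- sum(tab)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hx <- ent(rowSums(tab) / n)
  hy <- ent(colSums(tab) / n)
  hxy <- ent(as.vector(tab) / n)
  if (hx + hy == 0) return(0)
  mi <- max(0, hx + hy - hxy)
  min(1, 2 * mi / (hx + hy))
}

# Cached SU environment over a discretized feature matrix: su_cf(i) and
# su_ff(i, j) computed lazily.
#' @noRd
su_cache <- function(bins_mat, class_bins) {
  p <- ncol(bins_mat)
  env <- new.env(parent = emptyenv())
  env$cf <- rep(NA_real_, p)
  env$ff <- matrix(NA_real_, p, p)
  env$cf_get <- function(i) {
    if (is.na(env$cf[i])) {
      env$cf[i] <- symmetrical_uncertainty(bins_mat[, i], class_bins)
    }
    env$cf[i]
  }
  env$ff_get <- function(i, j) {
    if (is.na(env$ff[i, j])) {
      v <- symmetrical_uncertainty(bins_mat[, i], bins_mat[, j])
      env$ff[i, j] <- v
      env$ff[j, i] <- v
    }
    env$ff[i, j]
  }
  env
}

#' @noRd
merit_from_su <- function(cache, subset_idx) {
  k <- length(subset_idx)
  if (k == 0) return(0)
  r_cf <- mean(vapply(subset_idx, cache$cf_get, numeric(1)))
  if (k == 1) return(r_cf)
  pairs <- utils::combn(subset_idx, 2)
  r_ff <- mean(vapply(seq_len(ncol(pairs)),
                      function(m) cache$ff_get(pairs[1, m], pairs[2, m]),
                      numeric(1)))
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

#' CFS merit of a feature subset
#'
#' Correlation-based feature selection merit
#' \eqn{Merit(S) = k \bar r_{cf} / \sqrt{k + k (k-1) \bar r_{ff}}},
#' where the correlations are mean symmetrical uncertainties of features
#' with the class (\eqn{\bar r_{cf}}) and among features
#' (\eqn{\bar r_{ff}}). For a single feature the merit equals its SU with
#' the class. Values are discretized with [discretize()] before scoring.
#'
#' @param x Numeric matrix, samples x features (with column names), or a
#'   single numeric vector.
#' @param y Class labels, one per sample.
#' @param bins Bins for [discretize()].
#' @return A single numeric merit (>= 0).
#' @export
cfs_merit <- function(x, y, bins = 3) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (ncol(x) == 0) stop("the feature subset must be non-empty")
  bins_mat <- apply(x, 2, discretize, bins = bins)
  if (is.vector(bins_mat)) bins_mat <- matrix(bins_mat, ncol = ncol(x))
  cache <- su_cache(bins_mat, as.character(y))
  merit_from_su(cache, seq_len(ncol(x)))
}

#' Best-first search over feature subsets
#'
#' Best-first forward search on the subset lattice under the CFS merit:
#' starts from the empty set, expands the open subset with the highest
#' merit by single-feature additions, and stops after `max_stale`
#' consecutive expansions that fail to improve the global best.
#' Deterministic: ties are broken by feature name.
#'
#' @param x Numeric matrix, samples x features, with column names.
#' @param y Class labels, one per sample.
#' @param bins Bins for [discretize()].
#' @param max_stale Stop after this many non-improving expansions.
#' @return A list with `features` (selected column names, sorted) and
#'   `merit`.
#' @export
best_first_search <- function(x, y, bins = 3, max_stale = 5) {
  if (is.null(ncol(x)) || ncol(x) == 0) stop("empty feature list")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  feat_order <- order(colnames(x))
  x <- x[, feat_order, drop = FALSE]  # lexicographic feature order
  p <- ncol(x)
  bins_mat <- apply(x, 2, discretize, bins = bins)
  if (is.vector(bins_mat)) bins_mat <- matrix(bins_mat, ncol = p)
  cache <- su_cache(bins_mat, as.character(y))

  cf <- vapply(seq_len(p), cache$cf_get, numeric(1))
  ff_row <- function(f, idx) {
    vapply(idx, function(s) cache$ff_get(s, f), numeric(1))
  }
  merit_of <- function(k, sum_cf, sum_ff) {
    if (k == 0) return(0)
    if (k == 1) return(sum_cf)
    r_cf <- sum_cf / k
    r_ff <- sum_ff / (k * (k - 1) / 2)
    k * r_cf / sqrt(k + k * (k - 1) * r_ff)
  }

  key_of <- function(idx) paste0("k", paste(idx, collapse = ","))
  open <- list(list(idx = integer(0), sum_cf = 0, sum_ff = 0))
  open_keys <- "k"
  open_merit <- 0
  seen <- new.env(parent = emptyenv()); assign("k", TRUE, envir = seen)
  best_merit <- 0; best_set <- integer(0)
  stale <- 0
  while (length(open) > 0 && stale < max_stale) {
    pick <- order(-open_merit, open_keys)[1]
    state <- open[[pick]]
    open <- open[-pick]
    open_keys <- open_keys[-pick]
    open_merit <- open_merit[-pick]
    improved <- FALSE
    for (f in setdiff(seq_len(p), state$idx)) {
      child_idx <- sort(c(state$idx, f))
      k <- key_of(child_idx)
      if (exists(k, envir = seen, inherits = FALSE)) next
      assign(k, TRUE, envir = seen)
      child <- list(idx = child_idx,
                    sum_cf = state$sum_cf + cf[f],
                    sum_ff = state$sum_ff + sum(ff_row(f, state$idx)))
      mer <- merit_of(length(child_idx), child$sum_cf, child$sum_ff)
      open <- c(open, list(child))
      open_keys <- c(open_keys, k)
      open_merit <- c(open_merit, mer)
      if (mer > best_merit + 1e-12) {
        best_merit <- mer
        best_set <- child_idx
        improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
  }
  list(features = colnames(x)[best_set], merit = best_merit)
}

#' Staged Linctype marker-panel selection
#'
#' Assembles the subtype-classification panel in four stages:
#' \enumerate{
#'   \item best-first CFS on the two-class problem (cancer vs control);
#'   \item best-first CFS restricted to the stage-1 features on the
#'     six-class problem (five subtypes + control);
#'   \item per subtype, best-first CFS on the one-vs-rest problem; every
#'     panel member found by a subtype's search is tagged with that
#'     subtype, and features not already selected are added;
#'   \item the `n_low` transcripts with the lowest and `n_high` with the
#'     highest mean expression across cancer samples.
#' }
#' The panel is the union, with per-member provenance tags.
#'
#' @param m FPKM matrix, transcripts x samples (post low-expression
#'   filter).
#' @param meta Sample metadata (`sample_id`, `group`).
#' @param n_low,n_high Stage-4 extreme counts (defaults 6 and 3).
#' @param bins,max_stale Passed to the CFS search.
#' @return An object of class `linctype_panel`: a list with `panel`
#'   (data.frame `transcript_id`, `provenance` comma-joined tags),
#'   `stages` (per-stage feature vectors) and `merits`.
#' @export
select_linctype <- function(m, meta, n_low = 6, n_high = 3,
                            bins = 3, max_stale = 5) {
  m <- check_matrix(m)
  voc <- group_vocabulary()
  if (!all(meta$group %in% voc$all)) {
    stop("metadata groups outside the study vocabulary")
  }
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata must cover all samples")
  is_cancer <- meta$group %in% voc$subtypes
  if (!any(is_cancer) || !all(voc$subtypes %in% meta$group)) {
    stop("all five tumor subtypes and control samples are required")
  }
  x <- t(m)  # samples x transcripts; equal-frequency bins are monotone-
             # invariant, so no log transform is needed

  two_class <- ifelse(is_cancer, "cancer", "control")
  s1 <- best_first_search(x, two_class, bins = bins, max_stale = max_stale)

  six_class <- ifelse(is_cancer, meta$group, "control")
  x1 <- x[, s1$features, drop = FALSE]
  s2 <- if (length(s1$features) > 0) {
    best_first_search(x1, six_class, bins = bins, max_stale = max_stale)
  } else list(features = character(0), merit = 0)

  tags <- list()
  add_tag <- function(tags, ids, tag) {
    for (id in ids) tags[[id]] <- c(tags[[id]], tag)
    tags
  }
  tags <- add_tag(tags, s1$features, "two_class")
  tags <- add_tag(tags, s2$features, "six_class")

  s3 <- list(); s3_merit <- numeric(0)
  for (st in voc$subtypes) {
    ovr <- ifelse(meta$group == st, st, "rest")
    res <- best_first_search(x, ovr, bins = bins, max_stale = max_stale)
    s3[[st]] <- res$features
    s3_merit[st] <- res$merit
    tags <- add_tag(tags, res$features, paste0("subtype_specific:", st))
  }

  cancer_mean <- rowMeans(m[, is_cancer, drop = FALSE])
  ord <- order(cancer_mean, rownames(m))
  low_ids <- if (n_low > 0) rownames(m)[ord][seq_len(min(n_low, nrow(m)))] else character(0)
  ord_hi <- order(-cancer_mean, rownames(m))
  high_ids <- if (n_high > 0) rownames(m)[ord_hi][seq_len(min(n_high, nrow(m)))] else character(0)
  tags <- add_tag(tags, low_ids, "extreme_low")
  tags <- add_tag(tags, high_ids, "extreme_high")

  panel <- data.frame(
    transcript_id = names(tags),
    provenance = vapply(tags, function(t) paste(unique(t), collapse = ","),
                        character(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  panel <- panel[order(panel$transcript_id), , drop = FALSE]
  rownames(panel) <- NULL
  structure(list(
    panel = panel,
    stages = list(two_class = s1$features, six_class = s2$features,
                  subtype_specific = s3,
                  extreme_low = low_ids, extreme_high = high_ids),
    merits = c(two_class = s1$merit, six_class = s2$merit, s3_merit)
  ), class = "linctype_panel")
}

#' @export
print.linctype_panel <- function(x, ...) {
  sz <- vapply(x$stages, function(s) length(unlist(s)), integer(1))
  cat("linctype_panel:", nrow(x$panel), "markers\n")
  cat("  stage sizes:", paste(sprintf("%s=%d", names(sz), sz),
                              collapse = ", "), "\n")
  invisible(x)
}
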