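# Panel evaluation: row-centering, 2-way hierarchical clustering, PCA
# projection, k-means with k-means++ seeding, Kaplan-Meier curves,
# log-rank tests and median dichotomization.

#' Row-center an expression matrix
#'
#' Subtracts each transcript row's mean so every row has mean 0
#' (idempotent).
#'
#' @param m Numeric matrix, transcripts x samples.
#' @return The centered matrix.
#' @export
row_center <- function(m) {
  m <- as.matrix(m)
  m - rowMeans(m)
}

#' Two-way hierarchical clustering of an expression matrix
#'
#' Agglomerative clustering of samples (and transcripts) on the
#' row-centered matrix with Euclidean distance. The sample tree is cut at
#' `k` clusters.
#'
#' @param m Numeric matrix, transcripts x samples.
#' @param k Number of sample clusters.
#' @param linkage Agglomeration method (default `"average"`).
#' @return A list with `assignment` (named integer vector over samples),
#'   `sample_tree` and `transcript_tree` (`hclust` objects), `method`,
#'   `k`.
#' @export
hierarchical_cluster <- function(m, k, linkage = "average") {
  cm <- row_center(m)
  sample_tree <- stats::hclust(stats::dist(t(cm)), method = linkage)
  transcript_tree <- if (nrow(cm) > 1) {
    stats::hclust(stats::dist(cm), method = linkage)
  } else NULL
  assignment <- stats::cutree(sample_tree, k = k)
  list(assignment = assignment, sample_tree = sample_tree,
       transcript_tree = transcript_tree, method = "hierarchical", k = k)
}

#' Project samples onto the first principal components
#'
#' PCA of the feature-centered matrix; samples (columns of `m`) are
#' projected onto the top `n_components` axes. Component signs are fixed
#' by making the largest-magnitude loading of each component positive.
#'
#' @param m Numeric matrix, transcripts x samples.
#' @param n_components Number of components (default 2).
#' @return A list with `scores` (samples x components), `var_explained`
#'   (proportion per component) and `rotation` (feature loadings).
#' @export
pca_project <- function(m, n_components = 2) {
  m <- as.matrix(m)
  n_components <- min(n_components, ncol(m) - 1, nrow(m))
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sco <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
       rotation = rot)
}

# k-means++ center selection on a samples x features matrix.
#' @noRd
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    dn <- rowSums((X - matrix(X[centers[j + 1], ], n, ncol(X),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  X[centers, , drop = FALSE]
}

#' k-means clustering of samples
#'
#' Lloyd k-means on the row-centered matrix's samples, with k-means++
#' seeding and the best of `restarts` runs by total within-cluster sum of
#' squares. Deterministic given `seed`.
#'
#' @param m Numeric matrix, transcripts x samples.
#' @param k Number of clusters (default 5).
#' @param restarts Number of seeded restarts (default 50).
#' @param seed RNG seed.
#' @return A list with `assignment` (named integer vector over samples),
#'   `centers`, `tot_withinss`, `method`, `k`.
#' @export
kmeans_cluster <- function(m, k = 5, restarts = 50, seed = 1) {
  X <- t(row_center(m))
  if (k > nrow(X)) stop("k exceeds the number of samples")
  fit <- with_rng(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(X, k)
      # duplicate seeded centers can arise with duplicated samples; jitter
      # is not needed because Lloyd handles coincident centers by leaving
      # one cluster empty only if centers are identical -- deduplicate:
      if (nrow(unique(centers)) < k) next
      km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                           iter.max = 100,
                                           algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) {
      # all restarts degenerate (fewer distinct points than k)
      stats::kmeans(X, centers = unique(X)[seq_len(min(k, nrow(unique(X)))), ,
                                           drop = FALSE],
                    iter.max = 100, algorithm = "Lloyd")
    } else best
  })
  list(assignment = stats::setNames(fit$cluster, rownames(X)),
       centers = fit$centers,
       tot_withinss = fit$tot.withinss,
       method = "kmeans", k = k)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)};
#' censored times reduce the risk set only.
#'
#' @param times Nonnegative event/censoring times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A data.frame with `time`, `n_risk`, `n_event`, `surv`
#'   (one row per distinct observed time).
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("times must be nonnegative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Log-rank test across survival groups
#'
#' Observed-minus-expected chi-square over pooled event times with
#' `g - 1` degrees of freedom.
#'
#' @param times Nonnegative times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels (>= 2 groups).
#' @return A list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE))
}

#' Dichotomize an expression vector at its median
#'
#' Labels a value `"high"` when it is at or above the study-specific
#' median, `"low"` below it.
#'
#' @param values Numeric vector.
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
dichotomize_by_median <- function(values) {
  ifelse(values >= stats::median(values), "high", "low")
}
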