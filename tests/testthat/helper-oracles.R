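# Independent brute-force / closed-form oracles used by the tests. These
# deliberately avoid the package's code paths.

# Minimum gap between a query span and a set of spans, scanning all pairs.
oracle_min_gap <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  best <- Inf
  for (i in seq_along(s_chrom)) {
    if (s_chrom[i] != q_chrom) next
    if (q_start < s_end[i] && s_start[i] < q_end) {
      gap <- 0
    } else if (q_start >= s_end[i]) {
      gap <- q_start - s_end[i]
    } else {
      gap <- s_start[i] - q_end
    }
    best <- min(best, gap)
  }
  best
}

# Longest ORF by brute force over all (start, frame) combinations.
oracle_longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0
  for (i in seq_len(max(n - 5, 0))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      codon <- substr(s, j, j + 2)
      if (codon %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2 - i + 1)
        break
      }
      j <- j + 3
    }
  }
  best
}

# Direct-summation hexamer log-likelihood ratio over explicit positions.
oracle_hexamer <- function(seq, tables, from, to) {
  s <- toupper(seq)
  pos <- seq(from, to - 5, by = 3)
  vals <- vapply(pos, function(i) {
    h <- substr(s, i, i + 5)
    log(tables$coding[[h]] / tables$noncoding[[h]])
  }, numeric(1))
  mean(vals)
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Upper-tail hypergeometric by explicit enumeration of the overlap pmf.
oracle_hyper <- function(k, set_size, universe, draws) {
  ks <- k:min(set_size, draws)
  sum(choose(set_size, ks) * choose(universe - set_size, draws - ks)) /
    choose(universe, draws)
}

# Product-limit estimator by hand.
oracle_km <- function(times, events) {
  tt <- sort(unique(times))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    n_i <- sum(times >= tt[i])
    d_i <- sum(times == tt[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# Two-group log-rank chi-square from the O/E/V sums at pooled event times.
oracle_logrank2 <- function(times, events, groups) {
  g <- sort(unique(groups))
  stopifnot(length(g) == 2)
  evt <- sort(unique(times[events == 1]))
  o1 <- 0; e1 <- 0; v1 <- 0
  for (t in evt) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & groups == g[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v1
}

# Naive O(n^3) average-linkage agglomeration, returning merge heights.
oracle_average_linkage_heights <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  D <- as.matrix(stats::dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  heights
}

# CFS merit evaluated directly from symmetrical uncertainties.
oracle_cfs_merit <- function(bins_list, class_bins) {
  k <- length(bins_list)
  r_cf <- mean(vapply(bins_list, symmetrical_uncertainty, numeric(1),
                      y = class_bins))
  if (k == 1) return(r_cf)
  pairs <- utils::combn(k, 2)
  r_ff <- mean(vapply(seq_len(ncol(pairs)), function(m) {
    symmetrical_uncertainty(bins_list[[pairs[1, m]]],
                            bins_list[[pairs[2, m]]])
  }, numeric(1)))
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

# Exhaustive best subset by CFS merit over all non-empty subsets.
oracle_best_subset <- function(x, y, bins = 3) {
  p <- ncol(x)
  bins_list <- lapply(seq_len(p), function(j) discretize(x[, j], bins))
  cls <- as.character(y)
  best <- 0
  for (mask in 1:(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    mer <- oracle_cfs_merit(bins_list[idx], cls)
    if (mer > best) best <- mer
  }
  best
}

# Fickett lookup written independently (scalar, straightforward).
oracle_fickett <- function(seq) {
  pos_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  con_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  pp <- list(A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
             C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
             G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
             T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pw <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  cp <- list(A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
             C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
             G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
             T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  cw <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  chars <- strsplit(toupper(seq), "")[[1]]
  total <- sum(chars != "N")
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    c1 <- sum(chars[seq(1, length(chars), 3)] == b)
    c2 <- sum(chars[seq(2, length(chars), 3)] == b)
    c3 <- sum(chars[seq(3, length(chars), 3)] == b)
    ratio <- max(c1, c2, c3) / (min(c1, c2, c3) + 1)
    frac <- (c1 + c2 + c3) / total
    score <- score + pp[[b]][which(ratio >= pos_breaks)[1]] * pw[[b]] +
      cp[[b]][which(frac >= con_breaks)[1]] * cw[[b]]
  }
  score
}
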