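# Coexpression network: cis/trans pair locality, correlation edges with a
# PPI constraint for coding-coding pairs, greedy cohesiveness module
# detection, and hypergeometric gene-set enrichment.

#' Classify the genomic locality of a transcript pair
#'
#' cis: same chromosome with a span gap of at most `cis_window` bp;
#' trans: different chromosomes, or a gap greater than `trans_dist` bp;
#' neither: in between. The classification is symmetric in its arguments.
#'
#' @param catalog A [transcript_catalog()] containing both transcripts.
#' @param id1,id2 Transcript ids (vectors allowed, recycled pairwise).
#' @param cis_window cis gap threshold in bp (default 100 kb).
#' @param trans_dist trans gap threshold in bp (default 1 Mb).
#' @return Character vector in `{"cis", "trans", "neither"}`.
#' @export
classify_pair_locality <- function(catalog, id1, id2,
                                   cis_window = 1e5, trans_dist = 1e6) {
  tx <- transcripts(catalog)
  i1 <- match(id1, tx$transcript_id)
  i2 <- match(id2, tx$transcript_id)
  if (anyNA(i1) || anyNA(i2)) stop("unknown transcript id in pair list")
  same_chrom <- tx$chrom[i1] == tx$chrom[i2]
  gap <- pmax(0, pmax(tx$span_start[i1], tx$span_start[i2]) -
                pmin(tx$span_end[i1], tx$span_end[i2]))
  ifelse(!same_chrom, "trans",
  ifelse(gap <= cis_window, "cis",
  ifelse(gap > trans_dist, "trans", "neither")))
}

#' Candidate transcript pairs by type
#'
#' Enumerates the pair classes used for network construction among a set
#' of transcripts: lincRNA-coding, coding-coding and lincRNA-lincRNA.
#' "lincRNA" here means any non-coding transcript in the catalog
#' (known noncoding or accepted candidate).
#'
#' @param catalog A [transcript_catalog()].
#' @param ids Transcript ids to pair (default: all in the catalog).
#' @return A data.frame with `id1`, `id2`, `pair_type`.
#' @export
candidate_pairs <- function(catalog, ids = NULL) {
  tx <- transcripts(catalog)
  if (!is.null(ids)) tx <- tx[tx$transcript_id %in% ids, , drop = FALSE]
  if (nrow(tx) < 2) stop("need at least two transcripts")
  coding <- tx$biotype == "coding"
  idx <- utils::combn(nrow(tx), 2)
  type <- ifelse(coding[idx[1, ]] & coding[idx[2, ]], "coding-coding",
          ifelse(!coding[idx[1, ]] & !coding[idx[2, ]], "lincRNA-lincRNA",
                 "lincRNA-coding"))
  data.frame(id1 = tx$transcript_id[idx[1, ]],
             id2 = tx$transcript_id[idx[2, ]],
             pair_type = type,
             stringsAsFactors = FALSE)
}

#' @noRd
ppi_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Build coexpression edges
#'
#' Keeps a pair as an edge when its Pearson correlation exceeds `r_min`
#' (strictly) at `p < p_max`. Coding-coding pairs must additionally be
#' supported by the protein-protein interaction list; pairs involving a
#' lincRNA never require PPI support. Locality (cis/trans/neither) is
#' recorded for every tested pair.
#'
#' @param m FPKM matrix, transcripts x samples.
#' @param pairs Data.frame with `id1`, `id2`, `pair_type` (see
#'   [candidate_pairs()]).
#' @param catalog A [transcript_catalog()] for locality classification;
#'   the PPI list is interpreted on gene ids from this catalog.
#' @param ppi Data.frame of undirected PPI edges with columns `gene_a`,
#'   `gene_b`, or NULL for no PPI evidence at all.
#' @param r_min Correlation threshold (strict, default 0.6).
#' @param p_max p-value threshold (default 1e-5).
#' @return A list with `edges` (kept edges) and `tested` (all pairs with
#'   `r`, `p`, `locality`, `ppi_supported`, `kept`).
#' @export
build_edges <- function(m, pairs, catalog, ppi = NULL,
                        r_min = 0.6, p_max = 1e-5) {
  m <- check_matrix(m)
  missing_ids <- setdiff(unique(c(pairs$id1, pairs$id2)), rownames(m))
  if (length(missing_ids) > 0) {
    stop("no expression for: ", paste(missing_ids, collapse = ", "))
  }
  lm1 <- log2(m[pairs$id1, , drop = FALSE] + 1)
  lm2 <- log2(m[pairs$id2, , drop = FALSE] + 1)
  r <- rowwise_cor(lm1, lm2)
  p <- pearson_p(r, ncol(m))
  tx <- transcripts(catalog)
  g1 <- tx$gene_id[match(pairs$id1, tx$transcript_id)]
  g2 <- tx$gene_id[match(pairs$id2, tx$transcript_id)]
  ppi_supported <- rep(FALSE, nrow(pairs))
  if (!is.null(ppi) && nrow(ppi) > 0) {
    ppi_supported <- ppi_key(g1, g2) %in% ppi_key(ppi$gene_a, ppi$gene_b)
  }
  tested <- data.frame(
    id1 = pairs$id1,
    id2 = pairs$id2,
    pair_type = pairs$pair_type,
    r = r,
    p = p,
    locality = classify_pair_locality(catalog, pairs$id1, pairs$id2),
    ppi_supported = ppi_supported,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  tested$kept <- !is.na(tested$r) & tested$r > r_min & tested$p < p_max &
    (tested$pair_type != "coding-coding" | tested$ppi_supported)
  list(edges = tested[tested$kept, , drop = FALSE], tested = tested)
}

# Cohesiveness f(V) = w_in / (w_in + w_bound) of a vertex set in an
# adjacency-list graph with unit edge weights.
#' @noRd
cohesiveness <- function(adj, members) {
  w_in <- 0; w_bound <- 0
  for (v in members) {
    nb <- adj[[v]]
    w_in <- w_in + sum(nb %in% members)
    w_bound <- w_bound + sum(!(nb %in% members))
  }
  w_in <- w_in / 2
  if (w_in + w_bound == 0) return(0)
  w_in / (w_in + w_bound)
}

#' Detect network modules by greedy cohesiveness growth
#'
#' Seeds at the highest-degree unassigned vertex and repeatedly applies
#' the single vertex addition or removal that most increases the
#' cohesiveness \eqn{f(V) = w_{in}/(w_{in} + w_{bound})}, stopping at a
#' local maximum. Modules smaller than `min_size` are discarded and
#' module pairs with Jaccard overlap above `overlap_max` are merged.
#' Fully deterministic: ties are broken by higher degree, then
#' lexicographic vertex id.
#'
#' @param edges Data.frame of undirected edges (`id1`, `id2`).
#' @param min_size Minimum module size (default 3).
#' @param overlap_max Jaccard threshold above which modules merge.
#' @return A list of modules, each a list with `members` (sorted ids) and
#'   `cohesiveness`.
#' @export
detect_modules <- function(edges, min_size = 3, overlap_max = 0.8) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  verts <- sort(unique(c(edges$id1, edges$id2)))
  adj <- stats::setNames(vector("list", length(verts)), verts)
  for (i in seq_len(nrow(edges))) {
    a <- edges$id1[i]; b <- edges$id2[i]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  deg <- vapply(adj, length, integer(1))
  order_ids <- verts[order(-deg, verts)]
  assigned <- character(0)
  modules <- list()
  for (seed in order_ids) {
    if (seed %in% assigned) next
    members <- seed
    f <- cohesiveness(adj, members)
    repeat {
      cand_add <- sort(setdiff(unique(unlist(adj[members])), members))
      cand_rm <- if (length(members) > 2) sort(members) else character(0)
      # deterministic candidate order: higher degree first, then id
      cand_add <- cand_add[order(-deg[cand_add], cand_add)]
      cand_rm <- cand_rm[order(-deg[cand_rm], cand_rm)]
      best_f <- f; best_set <- NULL
      for (v in cand_add) {
        fv <- cohesiveness(adj, c(members, v))
        if (fv > best_f + 1e-12) { best_f <- fv; best_set <- c(members, v) }
      }
      for (v in cand_rm) {
        fv <- cohesiveness(adj, setdiff(members, v))
        if (fv > best_f + 1e-12) { best_f <- fv; best_set <- setdiff(members, v) }
      }
      if (is.null(best_set)) break
      members <- best_set
      f <- best_f
    }
    if (length(members) >= min_size) {
      modules[[length(modules) + 1]] <- list(members = sort(members),
                                             cohesiveness = f)
      assigned <- union(assigned, members)
    } else {
      assigned <- union(assigned, seed)
    }
  }
  merge_modules(modules, overlap_max)
}

#' @noRd
merge_modules <- function(modules, overlap_max) {
  changed <- TRUE
  while (changed && length(modules) > 1) {
    changed <- FALSE
    for (i in seq_along(modules)) {
      for (j in seq_along(modules)) {
        if (j <= i) next
        a <- modules[[i]]$members; b <- modules[[j]]$members
        jac <- length(intersect(a, b)) / length(union(a, b))
        if (jac > overlap_max) {
          modules[[i]]$members <- sort(union(a, b))
          modules <- modules[-j]
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  modules
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a gene list
#' (e.g. a module's coding genes) and each gene set, within a stated
#' universe, with Benjamini-Hochberg adjustment across sets. Set members
#' outside the universe are dropped before testing.
#'
#' @param genes Character vector of query genes (must lie in `universe`).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @return A data.frame with `term`, `overlap`, `set_size`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(genes, gene_sets, universe) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (!all(genes %in% universe)) stop("query genes must lie in the universe")
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    k <- length(intersect(genes, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(genes), lower.tail = FALSE)
    data.frame(term = term, overlap = k, set_size = length(set), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}
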