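# End-to-end orchestration: simulate -> train scorers -> discover ->
# filter -> differential expression -> panel -> clustering -> survival,
# plus the methylation and coexpression-network side analyses.

#' Run the full MS-lincRNA pipeline on a simulated study
#'
#' Executes every stage on data from [simulate_study()]:
#' \enumerate{
#'   \item coding-potential scorers trained on labelled model sequences;
#'   \item novel-lincRNA discovery ([filter_novel_lincrnas()]);
#'   \item low-expression filtering of the known + accepted matrix;
#'   \item tumor-vs-control differential expression and expression-class
#'     assignment;
#'   \item promoter methylation-expression correlations;
#'   \item coexpression network (edges + modules) with the PPI
#'     constraint;
#'   \item staged Linctype panel selection;
#'   \item k-means (k = 5) subtype recovery on the discovery tumor
#'     samples and on the tumor-only validation cohort;
#'   \item log-rank survival comparison across the validation clusters.
#' }
#'
#' @param design A [simulation_design()].
#' @param sim Optional pre-computed [simulate_study()] result.
#' @param n_train Training sequences per class for the scorers.
#' @return A list with the outputs of every stage (`sim`, `scorers`,
#'   `discovery`, `matrix`, `de`, `classes`, `meth`, `network`,
#'   `modules`, `panel`, `clusters`, `validation_clusters`, `survival`).
#' @export
run_linctype_pipeline <- function(design, sim = NULL, n_train = 300) {
  sim <- sim %||% simulate_study(design)
  train <- simulate_codepot_sequences(n_per_class = n_train,
                                      seed = design$seed + 808L)
  scorers <- train_scorers(train$seqs, train$labels)

  cand_ids <- transcripts(sim$novel)$transcript_id
  discovery <- filter_novel_lincrnas(sim$novel, sim$known,
                                     sim$sequences[cand_ids], scorers)

  known_ids <- transcripts(sim$known)$transcript_id
  analysis_ids <- c(known_ids, discovery$accepted$transcript_id)
  m <- low_expression_filter(
    sim$expression$m[analysis_ids, , drop = FALSE])
  meta <- sim$expression$meta

  de <- tumor_control_de(m, meta)
  classes <- assign_expression_class(de)

  combined <- transcript_catalog(rbind(sim$known$exons, sim$novel$exons))
  analysis_catalog <- subset_catalog(combined, rownames(m))
  meth <- significant_meth_regulators(analysis_catalog,
                                      sim$methylation$sites,
                                      sim$methylation$beta, m)

  pairs <- candidate_pairs(analysis_catalog, rownames(m))
  network <- build_edges(m, pairs, analysis_catalog, sim$ppi)
  modules <- detect_modules(network$edges)

  panel <- select_linctype(m, meta)
  panel_ids <- intersect(panel$panel$transcript_id, rownames(m))

  tumor_samples <- meta$sample_id[meta$group %in%
                                    group_vocabulary()$subtypes]
  clusters <- kmeans_cluster(log2(m[panel_ids, tumor_samples,
                                    drop = FALSE] + 1),
                             k = 5, seed = design$seed + 909L)

  vm <- sim$validation$m[intersect(panel_ids,
                                   rownames(sim$validation$m)), ,
                         drop = FALSE]
  validation_clusters <- kmeans_cluster(log2(vm + 1), k = 5,
                                        seed = design$seed + 910L)
  surv <- sim$validation$survival
  cl <- validation_clusters$assignment[surv$sample_id]
  survival_result <- logrank_test(surv$time, surv$event, cl)

  list(sim = sim, scorers = scorers, discovery = discovery, matrix = m,
       de = de, classes = classes, meth = meth, network = network,
       modules = modules, panel = panel, clusters = clusters,
       validation_clusters = validation_clusters,
       survival = survival_result)
}
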