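#' Run the full mining pipeline on a dataset
#'
#' Executes every stage in order on a generated (or loaded) dataset:
#' type-vs-rest and condition-within-type differential expression, novel
#' marker nomination by CESG, cell-type abundance (ACT) by condition, NMF
#' pattern extraction with cell-type predictive power, regulon RAS/RSS/Z
#' scoring with the condition-wise RSS fold change, and loop construction in
#' both cell-specific mode (vs-rest DEG sets, cell-specific regulons,
#' overall pattern power) and disease mode (condition DEG sets, disease
#' regulons, disease-stratified pattern power).
#'
#' @param dataset list with `expr`, `annotation`, `known_markers`,
#'   `regulons` as returned by [simulateDataset()] (truth optional).
#' @param nmf_k NMF rank (default: number of cell types + 2, leaving slack
#'   factors for the shared baseline).
#' @param nmf_seed seed of the NMF initialization.
#' @param top_n pattern gene-set size (default 50).
#' @param power_threshold pattern selection gate (default 0.7).
#' @param alpha loop edge gate (default 0.05).
#' @param max_iter,tol NMF stopping rule.
#' @return list with every intermediate and both [LoopGraph-class] objects
#'   (`loops_cell`, `loops_disease`).
#' @export
runPipeline <- function(dataset, nmf_k = NULL, nmf_seed = 1, top_n = 50,
                        power_threshold = 0.7, alpha = 0.05, max_iter = 300,
                        tol = 1e-7) {
  expr <- dataset$expr; ann <- dataset$annotation
  universe <- geneIds(expr)
  n_types <- nlevels(droplevels(ann$cell_type))
  if (is.null(nmf_k)) nmf_k <- n_types + 2L

  de_rest <- deByType(expr, ann, "vs_rest")
  degs_rest <- .setsFromRecords(de_rest, universe)
  de_cond <- deByType(expr, ann, "condition_within_type")
  degs_cond <- .setsFromRecords(de_cond, universe)
  novel <- identifyNovelMarkers(expr, ann, dataset$known_markers, de_rest)
  act <- computeACT(ann, "condition")

  decomp <- nmfDecompose(expr, k = nmf_k, seed = nmf_seed,
                         max_iter = max_iter, tol = tol)
  power <- predictivePower(decomp, ann)
  power_cond <- predictivePower(decomp, ann, stratify_by_condition = TRUE)
  sel_pat <- selectPatterns(power, power_threshold)
  pat_sets <- patternGeneSets(decomp, top_n = top_n)

  activity <- scoreRegulons(expr, dataset$regulons, ann)
  sel_reg_cell <- selectRegulons(activity, "cell_specific")
  sel_reg_dis <- selectRegulons(activity, "disease")

  loops_cell <- buildLoops(splitSetsByType(pat_sets, sel_pat),
                           splitSetsByType(dataset$regulons, sel_reg_cell),
                           degs_rest, universe, alpha = alpha)
  dis_level <- levels(droplevels(ann$condition))[1]
  sel_pat_dis <- if (dis_level %in% names(power_cond))
    selectPatterns(power_cond[[dis_level]], power_threshold) else list()
  loops_disease <- buildLoops(splitSetsByType(pat_sets, sel_pat_dis),
                              splitSetsByType(dataset$regulons, sel_reg_dis),
                              degs_cond, universe, alpha = alpha,
                              disease_flag = TRUE)
  list(de_vs_rest = de_rest, deg_sets_vs_rest = degs_rest,
       de_condition = de_cond, deg_sets_condition = degs_cond,
       novel_markers = novel, act = act, decomposition = decomp,
       power = power, power_by_condition = power_cond,
       selected_patterns = sel_pat, pattern_sets = pat_sets,
       activity = activity, selected_regulons = sel_reg_cell,
       selected_regulons_disease = sel_reg_dis,
       loops_cell = loops_cell, loops_disease = loops_disease)
}

# filtered DEG GeneSetCollection from precomputed per-type DE records
.setsFromRecords <- function(records, universe, lfc_min = 0.25, alpha = 0.05) {
  sets <- lapply(names(records), function(ct)
    methods::new("GeneSet", name = ct, kind = "deg_set",
                 genes = filterDEGs(records[[ct]], lfc_min, alpha)$gene))
  GeneSetCollection(sets, universe = universe)
}
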