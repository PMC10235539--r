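#' Expressing-cell fractions of a gene inside and outside a cell type
#'
#' A cell "expresses" a gene when its value exceeds `threshold` (default 0 on
#' the log-normalized matrix; the detection cutoff is configurable because no
#' canonical threshold exists). With m expressing cells among the M cells of
#' the type and K expressing cells among the N - M remaining cells,
#' pct1 = m/M and pct2 = K/(N - M).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param ann a [CellAnnotation-class] covering all cells of `expr`.
#' @param gene,cell_type the gene symbol and cell-type label to profile.
#' @param threshold detection cutoff; expression means value > threshold.
#' @return list with `pct1`, `pct2`, `m`, `M`, `K`, `N`. When the annotation
#'   holds a single cell type, `pct2` is `NaN` and a warning is raised
#'   (degenerate partition).
#' @export
expressionFractions <- function(expr, ann, gene, cell_type, threshold = 0) {
  ann <- .checkAligned(expr, ann)
  if (!gene %in% geneIds(expr)) stop(sprintf("unknown gene: %s", gene))
  if (!cell_type %in% levels(ann$cell_type))
    stop(sprintf("unknown cell type: %s", cell_type))
  x <- as.numeric(exprValues(expr)[gene, ])
  in_type <- ann$cell_type == cell_type
  m <- sum(x[in_type] > threshold)
  M <- sum(in_type)
  K <- sum(x[!in_type] > threshold)
  N <- length(x)
  if (N == M) warning(sprintf(
    "single cell type '%s' in annotation: pct2 undefined", cell_type))
  list(pct1 = m / M, pct2 = if (N > M) K / (N - M) else NaN,
       m = m, M = M, K = K, N = N)
}

#' Cell expression specificity of a gene (CESG)
#'
#' CESG = pct1 / pct2, the ratio of the expressing-cell fraction inside a
#' cell type to the fraction outside it. A gene expressed inside the type but
#' nowhere else has CESG = Inf (exclusive marker); a gene not expressed in
#' the type has CESG = 0. Vectorized over its arguments.
#'
#' @param pct1,pct2 fractions in 0..1 from [expressionFractions()].
#' @return non-negative CESG values (possibly `Inf`).
#' @export
computeCESG <- function(pct1, pct2) {
  stopifnot(all(pct1 >= 0 & pct1 <= 1, na.rm = TRUE),
            all(pct2 >= 0 & pct2 <= 1, na.rm = TRUE))
  if (any(pct1 == 0 & pct2 == 0, na.rm = TRUE))
    warning("gene unexpressed everywhere: CESG defined as 0")
  out <- ifelse(pct1 == 0, 0, ifelse(pct2 == 0, Inf, pct1 / pct2))
  out
}

# vectorized pct1/pct2/CESG for every gene of one cell type
.cesgByType <- function(expr, ann, cell_type, threshold = 0) {
  X <- exprValues(expr)
  in_type <- ann$cell_type == cell_type
  M <- sum(in_type); N <- ncol(X)
  m <- as.numeric(Matrix::rowSums(X[, in_type, drop = FALSE] > threshold))
  K <- as.numeric(Matrix::rowSums(X[, !in_type, drop = FALSE] > threshold))
  pct1 <- m / M
  pct2 <- if (N > M) K / (N - M) else rep(NaN, length(m))
  cesg <- ifelse(pct1 == 0, 0, ifelse(pct2 == 0, Inf, pct1 / pct2))
  data.frame(gene = geneIds(expr), pct1 = pct1, pct2 = pct2, cesg = cesg,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Nominate novel cell-type markers by CESG
#'
#' For each cell type, candidate genes are those with `avg_log2FC > 1` and
#' adjusted p < 0.05 in the type-vs-rest differential expression (supplied in
#' `deg_by_type`), not in the known marker set of the type, and with CESG
#' strictly greater than the reference CESG of that type's known markers.
#' The reference is the maximum CESG among known markers (conservative
#' choice). When a known marker is exclusively expressed (CESG = Inf), only
#' candidates that are themselves exclusive can be called; among infinite
#' CESG values the ranking falls back to pct1.
#'
#' @param expr,ann expression and annotation.
#' @param known_markers a [GeneSetCollection-class] with one
#'   `known_marker` set per cell type, named by the cell type.
#' @param deg_by_type named list (per cell type) of data frames from
#'   [wilcoxonDE()] run type-vs-rest, holding `gene`, `avg_log2FC`, `p_adj`.
#' @param lfc_min,alpha candidate gates on the DE results.
#' @param threshold detection cutoff passed to the fraction computation.
#' @return data.frame of candidate scores sorted within type by CESG
#'   descending (infinite ties by pct1, then avg_log2FC, then gene id) with
#'   columns gene, cell_type, pct1, pct2, cesg, avg_log2FC, p_adj,
#'   reference_cesg, is_novel_candidate, flag. Types lacking known markers
#'   get flag `"no_reference"` and are never called novel.
#' @export
identifyNovelMarkers <- function(expr, ann, known_markers, deg_by_type,
                                 lfc_min = 1, alpha = 0.05, threshold = 0) {
  ann <- .checkAligned(expr, ann)
  out <- list()
  for (ct in levels(droplevels(ann$cell_type))) {
    de <- deg_by_type[[ct]]
    if (is.null(de)) next
    cand <- de[de$avg_log2FC > lfc_min & de$p_adj < alpha, , drop = FALSE]
    known <- if (ct %in% geneSetNames(known_markers))
      setGenes(known_markers[[ct]]) else character()
    cand <- cand[!cand$gene %in% known, , drop = FALSE]
    if (!nrow(cand)) next
    tab <- .cesgByType(expr, ann, ct, threshold)
    rownames(tab) <- tab$gene
    ct_tab <- tab[cand$gene, , drop = FALSE]
    ct_tab$avg_log2FC <- cand$avg_log2FC
    ct_tab$p_adj <- cand$p_adj
    ct_tab$cell_type <- ct
    if (length(known_in <- intersect(known, tab$gene))) {
      ref <- max(tab[known_in, "cesg"])
      ct_tab$reference_cesg <- ref
      ct_tab$is_novel_candidate <-
        if (is.infinite(ref)) is.infinite(ct_tab$cesg) else ct_tab$cesg > ref
      ct_tab$flag <- ""
    } else {
      ct_tab$reference_cesg <- NA_real_
      ct_tab$is_novel_candidate <- FALSE
      ct_tab$flag <- "no_reference"
    }
    ord <- order(-ct_tab$cesg,
                 -ifelse(is.infinite(ct_tab$cesg), ct_tab$pct1, 0),
                 -ct_tab$avg_log2FC, ct_tab$gene)
    out[[ct]] <- ct_tab[ord, , drop = FALSE]
  }
  if (!length(out))
    return(data.frame(gene = character(), cell_type = character(),
                      pct1 = numeric(), pct2 = numeric(), cesg = numeric(),
                      avg_log2FC = numeric(), p_adj = numeric(),
                      reference_cesg = numeric(),
                      is_novel_candidate = logical(), flag = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("gene", "cell_type", "pct1", "pct2", "cesg", "avg_log2FC",
          "p_adj", "reference_cesg", "is_novel_candidate", "flag")]
}
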