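#' Regulon activity scores (RAS) per cell
#'
#' AUCell-style rank-based score. For each cell, genes are ranked by
#' decreasing expression, ties broken by a fixed random permutation seeded
#' from the cell's column index (so the score is deterministic for a given
#' matrix). The RAS of a regulon is the area under the step recovery curve
#' of its target genes within the top `ceiling(top_fraction * G)` ranks,
#' normalized by the maximal achievable area, giving a value in 0..1.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param regulons a [GeneSetCollection-class] of `regulon_targets` sets
#'   (TF -> target genes); targets absent from the matrix are ignored.
#' @param top_fraction fraction of top-ranked genes that defines the early
#'   recovery window (default 0.05).
#' @return regulons x cells matrix of RAS values; a regulon with no target
#'   present in the matrix yields a row of NA with a warning.
#' @export
computeRAS <- function(expr, regulons, top_fraction = 0.05) {
  stopifnot(methods::is(expr, "ExpressionMatrix"),
            methods::is(regulons, "GeneSetCollection"))
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)")
  X <- .asDense(exprValues(expr))
  G <- nrow(X)
  thr <- ceiling(top_fraction * G)
  reg_idx <- lapply(geneSets(regulons), function(s)
    which(rownames(X) %in% setGenes(s)))
  empty <- lengths(reg_idx) == 0
  if (any(empty))
    warning(sprintf("regulon(s) with no genes in the matrix: %s",
                    paste(names(reg_idx)[empty], collapse = ", ")))
  maxarea <- vapply(lengths(reg_idx), function(g)
    sum(pmin(seq_len(thr), g)), numeric(1))
  out <- matrix(NA_real_, length(reg_idx), ncol(X),
                dimnames = list(names(reg_idx), colnames(X)))
  rk <- integer(G)
  for (j in seq_len(ncol(X))) {
    tie_key <- .withSeed(j, sample.int(G))
    ord <- order(-X[, j], tie_key)
    rk[ord] <- seq_len(G)
    for (i in which(!empty)) {
      r <- rk[reg_idx[[i]]]
      r <- r[r <= thr]
      # area under the step recovery curve: each hit at rank r contributes
      # one unit for every window position from r to thr
      out[i, j] <- sum(thr - r + 1) / maxarea[i]
    }
  }
  out
}

#' Regulon specificity scores (RSS) per cell type
#'
#' RSS(R, C) = 1 - JSD(P^R, P^C) where P^R is the regulon's RAS vector
#' normalized to sum 1 over cells and P^C is the uniform indicator
#' distribution over the cells of type C. The Jensen-Shannon divergence is
#' computed with log base 2 so RSS lies in 0..1: identical distributions
#' give RSS = 1, disjoint supports give RSS = 0.
#'
#' @param ras regulons x cells matrix from [computeRAS()].
#' @param ann a [CellAnnotation-class] covering the RAS columns.
#' @return regulons x cell-types RSS matrix; an all-zero (or all-NA) RAS row
#'   yields an NA row with a warning.
#' @export
computeRSS <- function(ras, ann) {
  stopifnot(methods::is(ann, "CellAnnotation"))
  idx <- match(colnames(ras), ann$cell_id)
  if (anyNA(idx)) stop("RAS cells missing from annotation")
  ct <- droplevels(factor(ann$cell_type[idx]))
  types <- levels(ct)
  out <- matrix(NA_real_, nrow(ras), length(types),
                dimnames = list(rownames(ras), types))
  pc <- lapply(types, function(l) {
    q <- as.numeric(ct == l)
    q / sum(q)
  })
  names(pc) <- types
  for (i in seq_len(nrow(ras))) {
    v <- ras[i, ]
    if (anyNA(v) || sum(v) == 0) {
      warning(sprintf("regulon %s has all-zero or missing RAS: RSS undefined",
                      rownames(ras)[i]))
      next
    }
    p <- v / sum(v)
    out[i, ] <- vapply(types, function(l) 1 - .jsd(p, pc[[l]]), numeric(1))
  }
  out
}

# per-regulon standardization of mean RAS across cell types
.rasZscore <- function(ras, ann) {
  idx <- match(colnames(ras), ann$cell_id)
  ct <- droplevels(factor(ann$cell_type[idx]))
  means <- vapply(levels(ct), function(l)
    rowMeans(ras[, ct == l, drop = FALSE]), numeric(nrow(ras)))
  if (nrow(ras) == 1) means <- matrix(means, nrow = 1,
                                      dimnames = list(rownames(ras), levels(ct)))
  t(apply(means, 1, function(m) {
    s <- stats::sd(m)
    if (is.na(s) || s == 0) rep(NA_real_, length(m)) else (m - mean(m)) / s
  }))
}

#' Score regulon activity, specificity and condition contrast
#'
#' One-stop computation of the [RegulonActivity-class] object: RAS per cell,
#' RSS per cell type, per-type Z-scores of mean RAS (standardized across
#' cell types within each regulon), and, when the annotation has two or more
#' condition levels, the condition-wise RSS log2 fold change via
#' [rssConditionFoldChange()].
#'
#' @param expr,regulons,top_fraction as in [computeRAS()].
#' @param ann a [CellAnnotation-class].
#' @param condition_contrast `NULL` to skip the fold change, or a character
#'   vector of the two levels (numerator first); defaults to the first two
#'   condition levels when the annotation has them.
#' @return a [RegulonActivity-class].
#' @export
scoreRegulons <- function(expr, regulons, ann, top_fraction = 0.05,
                          condition_contrast = NULL) {
  ann <- .checkAligned(expr, ann)
  ras <- computeRAS(expr, regulons, top_fraction)
  rss <- computeRSS(ras, ann)
  z <- .rasZscore(ras, ann)
  lv <- levels(droplevels(ann$condition))
  if (is.null(condition_contrast) && length(lv) >= 2)
    condition_contrast <- lv[1:2]
  if (!is.null(condition_contrast)) {
    fc <- rssConditionFoldChange(expr, regulons, ann,
                                 level_a = condition_contrast[1],
                                 level_b = condition_contrast[2],
                                 top_fraction = top_fraction)
    methods::new("RegulonActivity", ras = ras, rss = rss, zscore = z,
                 rss_log2fc = fc, fc_levels = condition_contrast)
  } else {
    methods::new("RegulonActivity", ras = ras, rss = rss, zscore = z,
                 rss_log2fc = matrix(numeric(), 0, 0),
                 fc_levels = character())
  }
}

#' Condition-wise RSS log2 fold change
#'
#' RAS and RSS are recomputed separately on the cells of each condition
#' level; the result is `log2(RSS_A / RSS_B)` per (regulon, cell type),
#' clipped to +/- 10 (a zero RSS in numerator or denominator is reported as
#' the -10/+10 sentinel and flagged in the `"clipped"` attribute).
#'
#' @param expr,regulons,top_fraction as in [computeRAS()].
#' @param ann a [CellAnnotation-class].
#' @param level_a,level_b the two condition levels (numerator first);
#'   default to the first two levels.
#' @param clip magnitude cap of the log2 fold change (default 10).
#' @return regulons x cell-types matrix (cell types present in both levels),
#'   with attribute `clipped` marking sentinel entries.
#' @export
rssConditionFoldChange <- function(expr, regulons, ann, level_a = NULL,
                                   level_b = NULL, top_fraction = 0.05,
                                   clip = 10) {
  ann <- .checkAligned(expr, ann)
  lv <- levels(droplevels(ann$condition))
  if (is.null(level_a)) level_a <- lv[1]
  if (is.null(level_b)) level_b <- lv[2]
  if (is.na(level_b) || !all(c(level_a, level_b) %in% lv))
    stop("both condition levels must be present in the annotation")
  one <- function(level) {
    cells <- ann$cell_id[ann$condition == level]
    sub <- ExpressionMatrix(exprValues(expr)[, cells, drop = FALSE])
    ras <- computeRAS(sub, regulons, top_fraction)
    computeRSS(ras, ann[match(cells, ann$cell_id), , drop = FALSE])
  }
  ra <- one(level_a); rb <- one(level_b)
  common <- intersect(colnames(ra), colnames(rb))
  ra <- ra[, common, drop = FALSE]; rb <- rb[, common, drop = FALSE]
  fc <- matrix(NA_real_, nrow(ra), length(common),
               dimnames = list(rownames(ra), common))
  clipped <- matrix(FALSE, nrow(ra), length(common),
                    dimnames = dimnames(fc))
  both_zero <- ra == 0 & rb == 0
  fc[] <- log2(ra / rb)
  fc[both_zero] <- 0
  clipped[] <- is.finite(fc) & abs(fc) > clip | is.infinite(fc) | is.nan(fc)
  fc[fc > clip] <- clip
  fc[fc < -clip] <- -clip
  fc[is.nan(fc)] <- 0
  attr(fc, "clipped") <- clipped
  fc
}

#' Select cell-type-specific or disease-associated regulons
#'
#' `cell_specific` mode assigns regulon r to cell type c when RSS(r, c) is
#' at least `rss_min` (default 0.1) and the Z-score of the regulon's mean
#' RAS in c, standardized across all cell types, is at least `z_min`
#' (default 2); the standardization needs at least 3 cell types. `disease`
#' mode assigns the regulon when the magnitude of its condition-wise RSS
#' log2 fold change in that type exceeds `lfc_min` (default 1, strict).
#'
#' @param activity a [RegulonActivity-class] from [scoreRegulons()].
#' @param mode `"cell_specific"` or `"disease"`.
#' @param rss_min,z_min,lfc_min the selection gates.
#' @return named list: cell type -> character vector of regulon names.
#' @export
selectRegulons <- function(activity, mode = c("cell_specific", "disease"),
                           rss_min = 0.1, z_min = 2, lfc_min = 1) {
  mode <- match.arg(mode)
  stopifnot(methods::is(activity, "RegulonActivity"))
  if (mode == "cell_specific") {
    rss <- rssMatrix(activity); z <- rasZscore(activity)
    if (ncol(rss) < 3)
      stop("Z-score standardization needs at least 3 cell types")
    sel <- !is.na(rss) & rss >= rss_min & !is.na(z) & z >= z_min
  } else {
    fc <- rssLog2FC(activity)
    if (!length(fc))
      stop("disease mode needs condition-wise RSS (see scoreRegulons)")
    sel <- !is.na(fc) & abs(fc) > lfc_min
  }
  out <- lapply(colnames(sel), function(ct) rownames(sel)[sel[, ct]])
  setNames(out, colnames(sel))
}
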