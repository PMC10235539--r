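#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test with the tie-corrected,
#' continuity-corrected normal approximation; when the combined group size is
#' at most `exact_max_n` cells the p-value comes from exact enumeration of
#' all rank assignments instead. The average log2 fold change is computed on
#' the de-logged scale with a pseudocount of 1:
#' `avg_log2FC = log2((mean(expm1(x_a)) + 1) / (mean(expm1(x_b)) + 1))`.
#' Genes expressed in at least one cell of either group are tested;
#' Bonferroni adjustment is over the tested genes. A gene constant across
#' both groups gets p = 1 and avg_log2FC = 0.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param cells_a,cells_b disjoint non-empty cell id vectors (each of size
#'   at least 2).
#' @param contrast label stored on every record.
#' @param exact_max_n switch to exact enumeration when
#'   `length(cells_a) + length(cells_b)` is at most this (default 12).
#' @return data.frame with gene, contrast, avg_log2FC, p_value, p_adj,
#'   pct1, pct2 (expressing fractions in groups a and b).
#' @export
wilcoxonDE <- function(expr, cells_a, cells_b, contrast = "a_vs_b",
                       exact_max_n = 12) {
  stopifnot(methods::is(expr, "ExpressionMatrix"))
  if (length(intersect(cells_a, cells_b)))
    stop("cell groups must be disjoint")
  if (length(cells_a) < 2 || length(cells_b) < 2)
    stop("each group needs at least 2 cells")
  miss <- setdiff(c(cells_a, cells_b), cellIds(expr))
  if (length(miss)) stop(sprintf("unknown cell id(s): %s",
                                 paste(head(miss, 5), collapse = ", ")))
  X <- .asDense(exprValues(expr))
  Xa <- X[, cells_a, drop = FALSE]
  Xb <- X[, cells_b, drop = FALSE]
  keep <- rowSums(Xa > 0) + rowSums(Xb > 0) >= 1
  Xa <- Xa[keep, , drop = FALSE]; Xb <- Xb[keep, , drop = FALSE]
  na <- ncol(Xa); nb <- ncol(Xb); n <- na + nb
  Xab <- cbind(Xa, Xb)
  constant <- .rowsConstant(Xab)
  if (n <= exact_max_n) {
    p <- .wilcoxExact(Xab, na)
  } else {
    p <- .wilcoxNormal(Xab, na)
  }
  ea <- rowMeans(expm1(Xa)); eb <- rowMeans(expm1(Xb))
  lfc <- log2((ea + 1) / (eb + 1))
  p[constant] <- 1
  lfc[constant] <- 0
  data.frame(gene = rownames(Xab), contrast = contrast, avg_log2FC = lfc,
             p_value = p, p_adj = stats::p.adjust(p, "bonferroni"),
             pct1 = rowMeans(Xa > 0), pct2 = rowMeans(Xb > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

# rows whose values are all identical (no signal by construction)
.rowsConstant <- function(X) {
  apply(X, 1, function(x) all(x == x[1]))
}

# tie-corrected normal approximation with continuity correction; the first
# `na` columns of Xab are group a
.wilcoxNormal <- function(Xab, na) {
  n <- ncol(Xab); nb <- n - na
  st <- apply(Xab, 1, function(x) {
    r <- rank(x)
    rl <- rle(sort(x))$lengths
    c(sum(r[seq_len(na)]), sum(rl^3 - rl))
  })
  .wilcoxNormalFromStats(st[1, ], st[2, ], na, nb)
}

.wilcoxNormalFromStats <- function(W, tiesum, na, nb) {
  n <- na + nb
  U <- W - na * (na + 1) / 2
  mu <- na * nb / 2
  v <- na * nb / 12 * ((n + 1) - tiesum / (n * (n - 1)))
  p <- rep(1, length(W))
  ok <- v > 0
  cc <- pmax(abs(U[ok] - mu) - 0.5, 0)   # continuity correction
  p[ok] <- pmin(1, 2 * pnorm(cc / sqrt(v[ok]), lower.tail = FALSE))
  p
}

# exact two-sided p by enumeration of all C(n, na) rank assignments,
# valid with ties: p = min(1, 2 * min(P(W <= w), P(W >= w)))
.wilcoxExact <- function(Xab, na) {
  n <- ncol(Xab)
  idx <- combn(n, na)
  apply(Xab, 1, function(x) {
    r <- rank(x)
    sums <- colSums(matrix(r[idx], nrow = na))
    w <- sum(r[seq_len(na)])
    eps <- 1e-9
    min(1, 2 * min(mean(sums <= w + eps), mean(sums >= w - eps)))
  })
}

#' Filter differential expression records to significant DEGs
#'
#' Keeps records with `|avg_log2FC| >= lfc_min` (boundary inclusive, both
#' directions) and `p_adj < alpha` (strict).
#'
#' @param records data.frame from [wilcoxonDE()].
#' @param lfc_min,alpha the gates (defaults 0.25 and 0.05).
#' @return the filtered data.frame.
#' @export
filterDEGs <- function(records, lfc_min = 0.25, alpha = 0.05) {
  records[abs(records$avg_log2FC) >= lfc_min & records$p_adj < alpha, ,
          drop = FALSE]
}

#' Per-cell-type differential expression records
#'
#' Runs [wilcoxonDE()] for every cell type, either against all remaining
#' cells (`vs_rest`) or between two condition levels within the type
#' (`condition_within_type`). The `vs_rest` path shares one ranking of each
#' gene across all cells between the per-type contrasts, so it scales to
#' many types. Types with fewer than `min_cells` cells on either side are
#' skipped with a warning.
#'
#' @param expr,ann expression and annotation.
#' @param contrast_kind `"vs_rest"` or `"condition_within_type"`.
#' @param level_a,level_b condition levels for the within-type contrast
#'   (default: the first two levels of the condition factor).
#' @param min_cells minimum cells per side (default 3).
#' @return named list (per cell type) of [wilcoxonDE()] data frames.
#' @export
deByType <- function(expr, ann,
                     contrast_kind = c("vs_rest", "condition_within_type"),
                     level_a = NULL, level_b = NULL, min_cells = 3) {
  contrast_kind <- match.arg(contrast_kind)
  ann <- .checkAligned(expr, ann)
  types <- levels(droplevels(ann$cell_type))
  out <- list()
  if (contrast_kind == "vs_rest") {
    X <- .asDense(exprValues(expr))
    keep <- rowSums(X > 0) >= 1
    X <- X[keep, , drop = FALSE]
    st <- apply(X, 1, function(x) {
      r <- rank(x)
      rl <- rle(sort(x))$lengths
      list(r = r, tiesum = sum(rl^3 - rl))
    })
    R <- t(vapply(st, `[[`, numeric(ncol(X)), "r"))
    tiesum <- vapply(st, `[[`, numeric(1), "tiesum")
    n <- ncol(X)
    E <- expm1(X)
    Esum <- rowSums(E)
    Psum <- rowSums(X > 0)
    constant <- .rowsConstant(X)
    for (ct in types) {
      in_type <- ann$cell_type == ct
      na <- sum(in_type); nb <- n - na
      if (na < min_cells || nb < min_cells) {
        warning(sprintf("cell type %s too small for testing (%d vs %d cells)",
                        ct, na, nb))
        next
      }
      W <- rowSums(R[, in_type, drop = FALSE])
      p <- .wilcoxNormalFromStats(W, tiesum, na, nb)
      ea <- rowSums(E[, in_type, drop = FALSE]) / na
      eb <- (Esum - ea * na) / nb
      lfc <- log2((ea + 1) / (eb + 1))
      pa <- rowSums(X[, in_type, drop = FALSE] > 0)
      p[constant] <- 1; lfc[constant] <- 0
      out[[ct]] <- data.frame(
        gene = rownames(X), contrast = sprintf("%s:vs_rest", ct),
        avg_log2FC = lfc, p_value = p,
        p_adj = stats::p.adjust(p, "bonferroni"),
        pct1 = pa / na, pct2 = (Psum - pa) / nb,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  } else {
    cl <- levels(ann$condition)
    if (is.null(level_a)) level_a <- cl[1]
    if (is.null(level_b)) level_b <- cl[2]
    if (is.na(level_b) || !all(c(level_a, level_b) %in% cl))
      stop("two condition levels are required for a within-type contrast")
    for (ct in types) {
      ca <- ann$cell_id[ann$cell_type == ct & ann$condition == level_a]
      cb <- ann$cell_id[ann$cell_type == ct & ann$condition == level_b]
      if (length(ca) < min_cells || length(cb) < min_cells) {
        warning(sprintf("cell type %s too small for testing (%d vs %d cells)",
                        ct, length(ca), length(cb)))
        next
      }
      out[[ct]] <- wilcoxonDE(expr, ca, cb,
                              contrast = sprintf("%s:%s_vs_%s", ct, level_a,
                                                 level_b))
    }
  }
  out
}

#' Per-cell-type DEG gene sets
#'
#' Convenience wrapper: [deByType()] then [filterDEGs()], returning one
#' `deg_set` [GeneSet-class] per cell type. Types skipped for size yield an
#' empty set (with the size warning from [deByType()]).
#'
#' @inheritParams deByType
#' @param lfc_min,alpha DEG gates passed to [filterDEGs()].
#' @return a [GeneSetCollection-class] of `deg_set` sets named by cell type.
#' @export
degSetsByType <- function(expr, ann,
                          contrast_kind = c("vs_rest", "condition_within_type"),
                          level_a = NULL, level_b = NULL, lfc_min = 0.25,
                          alpha = 0.05, min_cells = 3) {
  contrast_kind <- match.arg(contrast_kind)
  ann2 <- .checkAligned(expr, ann)
  recs <- deByType(expr, ann, contrast_kind, level_a, level_b, min_cells)
  types <- levels(droplevels(ann2$cell_type))
  sets <- lapply(types, function(ct) {
    genes <- if (!is.null(recs[[ct]]))
      filterDEGs(recs[[ct]], lfc_min, alpha)$gene else character()
    methods::new("GeneSet", name = ct, kind = "deg_set", genes = genes)
  })
  GeneSetCollection(sets, universe = geneIds(expr))
}
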