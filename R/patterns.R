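#' Seeded non-negative matrix factorization of expression
#'
#' Factorizes the non-negative genes x cells matrix X into amplitude
#' (genes x k gene weights) and pattern (k x cells sample weights) matrices
#' by Lee-Seung multiplicative updates on the Frobenius objective, from a
#' uniform random non-negative initialization drawn under `seed`. The
#' objective is non-increasing at every update; iteration stops when the
#' relative change of the reconstruction error falls below `tol` or after
#' `max_iter` iterations. Identical seeds give bitwise-identical factors.
#'
#' @param expr an [ExpressionMatrix-class] (or plain non-negative matrix).
#' @param k number of patterns, `1 <= k < min(genes, cells)`.
#' @param seed integer RNG seed for the initialization.
#' @param max_iter,tol stopping rule.
#' @return a [PatternDecomposition-class]; patterns are named
#'   `Pattern_1 ... Pattern_k`.
#' @export
nmfDecompose <- function(expr, k, seed = 1, max_iter = 500, tol = 1e-5) {
  X <- if (methods::is(expr, "ExpressionMatrix"))
    .asDense(exprValues(expr)) else .asDense(expr)
  if (any(X < 0)) stop("input matrix must be non-negative")
  if (k < 1 || k >= min(dim(X)))
    stop(sprintf("k = %d out of range [1, %d)", k, min(dim(X))))
  normX <- sqrt(sum(X^2))
  if (normX == 0) stop("all-zero matrix cannot be factorized")
  eps <- .Machine$double.eps
  init <- .withSeed(seed, {
    scale <- sqrt(mean(X) / k)
    list(W = matrix(runif(nrow(X) * k), ncol = k) * scale,
         H = matrix(runif(k * ncol(X)), nrow = k) * scale)
  })
  W <- init$W; H <- init$H
  trace <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  prev <- Inf
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H) / (W %*% tcrossprod(H) + eps))
    err <- sqrt(sum((X - W %*% H)^2)) / normX
    trace[it] <- err
    if (is.finite(prev) && abs(prev - err) < tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- err
  }
  pn <- sprintf("Pattern_%d", seq_len(k))
  dimnames(W) <- list(rownames(X), pn)
  dimnames(H) <- list(pn, colnames(X))
  methods::new("PatternDecomposition", amplitude = W, pattern = H,
               k = as.integer(k), seed = as.integer(seed),
               reconstruction_error = trace[it],
               error_trace = trace[seq_len(it)], iterations = it,
               converged = converged)
}

#' Cell-type predictive power of expression patterns
#'
#' Entry (p, c) is the AUROC of pattern p's per-cell sample weights for
#' discriminating cells of type c from all other cells (Mann-Whitney U
#' statistic over n_c * n_other, midrank tie convention). A value near 1
#' means the pattern weights single out that cell type. With
#' `stratify_by_condition` the table is computed separately within each
#' condition level (disease-state-resolved pattern specificity).
#'
#' @param decomp a [PatternDecomposition-class].
#' @param ann a [CellAnnotation-class] covering the decomposition's cells.
#' @param stratify_by_condition compute one table per condition level.
#' @return patterns x cell-types matrix of AUC values in 0..1 (NA where a
#'   type has fewer than 2 cells), or a named list of such matrices when
#'   stratified.
#' @export
predictivePower <- function(decomp, ann, stratify_by_condition = FALSE) {
  stopifnot(methods::is(decomp, "PatternDecomposition"),
            methods::is(ann, "CellAnnotation"))
  H <- patternMatrix(decomp)
  idx <- match(colnames(H), ann$cell_id)
  if (anyNA(idx)) stop("decomposition cells missing from annotation")
  ann <- ann[idx, , drop = FALSE]
  one <- function(cells_mask) {
    types <- levels(droplevels(factor(ann$cell_type[cells_mask])))
    sub <- H[, cells_mask, drop = FALSE]
    ct_lab <- ann$cell_type[cells_mask]
    out <- matrix(NA_real_, nrow(H), length(types),
                  dimnames = list(rownames(H), types))
    for (ct in types) {
      pos <- ct_lab == ct
      out[, ct] <- apply(sub, 1, .aucRank, pos = pos)
    }
    out
  }
  if (!stratify_by_condition) return(one(rep(TRUE, ncol(H))))
  lv <- levels(droplevels(ann$condition))
  setNames(lapply(lv, function(l) one(ann$condition == l)), lv)
}

#' Select patterns with high predictive power
#'
#' Per cell type, the patterns whose AUC meets the threshold (boundary
#' inclusive, default 0.7), sorted by decreasing AUC.
#'
#' @param power patterns x types AUC matrix from [predictivePower()].
#' @param threshold minimum AUC (default 0.7).
#' @return named list: cell type -> character vector of pattern names.
#' @export
selectPatterns <- function(power, threshold = 0.7) {
  out <- lapply(colnames(power), function(ct) {
    v <- power[, ct]
    v <- v[!is.na(v) & v >= threshold]
    names(sort(v, decreasing = TRUE))
  })
  setNames(out, colnames(power))
}

#' Gene sets from pattern amplitude columns
#'
#' Membership of a pattern is defined from its amplitude (gene weight)
#' column: either the `top_n` genes by weight, or the genes whose weight
#' strictly exceeds the `quantile` of the column (e.g. 0.99 keeps the top
#' 1 percent). Ties at the top_n boundary are broken by gene id.
#'
#' @param decomp a [PatternDecomposition-class].
#' @param top_n number of top-weight genes per pattern (default 50); capped
#'   at the gene count with a warning.
#' @param quantile if non-NULL, use the weight-quantile rule instead.
#' @return a [GeneSetCollection-class] of `pattern_top_genes` sets named by
#'   pattern.
#' @export
patternGeneSets <- function(decomp, top_n = 50, quantile = NULL) {
  W <- amplitudeMatrix(decomp)
  G <- nrow(W)
  if (is.null(quantile) && top_n > G) {
    warning(sprintf("top_n = %d exceeds gene count %d; capped", top_n, G))
    top_n <- G
  }
  sets <- lapply(colnames(W), function(pn) {
    w <- W[, pn]
    genes <- if (is.null(quantile)) {
      rownames(W)[order(-w, rownames(W))[seq_len(top_n)]]
    } else {
      rownames(W)[w > stats::quantile(w, quantile)]
    }
    GeneSet(pn, "pattern_top_genes", genes)
  })
  GeneSetCollection(sets, universe = rownames(W))
}
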