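# internal helpers shared across stages

# evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so module-level determinism never leaks
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Jensen-Shannon divergence with log base 2 (so the value lies in [0, 1]);
# p and q must each sum to 1. 0 * log(0) terms are dropped.
.jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# midrank AUROC of `scores` for the positive mask `pos`
.aucRank <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2L || n0 < 1L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.asDense <- function(x) {
  if (methods::is(x, "Matrix")) as.matrix(x) else x
}

# expression matrix + annotation consistency gate used by every stage
.checkAligned <- function(expr, ann) {
  stopifnot(methods::is(expr, "ExpressionMatrix"), methods::is(ann, "CellAnnotation"))
  miss <- setdiff(cellIds(expr), ann$cell_id)
  if (length(miss))
    stop(sprintf("cells missing from annotation: %s",
                 paste(head(miss, 5), collapse = ", ")))
  ann[match(cellIds(expr), ann$cell_id), , drop = FALSE]
}
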