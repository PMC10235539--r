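# shared fixtures built in code; the small configuration keeps unit tests
# fast while preserving every planted structure of the default generator

smallSimConfig <- function(seed = 1, ...) {
  # proportions mirror the default generator; the stronger condition shift
  # compensates the reduced per-group cell count, and the planted blocks
  # stay well inside the 5 percent AUCell window (50 of 1000 genes)
  args <- list(n_cell_types = 6, cells_per_type = 40, n_genes = 1000,
               pattern_gene_size = 25, regulon_size = 15,
               n_degs_per_type = 12, loop_overlap = 6, deg_effect = 2.5,
               n_disease_regulons = 1, seed = seed)
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

# memoized small dataset so independent test files do not regenerate it
.sim_cache <- new.env(parent = emptyenv())
getSmallSim <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulateDataset(smallSimConfig(seed))
  .sim_cache[[key]]
}

# tiny deterministic expression fixture: values chosen by hand
toyExpr <- function() {
  v <- matrix(c(1.0, 0.0, 2.0,
                0.0, 1.5, 0.0,
                3.0, 3.0, 3.0), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"), c("c1", "c2", "c3")))
  ExpressionMatrix(v)
}

# greedy cosine assignment of planted programs to recovered amplitude
# columns (equivalent to the optimal assignment for well-separated programs)
matchPrograms <- function(decomp, planted) {
  W <- amplitudeMatrix(decomp)
  cs <- sapply(names(planted), function(pn) {
    p <- planted[[pn]]
    v <- numeric(nrow(W)); names(v) <- rownames(W); v[p$genes] <- p$weights
    apply(W, 2, function(w) sum(w * v) / sqrt(sum(w^2) * sum(v^2)))
  })   # factors x programs
  assign <- setNames(character(ncol(cs)), colnames(cs))
  free <- rownames(cs)
  for (rep in seq_len(ncol(cs))) {
    i <- which(cs == max(cs[free, colnames(cs)[!nzchar(assign)], drop = FALSE]),
               arr.ind = TRUE)[1, ]
    f <- rownames(cs)[i[1]]; p <- colnames(cs)[i[2]]
    if (nzchar(assign[p]) || !(f %in% free)) next
    assign[p] <- f
    free <- setdiff(free, f)
    cs[, p] <- -Inf
    cs[f, ] <- -Inf
  }
  assign
}

# independent brute-force recovery-curve RAS oracle (used against computeRAS)
bruteRAS <- function(x, gene_names, regulon_genes, top_fraction, cell_index) {
  G <- length(x)
  thr <- ceiling(top_fraction * G)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(cell_index)
  key <- sample.int(G)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  ord <- order(-x, key)
  ranked <- gene_names[ord]
  hits <- cumsum(ranked %in% regulon_genes)[seq_len(thr)]
  g <- sum(gene_names %in% regulon_genes)
  sum(hits) / sum(pmin(seq_len(thr), g))
}
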