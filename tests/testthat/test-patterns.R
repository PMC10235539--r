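test_that("an exact rank-1 matrix is recovered to numerical precision", {
  set.seed(3)
  u <- abs(rnorm(40)) + 0.1; v <- abs(rnorm(25)) + 0.1
  X <- outer(u, v)
  dimnames(X) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:25))
  d <- nmfDecompose(X, k = 1, seed = 1, max_iter = 2000, tol = 1e-12)
  expect_lt(d@reconstruction_error, 1e-6)
})

test_that("the factorization is deterministic under a fixed seed", {
  X <- as.matrix(exprValues(getSmallSim()$expr))[1:100, 1:60]
  d1 <- nmfDecompose(X, k = 3, seed = 7, max_iter = 50)
  d2 <- nmfDecompose(X, k = 3, seed = 7, max_iter = 50)
  expect_identical(amplitudeMatrix(d1), amplitudeMatrix(d2))
  expect_identical(patternMatrix(d1), patternMatrix(d2))
})

test_that("the Frobenius objective is non-increasing at every update", {
  X <- as.matrix(exprValues(getSmallSim()$expr))[1:150, 1:80]
  d <- nmfDecompose(X, k = 4, seed = 2, max_iter = 120, tol = 0)
  expect_true(all(diff(d@error_trace) <= 1e-10))
})

test_that("rank and degenerate-input preconditions are enforced", {
  X <- matrix(1, 5, 4, dimnames = list(sprintf("g%d", 1:5),
                                       sprintf("c%d", 1:4)))
  expect_error(nmfDecompose(X, k = 4), "out of range")
  expect_error(nmfDecompose(X, k = 0), "out of range")
  X0 <- matrix(0, 5, 4, dimnames = dimnames(X))
  expect_error(nmfDecompose(X0, k = 2), "all-zero")
})

test_that("planted programs are recovered by matched amplitude columns", {
  for (s in 1:3) {
    set.seed(s)
    # 3 disjoint non-negative programs over 60 genes x 45 cells plus noise
    W0 <- matrix(0, 60, 3); H0 <- matrix(0, 3, 45)
    for (j in 1:3) {
      W0[(j - 1) * 20 + 1:20, j] <- runif(20, 0.5, 1)
      H0[j, (j - 1) * 15 + 1:15] <- runif(15, 1, 2)
    }
    X <- W0 %*% H0 + matrix(runif(60 * 45, 0, 0.05), 60)
    dimnames(X) <- list(sprintf("g%02d", 1:60), sprintf("c%02d", 1:45))
    d <- nmfDecompose(X, k = 3, seed = s, max_iter = 1500, tol = 1e-10)
    planted <- lapply(1:3, function(j)
      list(genes = rownames(X)[W0[, j] > 0], weights = W0[W0[, j] > 0, j]))
    names(planted) <- sprintf("prog%d", 1:3)
    assign <- matchPrograms(d, planted)
    expect_length(unique(assign), 3)
    for (pn in names(planted)) {
      v <- numeric(nrow(X)); names(v) <- rownames(X)
      v[planted[[pn]]$genes] <- planted[[pn]]$weights
      w <- amplitudeMatrix(d)[, assign[[pn]]]
      expect_gt(sum(w * v) / sqrt(sum(w^2) * sum(v^2)), 0.9)
    }
  }
})

test_that("predictive power is the pairwise-concordance AUROC", {
  H <- matrix(c(0.9, 0.2, 0.5, 0.1), nrow = 1,
              dimnames = list("Pattern_1", c("c1", "c2", "c3", "c4")))
  d <- methods::new("PatternDecomposition",
                    amplitude = matrix(1, 2, 1, dimnames = list(c("g1", "g2"),
                                                                "Pattern_1")),
                    pattern = H, k = 1L, seed = 1L,
                    reconstruction_error = 0, error_trace = 0,
                    iterations = 1L, converged = TRUE)
  ann <- CellAnnotation(data.frame(cell_id = colnames(H),
                                   cell_type = c("c", "c", "o", "o")))
  expect_equal(predictivePower(d, ann)["Pattern_1", "c"], 0.75)

  # perfect separation
  H2 <- H; H2[1, ] <- c(5, 4, 1, 2)
  d@pattern <- H2
  expect_equal(predictivePower(d, ann)["Pattern_1", "c"], 1.0)
})

test_that("rank-based AUC equals brute-force pair counting", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    pos <- seq_len(n) %in% sample(n, sample(2:(n - 2), 1))
    brute <- {
      sp <- scores[pos]; sn <- scores[!pos]
      pairs <- outer(sp, sn, function(a, b)
        (a > b) + 0.5 * (a == b))
      mean(pairs)
    }
    expect_equal(scRegLoops:::.aucRank(scores, pos), brute, tolerance = 1e-12)
  }
})

test_that("label permutation centres predictive power at one half", {
  sim <- getSmallSim()
  d <- nmfDecompose(sim$expr, k = 3, seed = 1, max_iter = 60)
  df <- as.data.frame(sim$annotation)
  aucs <- numeric(100)
  set.seed(17)
  for (b in 1:100) {
    df$cell_type <- sample(df$cell_type)
    pw <- predictivePower(d, CellAnnotation(df))
    aucs[b] <- mean(pw)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("pattern selection is boundary-inclusive at the power threshold", {
  pw <- matrix(c(0.70, 0.69, 0.5, 0.95), 2, 2,
               dimnames = list(c("Pattern_1", "Pattern_2"), c("a", "b")))
  sel <- selectPatterns(pw)
  expect_equal(sel$a, "Pattern_1")       # 0.70 in, 0.69 out
  expect_equal(sel$b, "Pattern_2")
  expect_equal(selectPatterns(matrix(0.5, 2, 1,
                                     dimnames = list(c("p1", "p2"), "a")))$a,
               character(0))
})

test_that("pattern gene sets follow the top-n and quantile rules", {
  set.seed(8)
  W <- matrix(runif(2000 * 2), ncol = 2,
              dimnames = list(sprintf("g%04d", 1:2000), c("Pattern_1",
                                                          "Pattern_2")))
  d <- methods::new("PatternDecomposition", amplitude = W,
                    pattern = matrix(0.1, 2, 3,
                                     dimnames = list(colnames(W),
                                                     c("c1", "c2", "c3"))),
                    k = 2L, seed = 1L, reconstruction_error = 0,
                    error_trace = 0, iterations = 1L, converged = TRUE)
  gs <- patternGeneSets(d, top_n = 50)
  expect_true(all(vapply(geneSets(gs), function(s) length(setGenes(s)),
                         integer(1)) == 50L))
  # top-n genes are exactly the highest-weight genes
  expect_setequal(setGenes(gs[["Pattern_1"]]),
                  rownames(W)[order(-W[, 1])[1:50]])
  gq <- patternGeneSets(d, quantile = 0.99)
  expect_true(all(vapply(geneSets(gq), function(s) length(setGenes(s)),
                         integer(1)) == 20L))
  expect_warning(gcap <- patternGeneSets(d, top_n = 5000), "capped")
  expect_length(setGenes(gcap[["Pattern_1"]]), 2000)
})

test_that("amplitude columns with few non-zeros reduce to those genes", {
  W <- matrix(0, 30, 1, dimnames = list(sprintf("g%02d", 1:30), "Pattern_1"))
  W[1:10, 1] <- runif(10, 0.5, 1)
  d <- methods::new("PatternDecomposition", amplitude = W,
                    pattern = matrix(0.1, 1, 2,
                                     dimnames = list("Pattern_1",
                                                     c("c1", "c2"))),
                    k = 1L, seed = 1L, reconstruction_error = 0,
                    error_trace = 0, iterations = 1L, converged = TRUE)
  expect_setequal(setGenes(patternGeneSets(d, top_n = 10)[["Pattern_1"]]),
                  sprintf("g%02d", 1:10))
})
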