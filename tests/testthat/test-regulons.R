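# expression vector that puts chosen genes at chosen descending ranks
exprWithRanks <- function(G, rank_of_gene) {
  x <- rev(seq_len(G)) / G          # strictly decreasing: rank i = gene i
  names(x) <- sprintf("g%03d", seq_len(G))
  x
}

rasFixture <- function(G, regulon_ranks, top_fraction) {
  x <- exprWithRanks(G)
  v <- matrix(x, ncol = 1, dimnames = list(names(x), "c1"))
  reg <- GeneSetCollection(list(GeneSet("R", "regulon_targets",
                                        names(x)[regulon_ranks])))
  computeRAS(ExpressionMatrix(v), reg, top_fraction)["R", "c1"]
}

test_that("RAS attains its boundary values for extreme rankings", {
  # all 5 targets in the top 5 ranks with threshold 5 -> 1
  expect_equal(rasFixture(100, 1:5, 0.05), 1.0)
  # no target inside the window -> 0
  expect_equal(rasFixture(100, 96:100, 0.05), 0.0)
})

test_that("RAS matches the step-sum recovery area", {
  # 5 targets at ranks 2,4,6,8,10, window 10 of 200 genes:
  # area 25 over maximal 40
  expect_equal(rasFixture(200, c(2, 4, 6, 8, 10), 0.05), 25 / 40)
})

test_that("RAS equals the brute-force recovery computation", {
  set.seed(21)
  for (rep in 1:5) {
    G <- 150
    v <- matrix(round(abs(rnorm(G * 4)), 2), nrow = G,
                dimnames = list(sprintf("g%03d", 1:G), sprintf("c%d", 1:4)))
    em <- ExpressionMatrix(v)
    genes <- sample(rownames(v), 12)
    reg <- GeneSetCollection(list(GeneSet("R", "regulon_targets", genes)))
    ras <- computeRAS(em, reg, 0.1)
    for (j in 1:4)
      expect_equal(ras["R", j],
                   bruteRAS(v[, j], rownames(v), genes, 0.1, j),
                   tolerance = 1e-12)
  }
})

test_that("regulons absent from the matrix give NA rows with a warning", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  reg <- GeneSetCollection(list(GeneSet("gone", "regulon_targets", "zz")))
  expect_warning(ras <- computeRAS(ExpressionMatrix(v), reg), "no genes")
  expect_true(all(is.na(ras)))
})

rssCase <- function(ras_row, types) {
  ras <- matrix(ras_row, nrow = 1,
                dimnames = list("R", sprintf("c%03d", seq_along(ras_row))))
  ann <- CellAnnotation(data.frame(cell_id = colnames(ras),
                                   cell_type = types))
  computeRSS(ras, ann)
}

test_that("RSS boundary cases follow the 1 - JSD definition", {
  # activity uniform over exactly the type's cells -> identical
  # distributions -> RSS 1
  r <- rssCase(c(1, 1, 0, 0), c("C", "C", "o", "o"))
  expect_equal(r["R", "C"], 1.0)
  # disjoint supports -> JSD 1 -> RSS 0
  expect_equal(r["R", "o"], 0.0)
})

test_that("uniform activity over half-support type gives the closed form", {
  # JSD(uniform over 2n, uniform over n) = 1 - 0.5*log2(3) + ... = 0.31128
  r <- rssCase(rep(1, 40), rep(c("C", "o"), each = 20))
  expect_equal(r["R", "C"], 1 - 0.31128, tolerance = 1e-4)
})

test_that("JSD is symmetric and bounded in [0, 1] with log base 2", {
  set.seed(31)
  for (rep in 1:25) {
    n <- 30
    p <- runif(n); p <- p / sum(p)
    q <- runif(n) * rbinom(n, 1, 0.7); q <- q / sum(q)
    if (!is.finite(sum(q))) next
    j1 <- scRegLoops:::.jsd(p, q); j2 <- scRegLoops:::.jsd(q, p)
    expect_equal(j1, j2, tolerance = 1e-12)
    expect_gte(j1, 0); expect_lte(j1, 1 + 1e-12)
  }
})

test_that("all-zero RAS rows yield missing RSS with a warning", {
  expect_warning(r <- rssCase(c(0, 0, 0, 0), c("C", "C", "o", "o")),
                 "all-zero")
  expect_true(all(is.na(r)))
})

test_that("regulon selection applies the RSS and Z gates", {
  sim <- getSmallSim()
  act <- suppressWarnings(scoreRegulons(sim$expr, sim$regulons,
                                        sim$annotation))
  sel <- selectRegulons(act, "cell_specific")
  for (rn in grep("^TF_disease", names(sim$truth$planted_regulons),
                  invert = TRUE, value = TRUE)) {
    tt <- sim$truth$planted_regulons[[rn]]$active_types
    picked <- names(sel)[vapply(sel, function(x) rn %in% x, logical(1))]
    expect_equal(picked, tt)
  }
  # RSS below the gate is never selected regardless of Z
  fake <- act
  fake@rss[] <- 0.09
  expect_true(all(lengths(selectRegulons(fake, "cell_specific")) == 0))
})

test_that("Z standardization refuses fewer than 3 cell types", {
  v <- matrix(abs(rnorm(40)), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:4)))
  ann <- CellAnnotation(data.frame(cell_id = colnames(v),
                                   cell_type = c("a", "a", "b", "b")))
  reg <- GeneSetCollection(list(GeneSet("R", "regulon_targets",
                                        rownames(v)[1:3])))
  act <- suppressWarnings(scoreRegulons(ExpressionMatrix(v), reg, ann))
  expect_error(selectRegulons(act, "cell_specific"), "at least 3")
})

test_that("condition-wise RSS fold change detects disease-only regulons", {
  sim <- getSmallSim()
  act <- suppressWarnings(scoreRegulons(sim$expr, sim$regulons,
                                        sim$annotation))
  dis <- grep("^TF_disease", names(sim$truth$planted_regulons), value = TRUE)
  sel <- selectRegulons(act, "disease")
  for (rn in dis) {
    tt <- sim$truth$planted_regulons[[rn]]$active_types
    fc <- rssLog2FC(act)
    expect_gt(fc[rn, tt], 1)
    expect_true(rn %in% sel[[tt]])
  }
})

test_that("identical activity across conditions gives log2FC 0, zero RSS clips", {
  # same cells in both conditions by construction: symmetric design
  set.seed(4)
  v <- matrix(abs(rnorm(50 * 20)), 50,
              dimnames = list(sprintf("g%03d", 1:50), sprintf("c%02d", 1:20)))
  v2 <- cbind(v, v)
  colnames(v2) <- sprintf("c%02d", 1:40)
  ann <- CellAnnotation(data.frame(
    cell_id = colnames(v2),
    cell_type = rep(rep(c("a", "b"), each = 10), 2),
    condition = rep(c("disease", "control"), each = 20)))
  reg <- GeneSetCollection(list(GeneSet("R", "regulon_targets",
                                        sprintf("g%03d", 1:5))))
  fc <- rssConditionFoldChange(ExpressionMatrix(v2), reg, ann)
  expect_equal(unname(fc["R", ]), c(0, 0), tolerance = 1e-12)
})

test_that("RSS is maximal at the planted type for planted regulons", {
  for (s in 1:3) {
    sim <- getSmallSim(s)
    act <- suppressWarnings(scoreRegulons(sim$expr, sim$regulons,
                                          sim$annotation))
    rss <- rssMatrix(act)
    for (rn in grep("^TF_disease", rownames(rss), invert = TRUE,
                    value = TRUE)) {
      tt <- sim$truth$planted_regulons[[rn]]$active_types
      expect_equal(colnames(rss)[which.max(rss[rn, ])], tt)
    }
  }
})
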