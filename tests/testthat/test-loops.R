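# exhaustive oracle: probability that a random n-subset of 1..N overlaps the
# first M elements in at least k positions, by enumeration of all draws
enumPloop <- function(k, M, n, N) {
  draws <- combn(N, n)
  mean(colSums(draws <= M) >= k)
}

test_that("P_loop boundary and worked cases match enumeration", {
  expect_equal(hypergeomPloop(0, 5, 5, 10), 1.0)
  expect_equal(hypergeomPloop(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeomPloop(3, 10, 5, 20), 0.5, tolerance = 1e-12)
})

test_that("P_loop agrees with exhaustive enumeration on small universes", {
  for (N in c(5, 8)) for (M in 1:N) for (n in 1:N)
    for (k in 0:min(M, n))
      expect_equal(hypergeomPloop(k, M, n, N), enumPloop(k, M, n, N),
                   tolerance = 1e-12)
})

test_that("the exposed PMF is the closed-form point mass", {
  for (N in c(10, 20)) for (M in c(3, 7)) for (n in c(2, 6))
    for (k in 0:min(M, n))
      expect_equal(hypergeomPmf(k, M, n, N),
                   choose(M, k) * choose(N - M, n - k) / choose(N, n),
                   tolerance = 1e-12)
})

test_that("P_loop is symmetric in the two set sizes, monotone in k", {
  for (rep in 1:10) {
    set.seed(rep)
    N <- sample(50:500, 1); M <- sample(N, 1); n <- sample(N, 1)
    ks <- 0:min(M, n)
    p1 <- hypergeomPloop(ks, M, n, N)
    p2 <- hypergeomPloop(ks, n, M, N)
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_true(all(diff(p1) <= 1e-15))
  }
})

test_that("parameter violations are rejected with the constraint named", {
  expect_error(hypergeomPloop(1, 11, 5, 10), "M <= N")
  expect_error(hypergeomPloop(1, 5, 11, 10), "n <= N")
  expect_error(hypergeomPloop(6, 5, 7, 10), "k <= min")
  expect_error(hypergeomPloop(-1, 5, 5, 10), "k >= 0")
})

makeSets <- function(genes_list, kind) {
  lapply(seq_along(genes_list), function(i)
    GeneSet(names(genes_list)[i], kind, genes_list[[i]]))
}

test_that("identical sets form a ternary loop, disjoint sets never do", {
  universe <- sprintf("g%04d", 1:2000)
  common <- universe[1:30]
  g <- buildLoops(
    list(tA = setNames(makeSets(list(P1 = common), "pattern_top_genes"), "P1")),
    list(tA = setNames(makeSets(list(R1 = common), "regulon_targets"), "R1")),
    list(tA = setNames(makeSets(list(D1 = common), "deg_set"), "D1")),
    universe)
  expect_equal(nrow(loopTable(g)), 1)
  expect_true(all(loopEdges(g)$p_loop < 1e-10))

  g2 <- buildLoops(
    list(tA = setNames(makeSets(list(P1 = universe[1:30]),
                                "pattern_top_genes"), "P1")),
    list(tA = setNames(makeSets(list(R1 = universe[31:60]),
                                "regulon_targets"), "R1")),
    list(tA = setNames(makeSets(list(D1 = universe[61:90]), "deg_set"),
                       "D1")),
    universe)
  expect_equal(nrow(loopTable(g2)), 0)
  expect_true(all(loopEdges(g2)$k_overlap == 0))
  expect_true(all(loopEdges(g2)$p_loop == 1))
})

test_that("within-kind pairs are never tested", {
  universe <- sprintf("g%04d", 1:500)
  pats <- setNames(makeSets(list(P1 = universe[1:20], P2 = universe[1:20]),
                            "pattern_top_genes"), c("P1", "P2"))
  g <- buildLoops(list(tA = pats),
                  list(tA = setNames(makeSets(list(R1 = universe[1:20]),
                                              "regulon_targets"), "R1")),
                  list(tA = setNames(makeSets(list(D1 = universe[1:20]),
                                              "deg_set"), "D1")),
                  universe)
  expect_false(any(g@edges$kinds == "pattern-pattern"))
  expect_equal(sort(unique(g@edges$kinds)),
               c("pattern-deg", "pattern-regulon", "regulon-deg"))
})

test_that("random independent sets respect the alpha gate rate", {
  set.seed(55)
  N <- 2000; universe <- sprintf("g%04d", 1:N)
  rej <- logical(1000)
  for (i in seq_len(1000)) {
    a <- sample(universe, 40); b <- sample(universe, 30)
    k <- length(intersect(a, b))
    rej[i] <- hypergeomPloop(k, 40, 30, N) < 0.05
  }
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(rej), 0.05 + 2 * se)
})

test_that("pathway annotation marks membership and summarizes coverage", {
  universe <- sprintf("g%04d", 1:2000)
  common <- c("SPP1", universe[1:29])
  g <- buildLoops(
    list(tA = setNames(makeSets(list(P1 = common), "pattern_top_genes"), "P1")),
    list(tA = setNames(makeSets(list(R1 = common), "regulon_targets"), "R1")),
    list(tA = setNames(makeSets(list(D1 = common), "deg_set"), "D1")),
    c(universe, "SPP1"))
  pw <- GeneSetCollection(c(
    list(GeneSet("SPP1_pathway", "pathway", "SPP1")),
    lapply(1:56, function(i)
      GeneSet(sprintf("pw%02d", i), "pathway",
              if (i <= 17) universe[i] else sprintf("zz%03d", i)))))
  ga <- annotatePathways(g, pw)
  expect_true("SPP1_pathway" %in% ga@node_pathways[["tA|P1"]])
  expect_false("pw40" %in% unlist(ga@node_pathways))
  # 18 of the 57 supplied pathways touch loop nodes
  expect_equal(ga@pathway_summary$n_touched, 18)
  expect_equal(ga@pathway_summary$fraction, 18 / 57, tolerance = 1e-12)

  expect_warning(annotatePathways(g, GeneSetCollection(list())), "empty")
})

test_that("graph export writes valid typed GraphML and edge TSVs", {
  skip_if_not_installed("xml2")
  universe <- sprintf("g%04d", 1:2000)
  common <- universe[1:30]
  g <- buildLoops(
    list(tA = setNames(makeSets(list(P1 = common), "pattern_top_genes"), "P1")),
    list(tA = setNames(makeSets(list(R1 = common), "regulon_targets"), "R1")),
    list(tA = setNames(makeSets(list(D1 = common), "deg_set"), "D1")),
    universe)
  p <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(g, p, "graphml")
  doc <- xml2::read_xml(p)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, ".//d1:node", ns), 3)
  expect_length(xml2::xml_find_all(doc, ".//d1:edge", ns), 3)

  # empty graph is still a valid document
  g0 <- buildLoops(list(), list(), list(), universe)
  exportGraph(g0, p, "graphml")
  expect_length(xml2::xml_find_all(xml2::read_xml(p), ".//d1:node",
                                   xml2::xml_ns(doc)), 0)

  # edge TSV round-trips
  pt <- withr::local_tempfile(fileext = ".tsv")
  exportGraph(g, pt, "edge_tsv")
  back <- read.delim(pt)
  expect_equal(back$node_1, g@edges$node_1)
  expect_equal(back$p_loop, g@edges$p_loop, tolerance = 1e-12)
  expect_equal(back$k_overlap, g@edges$k_overlap)
})

test_that("planted ternary loops are recovered end to end", {
  found <- total <- 0
  for (s in 1:3) {
    sim <- getSmallSim(s)
    res <- suppressWarnings(suppressMessages(runPipeline(sim)))
    lt <- loopTable(res$loops_cell)
    pl <- sim$truth$planted_loops
    for (i in seq_len(nrow(pl))) {
      total <- total + 1
      found <- found + any(lt$regulon == pl$regulon[i] &
                             lt$cell_type == pl$cell_type[i])
    }
  }
  expect_gte(found / total, 0.9)
})
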