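#' Hypergeometric overlap probability of two gene sets (P_loop)
#'
#' Upper-tail probability P(X >= k) that two gene sets of sizes M and n drawn
#' from a universe of N genes share at least k members, under the
#' hypergeometric(N, M, n) null. The tail (standard over-representation
#' convention) is what gates loop edges; the point-mass
#' P(X = k) = C(M, k) C(N - M, n - k) / C(N, n) is exposed separately as
#' [hypergeomPmf()] for exact comparison. Both are evaluated through the
#' log-space hypergeometric routines of the stats package. Vectorized.
#'
#' @param k observed overlap, `0 <= k <= min(M, n)`.
#' @param M,n the two set sizes, each at most N.
#' @param N universe size (total genes).
#' @return P(X >= k), in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeomPloop <- function(k, M, n, N) {
  .checkHyper(k, M, n, N)
  phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' @describeIn hypergeomPloop the hypergeometric point mass P(X = k).
#' @export
hypergeomPmf <- function(k, M, n, N) {
  .checkHyper(k, M, n, N)
  dhyper(k, M, N - M, n)
}

.checkHyper <- function(k, M, n, N) {
  if (any(M > N)) stop("constraint violated: M <= N")
  if (any(n > N)) stop("constraint violated: n <= N")
  if (any(k < 0)) stop("constraint violated: k >= 0")
  if (any(k > pmin(M, n))) stop("constraint violated: k <= min(M, n)")
  invisible(TRUE)
}

#' Build cell-specific TF regulatory loops
#'
#' Within each cell type, every cross-kind pair among the selected pattern
#' gene sets, selected regulon target sets and DEG sets is tested for
#' overlap enrichment with [hypergeomPloop()] against the common gene
#' universe; within-kind pairs are not tested. Edges with `p_loop < alpha`
#' (strict, unadjusted by default) are kept, and a ternary loop is emitted
#' for every (pattern, regulon, DEG set) triple whose three pairwise edges
#' are all kept. Sets are restricted to the universe before testing; empty
#' families for a type simply yield no loops there.
#'
#' @param patterns_by_type,regulons_by_type named lists (cell type -> list
#'   of [GeneSet-class]) of the selected patterns and regulons; see
#'   [splitSetsByType()] for assembling them from selection maps.
#' @param deg_sets a [GeneSetCollection-class] of per-type DEG sets (set
#'   names are cell types), or a named list of GeneSet lists like the other
#'   two arguments.
#' @param universe character vector of all genes (N of the test).
#' @param alpha significance gate on `p_loop` (default 0.05).
#' @param disease_flag mark the graph as built from disease-mode selections.
#' @param p_adjust `"none"` (default, the raw gate) or `"BH"` to gate on
#'   Benjamini-Hochberg adjusted edge p-values instead.
#' @return a [LoopGraph-class].
#' @export
buildLoops <- function(patterns_by_type, regulons_by_type, deg_sets, universe,
                       alpha = 0.05, disease_flag = FALSE,
                       p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  N <- length(unique(universe))
  if (N == 0) stop("empty gene universe")
  degs_by_type <- if (methods::is(deg_sets, "GeneSetCollection")) {
    sets <- geneSets(deg_sets)
    setNames(lapply(sets, list), names(sets))
  } else deg_sets
  types <- unique(c(names(patterns_by_type), names(regulons_by_type),
                    names(degs_by_type)))
  nodes <- list(); node_genes <- list(); edges <- list(); loops <- list()
  kind_of <- c(pattern = "pattern", regulon = "regulon", deg = "deg_set")
  for (ct in types) {
    fams <- list(
      pattern = .loopFamily(patterns_by_type[[ct]], universe),
      regulon = .loopFamily(regulons_by_type[[ct]], universe),
      deg = .loopFamily(degs_by_type[[ct]], universe))
    if (any(lengths(fams) == 0)) {
      message(sprintf("cell type %s lacks a non-empty gene-set family: no loops",
                      ct))
    }
    for (fam in names(fams)) {
      for (nm in names(fams[[fam]])) {
        id <- sprintf("%s|%s", ct, nm)
        nodes[[id]] <- data.frame(id = id, name = nm, kind = kind_of[[fam]],
                                  cell_type = ct,
                                  size = length(fams[[fam]][[nm]]),
                                  stringsAsFactors = FALSE)
        node_genes[[id]] <- fams[[fam]][[nm]]
      }
    }
    pair_p <- function(fam1, fam2) {
      res <- list()
      for (n1 in names(fams[[fam1]])) for (n2 in names(fams[[fam2]])) {
        g1 <- fams[[fam1]][[n1]]; g2 <- fams[[fam2]][[n2]]
        k <- length(intersect(g1, g2))
        res[[sprintf("%s~%s", n1, n2)]] <- data.frame(
          node_1 = sprintf("%s|%s", ct, n1), node_2 = sprintf("%s|%s", ct, n2),
          cell_type = ct, kinds = sprintf("%s-%s", fam1, fam2),
          k_overlap = k, M = length(g1), n = length(g2), N = N,
          p_loop = hypergeomPloop(k, length(g1), length(g2), N),
          pmf = hypergeomPmf(k, length(g1), length(g2), N),
          stringsAsFactors = FALSE)
      }
      res
    }
    ed <- c(pair_p("pattern", "regulon"), pair_p("pattern", "deg"),
            pair_p("regulon", "deg"))
    if (length(ed)) edges[[ct]] <- do.call(rbind, ed)
    # ternary loops: all three pairwise edges significant
    if (all(lengths(fams) > 0)) {
      etab <- edges[[ct]]
      padj <- if (p_adjust == "BH") stats::p.adjust(etab$p_loop, "BH")
              else etab$p_loop
      sig <- function(a, b) {
        i <- (etab$node_1 == a & etab$node_2 == b) |
             (etab$node_1 == b & etab$node_2 == a)
        any(i & padj < alpha)
      }
      for (pn in names(fams$pattern)) for (rn in names(fams$regulon))
        for (dn in names(fams$deg)) {
          a <- sprintf("%s|%s", ct, pn); b <- sprintf("%s|%s", ct, rn)
          d <- sprintf("%s|%s", ct, dn)
          if (sig(a, b) && sig(a, d) && sig(b, d)) {
            i <- (etab$node_1 %in% c(a, b, d)) & (etab$node_2 %in% c(a, b, d))
            loops[[length(loops) + 1L]] <- data.frame(
              pattern = pn, regulon = rn, deg_set = dn, cell_type = ct,
              max_p = max(etab$p_loop[i]), stringsAsFactors = FALSE)
          }
        }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_1 = character(), node_2 = character(),
               cell_type = character(), kinds = character(),
               k_overlap = integer(), M = integer(), n = integer(),
               N = integer(), p_loop = numeric(), pmf = numeric(),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  padj_all <- if (nrow(edges) && p_adjust == "BH")
    stats::p.adjust(edges$p_loop, "BH") else edges$p_loop
  edges$kept <- padj_all < alpha
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(id = character(), name = character(), kind = character(),
               cell_type = character(), size = integer(),
               stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  loops <- if (length(loops)) do.call(rbind, loops) else
    data.frame(pattern = character(), regulon = character(),
               deg_set = character(), cell_type = character(),
               max_p = numeric(), stringsAsFactors = FALSE)
  methods::new("LoopGraph", nodes = nodes, node_genes = node_genes,
               edges = edges, loops = loops, alpha = alpha,
               universe_size = as.integer(N), disease_flag = disease_flag,
               node_pathways = list(), pathway_summary = list())
}

# normalize a per-type family argument (GeneSetCollection / list of GeneSet /
# NULL) into a named list of universe-restricted gene vectors, dropping sets
# that end up empty (empty sets cannot enter an overlap test)
.loopFamily <- function(x, universe) {
  sets <- if (is.null(x)) list()
  else if (methods::is(x, "GeneSetCollection")) geneSets(x)
  else if (methods::is(x, "GeneSet")) list(x)
  else x
  if (length(sets))
    names(sets) <- vapply(sets, setName, character(1))
  out <- lapply(sets, function(s) intersect(setGenes(s), universe))
  out[lengths(out) > 0]
}

#' Assemble per-type gene-set families from a selection map
#'
#' Turns a selection map (cell type -> set names, as produced by
#' [selectPatterns()] or [selectRegulons()]) and the collection holding
#' those sets into the per-type list-of-GeneSet structure [buildLoops()]
#' consumes.
#'
#' @param collection a [GeneSetCollection-class].
#' @param assignment named list: cell type -> character vector of set names.
#' @return named list: cell type -> named list of [GeneSet-class].
#' @export
splitSetsByType <- function(collection, assignment) {
  out <- lapply(assignment, function(nms) {
    nms <- intersect(nms, geneSetNames(collection))
    setNames(lapply(nms, function(nm) collection[[nm]]), nms)
  })
  out[lengths(out) > 0]
}

#' Annotate loop nodes with pathway membership
#'
#' Each node of the graph gains the list of supplied pathways sharing at
#' least `min_overlap` genes with it; the summary records the fraction of
#' supplied pathways touched by at least one node participating in a
#' ternary loop.
#'
#' @param graph a [LoopGraph-class].
#' @param pathways a [GeneSetCollection-class] of `pathway` sets (e.g.
#'   ligand-receptor pathway memberships exported from a communication
#'   analysis).
#' @param min_overlap minimum shared genes to annotate (default 1).
#' @return the graph with `node_pathways` and `pathway_summary` filled in.
#' @export
annotatePathways <- function(graph, pathways, min_overlap = 1) {
  stopifnot(methods::is(graph, "LoopGraph"))
  if (!length(geneSets(pathways))) {
    warning("empty pathway collection: nothing annotated")
    return(graph)
  }
  pw <- lapply(geneSets(pathways), setGenes)
  ann <- lapply(graph@node_genes, function(g) {
    hits <- vapply(pw, function(p) length(intersect(g, p)) >= min_overlap,
                   logical(1))
    names(pw)[hits]
  })
  # nodes participating in at least one ternary loop
  lt <- graph@loops
  loop_ids <- unique(c(sprintf("%s|%s", lt$cell_type, lt$pattern),
                       sprintf("%s|%s", lt$cell_type, lt$regulon),
                       sprintf("%s|%s", lt$cell_type, lt$deg_set)))
  touched <- unique(unlist(ann[intersect(loop_ids, names(ann))]))
  graph@node_pathways <- ann
  graph@pathway_summary <- list(
    n_pathways = length(pw), n_touched = length(touched),
    fraction = length(touched) / length(pw), touched = sort(touched))
  graph
}

#' Export a loop graph
#'
#' `graphml` writes a typed graph (node kinds pattern / regulon / deg_set,
#' plus pathway nodes when annotated) via igraph; `edge_tsv` writes the
#' plain edge table. Node ordering is deterministic (sorted ids).
#'
#' @param graph a [LoopGraph-class].
#' @param path output file.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param kept_only export only edges passing the alpha gate (default TRUE
#'   for graphml, FALSE for the TSV which is a full record).
#' @return invisibly, `path`.
#' @export
exportGraph <- function(graph, path, format = c("graphml", "edge_tsv"),
                        kept_only = NULL) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    ed <- graph@edges
    if (isTRUE(kept_only)) ed <- ed[ed$kept, , drop = FALSE]
    write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(kept_only)) kept_only <- TRUE
  nodes <- graph@nodes[, c("id", "kind", "cell_type", "size")]
  ed <- graph@edges
  if (kept_only) ed <- ed[ed$kept, , drop = FALSE]
  el <- ed[, c("node_1", "node_2", "p_loop", "k_overlap")]
  if (length(graph@node_pathways)) {
    pw_nodes <- sort(unique(unlist(graph@node_pathways)))
    if (length(pw_nodes)) {
      nodes <- rbind(nodes, data.frame(id = pw_nodes, kind = "pathway",
                                       cell_type = NA_character_,
                                       size = NA_integer_,
                                       stringsAsFactors = FALSE))
      for (id in names(graph@node_pathways)) {
        hit <- graph@node_pathways[[id]]
        if (length(hit))
          el <- rbind(el, data.frame(node_1 = id, node_2 = hit,
                                     p_loop = NA_real_, k_overlap = NA_integer_,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
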