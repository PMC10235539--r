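#' @import methods
#' @importFrom stats phyper dhyper pnorm quantile rlnorm rnbinom runif setNames
#' @importFrom utils read.delim write.table combn head
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.GENESET_KINDS <- c("known_marker", "regulon_targets", "pattern_top_genes",
                    "deg_set", "pathway")

#' Gene by cell expression container
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single non-negative `logexpr` assay of log-normalized expression with
#' unique gene symbols as row names and unique cell barcodes as column names.
#' All downstream scoring (CESG, DE, NMF patterns, RAS) consumes this class.
#'
#' @slot ... inherited from `SummarizedExperiment`; the only assay is
#'   `logexpr`, a dense or sparse genes x cells matrix.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!identical(a, "logexpr"))
    return("assay must be a single matrix named 'logexpr'")
  v <- SummarizedExperiment::assay(object, "logexpr")
  g <- rownames(v); s <- colnames(v)
  if (is.null(g) || is.null(s))
    return("gene (row) and cell (column) ids are required")
  if (anyDuplicated(g))
    return(sprintf("duplicate gene ids: %s",
                   paste(unique(g[duplicated(g)]), collapse = ", ")))
  if (anyDuplicated(s))
    return(sprintf("duplicate cell ids: %s",
                   paste(unique(s[duplicated(s)]), collapse = ", ")))
  mn <- if (methods::is(v, "sparseMatrix")) min(v@x, 0) else min(v)
  if (is.na(mn) || mn < 0)
    return("expression values must be non-negative and non-missing")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values non-negative genes x cells matrix (base or `Matrix`) of
#'   log-normalized expression.
#' @param gene_ids,cell_ids unique identifiers; default to the dimnames of
#'   `values`.
#' @param raw_counts if `TRUE`, `values` are raw counts and a library-size
#'   normalization (counts scaled to a common library size of 1e4) followed by
#'   `log1p` is applied once here.
#' @return validated [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, gene_ids = rownames(values),
                             cell_ids = colnames(values), raw_counts = FALSE) {
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required")
  if (length(gene_ids) != nrow(values))
    stop(sprintf("gene id list has %d entries but matrix has %d rows",
                 length(gene_ids), nrow(values)))
  if (length(cell_ids) != ncol(values))
    stop(sprintf("cell id list has %d entries but matrix has %d columns",
                 length(cell_ids), ncol(values)))
  dimnames(values) <- list(as.character(gene_ids), as.character(cell_ids))
  if (raw_counts) {
    lib <- colSums(values)
    if (any(lib == 0)) stop("cell with zero total counts cannot be normalized")
    values <- log1p(sweep(as.matrix(values), 2, lib, "/") * 1e4)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = values))
  out <- methods::as(se, "ExpressionMatrix")
  methods::validObject(out)
  out
}

#' @describeIn ExpressionMatrix the expression values (genes x cells)
#' @param x an `ExpressionMatrix`
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "logexpr")

#' @describeIn ExpressionMatrix gene symbols (row ids)
#' @export
geneIds <- function(x) rownames(x)

#' @describeIn ExpressionMatrix cell barcodes (column ids)
#' @export
cellIds <- function(x) colnames(x)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s)\n",
              nrow(object), ncol(object),
              class(SummarizedExperiment::assay(object))[1]))
})

#' Per-cell annotation table
#'
#' A [S4Vectors::DataFrame] subclass with one row per cell and columns
#' `cell_id`, `cell_type`, `condition`, `region`, `donor`. Optional columns
#' missing at construction are filled with the single level `"unspecified"`.
#'
#' @export
setClass("CellAnnotation", contains = "DFrame")

.ANN_COLS <- c("cell_id", "cell_type", "condition", "region", "donor")

setValidity("CellAnnotation", function(object) {
  miss <- setdiff(.ANN_COLS, colnames(object))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(object$cell_id))
    return(sprintf("duplicate cell_id: %s",
                   paste(unique(object$cell_id[duplicated(object$cell_id)]),
                         collapse = ", ")))
  for (col in setdiff(.ANN_COLS, "cell_id")) {
    if (!is.factor(object[[col]]))
      return(sprintf("column %s must be a factor", col))
    if (nlevels(object[[col]]) < 1)
      return(sprintf("column %s has no levels", col))
  }
  TRUE
})

#' Construct a CellAnnotation
#'
#' @param df data.frame-like with at least `cell_id` and `cell_type`;
#'   `condition`, `region` and `donor` are optional.
#' @return validated [CellAnnotation-class].
#' @export
CellAnnotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("cell_id", "cell_type"))
    if (!col %in% colnames(df)) stop(sprintf("missing mandatory column: %s", col))
  for (col in setdiff(.ANN_COLS, c("cell_id", "cell_type")))
    if (!col %in% colnames(df)) df[[col]] <- "unspecified"
  df$cell_id <- trimws(as.character(df$cell_id))
  for (col in setdiff(.ANN_COLS, "cell_id")) {
    # a pre-set factor keeps its level order (e.g. disease before control);
    # plain character columns get alphabetical levels
    df[[col]] <- if (is.factor(df[[col]]))
      factor(trimws(as.character(df[[col]])),
             levels = trimws(levels(df[[col]])))
    else factor(trimws(as.character(df[[col]])))
  }
  out <- S4Vectors::DataFrame(df[, .ANN_COLS, drop = FALSE])
  rownames(out) <- df$cell_id
  out <- methods::as(out, "CellAnnotation")
  methods::validObject(out)
  out
}

#' @describeIn CellAnnotation cell-type labels (factor, one per cell)
#' @param x a `CellAnnotation`
#' @export
cellTypes <- function(x) x$cell_type

#' @describeIn CellAnnotation condition labels (factor, one per cell)
#' @export
conditions <- function(x) x$condition

setMethod("show", "CellAnnotation", function(object) {
  cat(sprintf(
    "CellAnnotation: %d cells | %d types | %d conditions | %d regions | %d donors\n",
    nrow(object), nlevels(object$cell_type), nlevels(object$condition),
    nlevels(object$region), nlevels(object$donor)))
})

#' Named gene set
#'
#' @slot name set identifier.
#' @slot kind one of `known_marker`, `regulon_targets`, `pattern_top_genes`,
#'   `deg_set`, `pathway`.
#' @slot genes character vector of unique gene symbols (case-sensitive).
#' @export
setClass("GeneSet", representation(name = "character", kind = "character",
                                   genes = "character"))

setValidity("GeneSet", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (!object@kind %in% .GENESET_KINDS)
    return(sprintf("kind must be one of: %s", paste(.GENESET_KINDS, collapse = ", ")))
  if (anyDuplicated(object@genes))
    return(sprintf("duplicate genes in set %s", object@name))
  TRUE
})

#' Construct a GeneSet
#' @param name,kind,genes see [GeneSet-class]; duplicate genes are dropped
#'   with a warning (set semantics).
#' @export
GeneSet <- function(name, kind, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning(sprintf("duplicate genes in set %s collapsed", name))
    genes <- unique(genes)
  }
  methods::new("GeneSet", name = name, kind = kind, genes = genes)
}

#' @describeIn GeneSet member genes
#' @param x a `GeneSet`
#' @export
setGenes <- function(x) x@genes

#' @describeIn GeneSet set name
#' @export
setName <- function(x) x@name

#' @describeIn GeneSet set kind
#' @export
setKind <- function(x) x@kind

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet %s [%s]: %d genes\n", object@name, object@kind,
              length(object@genes)))
})

#' Collection of named gene sets
#'
#' @slot sets named list of [GeneSet-class]; list names equal set names.
#' @slot universe optional explicit gene universe (character, may be empty).
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets)) {
    if (!all(vapply(object@sets, methods::is, logical(1), "GeneSet")))
      return("all elements must be GeneSet objects")
    nm <- vapply(object@sets, setName, character(1))
    if (anyDuplicated(nm))
      return(sprintf("duplicate set names: %s",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (!identical(unname(names(object@sets)), unname(nm)))
      return("list names must match set names")
  }
  TRUE
})

#' Construct a GeneSetCollection
#' @param sets list of [GeneSet-class] objects.
#' @param universe optional gene universe.
#' @export
GeneSetCollection <- function(sets = list(), universe = character()) {
  names(sets) <- vapply(sets, setName, character(1))
  methods::new("GeneSetCollection", sets = sets, universe = universe)
}

#' @describeIn GeneSetCollection the list of gene sets
#' @param x a `GeneSetCollection`
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection names of the member sets
#' @export
geneSetNames <- function(x) names(x@sets)

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  kinds <- table(vapply(object@sets, setKind, character(1)))
  cat(sprintf("GeneSetCollection: %d sets (%s)%s\n", length(object@sets),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
              if (length(object@universe))
                sprintf(", universe of %d genes", length(object@universe)) else ""))
})

#' Cell-type abundance table (ACT)
#'
#' ACT(c, k) is the observed/expected abundance of cell type c in condition
#' level k: the within-level proportion of the type over its overall
#' proportion. ACT > 1 marks enrichment of the type under that level.
#'
#' @slot act cell types x levels matrix of abundance ratios.
#' @slot counts the underlying contingency table of cell counts.
#' @slot field the annotation column the levels come from.
#' @export
setClass("ACTTable", representation(act = "matrix", counts = "matrix",
                                    field = "character"))

setValidity("ACTTable", function(object) {
  if (!identical(dim(object@act), dim(object@counts)))
    return("act and counts dimensions differ")
  if (any(object@act < 0, na.rm = TRUE)) return("ACT values must be >= 0")
  TRUE
})

setMethod("show", "ACTTable", function(object) {
  cat(sprintf("ACTTable by '%s': %d cell types x %d levels\n", object@field,
              nrow(object@act), ncol(object@act)))
  print(round(object@act, 2))
})

#' @describeIn ACTTable the ACT ratio matrix
#' @param x an `ACTTable`
#' @export
actValues <- function(x) x@act

#' @describeIn ACTTable the underlying cell-count contingency table
#' @export
actCounts <- function(x) x@counts

#' Non-negative pattern decomposition
#'
#' Result of a seeded multiplicative-update NMF of the expression matrix into
#' an amplitude matrix A (genes x k, gene weights) and a pattern matrix P
#' (k x cells, sample weights) with A %*% P approximating the input.
#'
#' @slot amplitude genes x k non-negative gene-weight matrix.
#' @slot pattern k x cells non-negative sample-weight matrix.
#' @slot k number of patterns.
#' @slot seed RNG seed of the initialization.
#' @slot reconstruction_error final relative Frobenius error
#'   ||X - AP|| / ||X||.
#' @slot error_trace per-iteration relative error (non-increasing).
#' @slot iterations,converged fitting diagnostics.
#' @export
setClass("PatternDecomposition",
         representation(amplitude = "matrix", pattern = "matrix",
                        k = "integer", seed = "integer",
                        reconstruction_error = "numeric",
                        error_trace = "numeric", iterations = "integer",
                        converged = "logical"))

setValidity("PatternDecomposition", function(object) {
  if (any(object@amplitude < 0) || any(object@pattern < 0))
    return("factor matrices must be non-negative")
  if (ncol(object@amplitude) != object@k || nrow(object@pattern) != object@k)
    return("factor dimensions do not match k")
  TRUE
})

setMethod("show", "PatternDecomposition", function(object) {
  cat(sprintf(
    "PatternDecomposition: %d genes x %d cells, k = %d (seed %d)\n  relative error %.4g after %d iterations%s\n",
    nrow(object@amplitude), ncol(object@pattern), object@k, object@seed,
    object@reconstruction_error, object@iterations,
    if (object@converged) ", converged" else ""))
})

#' @describeIn PatternDecomposition gene-weight (amplitude) matrix
#' @param x a `PatternDecomposition`
#' @export
amplitudeMatrix <- function(x) x@amplitude

#' @describeIn PatternDecomposition sample-weight (pattern) matrix
#' @export
patternMatrix <- function(x) x@pattern

#' Regulon activity and specificity scores
#'
#' @slot ras regulons x cells activity matrix (recovery-curve AUC, in 0..1).
#' @slot rss regulons x cell-types specificity matrix (1 - JSD, in 0..1).
#' @slot zscore regulons x cell-types standardization of per-type mean RAS.
#' @slot rss_log2fc regulons x cell-types log2 RSS fold change between two
#'   condition levels (clipped to +/- 10); 0 x 0 matrix when not computed.
#' @slot fc_levels the two condition levels of `rss_log2fc` (A over B).
#' @export
setClass("RegulonActivity",
         representation(ras = "matrix", rss = "matrix", zscore = "matrix",
                        rss_log2fc = "matrix", fc_levels = "character"))

setMethod("show", "RegulonActivity", function(object) {
  cat(sprintf("RegulonActivity: %d regulons x %d cells; RSS over %d cell types%s\n",
              nrow(object@ras), ncol(object@ras), ncol(object@rss),
              if (length(object@fc_levels))
                sprintf("; RSS log2FC %s vs %s",
                        object@fc_levels[1], object@fc_levels[2]) else ""))
})

#' @describeIn RegulonActivity per-cell regulon activity scores
#' @param x a `RegulonActivity`
#' @export
rasMatrix <- function(x) x@ras

#' @describeIn RegulonActivity per-type regulon specificity scores
#' @export
rssMatrix <- function(x) x@rss

#' @describeIn RegulonActivity per-type Z-scores of mean activity
#' @export
rasZscore <- function(x) x@zscore

#' @describeIn RegulonActivity condition-wise RSS log2 fold changes
#' @export
rssLog2FC <- function(x) x@rss_log2fc

#' Regulatory loop graph
#'
#' Nodes are gene sets of three kinds (pattern, regulon targets, DEG set)
#' grouped by cell type; edges are cross-kind pairwise hypergeometric overlap
#' tests; ternary loops are triples whose three pairwise edges are all kept
#' at the alpha gate.
#'
#' @slot nodes data.frame: id, kind, cell_type, size.
#' @slot node_genes named list of member gene vectors per node id.
#' @slot edges data.frame: node_1, node_2, cell_type, k_overlap, M, n, N,
#'   p_loop, pmf, kept.
#' @slot loops data.frame: pattern, regulon, deg_set, cell_type, max_p.
#' @slot alpha the P_loop significance gate.
#' @slot universe_size total genes N.
#' @slot disease_flag whether the inputs came from disease-mode selection.
#' @slot node_pathways named list (per node id) of annotated pathway names.
#' @slot pathway_summary list with counts from [annotatePathways()].
#' @export
setClass("LoopGraph",
         representation(nodes = "data.frame", node_genes = "list",
                        edges = "data.frame", loops = "data.frame",
                        alpha = "numeric", universe_size = "integer",
                        disease_flag = "logical", node_pathways = "list",
                        pathway_summary = "list"))

setMethod("show", "LoopGraph", function(object) {
  cat(sprintf(
    "LoopGraph%s: %d nodes, %d significant of %d tested edges (alpha %.3g), %d ternary loops\n",
    if (object@disease_flag) " (disease mode)" else "",
    nrow(object@nodes), sum(object@edges$kept), nrow(object@edges),
    object@alpha, nrow(object@loops)))
  if (length(object@pathway_summary))
    cat(sprintf("  pathways touched by loop nodes: %d/%d (%.1f%%)\n",
                object@pathway_summary$n_touched,
                object@pathway_summary$n_pathways,
                100 * object@pathway_summary$fraction))
})

#' @describeIn LoopGraph the extracted ternary loops
#' @param x a `LoopGraph`
#' @export
loopTable <- function(x) x@loops

#' @describeIn LoopGraph all tested pairwise overlap edges
#' @export
loopEdges <- function(x) x@edges

#' @describeIn LoopGraph the typed node table
#' @export
loopNodes <- function(x) x@nodes
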