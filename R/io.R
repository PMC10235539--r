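#' Read an expression matrix
#'
#' Reads a genes x cells matrix of log-normalized expression from either a
#' CellRanger-style MatrixMarket triplet (`matrix.mtx` + gene and barcode
#' TSVs) or a dense TSV/CSV with gene ids in the first column and cell ids in
#' the header. MTX coordinates are 1-based on disk per the MatrixMarket
#' standard; in R the matrix is addressed by ids, never by file coordinates.
#'
#' Gene symbols are matched case-sensitively everywhere in the package; no
#' alias resolution is attempted (silent symbol mapping is a reproducibility
#' hazard).
#'
#' @param matrix_path path to the matrix file.
#' @param genes_path,cells_path id files (one id per line, or TSV whose first
#'   column is the id); required for `format = "mtx"`.
#' @param format one of `"mtx"`, `"tsv"`, `"csv"`.
#' @param raw_counts set `TRUE` when the file holds raw counts; a library-size
#'   + `log1p` normalization is then applied once at load.
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                           format = c("mtx", "tsv", "csv"),
                           raw_counts = FALSE) {
  format <- match.arg(format)
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(cells_path))
      stop("mtx format requires genes_path and cells_path companion files")
    m <- tryCatch(Matrix::readMM(matrix_path),
                  error = function(e) stop(sprintf(
                    "malformed MatrixMarket file %s: %s", matrix_path,
                    conditionMessage(e))))
    genes <- .readIdColumn(genes_path)
    cells <- .readIdColumn(cells_path)
    if (length(genes) != nrow(m))
      stop(sprintf("gene file %s has %d ids but matrix has %d rows",
                   genes_path, length(genes), nrow(m)))
    if (length(cells) != ncol(m))
      stop(sprintf("cell file %s has %d ids but matrix has %d columns",
                   cells_path, length(cells), ncol(m)))
    .checkUniqueIds(genes, "gene")
    .checkUniqueIds(cells, "cell")
    return(ExpressionMatrix(methods::as(m, "CsparseMatrix"), genes, cells,
                            raw_counts = raw_counts))
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- read.delim(matrix_path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- trimws(as.character(tab[[1]]))
  .checkUniqueIds(genes, "gene")
  cells <- trimws(colnames(tab)[-1])
  .checkUniqueIds(cells, "cell")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop(sprintf("non-numeric values in %s", matrix_path))
  ExpressionMatrix(vals, genes, cells, raw_counts = raw_counts)
}

.readIdColumn <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  trimws(as.character(tab[[1]]))
}

.checkUniqueIds <- function(ids, what) {
  if (anyDuplicated(ids))
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  invisible(ids)
}

#' Write an expression matrix
#'
#' Inverse of [readExpression()]: MTX triplet (matrix + gene/cell id files)
#' or dense TSV/CSV with genes as rows.
#'
#' @param x an [ExpressionMatrix-class].
#' @param matrix_path output matrix file.
#' @param genes_path,cells_path id file paths (mtx only).
#' @param format `"mtx"`, `"tsv"` or `"csv"`.
#' @return invisibly, `matrix_path`.
#' @export
writeExpression <- function(x, matrix_path, genes_path = NULL,
                            cells_path = NULL, format = c("mtx", "tsv", "csv")) {
  format <- match.arg(format)
  v <- exprValues(x)
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(cells_path))
      stop("mtx format requires genes_path and cells_path")
    Matrix::writeMM(methods::as(methods::as(v, "CsparseMatrix"), "generalMatrix"),
                    matrix_path)
    writeLines(geneIds(x), genes_path)
    writeLines(cellIds(x), cells_path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    tab <- data.frame(gene = geneIds(x), .asDense(v), check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(tab) <- c("gene", cellIds(x))
    write.table(tab, matrix_path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: `name TAB description TAB gene TAB gene ...`, one set
#' per line. Duplicate genes within a line are collapsed with a warning (set
#' semantics).
#'
#' @param path GMT file.
#' @param kind the [GeneSet-class] kind stamped on every set.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path, kind = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(f)))
    sets[[i]] <- GeneSet(trimws(f[1]), kind, trimws(f[-(1:2)]))
  }
  GeneSetCollection(sets)
}

#' Write a GeneSetCollection to GMT
#'
#' @param x a [GeneSetCollection-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGMT <- function(x, path) {
  lines <- vapply(geneSets(x), function(s)
    paste(c(setName(s), setKind(s), setGenes(s)), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell annotation table
#'
#' TSV with a header containing at least `cell_id` and `cell_type`;
#' `condition`, `region` and `donor` are optional and default to a single
#' `"unspecified"` level. Leading/trailing whitespace in ids and labels is
#' trimmed (reported via a message); nothing else is silently repaired.
#'
#' @param path annotation TSV.
#' @return a [CellAnnotation-class].
#' @export
readAnnotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("cell_id", "cell_type"))
    if (!col %in% colnames(tab))
      stop(sprintf("missing mandatory column: %s", col))
  if (any(tab$cell_id != trimws(tab$cell_id)))
    message("trimmed whitespace from cell ids")
  CellAnnotation(tab)
}

#' Write a cell annotation table
#' @param x a [CellAnnotation-class].
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
writeAnnotation <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
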