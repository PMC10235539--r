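#' Cell-type abundance across conditions (ACT)
#'
#' ACT(c, k) = (n_ck / n_k) / (n_c / n_total): the proportion of cell type c
#' within condition level k over its overall proportion (observed/expected,
#' Ro/e-style ratio). A type is enriched under level k when ACT > 1. The
#' weighted mean of ACT over levels (weights n_k / n_total) is exactly 1 for
#' every type, which makes the ratio comparable across unevenly sampled
#' conditions. Raw ratios are reported with the counts table attached so
#' stability under small counts can be judged directly; no shrinkage or
#' continuity correction is applied.
#'
#' @param ann a [CellAnnotation-class].
#' @param condition_field which annotation column defines the levels:
#'   `"condition"`, `"region"` or `"donor"`.
#' @return an [ACTTable-class]. A cell type absent from one level gets
#'   ACT = 0 there with a warning; a declared level containing no cells at
#'   all is an error.
#' @export
computeACT <- function(ann, condition_field = c("condition", "region", "donor")) {
  condition_field <- match.arg(condition_field)
  stopifnot(methods::is(ann, "CellAnnotation"))
  f <- ann[[condition_field]]
  if (nlevels(f) < 2)
    stop(sprintf("'%s' has %d level(s); at least 2 required", condition_field,
                 nlevels(f)))
  counts <- table(cell_type = droplevels(ann$cell_type), level = f)
  n_k <- colSums(counts)
  if (any(n_k == 0))
    stop(sprintf("level(s) with zero cells: %s",
                 paste(colnames(counts)[n_k == 0], collapse = ", ")))
  n_c <- rowSums(counts)
  n_tot <- sum(counts)
  act <- sweep(sweep(unclass(counts), 2, n_k, "/"), 1, n_c / n_tot, "/")
  if (any(counts == 0))
    warning("cell type absent from some level(s): ACT = 0 there")
  methods::new("ACTTable", act = act, counts = unclass(counts),
               field = condition_field)
}

#' Ratio of two ACT values
#'
#' Fold difference in the abundance of a cell type between two condition
#' levels. Summaries conventionally report it to one decimal. Division by a
#' zero ACT yields `Inf` with a warning.
#'
#' @param x an [ACTTable-class], or the numerator ACT value itself.
#' @param ... passed to the methods.
#' @return the abundance ratio (full precision).
#' @export
setGeneric("actRatio", function(x, ...) standardGeneric("actRatio"))

#' @describeIn actRatio ratio ACT(cell_type, level_a) / ACT(cell_type,
#'   level_b) from a computed table.
#' @param cell_type row of the table.
#' @param level_a,level_b numerator and denominator levels.
#' @export
setMethod("actRatio", "ACTTable", function(x, cell_type, level_a, level_b) {
  act <- actValues(x)
  if (!cell_type %in% rownames(act))
    stop(sprintf("unknown cell type: %s", cell_type))
  for (lv in c(level_a, level_b))
    if (!lv %in% colnames(act)) stop(sprintf("unknown level: %s", lv))
  actRatio(act[cell_type, level_a], act[cell_type, level_b])
})

#' @describeIn actRatio ratio of two plain ACT values (e.g. values quoted
#'   from a published table).
#' @param b denominator ACT value.
#' @export
setMethod("actRatio", "numeric", function(x, b) {
  stopifnot(length(x) == length(b))
  if (any(b == 0)) {
    warning("division by zero ACT: ratio reported as Inf")
  }
  x / b
})

#' Enrichment calls from an ACT table
#'
#' A cell type is called enriched under a level when ACT is strictly greater
#' than 1 (ACT exactly 1 is the independence boundary and is not enriched).
#'
#' @param x an [ACTTable-class].
#' @return logical matrix with the dimensions of the ACT table.
#' @export
enrichmentCalls <- function(x) {
  stopifnot(methods::is(x, "ACTTable"))
  actValues(x) > 1
}
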