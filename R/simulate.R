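#' Synthetic dataset configuration
#'
#' Parameters of the planted-truth generator. The defaults emulate a small
#' RPE/choroid-like dissociation: 8 cell types x 2 conditions x 2 regions,
#' 100 cells per type per condition (1,600 cells), 2,000 genes, with
#' exclusive markers, condition DEGs, co-expression programs, active
#' regulons and ternary loop structure planted per type.
#'
#' @slot n_cell_types number of cell types (default 8).
#' @slot cells_per_type cells per type per condition (default 100).
#' @slot n_genes total genes (default 2000).
#' @slot conditions,regions the two condition and region levels.
#' @slot n_markers_per_type exclusive markers planted per type (default 2;
#'   the first of each type is emitted as the "known" marker, the rest are
#'   the novel markers the pipeline should rediscover).
#' @slot marker_effect log-scale elevation of marker means inside their type
#'   (default 3); 0 disables marker planting entirely (null data).
#' @slot n_degs_per_type condition-shifted genes per type (default 20, half
#'   up, half down).
#' @slot deg_effect log-scale condition shift magnitude (default 1.5).
#' @slot pattern_gene_size genes per planted co-expression program (50).
#' @slot pattern_effect log-scale program elevation (default 1.5), scaled by
#'   a per-gene weight drawn in 0.5..1.
#' @slot regulon_size target genes per planted regulon (default 30).
#' @slot regulon_effect log-scale target elevation in active cells (2).
#' @slot n_patterns,n_regulons how many leading cell types receive a planted
#'   program / a type-specific regulon (default: all of them).
#' @slot n_disease_regulons extra regulons active only in (type, disease)
#'   strata (default 1), assigned to the leading cell types.
#' @slot loop_overlap genes shared among a type's program, regulon targets
#'   and condition-DEG set, forming the planted ternary loop (default 10).
#' @slot noise_dispersion negative-binomial size parameter (default 2).
#' @slot baseline_meanlog,baseline_sdlog log-normal law of per-gene baseline
#'   means (defaults log(0.5) and 1).
#' @slot region_bias named numeric: odds of the first region level for the
#'   named cell types (empty by default: regions carry no signal).
#' @slot seed RNG seed; the whole dataset is a deterministic function of the
#'   configuration.
#' @export
setClass("SimulationConfig",
         representation(n_cell_types = "integer", cells_per_type = "integer",
                        n_genes = "integer", conditions = "character",
                        regions = "character", n_markers_per_type = "integer",
                        marker_effect = "numeric", n_degs_per_type = "integer",
                        deg_effect = "numeric", pattern_gene_size = "integer",
                        pattern_effect = "numeric", regulon_size = "integer",
                        regulon_effect = "numeric", n_patterns = "integer",
                        n_regulons = "integer", n_disease_regulons = "integer",
                        loop_overlap = "integer", noise_dispersion = "numeric",
                        baseline_meanlog = "numeric", baseline_sdlog = "numeric",
                        region_bias = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  pos <- c(n_cell_types = object@n_cell_types,
           cells_per_type = object@cells_per_type, n_genes = object@n_genes)
  if (any(pos < 1)) return("counts must be positive")
  if (length(object@conditions) != 2 || length(object@regions) != 2)
    return("exactly two condition and two region levels are required")
  if (object@loop_overlap > min(object@pattern_gene_size, object@regulon_size,
                                object@n_degs_per_type))
    return("loop_overlap exceeds a planted set size")
  if (object@n_patterns > object@n_cell_types ||
      object@n_regulons > object@n_cell_types)
    return("n_patterns and n_regulons cannot exceed n_cell_types")
  if (.plantBudget(object) > object@n_genes)
    return(sprintf("planted structure needs %d genes but n_genes = %d",
                   .plantBudget(object), object@n_genes))
  TRUE
})

.plantBudget <- function(cfg) {
  n_loop_types <- min(cfg@n_patterns, cfg@n_regulons)
  cfg@n_cell_types * (cfg@n_markers_per_type + cfg@n_degs_per_type) +
    cfg@n_patterns * (cfg@pattern_gene_size - cfg@loop_overlap) +
    cfg@n_regulons * (cfg@regulon_size - cfg@loop_overlap) +
    n_loop_types * cfg@loop_overlap +
    max(0, cfg@n_patterns - n_loop_types) * cfg@loop_overlap +
    max(0, cfg@n_regulons - n_loop_types) * cfg@loop_overlap +
    cfg@n_disease_regulons * cfg@regulon_size
}

#' @describeIn SimulationConfig constructor with the documented defaults.
#' @param n_cell_types,cells_per_type,n_genes,conditions,regions,n_markers_per_type,marker_effect,n_degs_per_type,deg_effect,pattern_gene_size,pattern_effect,regulon_size,regulon_effect,n_patterns,n_regulons,n_disease_regulons,loop_overlap,noise_dispersion,baseline_meanlog,baseline_sdlog,region_bias,seed see the class slots.
#' @export
simulationConfig <- function(n_cell_types = 8, cells_per_type = 100,
                             n_genes = 2000,
                             conditions = c("disease", "control"),
                             regions = c("macula", "periphery"),
                             n_markers_per_type = 2, marker_effect = 3,
                             n_degs_per_type = 20, deg_effect = 1.5,
                             pattern_gene_size = 50, pattern_effect = 1.5,
                             regulon_size = 30, regulon_effect = 2,
                             n_patterns = n_cell_types,
                             n_regulons = n_cell_types,
                             n_disease_regulons = 1, loop_overlap = 10,
                             noise_dispersion = 2,
                             baseline_meanlog = log(0.5), baseline_sdlog = 1,
                             region_bias = numeric(), seed = 1) {
  methods::new("SimulationConfig",
               n_cell_types = as.integer(n_cell_types),
               cells_per_type = as.integer(cells_per_type),
               n_genes = as.integer(n_genes),
               conditions = as.character(conditions),
               regions = as.character(regions),
               n_markers_per_type = as.integer(n_markers_per_type),
               marker_effect = marker_effect,
               n_degs_per_type = as.integer(n_degs_per_type),
               deg_effect = deg_effect,
               pattern_gene_size = as.integer(pattern_gene_size),
               pattern_effect = pattern_effect,
               regulon_size = as.integer(regulon_size),
               regulon_effect = regulon_effect,
               n_patterns = as.integer(n_patterns),
               n_regulons = as.integer(n_regulons),
               n_disease_regulons = as.integer(n_disease_regulons),
               loop_overlap = as.integer(loop_overlap),
               noise_dispersion = noise_dispersion,
               baseline_meanlog = baseline_meanlog,
               baseline_sdlog = baseline_sdlog,
               region_bias = region_bias, seed = as.integer(seed))
}

.CELLTYPE_NAMES <- c("endothelial", "fibroblast", "macrophage", "mast",
                     "melanocyte", "RPE", "schwann", "TNK")

#' Generate a synthetic dataset with planted ground truth
#'
#' Counts are drawn per gene x cell from a negative binomial with gene
#' specific log-normal baseline means and size `noise_dispersion`, then
#' library-size normalized (common library 1e4) and log1p transformed.
#' Planted structure, all multiplicative on the mean scale:
#' exclusive markers (mean zero outside the type, elevated inside),
#' condition DEGs (shifted within one type between conditions),
#' co-expression programs (a weighted non-negative elevation shared by one
#' type's cells), regulon targets (jointly elevated in designated
#' (type, condition) strata), and ternary loops (loop_overlap genes seeded
#' simultaneously into one type's program, regulon targets and DEG set).
#' The output is bit-reproducible under the configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `expr` ([ExpressionMatrix-class]), `annotation`
#'   ([CellAnnotation-class]), `known_markers` and `regulons`
#'   ([GeneSetCollection-class]), and `truth` (a list holding
#'   `planted_markers`, `planted_degs`, `planted_patterns`,
#'   `planted_regulons`, `planted_loops`).
#' @export
simulateDataset <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  cfg <- config
  .withSeed(cfg@seed, {
    types <- if (cfg@n_cell_types <= length(.CELLTYPE_NAMES))
      .CELLTYPE_NAMES[seq_len(cfg@n_cell_types)]
    else c(.CELLTYPE_NAMES,
           sprintf("type_%d", seq_len(cfg@n_cell_types - length(.CELLTYPE_NAMES))))
    G <- cfg@n_genes
    genes <- sprintf("G%04d", seq_len(G))
    n_cells <- cfg@n_cell_types * 2L * cfg@cells_per_type
    cell_type <- rep(types, each = 2L * cfg@cells_per_type)
    condition <- rep(rep(cfg@conditions, each = cfg@cells_per_type),
                     times = cfg@n_cell_types)
    cells <- sprintf("cell_%05d", seq_len(n_cells))
    region <- character(n_cells)
    for (ct in types) {
      i <- cell_type == ct
      odds <- if (ct %in% names(cfg@region_bias)) cfg@region_bias[[ct]] else 1
      region[i] <- sample(cfg@regions, sum(i), replace = TRUE,
                          prob = c(odds, 1) / (odds + 1))
    }
    donor <- ifelse(condition == cfg@conditions[1],
                    sample(c("donor_1", "donor_2"), n_cells, replace = TRUE),
                    sample(c("donor_3", "donor_4"), n_cells, replace = TRUE))
    ann <- CellAnnotation(data.frame(
      cell_id = cells, cell_type = cell_type,
      condition = factor(condition, levels = cfg@conditions),
      region = factor(region, levels = cfg@regions), donor = donor,
      stringsAsFactors = FALSE))

    # --- gene role allocation (sequential, deterministic) ---
    cursor <- 0L
    take <- function(n) {
      if (cursor + n > G) stop("planted structure exceeds n_genes")
      out <- genes[cursor + seq_len(n)]
      cursor <<- cursor + n
      out
    }
    marker_df <- NULL; deg_df <- NULL
    patterns <- list(); regulons <- list(); loops_df <- NULL
    pat_genes <- list(); reg_genes <- list(); deg_genes <- list()
    for (ti in seq_len(cfg@n_cell_types)) {
      ct <- types[ti]
      mk <- take(cfg@n_markers_per_type)
      marker_df <- rbind(marker_df, data.frame(
        gene = mk, cell_type = ct,
        known = seq_along(mk) == 1L, stringsAsFactors = FALSE))
      has_pat <- ti <= cfg@n_patterns
      has_reg <- ti <= cfg@n_regulons
      shared <- if (has_pat && has_reg) take(cfg@loop_overlap) else character()
      d_own <- take(cfg@n_degs_per_type - length(shared))
      dg <- c(shared, d_own)
      deg_genes[[ct]] <- dg
      dirs <- rep(c(1, -1), length.out = length(dg))
      deg_df <- rbind(deg_df, data.frame(
        gene = dg, cell_type = ct,
        direction = ifelse(dirs > 0, "up", "down"), stringsAsFactors = FALSE))
      if (has_pat) {
        p_shared <- if (has_reg) shared else take(cfg@loop_overlap)
        pg <- c(p_shared, take(cfg@pattern_gene_size - cfg@loop_overlap))
        pat_genes[[ct]] <- pg
        patterns[[sprintf("program_%s", ct)]] <-
          list(cell_type = ct, genes = pg,
               weights = runif(length(pg), 0.5, 1))
      }
      if (has_reg) {
        r_shared <- if (has_pat) shared else take(cfg@loop_overlap)
        rg <- c(r_shared, take(cfg@regulon_size - cfg@loop_overlap))
        reg_genes[[ct]] <- rg
        regulons[[sprintf("TF_%s", ct)]] <-
          list(targets = rg, active_types = ct,
               active_conditions = cfg@conditions)
      }
      if (has_pat && has_reg)
        loops_df <- rbind(loops_df, data.frame(
          pattern = sprintf("program_%s", ct),
          regulon = sprintf("TF_%s", ct), deg_set = ct, cell_type = ct,
          stringsAsFactors = FALSE))
    }
    for (di in seq_len(cfg@n_disease_regulons)) {
      ct <- types[(di - 1L) %% cfg@n_cell_types + 1L]
      rg <- take(cfg@regulon_size)
      regulons[[sprintf("TF_disease_%d", di)]] <-
        list(targets = rg, active_types = ct,
             active_conditions = cfg@conditions[1])
    }

    # --- mean matrix and counts ---
    base <- rlnorm(G, cfg@baseline_meanlog, cfg@baseline_sdlog)
    names(base) <- genes
    # condition shifts and markers are planted on expressed genes (baseline
    # floored at the median of the baseline law): a fold change on a gene
    # the assay rarely detects is unidentifiable, and a marker absent from
    # most cells of its own type is not a marker
    floor_genes <- unique(c(deg_df$gene, marker_df$gene))
    base[floor_genes] <- pmax(base[floor_genes], exp(cfg@baseline_meanlog))
    mu <- matrix(base, G, n_cells, dimnames = list(genes, cells))
    if (cfg@marker_effect > 0) {
      for (i in seq_len(nrow(marker_df))) {
        g <- marker_df$gene[i]; ct <- marker_df$cell_type[i]
        mu[g, cell_type != ct] <- 0
        mu[g, cell_type == ct] <- mu[g, cell_type == ct] * exp(cfg@marker_effect)
      }
    }
    for (pn in names(patterns)) {
      p <- patterns[[pn]]
      i <- cell_type == p$cell_type
      mu[p$genes, i] <- mu[p$genes, i] * exp(cfg@pattern_effect * p$weights)
    }
    for (rn in names(regulons)) {
      r <- regulons[[rn]]
      i <- cell_type %in% r$active_types & condition %in% r$active_conditions
      mu[r$targets, i] <- mu[r$targets, i] * exp(cfg@regulon_effect)
    }
    for (i in seq_len(nrow(deg_df))) {
      g <- deg_df$gene[i]; ct <- deg_df$cell_type[i]
      dir <- if (deg_df$direction[i] == "up") 1 else -1
      j <- cell_type == ct & condition == cfg@conditions[1]
      mu[g, j] <- mu[g, j] * exp(dir * cfg@deg_effect)
    }
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = cfg@noise_dispersion),
                     G, n_cells, dimnames = dimnames(mu))
    lib <- colSums(counts)
    if (any(lib == 0)) stop("generated cell with zero library size; increase n_genes or baseline mean")
    expr <- ExpressionMatrix(log1p(sweep(counts, 2, lib, "/") * 1e4),
                             genes, cells)

    known_sets <- lapply(types, function(ct) {
      kg <- marker_df$gene[marker_df$cell_type == ct & marker_df$known]
      methods::new("GeneSet", name = ct, kind = "known_marker", genes = kg)
    })
    reg_sets <- lapply(names(regulons), function(rn)
      GeneSet(rn, "regulon_targets", regulons[[rn]]$targets))
    truth <- list(
      planted_markers = if (cfg@marker_effect > 0) marker_df else
        marker_df[0, , drop = FALSE],
      planted_degs = deg_df,
      planted_patterns = patterns,
      planted_regulons = regulons,
      planted_loops = if (is.null(loops_df)) data.frame() else loops_df)
    list(expr = expr, annotation = ann,
         known_markers = GeneSetCollection(known_sets, universe = genes),
         regulons = GeneSetCollection(reg_sets, universe = genes),
         truth = truth)
  })
}

#' Write a generated dataset as plain-text fixture files
#'
#' Writes the CellRanger-style MTX triplet (`matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv`), the annotation TSV, `known_markers.gmt` (the "known"
#' subset of planted markers, standing in for a curated marker database),
#' `regulons.gmt`, and `truth.json` with the full planted ground truth.
#'
#' @param dataset the list returned by [simulateDataset()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeFixture <- function(dataset, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             genes = file.path(out_dir, "genes.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             annotation = file.path(out_dir, "annotation.tsv"),
             known_markers = file.path(out_dir, "known_markers.gmt"),
             regulons = file.path(out_dir, "regulons.gmt"),
             truth = file.path(out_dir, "truth.json"))
  writeExpression(dataset$expr, paths["matrix"], paths["genes"],
                  paths["barcodes"], format = "mtx")
  writeAnnotation(dataset$annotation, paths["annotation"])
  writeGMT(dataset$known_markers, paths["known_markers"])
  writeGMT(dataset$regulons, paths["regulons"])
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
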