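#' Quality-control filtering of a single-cell counts matrix
#'
#' Removes low-complexity cells and putative doublets/triplets by total UMI
#' count, and mitochondrial genes by symbol prefix. Thresholds are strict:
#' cells with strictly fewer than `min_umi` or strictly more than `max_umi`
#' total UMIs are removed, so boundary cells are retained. Totals are computed
#' on the input matrix, before mitochondrial genes are dropped — the per-cell
#' UMI total is a property of the sequencing library, not of the gene subset
#' retained for analysis.
#'
#' @param matrix an [ExpressionMatrix()] on the counts scale.
#' @param annot per-cell annotation covering all cells (see
#'   [validate_annotation()]); filtered in step with the matrix.
#' @param config a [run_config()]; `qc_min_umi`, `qc_max_umi` and
#'   `qc_mito_prefix` are used.
#' @return A list with elements `matrix`, `annot` and `report`. The report is
#'   a one-row data.frame with `n_input_cells`, `n_low_complexity_removed`,
#'   `n_doublet_removed`, `n_mito_genes_removed`, `n_output_cells`.
#'   If no cell survives, a warning of class `glyco_empty_qc` is signalled and
#'   the (empty) result is still returned.
#' @examples
#' sim <- generate_sc_dataset(sc_sim_config(seed = 1, cells_per_population = 40))
#' qc <- qc_filter(sim$wt, sim$annot_wt, run_config())
#' qc$report
#' @export
qc_filter <- function(matrix, annot, config = run_config()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "counts")
    stop("qc_filter expects a counts-scale matrix")
  annot <- validate_annotation(annot, matrix)
  totals <- cell_totals(matrix)
  low <- totals < config$qc_min_umi
  high <- totals > config$qc_max_umi
  keep_cells <- !(low | high)
  mito <- startsWith(em_genes(matrix), config$qc_mito_prefix)
  report <- data.frame(
    n_input_cells = ncol(matrix$values),
    n_low_complexity_removed = sum(low),
    n_doublet_removed = sum(high),
    n_mito_genes_removed = sum(mito),
    n_output_cells = sum(keep_cells)
  )
  out <- ExpressionMatrix(matrix$values[!mito, keep_cells, drop = FALSE],
                          scale = "counts")
  annot_out <- annot[keep_cells, , drop = FALSE]
  rownames(annot_out) <- NULL
  if (!any(keep_cells))
    warning(structure(
      class = c("glyco_empty_qc", "warning", "condition"),
      list(message = "no cells survive QC filtering", call = sys.call())))
  list(matrix = out, annot = annot_out, report = report)
}

#' Log-normalize a counts matrix
#'
#' Each count is scaled to its cell's total (counts per `scale_factor`) and
#' log1p-transformed: `value = ln(1 + count * scale_factor / cell_total)`.
#' This is the scale on which all expression thresholds in the package (for
#' co-expression and high-expressor subsetting) are defined.
#'
#' @param matrix an [ExpressionMatrix()] on the counts scale; every cell must
#'   have a positive total.
#' @param scale_factor per-cell scaling target (default 10,000).
#' @return An [ExpressionMatrix()] tagged `"lognorm"`.
#' @examples
#' m <- matrix(c(100, 9900), nrow = 2,
#'             dimnames = list(c("Hk1", "Gapdh"), "c1"))
#' log_normalize(ExpressionMatrix(m, "counts"))$values
#' @export
log_normalize <- function(matrix, scale_factor = 10000) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "counts")
    stop("log_normalize applies to counts matrices only")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  totals <- cell_totals(matrix)
  if (any(totals == 0))
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(names(totals)[totals == 0], 5), collapse = ", "))
  v <- matrix$values
  if (is(v, "sparseMatrix")) {
    v <- as(v, "CsparseMatrix") %*% Matrix::Diagonal(x = scale_factor / totals)
    v@x <- log1p(v@x)
    dimnames(v) <- dimnames(matrix$values)
  } else {
    v <- log1p(sweep(v, 2L, scale_factor / totals, `*`))
  }
  ExpressionMatrix(v, scale = "lognorm")
}
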