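#' Expression matrix container
#'
#' A genes x cells matrix of non-negative expression values carrying a scale
#' tag: `"counts"` for raw UMI counts, `"lognorm"` for log-normalized values
#' (see [log_normalize()]). Row names are gene symbols (case-sensitive,
#' unique), column names are cell barcodes (unique).
#'
#' @param values numeric matrix or Matrix (genes x cells) with unique,
#'   non-empty dimnames; all values finite and >= 0.
#' @param scale `"counts"` or `"lognorm"`.
#' @return An `ExpressionMatrix` object (list with elements `values` and
#'   `scale`).
#' @examples
#' m <- matrix(c(0, 1, 2, 3, 4, 5), nrow = 3,
#'             dimnames = list(c("Hk1", "Pfkp", "Pfkfb3"), c("c1", "c2")))
#' em <- ExpressionMatrix(m, scale = "counts")
#' dim(em)
#' @export
ExpressionMatrix <- function(values, scale = c("counts", "lognorm")) {
  scale <- match.arg(scale)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!(is.matrix(values) || is(values, "Matrix")))
    stop("'values' must be a matrix or Matrix")
  gn <- if (nrow(values)) rownames(values) else character()
  cn <- if (ncol(values)) colnames(values) else character()
  if (is.null(gn) || is.null(cn))
    stop("expression matrix must have gene row names and cell column names")
  if (is.null(rownames(values))) rownames(values) <- gn
  if (is.null(colnames(values))) colnames(values) <- cn
  if (anyDuplicated(gn))
    stop("duplicate gene symbols: ",
         paste(unique(gn[duplicated(gn)]), collapse = ", "))
  if (anyDuplicated(cn))
    stop("duplicate cell barcodes: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  vx <- if (is(values, "sparseMatrix")) values@x else values
  if (length(vx) && (anyNA(vx) || any(!is.finite(vx))))
    stop("expression values must be finite and non-missing")
  if (length(vx) && any(vx < 0))
    stop("expression values must be non-negative")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' Genes and cells of an expression matrix
#' @param x an [ExpressionMatrix()].
#' @return Character vector of gene symbols / cell barcodes.
#' @export
em_genes <- function(x) rownames(x$values)

#' @rdname em_genes
#' @export
em_cells <- function(x) colnames(x$values)

#' Subset an expression matrix by gene and/or cell names
#'
#' @param x an [ExpressionMatrix()].
#' @param genes,cells character vectors of names to keep (`NULL` keeps all).
#' @return An `ExpressionMatrix` with the same scale tag.
#' @export
em_subset <- function(x, genes = NULL, cells = NULL) {
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes absent from matrix: ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(v))
    if (length(missing))
      stop("cells absent from matrix: ", paste(missing, collapse = ", "))
    v <- v[, cells, drop = FALSE]
  }
  ExpressionMatrix(v, scale = x$scale)
}

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Per-cell total counts
#' @param x an [ExpressionMatrix()] on the counts scale.
#' @return Named numeric vector of column sums (total UMIs per cell).
#' @export
cell_totals <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  Matrix::colSums(x$values)
}

#' Per-gene mean expression on the linear scale
#'
#' Means used for fold-change computation. For a counts matrix this is the
#' plain per-gene mean count; for a log-normalized matrix the log transform is
#' undone first (`expm1`), so means are taken on the normalized-counts scale.
#' Averaging after de-logging keeps a k-fold change in underlying counts a
#' k-fold change in the reported mean, which a mean of logged values would
#' compress.
#'
#' @param x an [ExpressionMatrix()].
#' @param cells optional barcodes restricting the mean.
#' @return Named numeric vector, one mean per gene.
#' @export
linear_gene_means <- function(x, cells = NULL) {
  v <- x$values
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(v))
    if (length(missing))
      stop("cells absent from matrix: ", paste(missing, collapse = ", "))
    v <- v[, cells, drop = FALSE]
  }
  if (ncol(v) == 0L) stop("no cells selected")
  if (x$scale == "lognorm") {
    if (is(v, "sparseMatrix")) {
      v@x <- expm1(v@x)
      Matrix::rowSums(v) / ncol(v)
    } else {
      rowMeans(expm1(v))
    }
  } else {
    Matrix::rowSums(v) / ncol(v)
  }
}

#' Validate a cell annotation table against a matrix
#'
#' The annotation carries one row per cell: `barcode`, `population` (ectoderm
#' -derived label or "non_ectoderm"), `genotype` ("WT"/"KO"), `stage`
#' ("E8.25"/"E9.5"), `total_umi`, `mito_fraction`.
#'
#' @param annot data.frame of per-cell annotations.
#' @param matrix optional [ExpressionMatrix()]; barcodes must cover its cells.
#' @return The annotation, row-ordered to match the matrix when given.
#' @export
validate_annotation <- function(annot, matrix = NULL) {
  req <- c("barcode", "population", "genotype", "stage", "total_umi",
           "mito_fraction")
  missing <- setdiff(req, names(annot))
  if (length(missing))
    stop("annotation lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(annot$barcode))
    stop("duplicate barcodes in annotation")
  if (!is.null(matrix)) {
    absent <- setdiff(em_cells(matrix), annot$barcode)
    if (length(absent))
      stop("annotation does not cover ", length(absent), " cells")
    annot <- annot[match(em_cells(matrix), annot$barcode), , drop = FALSE]
    rownames(annot) <- NULL
  }
  annot
}
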