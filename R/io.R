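#' Read an expression matrix from MatrixMarket or dense CSV
#'
#' MatrixMarket input is the classic triplet layout with companion name files
#' (one symbol/barcode per line, first tab-separated field used). Dense CSV
#' input has gene rows and cell columns with the gene symbol in the first
#' column. The matrix is returned genes x cells regardless of the on-disk
#' orientation: set `orientation = "cells_x_genes"` for MTX files written the
#' other way around.
#'
#' @param matrix_path path to the `.mtx` file (triplet form).
#' @param genes_path,barcodes_path companion name files for the MTX rows and
#'   columns (after orientation normalization, genes and cells respectively).
#' @param csv_path dense CSV alternative; mutually exclusive with
#'   `matrix_path`.
#' @param orientation `"genes_x_cells"` (default) or `"cells_x_genes"`.
#' @return An [ExpressionMatrix()] tagged `"counts"`.
#' @export
read_expression <- function(matrix_path = NULL, genes_path = NULL,
                            barcodes_path = NULL, csv_path = NULL,
                            orientation = c("genes_x_cells",
                                            "cells_x_genes")) {
  orientation <- match.arg(orientation)
  if (!is.null(csv_path)) {
    df <- utils::read.csv(csv_path, check.names = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    mode(m) <- "double"
    rownames(m) <- genes
    if (orientation == "cells_x_genes") m <- t(m)
    return(ExpressionMatrix(m, scale = "counts"))
  }
  if (is.null(matrix_path) || is.null(genes_path) || is.null(barcodes_path))
    stop("provide either csv_path or matrix_path + genes_path + barcodes_path")
  m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
  read_names <- function(p) {
    lines <- readLines(p)
    vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  }
  genes <- read_names(genes_path)
  cells <- read_names(barcodes_path)
  if (orientation == "cells_x_genes") m <- Matrix::t(m)
  if (nrow(m) != length(genes))
    stop(sprintf("matrix has %d gene rows but names file lists %d genes",
                 nrow(m), length(genes)))
  if (ncol(m) != length(cells))
    stop(sprintf("matrix has %d cell columns but names file lists %d barcodes",
                 ncol(m), length(cells)))
  dimnames(m) <- list(genes, cells)
  ExpressionMatrix(m, scale = "counts")
}

#' Write an expression matrix
#'
#' `write_expression_mtx()` writes the MatrixMarket triplet plus name files;
#' `write_expression_csv()` writes the dense gene x cell CSV. Both round-trip
#' through [read_expression()] value-identically.
#'
#' @param x an [ExpressionMatrix()].
#' @param matrix_path,genes_path,barcodes_path output paths for the MTX form.
#' @return Invisibly, the main output path.
#' @export
write_expression_mtx <- function(x, matrix_path, genes_path, barcodes_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  Matrix::writeMM(as(as(x$values, "CsparseMatrix"), "generalMatrix"),
                  matrix_path)
  writeLines(em_genes(x), genes_path)
  writeLines(em_cells(x), barcodes_path)
  invisible(matrix_path)
}

#' @rdname write_expression_mtx
#' @param csv_path output path for the CSV form.
#' @export
write_expression_csv <- function(x, csv_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = em_genes(x), as.matrix(x$values),
                   check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene symbols. Genes are de-duplicated preserving first occurrence; symbols
#' are matched case-sensitively downstream. A gene may belong to several sets.
#'
#' @param gmt_path path to the GMT file.
#' @return A named list of character vectors (a `GeneSetCatalog`).
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file contains no sets")
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d is unparseable (needs name, description, >=1 gene)",
                   i))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("GMT line %d defines an empty set '%s'", i, fields[[1L]]))
    if (fields[[1L]] %in% names(sets))
      stop("duplicate gene-set name: ", fields[[1L]])
    sets[[fields[[1L]]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param gmt_path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return Invisibly, `gmt_path`.
#' @export
write_gene_sets <- function(sets, gmt_path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  invisible(gmt_path)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' Used for predicted miRNA-target lists. Blank lines and leading/trailing
#' whitespace are dropped; duplicates are removed preserving order.
#'
#' @param path file path.
#' @return Character vector of gene symbols.
#' @export
read_target_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Write a tabular result deterministically
#'
#' TSV with header, rows sorted by the primary key (first column, then any
#' further columns to break ties), and floats printed at fixed precision so
#' that writing the same result twice is byte-identical.
#'
#' @param result a data.frame.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return Invisibly, `path`.
#' @export
write_table <- function(result, path, digits = 8L) {
  stopifnot(is.data.frame(result))
  df <- result
  if (nrow(df) > 1L) {
    ord <- do.call(order, unname(as.list(df)))
    df <- df[ord, , drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ",")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
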