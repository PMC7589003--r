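#' Threshold co-expression of a gene pair
#'
#' Counts the cells in which both genes' log-normalized expression is
#' strictly greater than `threshold` (default 1, the "expression of both
#' genes > 1" rule used for cyclin/Cdk pairs), and reports each gene's mean
#' expression within that co-expressing cell set.
#'
#' @param matrix an [ExpressionMatrix()] on the lognorm scale.
#' @param gene_a,gene_b gene symbols (must be present).
#' @param threshold expression cutoff, strict.
#' @return A one-row data.frame: `gene_a`, `gene_b`, `n_cells_total`,
#'   `n_coexpressing`, `fraction`, `mean_a_within`, `mean_b_within` (the
#'   within-set means are `NA` when no cell co-expresses).
#' @export
coexpression_count <- function(matrix, gene_a, gene_b, threshold = 1.0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  for (g in c(gene_a, gene_b))
    if (!g %in% em_genes(matrix)) stop("gene absent from matrix: ", g)
  va <- as.numeric(matrix$values[gene_a, ])
  vb <- as.numeric(matrix$values[gene_b, ])
  both <- va > threshold & vb > threshold
  n <- sum(both)
  data.frame(gene_a = gene_a, gene_b = gene_b,
             n_cells_total = length(va),
             n_coexpressing = n,
             fraction = n / length(va),
             mean_a_within = if (n) mean(va[both]) else NA_real_,
             mean_b_within = if (n) mean(vb[both]) else NA_real_)
}

#' Genotype ratio of co-expression
#'
#' KO-over-WT ratio of co-expression for the same gene pair, on the fraction
#' of cells (default — wildtype and knockout datasets rarely have equal cell
#' totals) or on the raw cell count. Both ratios are always reported.
#'
#' @param result_wt,result_ko one-row outputs of [coexpression_count()] for
#'   the same pair and threshold.
#' @param basis `"fraction"` (default) or `"count"`.
#' @return A list: `ratio` (chosen basis), `ratio_fraction`, `ratio_count`,
#'   `basis`, and logical `undefined` (WT quantity zero).
#' @export
coexpression_genotype_ratio <- function(result_wt, result_ko,
                                        basis = c("fraction", "count")) {
  basis <- match.arg(basis)
  if (result_wt$gene_a != result_ko$gene_a ||
      result_wt$gene_b != result_ko$gene_b)
    stop("genotype results refer to different gene pairs")
  ratio_of <- function(ko, wt) if (wt == 0) NA_real_ else ko / wt
  rf <- ratio_of(result_ko$fraction, result_wt$fraction)
  rc <- ratio_of(result_ko$n_coexpressing, result_wt$n_coexpressing)
  chosen <- if (basis == "fraction") rf else rc
  undefined <- is.na(chosen)
  if (undefined)
    warning("WT co-expression is zero; genotype ratio undefined")
  list(ratio = chosen, ratio_fraction = rf, ratio_count = rc,
       basis = basis, undefined = undefined)
}

#' Co-expression panel across gene pairs and genotypes
#'
#' Runs [coexpression_count()] for every pair within each genotype's cells
#' and attaches KO/WT ratios on both bases. Pairs naming a gene absent from
#' the matrix are flagged and reported with `NA` statistics; the remaining
#' pairs are computed normally.
#'
#' @param matrix an [ExpressionMatrix()] on the lognorm scale holding both
#'   genotypes' cells.
#' @param annot cell annotation covering the matrix (column `genotype`).
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param threshold expression cutoff, strict.
#' @return A data.frame with one row per (pair, genotype) plus
#'   `ratio_fraction`/`ratio_count` columns repeated on each pair's rows;
#'   rows are ordered by pair then genotype.
#' @export
coexpression_panel <- function(matrix, annot, pairs, threshold = 1.0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!nrow(pairs)) stop("empty pair list")
  annot <- validate_annotation(annot, matrix)
  genotypes <- sort(unique(annot$genotype))
  genes <- em_genes(matrix)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[[i]]
    gb <- pairs$gene_b[[i]]
    ok <- ga %in% genes && gb %in% genes
    per_geno <- list()
    for (gt in genotypes) {
      cells <- annot$barcode[annot$genotype == gt]
      sub <- em_subset(matrix, cells = cells)
      row <- if (ok) {
        cbind(coexpression_count(sub, ga, gb, threshold),
              data.frame(genotype = gt, missing_gene = FALSE))
      } else {
        data.frame(gene_a = ga, gene_b = gb, n_cells_total = length(cells),
                   n_coexpressing = NA_integer_, fraction = NA_real_,
                   mean_a_within = NA_real_, mean_b_within = NA_real_,
                   genotype = gt, missing_gene = TRUE)
      }
      per_geno[[gt]] <- row
    }
    ratio_f <- ratio_c <- NA_real_
    if (ok && all(c("WT", "KO") %in% genotypes)) {
      r <- suppressWarnings(
        coexpression_genotype_ratio(per_geno[["WT"]], per_geno[["KO"]]))
      ratio_f <- r$ratio_fraction
      ratio_c <- r$ratio_count
    }
    for (gt in genotypes) {
      per_geno[[gt]]$ratio_fraction <- ratio_f
      per_geno[[gt]]$ratio_count <- ratio_c
      rows[[length(rows) + 1L]] <- per_geno[[gt]]
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$gene_a, res$gene_b, res$genotype), , drop = FALSE]
  rownames(res) <- NULL
  res
}
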