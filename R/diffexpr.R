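#' Two-group differential expression by Wilcoxon rank-sum test
#'
#' For each gene, a two-sided Wilcoxon rank-sum (Mann-Whitney) test on the
#' log-normalized values of group A versus group B, using the normal
#' approximation with tie correction (no continuity correction) — the test
#' conventionally used for single-cell marker detection. Fold changes are
#' computed on de-logged means (see [linear_gene_means()]):
#' `log2FC = log2((mean_a + eps) / (mean_b + eps))` with `eps = 1e-9`, so a
#' gene silent in one group gets a large finite fold change and a gene silent
#' in both groups is reported with `log2FC = 0`, `p = 1`. P-values are
#' Benjamini-Hochberg adjusted across all tested genes.
#'
#' @param matrix an [ExpressionMatrix()] on the lognorm scale.
#' @param cells_a,cells_b disjoint barcode sets (>= 3 cells each).
#' @param min_frac optional prefilter: test only genes detected in at least
#'   this fraction of cells in either group (default 0, no prefilter).
#' @param min_abs_log2fc optional prefilter on |log2FC| (default 0).
#' @return A data.frame with columns `gene`, `log2_fold_change`, `p_value`,
#'   `adjusted_p`, `frac_expressing_a`, `frac_expressing_b`, sorted by
#'   `adjusted_p` then decreasing |log2FC| then gene.
#' @export
differential_expression <- function(matrix, cells_a, cells_b,
                                    min_frac = 0, min_abs_log2fc = 0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "lognorm")
    stop("differential_expression expects log-normalized values")
  cells_a <- as.character(cells_a)
  cells_b <- as.character(cells_b)
  if (length(intersect(cells_a, cells_b)))
    stop("cell groups must be disjoint")
  if (length(cells_a) < 3L || length(cells_b) < 3L)
    stop("each group needs at least 3 cells")
  eps <- 1e-9
  va <- as.matrix(em_subset(matrix, cells = cells_a)$values)
  vb <- as.matrix(em_subset(matrix, cells = cells_b)$values)
  mean_a <- rowMeans(expm1(va))
  mean_b <- rowMeans(expm1(vb))
  frac_a <- rowMeans(va > 0)
  frac_b <- rowMeans(vb > 0)
  silent <- mean_a == 0 & mean_b == 0
  l2fc <- ifelse(silent, 0, log2((mean_a + eps) / (mean_b + eps)))
  test_mask <- !silent &
    (pmax(frac_a, frac_b) >= min_frac) &
    (abs(l2fc) >= min_abs_log2fc)
  p <- rep(NA_real_, nrow(va))
  p[silent] <- 1
  idx <- which(test_mask)
  if (length(idx)) {
    pv <- vapply(idx, function(i) {
      wilcoxon_normal_p(va[i, ], vb[i, ])
    }, numeric(1))
    p[idx] <- pv
  }
  keep <- silent | test_mask
  res <- data.frame(gene = rownames(va)[keep],
                    log2_fold_change = l2fc[keep],
                    p_value = p[keep],
                    frac_expressing_a = frac_a[keep],
                    frac_expressing_b = frac_b[keep])
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[, c("gene", "log2_fold_change", "p_value", "adjusted_p",
                 "frac_expressing_a", "frac_expressing_b")]
  ord <- order(res$adjusted_p, -abs(res$log2_fold_change), res$gene)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Two-sided Mann-Whitney p via the normal approximation with tie correction
# and no continuity correction. Degenerate case (all values tied) -> p = 1.
wilcoxon_normal_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Subset cells by single-gene expression threshold
#'
#' Returns exactly the cells whose log-normalized expression of `gene` is
#' strictly greater than `threshold` — the rule used to isolate
#' high-expressor cells (e.g. cells with upregulated Pfkp, Pfkfb3 or Hk1)
#' before comparing them against the remainder.
#'
#' @param matrix an [ExpressionMatrix()] on the lognorm scale.
#' @param gene gene symbol (must be present).
#' @param threshold expression cutoff on the log-normalized scale.
#' @return Character vector of barcodes (possibly empty).
#' @export
subset_by_expression <- function(matrix, gene, threshold = 1.0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!gene %in% em_genes(matrix))
    stop("gene absent from matrix: ", gene)
  v <- as.numeric(matrix$values[gene, ])
  em_cells(matrix)[v > threshold]
}
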