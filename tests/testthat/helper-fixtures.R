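# Small builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive (loops, enumeration, stats:: reference
# implementations) and share no code with the package internals they check.

make_counts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (!is.null(genes)) rownames(m) <- genes
  if (!is.null(cells)) colnames(m) <- cells
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  ExpressionMatrix(m, scale = "counts")
}

make_lognorm <- function(values, genes = NULL, cells = NULL) {
  em <- make_counts(values, genes, cells)
  em$scale <- "lognorm"
  em
}

make_annot <- function(barcodes, population = "forebrain", genotype = "WT",
                       stage = "E8.25", totals = NA_integer_) {
  data.frame(barcode = barcodes,
             population = rep_len(population, length(barcodes)),
             genotype = rep_len(genotype, length(barcodes)),
             stage = rep_len(stage, length(barcodes)),
             total_umi = rep_len(totals, length(barcodes)),
             mito_fraction = 0)
}

# brute-force survivor scan: loop over every cell and gene
oracle_qc_survivors <- function(m, min_umi, max_umi) {
  keep <- character()
  for (cell in colnames(m)) {
    tot <- sum(m[, cell])
    if (tot >= min_umi && tot <= max_umi) keep <- c(keep, cell)
  }
  keep
}

# per-(population, set) double mean via explicit loops
oracle_pathway_mean <- function(m, pops, sets) {
  out <- list()
  for (pop in sort(unique(pops))) {
    cells <- which(pops == pop)
    for (s in names(sets)) {
      members <- intersect(sets[[s]], rownames(m))
      per_gene <- sapply(members, function(g) mean(m[g, cells]))
      out[[paste(pop, s)]] <- mean(per_gene)
    }
  }
  out
}

# enumerate cells for a threshold pair
oracle_coexpr <- function(m, a, b, t) {
  n <- 0L
  for (cell in colnames(m)) if (m[a, cell] > t && m[b, cell] > t) n <- n + 1L
  n
}

# reference rank-sum p-value (normal approximation, tie-corrected,
# no continuity correction) through stats::wilcox.test
oracle_wilcox_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
}

# enumerate every window and apply the published selection rule via lm()
oracle_window_fit <- function(time, absorbance, window, r2_gate = 0.95) {
  cand <- list()
  for (i in seq_along(time)) {
    if (time[i] + window > max(time) + 1e-9) next
    j <- max(which(time <= time[i] + window + 1e-9))
    if (j - i + 1 < 5) next
    fit <- stats::lm(absorbance[i:j] ~ time[i:j])
    cand[[length(cand) + 1L]] <- list(
      slope = unname(stats::coef(fit)[2]),
      r2 = summary(fit)$r.squared,
      t_start = time[i], t_end = time[j])
  }
  r2s <- sapply(cand, `[[`, "r2")
  slopes <- sapply(cand, `[[`, "slope")
  ok <- which(r2s >= r2_gate)
  k <- if (length(ok)) ok[which.max(abs(slopes[ok]))] else which.max(r2s)
  cand[[k]]
}
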