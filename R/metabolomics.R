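#' Metabolite abundance table
#'
#' Container for an untargeted LC/MS profiling run: a metabolites x samples
#' abundance matrix plus per-sample metadata (group, injection order, QC
#' flag) and per-metabolite pathway membership.
#'
#' @param abundance numeric matrix, metabolites x samples, non-negative, with
#'   dimnames.
#' @param samples data.frame with columns `sample`, `group` (e.g. "WT", "KO",
#'   "QC"), `injection_order` (unique integers), `is_qc` (logical).
#' @param metabolites data.frame with columns `metabolite`, `pathway`.
#' @return A `MetaboliteTable` (list with the three elements above).
#' @export
MetaboliteTable <- function(abundance, samples, metabolites) {
  stopifnot(is.matrix(abundance))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs metabolite row names and sample column names")
  if (any(abundance < 0) || anyNA(abundance))
    stop("abundances must be non-negative and non-missing")
  req_s <- c("sample", "group", "injection_order", "is_qc")
  if (!all(req_s %in% names(samples)))
    stop("samples needs columns: ", paste(req_s, collapse = ", "))
  if (anyDuplicated(samples$injection_order))
    stop("injection orders must be unique")
  if (!setequal(samples$sample, colnames(abundance)))
    stop("sample metadata does not match abundance columns")
  req_m <- c("metabolite", "pathway")
  if (!all(req_m %in% names(metabolites)))
    stop("metabolites needs columns: ", paste(req_m, collapse = ", "))
  if (!setequal(metabolites$metabolite, rownames(abundance)))
    stop("metabolite metadata does not match abundance rows")
  samples <- samples[match(colnames(abundance), samples$sample), ,
                     drop = FALSE]
  metabolites <- metabolites[match(rownames(abundance),
                                   metabolites$metabolite), , drop = FALSE]
  rownames(samples) <- rownames(metabolites) <- NULL
  structure(list(abundance = abundance, samples = samples,
                 metabolites = metabolites), class = "MetaboliteTable")
}

#' @exportS3Method base::print
print.MetaboliteTable <- function(x, ...) {
  cat(sprintf("MetaboliteTable: %d metabolites x %d samples (%d QC)\n",
              nrow(x$abundance), ncol(x$abundance), sum(x$samples$is_qc)))
  invisible(x)
}

#' Read / write a metabolite table as three CSV files
#'
#' `abundance_path`: metabolites x samples CSV with the metabolite name in
#' the first column; `samples_path` and `metabolites_path`: the two metadata
#' sheets as described in [MetaboliteTable()].
#'
#' @param abundance_path,samples_path,metabolites_path CSV paths.
#' @return A [MetaboliteTable()].
#' @export
read_metabolite_table <- function(abundance_path, samples_path,
                                  metabolites_path) {
  ab <- utils::read.csv(abundance_path, check.names = FALSE)
  m <- as.matrix(ab[, -1L, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- as.character(ab[[1L]])
  samples <- utils::read.csv(samples_path)
  samples$is_qc <- as.logical(samples$is_qc)
  metabolites <- utils::read.csv(metabolites_path)
  MetaboliteTable(m, samples, metabolites)
}

#' @rdname read_metabolite_table
#' @param x a [MetaboliteTable()].
#' @return Invisibly, `abundance_path`.
#' @export
write_metabolite_table <- function(x, abundance_path, samples_path,
                                   metabolites_path) {
  stopifnot(inherits(x, "MetaboliteTable"))
  df <- data.frame(metabolite = rownames(x$abundance), x$abundance,
                   check.names = FALSE)
  utils::write.csv(df, abundance_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$samples, samples_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$metabolites, metabolites_path, row.names = FALSE,
                   quote = FALSE)
  invisible(abundance_path)
}

#' Pooled-QC drift normalization
#'
#' Corrects instrument drift using pooled quality-control samples injected at
#' regular intervals. Per metabolite, each sample's value is divided by the
#' linear interpolation (in injection order) between its flanking QC values —
#' samples before the first or after the last QC reuse the nearest QC — and
#' rescaled by that metabolite's median QC value so that abundances stay on
#' their original scale. QC samples themselves are transformed the same way,
#' which maps every QC value of a metabolite to its median: a drift-free run
#' leaves the QC coefficient of variation at zero, and re-running the
#' normalization on its own output is a no-op.
#'
#' Metabolites with a zero in any QC sample cannot be interpolated reliably;
#' they are left unnormalized and listed in the `"flagged"` attribute.
#'
#' @param table a [MetaboliteTable()] with >= 2 QC samples.
#' @return A [MetaboliteTable()] with drift-corrected abundances and a
#'   `"flagged"` attribute naming any unnormalized metabolites.
#' @export
qc_drift_normalize <- function(table) {
  stopifnot(inherits(table, "MetaboliteTable"))
  qc_idx <- which(table$samples$is_qc)
  if (length(qc_idx) < 2L)
    stop("need at least 2 QC samples for drift normalization")
  orders <- table$samples$injection_order
  qc_orders <- orders[qc_idx]
  ab <- table$abundance
  out <- ab
  flagged <- character()
  for (i in seq_len(nrow(ab))) {
    qv <- ab[i, qc_idx]
    if (any(qv == 0)) {
      flagged <- c(flagged, rownames(ab)[i])
      next
    }
    interp <- stats::approx(qc_orders, qv, xout = orders, rule = 2,
                            ties = "ordered")$y
    out[i, ] <- ab[i, ] / interp * stats::median(qv)
  }
  res <- MetaboliteTable(out, table$samples, table$metabolites)
  attr(res, "flagged") <- flagged
  res
}

#' Per-metabolite differential abundance
#'
#' Two-sided two-sample Student t-test (equal variances by default; set
#' `var_equal = FALSE` for Welch) per metabolite between the KO and WT
#' groups, after excluding QC samples. The fold change is the ratio of raw
#' group means (KO over WT) regardless of `log_transform`, which only affects
#' the values entering the t-test. Significance is called at `p < alpha` with
#' no multiple-testing correction; a Benjamini-Hochberg column is reported
#' for reference but does not drive the `significant` flag.
#'
#' @param table a [MetaboliteTable()] (>= 2 samples per group).
#' @param alpha significance level.
#' @param group_a,group_b group labels; fold change and t statistic are
#'   `group_a` over/versus `group_b`.
#' @param log_transform test on `log(value + 1)` instead of natural scale.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return A data.frame: `metabolite`, `pathway`, `fold_change`, `p_value`,
#'   `adjusted_p`, `significant`, sorted by metabolite.
#' @export
differential_abundance <- function(table, alpha = 0.05,
                                   group_a = "KO", group_b = "WT",
                                   log_transform = FALSE, var_equal = TRUE) {
  stopifnot(inherits(table, "MetaboliteTable"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  sa <- !table$samples$is_qc & table$samples$group == group_a
  sb <- !table$samples$is_qc & table$samples$group == group_b
  if (sum(sa) < 2L || sum(sb) < 2L)
    stop("need at least 2 non-QC samples per group")
  ab <- table$abundance
  n <- nrow(ab)
  fc <- p <- numeric(n)
  for (i in seq_len(n)) {
    xa <- ab[i, sa]
    xb <- ab[i, sb]
    fc[i] <- mean(xa) / mean(xb)
    ta <- if (log_transform) log1p(xa) else xa
    tb <- if (log_transform) log1p(xb) else xb
    if (stats::var(ta) == 0 && stats::var(tb) == 0) {
      p[i] <- if (mean(ta) == mean(tb)) 1 else 0
    } else {
      p[i] <- stats::t.test(ta, tb, var.equal = var_equal)$p.value
    }
  }
  res <- data.frame(metabolite = rownames(ab),
                    pathway = table$metabolites$pathway,
                    fold_change = fc,
                    p_value = p,
                    adjusted_p = stats::p.adjust(p, method = "BH"),
                    significant = p < alpha)
  res <- res[order(res$metabolite), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pathway-level metabolite summaries
#'
#' Per pathway: how many metabolites were measured, how many were called
#' significant, and the cumulative fold change. "Cumulative" is computed as
#' the ratio of summed group means — total KO abundance of the pathway's
#' metabolites over total WT abundance — which weights abundant metabolites
#' more; the unweighted mean of per-metabolite fold changes is reported
#' alongside since the two definitions diverge whenever abundances are
#' unequal.
#'
#' @param results output of [differential_abundance()].
#' @param table the [MetaboliteTable()] the results were computed from.
#' @param group_a,group_b group labels as in [differential_abundance()].
#' @return A data.frame keyed by `pathway`: `n_metabolites`, `n_significant`,
#'   `frac_significant`, `cumulative_fold_change` (sum ratio),
#'   `mean_fold_change`. Pathways with no measured metabolite are skipped
#'   with a warning.
#' @export
pathway_metabolite_summary <- function(results, table,
                                       group_a = "KO", group_b = "WT") {
  stopifnot(inherits(table, "MetaboliteTable"))
  sa <- !table$samples$is_qc & table$samples$group == group_a
  sb <- !table$samples$is_qc & table$samples$group == group_b
  pathways <- unique(table$metabolites$pathway)
  rows <- list()
  for (pw in pathways) {
    mets <- table$metabolites$metabolite[table$metabolites$pathway == pw]
    sub <- results[results$metabolite %in% mets, , drop = FALSE]
    if (!nrow(sub)) {
      warning("pathway with no measured metabolites skipped: ", pw)
      next
    }
    ab <- table$abundance[sub$metabolite, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = pw,
      n_metabolites = nrow(sub),
      n_significant = sum(sub$significant),
      frac_significant = mean(sub$significant),
      cumulative_fold_change = sum(rowMeans(ab[, sa, drop = FALSE])) /
        sum(rowMeans(ab[, sb, drop = FALSE])),
      mean_fold_change = mean(sub$fold_change)
    )
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Rank the top significantly changed metabolites
#'
#' Splits significant metabolites into up- (fold change > 1) and
#' downregulated (< 1) lists, ordered by effect size: upregulated by
#' decreasing fold change, downregulated by increasing fold change, ties
#' broken by p-value then metabolite name.
#'
#' @param results output of [differential_abundance()].
#' @param n_top maximum list length (full list if fewer qualify).
#' @return A list of two data.frames, `up` and `down`.
#' @export
rank_top_changed <- function(results, n_top = 10L) {
  if (!nrow(results)) stop("empty results")
  sig <- results[results$significant, , drop = FALSE]
  up <- sig[sig$fold_change > 1, , drop = FALSE]
  up <- up[order(-up$fold_change, up$p_value, up$metabolite), , drop = FALSE]
  down <- sig[sig$fold_change < 1, , drop = FALSE]
  down <- down[order(down$fold_change, down$p_value, down$metabolite), ,
               drop = FALSE]
  list(up = utils::head(up, n_top), down = utils::head(down, n_top))
}
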