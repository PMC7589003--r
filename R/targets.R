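#' Intersect a predicted miRNA-target list with pathway gene sets
#'
#' Exact (case-sensitive) set intersection of a predicted-target gene list
#' with each set of a catalog — e.g. how many predicted miR-302 targets fall
#' among the glycolysis genes, and how many of those sit in upper glycolysis.
#' Optionally joins gene-level KO/WT fold changes onto the intersected
#' targets.
#'
#' @param target_list character vector of predicted target symbols
#'   (duplicates are removed before intersection).
#' @param catalog named list of gene sets.
#' @param fc_table optional gene-level output of [genotype_fold_change()]
#'   (any level carrying `gene` and `fold_change` columns); per-target fold
#'   changes are averaged over its rows for that gene.
#' @return A data.frame keyed by `pathway` with `n_pathway_genes`,
#'   `n_targets_in_pathway` and a comma-separated `target_genes` column
#'   (alphabetical). The `"details"` attribute holds a long data.frame
#'   (`pathway`, `gene`, and `fold_change` when `fc_table` was supplied).
#'   Empty intersections are valid zero-count rows.
#' @export
intersect_targets <- function(target_list, catalog, fc_table = NULL) {
  targets <- unique(as.character(target_list))
  if (!length(targets)) stop("empty target list")
  if (!length(catalog)) stop("empty gene-set catalog")
  rows <- lapply(names(catalog), function(pw) {
    set <- unique(catalog[[pw]])
    hit <- sort(intersect(targets, set))
    data.frame(pathway = pw,
               n_pathway_genes = length(set),
               n_targets_in_pathway = length(hit),
               target_genes = paste(hit, collapse = ","))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  details <- do.call(rbind, lapply(names(catalog), function(pw) {
    hit <- sort(intersect(targets, unique(catalog[[pw]])))
    if (!length(hit)) return(NULL)
    d <- data.frame(pathway = pw, gene = hit)
    if (!is.null(fc_table)) {
      d$fold_change <- vapply(hit, function(g) {
        v <- fc_table$fold_change[fc_table$gene %in% g]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    }
    d
  }))
  if (is.null(details)) {
    details <- data.frame(pathway = character(), gene = character())
    if (!is.null(fc_table)) details$fold_change <- numeric()
  }
  rownames(details) <- NULL
  attr(res, "details") <- details
  res
}
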