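#' Per-population pathway mean expression
#'
#' The central scoring step: for each cell population and each gene set, the
#' mean over member genes of the per-gene mean log-normalized expression over
#' that population's cells (genes first averaged over cells, then averaged
#' within the set, each gene weighted equally). Catalog genes absent from the
#' matrix are excluded and reflected in `n_genes_used`; a set with no matched
#' genes yields a flagged row with `NA` mean rather than being dropped.
#'
#' @param matrix an [ExpressionMatrix()] on the lognorm scale.
#' @param annot cell annotation covering the matrix (column `population`).
#' @param catalog named list of gene sets (see [read_gene_sets()]).
#' @return A data.frame keyed by (`population`, `pathway`) with
#'   `mean_expression`, `n_genes_used`, and logical `no_genes_matched`.
#' @export
population_pathway_mean <- function(matrix, annot, catalog) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  annot <- validate_annotation(annot, matrix)
  if (!length(catalog)) stop("empty gene-set catalog")
  pops <- sort(unique(annot$population))
  genes <- em_genes(matrix)
  rows <- list()
  for (pop in pops) {
    cells <- annot$barcode[annot$population == pop]
    gm <- Matrix::rowMeans(matrix$values[, cells, drop = FALSE])
    for (set_name in names(catalog)) {
      members <- intersect(catalog[[set_name]], genes)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop,
        pathway = set_name,
        mean_expression = if (length(members)) mean(gm[members]) else NA_real_,
        n_genes_used = length(members),
        no_genes_matched = length(members) == 0L
      )
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$pathway, res$population), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Normalize pathway means to the lowest-expressing population
#'
#' Within each pathway, divides every population's mean expression by the
#' minimum across populations, so the lowest-expressing population scores
#' exactly 1 and every other population's score reads as a fold difference
#' relative to it.
#'
#' @param scores output of [population_pathway_mean()].
#' @return The input with a `relative_score` column added.
#' @export
normalize_to_min_population <- function(scores) {
  stopifnot(all(c("population", "pathway", "mean_expression") %in%
                  names(scores)))
  res <- scores
  res$relative_score <- NA_real_
  for (pw in unique(res$pathway)) {
    i <- which(res$pathway == pw & !is.na(res$mean_expression))
    if (!length(i)) next
    m <- min(res$mean_expression[i])
    if (m <= 0)
      stop("pathway '", pw, "' has a non-positive minimum mean expression; ",
           "cannot normalize to the minimal population")
    res$relative_score[i] <- res$mean_expression[i] / m
  }
  res
}

#' Stage-to-stage change in pathway expression
#'
#' Element-wise ratio of pathway mean expression between two stages (later
#' over earlier, e.g. E9.5 over E8.25), per (population, pathway) key; values
#' above 1 denote upregulation at the later stage.
#'
#' @param scores_early,scores_late outputs of [population_pathway_mean()] at
#'   the two stages.
#' @return A data.frame keyed by (`population`, `pathway`) with
#'   `fold_change`. Keys present at only one stage are dropped and reported
#'   via a warning and the `"missing_keys"` attribute.
#' @export
stage_change <- function(scores_early, scores_late) {
  key <- function(d) paste(d$population, d$pathway, sep = "\r")
  ke <- key(scores_early)
  kl <- key(scores_late)
  shared <- intersect(ke, kl)
  missing <- union(setdiff(ke, kl), setdiff(kl, ke))
  if (length(missing))
    warning("keys present at one stage only: ",
            paste(gsub("\r", "/", missing), collapse = ", "))
  e <- scores_early[match(shared, ke), , drop = FALSE]
  l <- scores_late[match(shared, kl), , drop = FALSE]
  res <- data.frame(population = e$population,
                    pathway = e$pathway,
                    fold_change = l$mean_expression / e$mean_expression)
  res <- res[order(res$pathway, res$population), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "missing_keys") <- gsub("\r", "/", missing)
  res
}

# Per-gene per-population KO/WT fold changes on de-logged means.
# Returns a data.frame (population, gene, fold_change).
gene_population_fc <- function(matrix_wt, matrix_ko, annot_wt, annot_ko,
                               genes, eps = 1e-9) {
  pops_wt <- unique(annot_wt$population)
  pops_ko <- unique(annot_ko$population)
  shared <- sort(intersect(pops_wt, pops_ko))
  lost <- setdiff(union(pops_wt, pops_ko), shared)
  if (length(lost))
    warning("populations present in only one genotype excluded: ",
            paste(lost, collapse = ", "))
  if (!length(shared)) stop("no population shared between genotypes")
  rows <- lapply(shared, function(pop) {
    mw <- linear_gene_means(matrix_wt,
                            annot_wt$barcode[annot_wt$population == pop])
    mk <- linear_gene_means(matrix_ko,
                            annot_ko$barcode[annot_ko$population == pop])
    data.frame(population = pop, gene = genes,
               fold_change = (mk[genes] + eps) / (mw[genes] + eps))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Knockout-versus-wildtype fold-change aggregation
#'
#' The fold change is first computed for each gene individually within each
#' population — KO mean over WT mean on the de-logged scale (see
#' [linear_gene_means()]), with a `1e-9` pseudocount on both means — and then
#' averaged upward:
#' \describe{
#'   \item{`"gene"`}{per-gene per-population fold changes, keyed
#'     (population, pathway, gene).}
#'   \item{`"pathway"`}{arithmetic mean of the gene-level fold changes over
#'     each set's member genes, keyed (population, pathway).}
#'   \item{`"population"`}{mean over all unique catalog genes per population.}
#'   \item{`"ectoderm"`}{gene-level fold changes averaged across
#'     ectoderm-derived populations (every population except
#'     `non_ectoderm`), keyed (pathway, gene).}
#' }
#'
#' @param matrix_wt,matrix_ko [ExpressionMatrix()] objects on a shared gene
#'   universe (lognorm scale for the standard pipeline; counts accepted).
#' @param annot_wt,annot_ko matching cell annotations.
#' @param catalog named list of gene sets.
#' @param level aggregation level, see Details.
#' @param agg `"arithmetic"` (default) or `"geometric"` mean for every
#'   averaging step above the gene level.
#' @param non_ectoderm_label population label excluded by level
#'   `"ectoderm"`.
#' @return A data.frame with a `fold_change` column, `n_averaged` (number of
#'   values entering each mean) and level-appropriate key columns. Sets with
#'   no matched genes yield flagged `NA` rows.
#' @examples
#' sim <- generate_sc_dataset(sc_sim_config(seed = 1, cells_per_population = 60))
#' lw <- log_normalize(sim$wt); lk <- log_normalize(sim$ko)
#' fc <- genotype_fold_change(lw, lk, sim$annot_wt, sim$annot_ko,
#'                            sim$catalog, level = "pathway")
#' head(fc)
#' @export
genotype_fold_change <- function(matrix_wt, matrix_ko, annot_wt, annot_ko,
                                 catalog,
                                 level = c("gene", "pathway", "population",
                                           "ectoderm"),
                                 agg = c("arithmetic", "geometric"),
                                 non_ectoderm_label = "non_ectoderm") {
  level <- match.arg(level)
  agg <- match.arg(agg)
  stopifnot(inherits(matrix_wt, "ExpressionMatrix"),
            inherits(matrix_ko, "ExpressionMatrix"))
  if (matrix_wt$scale != matrix_ko$scale)
    stop("WT and KO matrices must share a scale")
  annot_wt <- validate_annotation(annot_wt, matrix_wt)
  annot_ko <- validate_annotation(annot_ko, matrix_ko)
  universe <- intersect(em_genes(matrix_wt), em_genes(matrix_ko))
  if (!length(universe)) stop("genotype matrices share no genes")
  cat_genes <- unique(unlist(catalog, use.names = FALSE))
  genes <- intersect(cat_genes, universe)
  if (!length(genes)) stop("no catalog gene present in both matrices")
  gfc <- gene_population_fc(matrix_wt, matrix_ko, annot_wt, annot_ko, genes)
  mean_fun <- if (agg == "arithmetic") mean else function(x) exp(mean(log(x)))

  membership <- lapply(catalog, function(s) intersect(s, genes))
  gene_rows <- do.call(rbind, lapply(names(membership), function(pw) {
    mem <- membership[[pw]]
    sub <- gfc[gfc$gene %in% mem, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(population = sub$population, pathway = pw, gene = sub$gene,
               fold_change = sub$fold_change, n_averaged = 1L)
  }))

  if (level == "gene") {
    res <- gene_rows
    # flag catalog sets with nothing matched
    unmatched <- names(membership)[lengths(membership) == 0L]
    if (length(unmatched)) {
      res <- rbind(res, data.frame(population = NA_character_,
                                   pathway = unmatched, gene = NA_character_,
                                   fold_change = NA_real_, n_averaged = 0L))
    }
    res <- res[order(res$pathway, res$population, res$gene), , drop = FALSE]
  } else if (level == "pathway") {
    res <- do.call(rbind, lapply(names(membership), function(pw) {
      mem <- membership[[pw]]
      pops <- sort(unique(gfc$population))
      if (!length(mem))
        return(data.frame(population = pops, pathway = pw,
                          fold_change = NA_real_, n_averaged = 0L))
      do.call(rbind, lapply(pops, function(pop) {
        v <- gfc$fold_change[gfc$population == pop & gfc$gene %in% mem]
        data.frame(population = pop, pathway = pw,
                   fold_change = mean_fun(v), n_averaged = length(v))
      }))
    }))
    res <- res[order(res$pathway, res$population), , drop = FALSE]
  } else if (level == "population") {
    pops <- sort(unique(gfc$population))
    res <- do.call(rbind, lapply(pops, function(pop) {
      v <- gfc$fold_change[gfc$population == pop]
      data.frame(population = pop, fold_change = mean_fun(v),
                 n_averaged = length(v))
    }))
  } else { # ectoderm
    ecto <- gfc[gfc$population != non_ectoderm_label, , drop = FALSE]
    if (!nrow(ecto)) stop("no ectoderm-derived population present")
    res <- do.call(rbind, lapply(names(membership), function(pw) {
      mem <- membership[[pw]]
      if (!length(mem))
        return(data.frame(pathway = pw, gene = NA_character_,
                          fold_change = NA_real_, n_averaged = 0L))
      do.call(rbind, lapply(mem, function(g) {
        v <- ecto$fold_change[ecto$gene == g]
        data.frame(pathway = pw, gene = g, fold_change = mean_fun(v),
                   n_averaged = length(v))
      }))
    }))
    res <- res[order(res$pathway, res$gene), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Glycolysis sub-pathway fold changes
#'
#' Applies [genotype_fold_change()] at the pathway level to a catalog of
#' glycolysis sub-pathway sets (glucose import/phosphorylation, upper and
#' lower glycolysis, the shift to oxidative phosphorylation, gluconeogenesis,
#' pentose phosphate). Sub-pathway sets may overlap; each is scored
#' independently.
#'
#' @inheritParams genotype_fold_change
#' @param glycolysis_subsets named list of sub-pathway gene sets.
#' @return A data.frame keyed by (`population`, `subpathway`) with
#'   `fold_change` and `n_averaged`; empty sub-pathways yield flagged `NA`
#'   rows.
#' @export
subpathway_fold_change <- function(matrix_wt, matrix_ko, annot_wt, annot_ko,
                                   glycolysis_subsets,
                                   agg = c("arithmetic", "geometric")) {
  res <- genotype_fold_change(matrix_wt, matrix_ko, annot_wt, annot_ko,
                              catalog = glycolysis_subsets,
                              level = "pathway", agg = match.arg(agg))
  names(res)[names(res) == "pathway"] <- "subpathway"
  res
}
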