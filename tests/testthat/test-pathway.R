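test_that("pathway means equal the brute-force genes-outer double mean", {
  m <- make_lognorm(matrix(c(2), 1, 1), genes = "Hk1", cells = "c1")
  annot <- make_annot("c1")
  res <- population_pathway_mean(m, annot, list(set = "Hk1"))
  expect_equal(res$mean_expression, 2)

  set.seed(13)
  mm <- matrix(round(runif(12 * 20, 0, 4), 2), nrow = 12,
               dimnames = list(sprintf("g%02d", 1:12), sprintf("c%02d", 1:20)))
  em <- make_lognorm(mm)
  pops <- rep(c("forebrain", "non_ectoderm"), each = 10)
  annot <- make_annot(colnames(mm), population = pops)
  sets <- list(five = sprintf("g%02d", 1:5),
               overlap = sprintf("g%02d", 4:9),
               with_absent = c("g10", "g11", "NotAGene"))
  res <- population_pathway_mean(em, annot, sets)
  oracle <- oracle_pathway_mean(mm, pops, sets)
  for (i in seq_len(nrow(res))) {
    key <- paste(res$population[i], res$pathway[i])
    expect_equal(res$mean_expression[i], oracle[[key]], tolerance = 1e-12,
                 label = key)
  }
  expect_identical(res$n_genes_used[res$pathway == "with_absent"], c(2L, 2L))

  # permuting cells leaves every score unchanged
  perm <- sample(colnames(mm))
  res2 <- population_pathway_mean(em_subset(em, cells = perm),
                                  annot[match(perm, annot$barcode), ], sets)
  expect_equal(res2, res)
})

test_that("a pathway with no matched genes yields a flagged row", {
  m <- make_lognorm(matrix(1, 1, 2), genes = "Hk1", cells = c("c1", "c2"))
  res <- population_pathway_mean(m, make_annot(c("c1", "c2")),
                                 list(ghost = c("NoA", "NoB")))
  expect_true(res$no_genes_matched)
  expect_identical(res$n_genes_used, 0L)
  expect_true(is.na(res$mean_expression))
})

test_that("min-population normalization gives the minimal population 1", {
  scores <- data.frame(population = c("neuroepithelium", "non_neural"),
                       pathway = "glycolysis",
                       mean_expression = c(2.4, 2.0))
  res <- normalize_to_min_population(scores)
  expect_equal(res$relative_score, c(1.2, 1.0))

  equal <- data.frame(population = c("a", "b", "c"), pathway = "p",
                      mean_expression = c(3, 3, 3))
  expect_equal(normalize_to_min_population(equal)$relative_score, rep(1, 3))

  tri <- data.frame(population = c("a", "b", "c"), pathway = "p",
                    mean_expression = c(1, 2, 4))
  expect_equal(normalize_to_min_population(tri)$relative_score, c(1, 2, 4))

  zero <- data.frame(population = c("a", "b"), pathway = "dead",
                     mean_expression = c(0, 2))
  expect_error(normalize_to_min_population(zero), "dead")
})

test_that("stage change is the element-wise ratio with missing keys reported", {
  early <- data.frame(population = c("a", "a", "b"),
                      pathway = c("p1", "p2", "p1"),
                      mean_expression = c(1.0, 2.0, 4.0))
  late <- data.frame(population = c("a", "a", "b"),
                     pathway = c("p1", "p2", "p1"),
                     mean_expression = c(1.3, 2.0, 2.0))
  res <- stage_change(early, late)
  expect_equal(res$fold_change[res$population == "a" & res$pathway == "p1"],
               1.3)
  expect_equal(res$fold_change[res$population == "b" & res$pathway == "p1"],
               0.5)
  expect_equal(stage_change(early, early)$fold_change, rep(1, 3))

  expect_warning(res2 <- stage_change(early[-1, ], late), "one stage only")
  expect_identical(attr(res2, "missing_keys"), "a/p1")
})

test_that("genotype fold change is 1 everywhere on identical inputs", {
  set.seed(19)
  mm <- matrix(rpois(10 * 12, 6) + 1, nrow = 10,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:12)))
  em <- log_normalize(ExpressionMatrix(mm, "counts"))
  annot <- make_annot(colnames(mm),
                      population = rep(c("forebrain", "non_ectoderm"), 6))
  sets <- list(p1 = sprintf("g%02d", 1:4), p2 = sprintf("g%02d", 3:10))
  for (lv in c("gene", "pathway", "population", "ectoderm")) {
    fc <- genotype_fold_change(em, em, annot, annot, sets, level = lv)
    expect_equal(fc$fold_change, rep(1, nrow(fc)), tolerance = 1e-9,
                 label = lv)
  }
})

test_that("pathway-level fold change is the mean of emitted gene-level rows", {
  set.seed(29)
  mw <- matrix(rpois(9 * 10, 8) + 1, nrow = 9,
               dimnames = list(sprintf("g%d", 1:9), sprintf("w%02d", 1:10)))
  mk <- matrix(rpois(9 * 10, 12) + 1, nrow = 9,
               dimnames = list(sprintf("g%d", 1:9), sprintf("k%02d", 1:10)))
  ew <- log_normalize(ExpressionMatrix(mw, "counts"))
  ek <- log_normalize(ExpressionMatrix(mk, "counts"))
  aw <- make_annot(colnames(mw), population = rep(c("fb", "nc"), 5))
  ak <- make_annot(colnames(mk), population = rep(c("fb", "nc"), 5),
                   genotype = "KO")
  sets <- list(trio = c("g1", "g2", "g3"), rest = sprintf("g%d", 4:9))
  gene_fc <- genotype_fold_change(ew, ek, aw, ak, sets, level = "gene")
  path_fc <- genotype_fold_change(ew, ek, aw, ak, sets, level = "pathway")
  for (i in seq_len(nrow(path_fc))) {
    sub <- gene_fc[gene_fc$pathway == path_fc$pathway[i] &
                     gene_fc$population == path_fc$population[i], ]
    expect_equal(path_fc$fold_change[i], mean(sub$fold_change),
                 tolerance = 1e-12)
    expect_identical(path_fc$n_averaged[i], nrow(sub))
  }
  # hand-averaged trio for one population
  fb_trio <- gene_fc$fold_change[gene_fc$pathway == "trio" &
                                   gene_fc$population == "fb"]
  expect_equal(path_fc$fold_change[path_fc$pathway == "trio" &
                                     path_fc$population == "fb"],
               (fb_trio[1] + fb_trio[2] + fb_trio[3]) / 3, tolerance = 1e-12)
})

test_that("populations present in one genotype only are excluded with warning", {
  mm <- matrix(rpois(4 * 6, 5) + 1, nrow = 4,
               dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:6)))
  em <- log_normalize(ExpressionMatrix(mm, "counts"))
  aw <- make_annot(colnames(mm), population = rep(c("fb", "mb"), 3))
  ak <- make_annot(colnames(mm), population = rep(c("fb", "hb"), 3),
                   genotype = "KO")
  expect_warning(fc <- genotype_fold_change(em, em, aw, ak,
                                            list(s = c("g1", "g2")),
                                            level = "pathway"),
                 "only one genotype")
  expect_identical(unique(fc$population), "fb")
})

test_that("an injected 4.5x multiplier is recovered across ectoderm populations", {
  cfg <- sc_sim_config(seed = 101, cells_per_population = 300,
                       genotype_multipliers = c(Pfkp = 4.5),
                       coexpression_pairs = list())
  sim <- generate_sc_dataset(cfg)
  lw <- log_normalize(sim$wt)
  lk <- log_normalize(sim$ko)
  fc <- genotype_fold_change(lw, lk, sim$annot_wt, sim$annot_ko,
                             sim$catalog["glycolysis"], level = "ectoderm")
  est <- fc$fold_change[fc$gene == "Pfkp"]
  expect_lt(abs(est - 4.5) / 4.5, 0.15)
})

test_that("sub-pathway injection moves only the injected sub-pathway", {
  catalog <- simulate_gene_catalog()
  upper <- catalog$upper_glycolysis
  cfg <- sc_sim_config(seed = 7, cells_per_population = 250,
                       genotype_multipliers = setNames(rep(2, length(upper)),
                                                       upper),
                       coexpression_pairs = list())
  sim <- generate_sc_dataset(cfg)
  lw <- log_normalize(sim$wt)
  lk <- log_normalize(sim$ko)
  subsets <- catalog[attr(catalog, "subpathways")]
  fc <- subpathway_fold_change(lw, lk, sim$annot_wt, sim$annot_ko, subsets)
  agg <- tapply(fc$fold_change, fc$subpathway, mean)
  expect_lt(abs(agg[["upper_glycolysis"]] - 2) / 2, 0.12)
  for (sp in c("glycolysis_to_oxphos", "pentose_phosphate"))
    expect_lt(abs(agg[[sp]] - 1), 0.12)
  # lower glycolysis shares no upper gene, stays near 1
  expect_lt(abs(agg[["lower_glycolysis"]] - 1), 0.12)

  empty <- subpathway_fold_change(lw, lk, sim$annot_wt, sim$annot_ko,
                                  c(subsets["upper_glycolysis"],
                                    list(ghost = "NotPresent")))
  expect_true(all(is.na(empty$fold_change[empty$subpathway == "ghost"])))
  expect_true(all(empty$n_averaged[empty$subpathway == "ghost"] == 0L))
})

test_that("raising the injected multiplier raises the estimated fold change", {
  est_for <- function(mult, seed) {
    cfg <- sc_sim_config(seed = seed, cells_per_population = 60,
                         populations = c("hindbrain", "non_ectoderm"),
                         genotype_multipliers = c(Pfkp = mult),
                         coexpression_pairs = list())
    sim <- generate_sc_dataset(cfg)
    fc <- genotype_fold_change(log_normalize(sim$wt), log_normalize(sim$ko),
                               sim$annot_wt, sim$annot_ko,
                               list(glycolysis = "Pfkp"), level = "ectoderm")
    fc$fold_change[fc$gene == "Pfkp"]
  }
  seeds <- 1:10
  e1 <- sapply(seeds, function(s) est_for(1, s))
  e2 <- sapply(seeds, function(s) est_for(2, s))
  e45 <- sapply(seeds, function(s) est_for(4.5, s))
  expect_lt(mean(e1), mean(e2))
  expect_lt(mean(e2), mean(e45))
})
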