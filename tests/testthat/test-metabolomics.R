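make_metab <- function(ab, groups, orders = seq_along(groups),
                       pathways = rep("glycolysis", nrow(ab))) {
  colnames(ab) <- sprintf("s%02d", seq_len(ncol(ab)))
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("m%02d", seq_len(nrow(ab)))
  MetaboliteTable(ab,
                  samples = data.frame(sample = colnames(ab), group = groups,
                                       injection_order = orders,
                                       is_qc = groups == "QC"),
                  metabolites = data.frame(metabolite = rownames(ab),
                                           pathway = pathways))
}

test_that("constant QC values make drift normalization the identity", {
  ab <- rbind(m1 = c(100, 50, 80, 100, 60, 100),
              m2 = c(10, 5, 8, 10, 6, 10))
  groups <- c("QC", "WT", "KO", "QC", "WT", "QC")
  tab <- make_metab(ab, groups)
  out <- qc_drift_normalize(tab)
  expect_equal(out$abundance, tab$abundance, tolerance = 1e-12)
})

test_that("noiseless linear drift is removed exactly", {
  orders <- 1:13
  drift <- seq(100, 200, length.out = 13) / 100
  groups <- rep("WT", 13)
  groups[c(1, 7, 13)] <- "QC"
  groups[c(3, 5, 9, 11)] <- "KO"
  base <- c(m1 = 40, m2 = 400)
  ab <- outer(base, drift)
  tab <- make_metab(ab, groups, orders)
  out <- qc_drift_normalize(tab)
  qc_cols <- out$samples$is_qc
  for (i in 1:2) {
    qc_vals <- out$abundance[i, qc_cols]
    expect_lt(stats::sd(qc_vals) / mean(qc_vals), 1e-9)
    # the study-sample trend is gone: every sample lands on the metabolite's
    # median QC level, flat across the run
    target <- median(tab$abundance[i, qc_cols])
    expect_equal(unname(out$abundance[i, !qc_cols]),
                 rep(target, sum(!qc_cols)), tolerance = 1e-9)
  }
})

test_that("a sample at a QC injection position is divided by that QC value", {
  # sample s2 shares no position, but interpolation at a QC's own order must
  # return that QC value; place a sample immediately adjacent and verify the
  # endpoint rule before the first QC (nearest QC reused)
  ab <- rbind(m1 = c(80, 100, 120, 90))
  groups <- c("WT", "QC", "WT", "QC")
  tab <- make_metab(ab, groups, orders = c(1, 2, 3, 4))
  out <- qc_drift_normalize(tab)
  med <- median(c(100, 90))
  expect_equal(out$abundance[1, 1], 80 / 100 * med)   # before first QC
  expect_equal(out$abundance[1, 3], 120 / ((100 + 90) / 2) * med)
})

test_that("zero QC values flag the metabolite and leave it unnormalized", {
  ab <- rbind(good = c(100, 50, 100), dead = c(0, 5, 0))
  tab <- make_metab(ab, c("QC", "WT", "QC"))
  out <- qc_drift_normalize(tab)
  expect_identical(attr(out, "flagged"), "dead")
  expect_equal(out$abundance["dead", ], tab$abundance["dead", ])
  expect_error(qc_drift_normalize(make_metab(ab[, 1:2, drop = FALSE],
                                             c("QC", "WT"))), "at least 2 QC")
})

test_that("drift normalization is idempotent", {
  sim <- generate_metabolite_dataset(seed = 3, drift_slope = 0.02)
  once <- qc_drift_normalize(sim$table)
  twice <- qc_drift_normalize(once)
  expect_lt(max(abs(twice$abundance - once$abundance) /
                  pmax(once$abundance, 1e-12)), 1e-9)
})

test_that("differential abundance handles identical and degenerate groups", {
  ab <- rbind(m1 = c(5, 6, 7, 5, 6, 7), m2 = rep(4, 6))
  tab <- make_metab(ab, rep(c("WT", "KO"), each = 3))
  res <- differential_abundance(tab, alpha = 0.05)
  expect_equal(res$fold_change, c(1, 1))
  expect_equal(res$p_value, c(1, 1))
  expect_false(any(res$significant))
  expect_error(differential_abundance(tab, alpha = 1.2), "alpha")
})

test_that("group swap inverts fold changes and preserves p-values", {
  sim <- generate_metabolite_dataset(seed = 11)
  norm <- qc_drift_normalize(sim$table)
  ab <- differential_abundance(norm, group_a = "KO", group_b = "WT")
  ba <- differential_abundance(norm, group_a = "WT", group_b = "KO")
  expect_equal(ba$fold_change, 1 / ab$fold_change, tolerance = 1e-12)
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-12)
})

test_that("a 1.9x injected metabolite is recovered and significant", {
  hits <- 0L
  for (s in 1:10) {
    sim <- generate_metabolite_dataset(
      seed = 100 + s, cv = 0.10, n_per_group = 5,
      group_fcs = c(fructose_bisphosphate = 1.9))
    res <- differential_abundance(qc_drift_normalize(sim$table))
    row <- res[res$metabolite == "fructose_bisphosphate", ]
    if (abs(row$fold_change - 1.9) / 1.9 < 0.15 && row$significant)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("the t-test matches stats::t.test and the flag matches alpha", {
  set.seed(83)
  ab <- matrix(rlnorm(20 * 8, log(100), 0.3), nrow = 20)
  tab <- make_metab(ab, rep(c("WT", "KO"), 4),
                    pathways = rep(c("glycolysis", "other"), 10))
  res <- differential_abundance(tab, alpha = 0.05)
  for (i in c(1, 7, 20)) {
    ref <- t.test(ab[i, tab$samples$group == "KO"],
                  ab[i, tab$samples$group == "WT"], var.equal = TRUE)$p.value
    expect_equal(res$p_value[res$metabolite == rownames(tab$abundance)[i]],
                 ref, tolerance = 1e-12)
  }
  expect_identical(res$significant, res$p_value < 0.05)
})

test_that("pathway summaries expose both cumulative definitions", {
  ab <- rbind(a = c(1, 1, 2, 2), b = c(3, 3, 3, 3))
  tab <- make_metab(ab, c("WT", "WT", "KO", "KO"),
                    pathways = c("glycolysis", "glycolysis"))
  res <- differential_abundance(tab)
  s <- pathway_metabolite_summary(res, tab)
  expect_equal(s$cumulative_fold_change, 5 / 4)   # sum ratio
  expect_equal(s$mean_fold_change, 1.5)           # mean of per-metabolite FCs
  expect_identical(s$n_metabolites, 2L)

  all_one <- make_metab(rbind(a = rep(2, 4), b = rep(5, 4)),
                        c("WT", "WT", "KO", "KO"))
  r1 <- differential_abundance(all_one)
  s1 <- pathway_metabolite_summary(r1, all_one)
  expect_equal(s1$cumulative_fold_change, 1)
  expect_equal(s1$mean_fold_change, 1)
})

test_that("the glycolysis 3-of-10 significance pattern is reproduced", {
  sim <- generate_metabolite_dataset(seed = 1)
  res <- differential_abundance(qc_drift_normalize(sim$table), alpha = 0.05)
  s <- pathway_metabolite_summary(res, sim$table)
  gly <- s[s$pathway == "glycolysis", ]
  expect_identical(gly$n_metabolites, 10L)
  expect_identical(gly$n_significant, 3L)
  expect_equal(gly$frac_significant, 0.30)
})

test_that("top-changed ranking orders by effect size with stable ties", {
  res <- data.frame(metabolite = c("dpa", "fbp", "low1", "low2", "ns"),
                    pathway = "x",
                    fold_change = c(2.2, 1.9, 0.5, 0.5, 3.0),
                    p_value = c(0.01, 0.01, 0.02, 0.01, 0.5),
                    adjusted_p = NA,
                    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  top <- rank_top_changed(res, n_top = 10)
  expect_identical(top$up$metabolite, c("dpa", "fbp"))
  expect_identical(top$down$metabolite, c("low2", "low1"))  # p breaks the tie
  expect_identical(nrow(rank_top_changed(res, n_top = 1)$up), 1L)
  none <- res; none$significant <- FALSE
  expect_identical(nrow(rank_top_changed(none)$up), 0L)

  sim <- generate_metabolite_dataset(seed = 1)
  r <- differential_abundance(qc_drift_normalize(sim$table))
  top_sim <- rank_top_changed(r)
  expect_identical(top_sim$up$metabolite[1], "docosapentaenoic_acid")
})

test_that("false-positive rates track alpha across levels in a null run", {
  sim <- generate_metabolite_dataset(
    n_per_pathway = c(null = 600L), group_fcs = c(), cv = 0.2,
    drift_slope = 0, n_per_group = 4, seed = 9)
  res <- differential_abundance(sim$table)
  for (a in c(0.01, 0.05, 0.10)) {
    frac <- mean(res$p_value < a)
    band <- qbinom(c(0.025, 0.975), 600, a) / 600
    expect_gte(frac, band[1])
    expect_lte(frac, band[2])
  }
})
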