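#' Default gene-set catalog for simulations
#'
#' Builds the five metabolic gene sets at the sizes used throughout the
#' package (fatty acid metabolism 63, antioxidant activity 86, oxidative
#' phosphorylation 144, glycolysis 67, folic acid metabolism 38), the six
#' glycolysis sub-pathway sets (which overlap within the 67 glycolysis
#' genes), and two cell-cycle sets (G1/S, G2/M). Canonical mouse symbols seed
#' each set (Hk1, Pfkp, Pfkfb3, Gapdh, ...; Ccnd1, Ccnb1, Cdk1, Cdk4, ...)
#' and synthetic symbols pad each set to size. Gene membership is
#' deterministic — no RNG involved.
#'
#' @return A named list of character vectors with attribute
#'   `"subpathways"` naming the glycolysis sub-pathway sets.
#' @export
simulate_gene_catalog <- function() {
  pad <- function(prefix, core, size)
    c(core, sprintf("%s%02d", prefix, seq_len(size - length(core))))

  glyco_core <- c("Slc2a1", "Slc2a3", "Hk1", "Hk2", "Gck", "Gpi1",
                  "Pfkp", "Pfkl", "Pfkm", "Pfkfb3", "Aldoa", "Aldoc",
                  "Tpi1", "Gapdh", "Pgk1", "Pgam1", "Eno1", "Eno2",
                  "Pkm", "Ldha", "Pdha1", "Pdhb", "Dlat", "Mpc1", "Mpc2",
                  "Fbp1", "Fbp2", "Pck2", "G6pc3",
                  "G6pdx", "Pgd", "Taldo1", "Tkt", "Rpia", "Rpe")
  glycolysis <- pad("Glyc", glyco_core, 67L)
  lower_pad <- grep("^Glyc0[1-5]$", glycolysis, value = TRUE)
  subpathways <- list(
    glucose_import_phosphorylation =
      c("Slc2a1", "Slc2a3", "Hk1", "Hk2", "Gck"),
    upper_glycolysis =
      c("Slc2a1", "Slc2a3", "Hk1", "Hk2", "Gck", "Gpi1",
        "Pfkp", "Pfkl", "Pfkm", "Pfkfb3", "Aldoa", "Aldoc"),
    lower_glycolysis =
      c("Tpi1", "Gapdh", "Pgk1", "Pgam1", "Eno1", "Eno2", "Pkm", "Ldha",
        lower_pad),
    glycolysis_to_oxphos = c("Pdha1", "Pdhb", "Dlat", "Mpc1", "Mpc2"),
    gluconeogenesis = c("Fbp1", "Fbp2", "Pck2", "G6pc3"),
    pentose_phosphate = c("G6pdx", "Pgd", "Taldo1", "Tkt", "Rpia", "Rpe")
  )
  catalog <- list(
    fatty_acid = pad("Faox", c("Fasn", "Acaca", "Acacb", "Scd1", "Cpt1a",
                               "Cpt2", "Acox1", "Hadha", "Hadhb", "Elovl6"),
                     63L),
    antioxidant = pad("Antx", c("Sod1", "Sod2", "Sod3", "Cat", "Gpx1",
                                "Gpx4", "Prdx1", "Prdx2", "Txn1", "Gsr"),
                      86L),
    oxidative_phosphorylation =
      pad("Oxph", c("Ndufa1", "Ndufb4", "Ndufs1", "Sdha", "Sdhb", "Uqcrc1",
                    "Uqcrc2", "Cox4i1", "Cox5a", "Atp5a1", "Atp5b"),
          144L),
    glycolysis = glycolysis,
    folic_acid = pad("Fola", c("Mthfr", "Dhfr", "Shmt1", "Shmt2", "Mthfd1",
                               "Mthfd2", "Tyms", "Folr1", "Slc19a1"),
                     38L)
  )
  catalog <- c(catalog, subpathways,
               list(g1s = c("Ccnd1", "Ccne1", "Cdk2", "Cdk4", "Cdk6", "E2f1"),
                    g2m = c("Ccnb1", "Ccna2", "Cdk1", "Plk1", "Aurka",
                            "Bub1")))
  attr(catalog, "subpathways") <- names(subpathways)
  catalog
}

#' Configuration for the single-cell simulator
#'
#' The generator emulates the study design: six cell populations (five
#' ectoderm-derived plus a non-ectoderm rest), two genotypes, two embryonic
#' stages, negative-binomial counts with a log-normal library-size factor,
#' and injected effects recorded as ground truth. Dropout arises implicitly
#' from NB zeros at these means.
#'
#' @param populations character vector of population labels.
#' @param cells_per_population cells per population per genotype (split
#'   evenly between the two stages).
#' @param genotype_multipliers named numeric vector, gene -> KO/WT mean
#'   multiplier (> 0). Defaults inject the headline pattern Pfkp 4.5x,
#'   Pfkfb3 2.5x, Hk1 2x.
#' @param population_effects named list pathway -> named numeric vector of
#'   per-population mean multipliers; default gives glycolysis a 1.2x lift in
#'   neuroepithelium and neural crest over non-neural ectoderm.
#' @param stage_multipliers named numeric vector pathway -> E9.5/E8.25 mean
#'   multiplier (applied to E9.5 cells of both genotypes); default folic acid
#'   1.3x.
#' @param coexpression_pairs list of lists with fields `gene_a`, `gene_b`,
#'   `p_wt`, `p_ko`, `boost_mean`: a latent Bernoulli "cycling" state raises
#'   both pair genes to `boost_mean` (times any genotype multiplier) in that
#'   fraction of cells, giving a closed-form expected co-expression fraction
#'   per genotype. Default pairs: Ccnd1/Ccnb1 and Pfkfb3/Cdk1 with KO
#'   fraction 1.6x the WT fraction.
#' @param pair_baseline_mean off-state baseline mean count for genes named in
#'   `coexpression_pairs` — kept low so cell-cycle genes are near-silent
#'   outside the cycling state (bimodal, as cyclins are) and the latent
#'   fraction is the expected co-expression fraction almost exactly.
#' @param n_background unperturbed background genes padding the
#'   transcriptome; they dominate the library so that injected multipliers
#'   perturb per-cell totals (and hence the normalization) only mildly.
#' @param baseline_mean_pathway,baseline_mean_background log-normal location
#'   of per-gene baseline mean counts.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param libsize_sdlog log-normal sd of the per-cell library factor.
#' @param frac_low,frac_high fractions of cells forced to extreme library
#'   factors (`low_factor`, `high_factor`) so totals span the QC thresholds
#'   and the UMI filters remove a predictable, truth-recorded set.
#' @param low_factor,high_factor the extreme library factors.
#' @param n_mito_genes mitochondrial genes (symbols prefixed `mt-`).
#' @param seed integer seed.
#' @return A list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(populations = c("forebrain", "midbrain",
                                          "hindbrain", "neural_crest",
                                          "non_neural_ectoderm",
                                          "non_ectoderm"),
                          cells_per_population = 300L,
                          genotype_multipliers = c(Pfkp = 4.5, Pfkfb3 = 2.5,
                                                   Hk1 = 2.0),
                          population_effects = list(
                            glycolysis = c(forebrain = 1.2, midbrain = 1.2,
                                           hindbrain = 1.2,
                                           neural_crest = 1.2,
                                           non_neural_ectoderm = 1.0,
                                           non_ectoderm = 1.0)),
                          stage_multipliers = c(folic_acid = 1.3),
                          coexpression_pairs = list(
                            list(gene_a = "Ccnd1", gene_b = "Ccnb1",
                                 p_wt = 0.10, p_ko = 0.16, boost_mean = 60),
                            list(gene_a = "Pfkfb3", gene_b = "Cdk1",
                                 p_wt = 0.10, p_ko = 0.16, boost_mean = 60)),
                          pair_baseline_mean = 0.02,
                          n_background = 2500L,
                          baseline_mean_pathway = 0.15,
                          baseline_mean_background = 0.3,
                          dispersion = 0.5,
                          libsize_sdlog = 0.3,
                          frac_low = 0.02, frac_high = 0.02,
                          low_factor = 0.05, high_factor = 4.0,
                          n_mito_genes = 5L,
                          seed = 1L) {
  if (any(genotype_multipliers <= 0))
    stop("genotype multipliers must be positive")
  if (cells_per_population < 1L)
    stop("need at least one cell per population")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(as.list(environment()), class = c("sc_sim_config", "list"))
}

#' Simulate a two-genotype single-cell dataset with known ground truth
#'
#' Counts are drawn as
#' `NB(mean = baseline x population effect x stage effect x genotype
#' multiplier x library factor, size = 1/dispersion)` per gene and cell.
#' Latent cycling states implement controlled co-expression fractions for
#' configured gene pairs. The returned `truth` records every injected
#' quantity (gene multipliers, per-pathway mean multipliers, stage and
#' population effects, expected co-expression fractions, and the barcodes
#' expected to fail the default UMI filters) so downstream recovery is
#' testable without re-deriving anything.
#'
#' @param config an [sc_sim_config()].
#' @return A list: `wt`, `ko` ([ExpressionMatrix()] counts), `annot_wt`,
#'   `annot_ko` (annotations incl. stage), `catalog` (gene sets,
#'   [simulate_gene_catalog()]), `truth` (list).
#' @export
generate_sc_dataset <- function(config = sc_sim_config()) {
  stopifnot(inherits(config, "sc_sim_config"))
  set.seed(config$seed)
  catalog <- simulate_gene_catalog()
  main_sets <- c("fatty_acid", "antioxidant", "oxidative_phosphorylation",
                 "glycolysis", "folic_acid", "g1s", "g2m")
  pathway_genes <- unique(unlist(catalog[main_sets], use.names = FALSE))
  bg_genes <- sprintf("Bgrd%04d", seq_len(config$n_background))
  mito_genes <- sprintf("mt-Sim%d", seq_len(config$n_mito_genes))
  genes <- c(pathway_genes, bg_genes, mito_genes)

  base <- c(
    stats::rlnorm(length(pathway_genes),
                  meanlog = log(config$baseline_mean_pathway), sdlog = 0.4),
    stats::rlnorm(length(bg_genes),
                  meanlog = log(config$baseline_mean_background), sdlog = 0.4),
    stats::rlnorm(length(mito_genes), meanlog = log(2), sdlog = 0.3))
  names(base) <- genes
  pair_genes <- unique(unlist(lapply(config$coexpression_pairs,
                                     function(p) c(p$gene_a, p$gene_b))))
  base[intersect(pair_genes, genes)] <- config$pair_baseline_mean

  # per-gene population effect, from per-pathway configuration
  pop_eff <- matrix(1, nrow = length(genes), ncol = length(config$populations),
                    dimnames = list(genes, config$populations))
  for (pw in names(config$population_effects)) {
    eff <- config$population_effects[[pw]]
    mem <- intersect(catalog[[pw]], genes)
    for (pop in intersect(names(eff), config$populations))
      pop_eff[mem, pop] <- eff[[pop]]
  }
  stage_eff <- setNames(rep(1, length(genes)), genes)
  for (pw in names(config$stage_multipliers))
    stage_eff[intersect(catalog[[pw]], genes)] <- config$stage_multipliers[[pw]]
  geno_mult <- setNames(rep(1, length(genes)), genes)
  known <- intersect(names(config$genotype_multipliers), genes)
  geno_mult[known] <- config$genotype_multipliers[known]

  simulate_genotype <- function(genotype) {
    n_pop <- config$cells_per_population
    n_cells <- n_pop * length(config$populations)
    population <- rep(config$populations, each = n_pop)
    stage <- rep(rep(c("E8.25", "E9.5"), length.out = n_pop),
                 times = length(config$populations))
    barcode <- sprintf("%s_%s_%04d", genotype, population,
                       stats::ave(seq_len(n_cells), population,
                                  FUN = seq_along))
    lib <- stats::rlnorm(n_cells, meanlog = 0, sdlog = config$libsize_sdlog)
    n_low <- round(config$frac_low * n_cells)
    n_high <- round(config$frac_high * n_cells)
    extreme <- sample.int(n_cells, n_low + n_high)
    lib[extreme[seq_len(n_low)]] <- config$low_factor
    lib[extreme[n_low + seq_len(n_high)]] <- config$high_factor

    mult <- if (genotype == "KO") geno_mult else setNames(rep(1, length(genes)),
                                                          genes)
    mu_gene <- base * mult                       # gene baseline incl. genotype
    counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, barcode))
    size <- 1 / config$dispersion
    # one NB draw per (population, stage) block keeps the generator fast
    for (pop in config$populations) {
      for (st in c("E8.25", "E9.5")) {
        ci <- which(population == pop & stage == st)
        if (!length(ci)) next
        mu_vec <- mu_gene * pop_eff[, pop] * (if (st == "E9.5") stage_eff else 1)
        mu_block <- outer(mu_vec, lib[ci])
        counts[, ci] <- stats::rnbinom(length(mu_block), size = size,
                                       mu = mu_block)
      }
    }
    # latent cycling state: both pair genes boosted in a controlled fraction;
    # the boost scales with the gene's genotype multiplier so injected KO/WT
    # effects survive inside cycling cells
    p_field <- if (genotype == "KO") "p_ko" else "p_wt"
    coexpr_truth <- list()
    for (pair in config$coexpression_pairs) {
      p <- pair[[p_field]]
      cycling <- stats::runif(n_cells) < p
      for (g in c(pair$gene_a, pair$gene_b)) {
        if (!g %in% genes) stop("co-expression pair gene not simulated: ", g)
        idx <- which(cycling)
        if (length(idx))
          counts[g, idx] <- stats::rnbinom(length(idx), size = size,
                                           mu = pair$boost_mean * mult[[g]] *
                                             lib[idx])
      }
      coexpr_truth[[paste(pair$gene_a, pair$gene_b, sep = "_")]] <-
        list(gene_a = pair$gene_a, gene_b = pair$gene_b,
             expected_fraction = p, realized_fraction = mean(cycling))
    }
    totals <- colSums(counts)
    annot <- data.frame(
      barcode = barcode, population = population, genotype = genotype,
      stage = stage, total_umi = as.integer(totals),
      mito_fraction = colSums(counts[mito_genes, , drop = FALSE]) / pmax(totals, 1))
    rownames(annot) <- NULL
    list(matrix = ExpressionMatrix(counts, scale = "counts"),
         annot = annot, coexpr = coexpr_truth)
  }

  wt <- simulate_genotype("WT")
  ko <- simulate_genotype("KO")

  # marginal KO/WT mean fold change per gene: equals the injected multiplier
  # except for co-expression pair genes, where the cycling-state mixture
  # (differing cycling fractions between genotypes) shifts the marginal mean
  effective_mult <- geno_mult
  for (pair in config$coexpression_pairs) {
    for (g in c(pair$gene_a, pair$gene_b)) {
      mix <- function(p) (1 - p) * base[[g]] + p * pair$boost_mean
      effective_mult[[g]] <- geno_mult[[g]] * mix(pair$p_ko) / mix(pair$p_wt)
    }
  }
  pathway_mult <- vapply(main_sets, function(pw) {
    mean(effective_mult[intersect(catalog[[pw]], genes)])
  }, numeric(1))
  subpathway_mult <- vapply(attr(catalog, "subpathways"), function(pw) {
    mean(effective_mult[intersect(catalog[[pw]], genes)])
  }, numeric(1))

  default_cfg <- run_config()
  expected_removed <- function(annot) {
    annot$barcode[annot$total_umi < default_cfg$qc_min_umi |
                    annot$total_umi > default_cfg$qc_max_umi]
  }
  truth <- list(
    seed = config$seed,
    gene_multipliers = as.list(geno_mult[known]),
    gene_marginal_fc = as.list(effective_mult[
      union(known, unlist(lapply(config$coexpression_pairs,
                                 function(p) c(p$gene_a, p$gene_b))))]),
    pathway_mean_multipliers = as.list(pathway_mult),
    subpathway_mean_multipliers = as.list(subpathway_mult),
    stage_multipliers = as.list(config$stage_multipliers),
    population_effects = config$population_effects,
    coexpression = list(WT = wt$coexpr, KO = ko$coexpr),
    qc_expected_removed = list(WT = expected_removed(wt$annot),
                               KO = expected_removed(ko$annot))
  )
  list(wt = wt$matrix, ko = ko$matrix, annot_wt = wt$annot,
       annot_ko = ko$annot, catalog = catalog, truth = truth)
}

#' Simulate an LC/MS metabolite run with pooled QC injections
#'
#' Study samples (two groups) receive log-normal abundances around a
#' per-metabolite base level, multiplied by the group fold change (KO only),
#' a linear injection-order drift `1 + drift_slope * (order - 1)`, and
#' multiplicative log-normal noise at the requested coefficient of variation.
#' Pooled QC samples are injected first, then after every
#' `qc_every - 1` study samples, and once at the end; their values are the
#' noise-free pool mean times the drift, emulating a technical replicate of
#' the pooled extract.
#'
#' Defaults mirror the study's glycolysis pattern: fructose bisphosphate
#' 1.9x, ATP 1.8x, pyruvate 1.4x among 10 glycolytic metabolites, a 2.2x
#' docosapentaenoic-acid rise and mild fatty-acid declines, with n = 5 per
#' group and 10% CV.
#'
#' @param n_per_pathway named integer vector, metabolites per pathway; the
#'   named defaults include 10 glycolysis metabolites.
#' @param group_fcs named numeric vector metabolite -> KO/WT fold change
#'   (metabolites not named get 1).
#' @param cv coefficient of variation of the multiplicative noise.
#' @param drift_slope linear drift per injection (0 = no drift).
#' @param qc_every a QC sample occupies every `qc_every`-th injection.
#' @param n_per_group study samples per group.
#' @param seed integer seed.
#' @return A list: `table` (a [MetaboliteTable()]) and `truth` (injected fold
#'   changes, drift slope, pathway map, expected-significant names).
#' @export
generate_metabolite_dataset <- function(n_per_pathway = c(glycolysis = 10L,
                                                          fatty_acid = 8L,
                                                          antioxidant = 6L,
                                                          vitamin = 6L,
                                                          other = 10L),
                                        group_fcs = c(
                                          fructose_bisphosphate = 1.9,
                                          atp = 1.8,
                                          pyruvate = 1.4,
                                          docosapentaenoic_acid = 2.2,
                                          palmitate = 0.7),
                                        cv = 0.10,
                                        drift_slope = 0.01,
                                        qc_every = 6L,
                                        n_per_group = 5L,
                                        seed = 1L) {
  if (n_per_group < 2L) stop("need at least 2 samples per group")
  if (cv <= 0) stop("cv must be positive")
  set.seed(seed)
  named_mets <- list(
    glycolysis = c("fructose_bisphosphate", "glucose_6_phosphate", "pyruvate",
                   "lactate", "atp", "adp", "phosphoenolpyruvate",
                   "dihydroxyacetone_phosphate", "glyceraldehyde_3_phosphate",
                   "fructose_6_phosphate"),
    fatty_acid = c("docosapentaenoic_acid", "palmitate", "oleate", "stearate",
                   "linoleate", "carnitine", "acetyl_carnitine", "malonate"),
    antioxidant = c("glutathione", "glutathione_disulfide", "ascorbate",
                    "cysteine", "taurine", "uric_acid"),
    vitamin = c("folate", "tetrahydrofolate", "thiamine", "riboflavin",
                "pyridoxine", "cobalamin"))
  metabolite <- character()
  pathway <- character()
  for (pw in names(n_per_pathway)) {
    n <- n_per_pathway[[pw]]
    core <- if (pw %in% names(named_mets)) named_mets[[pw]] else character()
    if (length(core) < n)
      core <- c(core, sprintf("%s_met%02d", pw, seq_len(n - length(core))))
    metabolite <- c(metabolite, core[seq_len(n)])
    pathway <- c(pathway, rep(pw, n))
  }
  n_met <- length(metabolite)
  fc <- setNames(rep(1, n_met), metabolite)
  fc[intersect(names(group_fcs), metabolite)] <-
    group_fcs[intersect(names(group_fcs), metabolite)]

  n_study <- 2L * n_per_group
  study_group <- sample(rep(c("WT", "KO"), each = n_per_group))
  # injection layout: QC first, QC at every qc_every-th injection, QC last
  orders <- integer(0)
  groups <- character(0)
  inj <- 1L
  groups <- "QC"; orders <- 1L
  si <- 0L
  while (si < n_study) {
    chunk <- min(qc_every - 1L, n_study - si)
    for (k in seq_len(chunk)) {
      inj <- inj + 1L
      si <- si + 1L
      groups <- c(groups, study_group[[si]])
      orders <- c(orders, inj)
    }
    inj <- inj + 1L
    groups <- c(groups, "QC")
    orders <- c(orders, inj)
  }
  is_qc <- groups == "QC"
  sample_id <- character(length(groups))
  sample_id[is_qc] <- sprintf("QC_%02d", seq_len(sum(is_qc)))
  sample_id[!is_qc] <- sprintf("%s_%02d", groups[!is_qc],
                               stats::ave(seq_len(sum(!is_qc)), groups[!is_qc],
                                          FUN = seq_along))
  base <- stats::rlnorm(n_met, meanlog = log(1e4), sdlog = 1)
  names(base) <- metabolite
  sdlog <- sqrt(log(1 + cv^2))
  drift <- 1 + drift_slope * (orders - 1)
  pool_mean <- base * (1 + fc) / 2        # equal group sizes in the pool
  ab <- matrix(0, nrow = n_met, ncol = length(groups),
               dimnames = list(metabolite, sample_id))
  for (j in seq_along(groups)) {
    if (is_qc[[j]]) {
      ab[, j] <- pool_mean * drift[[j]]
    } else {
      mu <- base * (if (groups[[j]] == "KO") fc else 1)
      ab[, j] <- mu * drift[[j]] *
        stats::rlnorm(n_met, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  }
  table <- MetaboliteTable(
    ab,
    samples = data.frame(sample = sample_id, group = groups,
                         injection_order = orders, is_qc = is_qc),
    metabolites = data.frame(metabolite = metabolite, pathway = pathway))
  truth <- list(seed = seed,
                fold_changes = as.list(fc),
                drift_slope = drift_slope,
                cv = cv,
                n_per_group = n_per_group,
                pathways = setNames(as.list(pathway), metabolite),
                expected_changed = names(fc)[fc != 1])
  list(table = table, truth = truth)
}

#' Simulate coupled-assay absorbance traces
#'
#' Piecewise lag/linear/plateau A340 traces sampled every minute: flat at
#' `a0` during the lag, linear at the embryo's slope for `linear_min`
#' minutes, then flat at the reached level, plus Gaussian noise.
#'
#' @param slopes named numeric vector or list embryo_id -> slope
#'   (dA340/min, typically negative for NADH consumption).
#' @param genotypes character vector (same length/names) of embryo genotypes.
#' @param lag_min,linear_min lag and linear-phase durations (minutes);
#'   `lag_min + linear_min` must not exceed `total_min`.
#' @param noise_sd Gaussian noise sd on each absorbance reading.
#' @param total_min trace duration; readings at 0, 1, ..., `total_min`.
#' @param a0 initial absorbance.
#' @param seed integer seed.
#' @return A list: `traces` (long data.frame as read by
#'   [read_kinetic_traces()]) and `truth` (per-embryo slopes, phase bounds,
#'   expected activity ratio KO/WT).
#' @export
generate_pfk_traces <- function(slopes = c(WT1 = -0.02, WT2 = -0.02,
                                           WT3 = -0.02, KO1 = -0.03,
                                           KO2 = -0.03, KO3 = -0.03),
                                genotypes = c(WT1 = "WT", WT2 = "WT",
                                              WT3 = "WT", KO1 = "KO",
                                              KO2 = "KO", KO3 = "KO"),
                                lag_min = 5, linear_min = 30,
                                noise_sd = 0.002, total_min = 60,
                                a0 = 1.0, seed = 1L) {
  if (lag_min + linear_min > total_min)
    stop("lag_min + linear_min must not exceed total_min")
  slopes <- unlist(slopes)
  if (is.null(names(slopes))) stop("slopes must be named by embryo id")
  if (!setequal(names(slopes), names(genotypes)))
    stop("slopes and genotypes must name the same embryos")
  set.seed(seed)
  t <- seq(0, total_min, by = 1)
  rows <- lapply(names(slopes), function(id) {
    s <- slopes[[id]]
    a <- ifelse(t <= lag_min, a0,
                ifelse(t <= lag_min + linear_min, a0 + s * (t - lag_min),
                       a0 + s * linear_min))
    a <- a + stats::rnorm(length(t), sd = noise_sd)
    data.frame(time_min = t, a340 = a, embryo_id = id,
               genotype = genotypes[[id]])
  })
  traces <- do.call(rbind, rows)
  rownames(traces) <- NULL
  mean_act <- function(gt) mean(abs(slopes[genotypes[names(slopes)] == gt]))
  truth <- list(seed = seed,
                slopes = as.list(slopes),
                genotypes = as.list(genotypes),
                lag_min = lag_min, linear_min = linear_min,
                noise_sd = noise_sd,
                expected_activity_ratio = mean_act("KO") / mean_act("WT"))
  list(traces = traces, truth = truth)
}

#' Simulate a predicted miRNA-target gene list with controlled overlap
#'
#' Samples a target list so that exactly `n_in_subpathway` targets come from
#' a nested sub-pathway set, `n_in_pathway - n_in_subpathway` from the
#' enclosing pathway outside the sub-pathway, and `n_outside` from genes in
#' no catalog set of interest — e.g. 12 predicted targets among the 67
#' glycolysis genes of which 4 sit in upper glycolysis.
#'
#' @param catalog named list of gene sets ([simulate_gene_catalog()]).
#' @param n_in_pathway targets inside `pathway` (>= `n_in_subpathway`).
#' @param n_in_subpathway targets inside `subpathway` (must be nested in
#'   `pathway`).
#' @param pathway,subpathway set names in `catalog`.
#' @param extra_genes pool of off-pathway symbols to draw `n_outside` from
#'   (defaults to synthetic background symbols not in the catalog).
#' @param n_outside number of off-pathway targets.
#' @param seed integer seed.
#' @return A list: `targets` (character vector, shuffled) and `truth`
#'   (the per-stratum memberships).
#' @export
generate_target_list <- function(catalog, n_in_pathway = 12L,
                                 n_in_subpathway = 4L,
                                 pathway = "glycolysis",
                                 subpathway = "upper_glycolysis",
                                 extra_genes = sprintf("Bgrd%04d", 1:100),
                                 n_outside = 20L, seed = 1L) {
  set.seed(seed)
  pw <- unique(catalog[[pathway]])
  sub <- intersect(unique(catalog[[subpathway]]), pw)
  if (n_in_subpathway > length(sub) ||
      (n_in_pathway - n_in_subpathway) > length(setdiff(pw, sub)) ||
      n_in_subpathway > n_in_pathway)
    stop("infeasible nesting: requested counts exceed set sizes")
  in_sub <- sample(sub, n_in_subpathway)
  in_pw <- sample(setdiff(pw, sub), n_in_pathway - n_in_subpathway)
  pool <- setdiff(extra_genes, unlist(catalog, use.names = FALSE))
  if (n_outside > length(pool))
    stop("not enough off-pathway genes available")
  outside <- if (n_outside) sample(pool, n_outside) else character()
  targets <- sample(c(in_sub, in_pw, outside))
  list(targets = targets,
       truth = list(seed = seed, in_subpathway = in_sub,
                    in_pathway_only = in_pw, outside = outside))
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth a `truth` list from any generator.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
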