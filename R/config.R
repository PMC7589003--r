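#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with its default. Defaults can be
#' overridden by a YAML/JSON file ([read_config()]) and again by individual
#' arguments (command-line flags take last precedence in the CLI).
#'
#' @param seed integer random seed.
#' @param qc_min_umi keep cells with at least this many total UMIs
#'   (strictly fewer are removed as low-complexity).
#' @param qc_max_umi keep cells with at most this many total UMIs
#'   (strictly more are removed as putative doublets/triplets).
#' @param qc_mito_prefix gene-symbol prefix identifying mitochondrial genes
#'   (mouse convention `"mt-"`).
#' @param norm_scale_factor per-cell scaling target for log normalization.
#' @param coexpr_threshold expression threshold (log-normalized scale) for
#'   co-expression and high-expressor subsetting.
#' @param metab_alpha significance level for metabolite t-tests.
#' @param pfk_window_minutes sliding-window span (minutes) for the linear
#'   region fit.
#' @param paths named list of input/output paths (free-form, used by the CLI).
#' @return A named list of class `glyco_config`.
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$qc_min_umi
#' @export
run_config <- function(seed = 1L,
                       qc_min_umi = 200L,
                       qc_max_umi = 2500L,
                       qc_mito_prefix = "mt-",
                       norm_scale_factor = 10000,
                       coexpr_threshold = 1.0,
                       metab_alpha = 0.05,
                       pfk_window_minutes = 10L,
                       paths = list()) {
  cfg <- list(seed = as.integer(seed),
              qc_min_umi = as.integer(qc_min_umi),
              qc_max_umi = as.integer(qc_max_umi),
              qc_mito_prefix = qc_mito_prefix,
              norm_scale_factor = as.numeric(norm_scale_factor),
              coexpr_threshold = as.numeric(coexpr_threshold),
              metab_alpha = as.numeric(metab_alpha),
              pfk_window_minutes = as.integer(pfk_window_minutes),
              paths = paths)
  validate_config(cfg)
  class(cfg) <- c("glyco_config", "list")
  cfg
}

validate_config <- function(cfg) {
  if (cfg$qc_min_umi >= cfg$qc_max_umi)
    stop("qc_min_umi must be smaller than qc_max_umi")
  if (!(cfg$metab_alpha > 0 && cfg$metab_alpha < 1))
    stop("metab_alpha must lie in (0, 1)")
  if (cfg$coexpr_threshold < 0)
    stop("coexpr_threshold must be >= 0")
  if (cfg$norm_scale_factor <= 0)
    stop("norm_scale_factor must be positive")
  if (cfg$pfk_window_minutes <= 0)
    stop("pfk_window_minutes must be positive")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads YAML (or JSON, a YAML subset) and merges it over the defaults of
#' [run_config()]. Keys may be flat (`qc_min_umi`) or nested
#' (`qc: {min_umi: 200}`); nested keys are flattened with a `_` separator.
#'
#' @param path file path.
#' @param ... overrides applied after the file (highest precedence).
#' @return A `glyco_config` list.
#' @export
read_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (key in names(raw)) {
    val <- raw[[key]]
    if (is.list(val) && key != "paths") {
      for (sub in names(val)) flat[[paste(key, sub, sep = "_")]] <- val[[sub]]
    } else {
      flat[[key]] <- val
    }
  }
  args <- utils::modifyList(flat, list(...))
  known <- names(formals(run_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, args)
}
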