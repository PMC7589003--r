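#' Fit the linear region of an absorbance trace
#'
#' Estimates enzymatic activity from a coupled-assay A340 time series by
#' ordinary least squares over a sliding window. Every contiguous window
#' spanning `window_minutes` is fit; the reported window is the one
#' maximizing |slope| among windows with r-squared >= `r2_gate`, falling back
#' to the maximum-r-squared window when none passes the gate (e.g. very noisy
#' or curved traces). The assay is read sign-agnostically: `activity` is
#' |slope|, so the fit works whether the coupled reaction consumes or
#' produces NADH.
#'
#' @param time numeric vector of times in minutes, strictly increasing
#'   (default acquisition: every minute for 60 minutes).
#' @param absorbance A340 values, same length.
#' @param window_minutes window span in minutes; each window must contain at
#'   least 5 points.
#' @param r2_gate minimum r-squared for a window to qualify (default 0.95).
#' @return A one-row data.frame: `slope` (signed, dA340/min), `t_start`,
#'   `t_end`, `r_squared`, `activity` (= |slope|), and logical `flagged`
#'   (constant trace: slope 0, r-squared reported as 0).
#' @examples
#' t <- 0:60
#' fit_linear_region(t, 1 - 0.01 * t)
#' @export
fit_linear_region <- function(time, absorbance, window_minutes = 10,
                              r2_gate = 0.95) {
  if (length(time) != length(absorbance))
    stop("time and absorbance lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  n <- length(time)
  span_end <- time + window_minutes
  starts <- which(span_end <= time[n] + 1e-9)
  if (!length(starts))
    stop("window_minutes exceeds the trace span")
  fits <- lapply(starts, function(i) {
    j <- max(which(time <= span_end[i] + 1e-9))
    if (j - i + 1L < 5L) return(NULL)
    tt <- time[i:j]
    aa <- absorbance[i:j]
    sxx <- sum((tt - mean(tt))^2)
    sxy <- sum((tt - mean(tt)) * (aa - mean(aa)))
    syy <- sum((aa - mean(aa))^2)
    slope <- sxy / sxx
    r2 <- if (syy == 0) NA_real_ else (sxy^2 / sxx) / syy
    list(i = i, j = j, slope = slope, r2 = r2)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("no window of ", window_minutes, " minutes spans at least 5 points")
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  flagged <- all(is.na(r2s))
  if (flagged) {
    best <- fits[[1L]]            # constant trace: any window, slope 0
    best_r2 <- 0
  } else {
    ok <- which(!is.na(r2s) & r2s >= r2_gate)
    k <- if (length(ok)) ok[which.max(abs(slopes[ok]))]
         else which.max(r2s)
    best <- fits[[k]]
    best_r2 <- r2s[[k]]
  }
  data.frame(slope = best$slope,
             t_start = time[best$i],
             t_end = time[best$j],
             r_squared = best_r2,
             activity = abs(best$slope),
             flagged = flagged)
}

#' Per-embryo PFK activity from a long-format trace table
#'
#' @param traces data.frame with columns `time_min`, `a340`, `embryo_id`,
#'   `genotype`.
#' @param window_minutes passed to [fit_linear_region()].
#' @return A data.frame with one row per embryo: `embryo_id`, `genotype`,
#'   plus the [fit_linear_region()] columns.
#' @export
pfk_activity <- function(traces, window_minutes = 10) {
  req <- c("time_min", "a340", "embryo_id", "genotype")
  if (!all(req %in% names(traces)))
    stop("traces needs columns: ", paste(req, collapse = ", "))
  ids <- unique(traces$embryo_id)
  rows <- lapply(ids, function(id) {
    sub <- traces[traces$embryo_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    fit <- fit_linear_region(sub$time_min, sub$a340, window_minutes)
    cbind(data.frame(embryo_id = id, genotype = sub$genotype[[1L]]), fit)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$genotype, res$embryo_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genotype fold change of PFK activity
#'
#' Ratio of mean KO activity to mean WT activity with a two-sided Student
#' t-test on the per-embryo activities (the study design is a handful of
#' embryos per genotype, e.g. 3 vs 3).
#'
#' @param results_wt,results_ko outputs of [fit_linear_region()] /
#'   [pfk_activity()] rows for each genotype (>= 2 embryos each).
#' @return A list: `ratio` (KO/WT), `p_value`, `mean_wt`, `mean_ko`, logical
#'   `undefined` (WT mean zero).
#' @export
activity_fold_change <- function(results_wt, results_ko) {
  aw <- results_wt$activity
  ak <- results_ko$activity
  if (length(aw) < 2L || length(ak) < 2L)
    stop("need at least 2 activities per genotype")
  mw <- mean(aw)
  mk <- mean(ak)
  undefined <- mw == 0
  if (undefined) warning("WT mean activity is zero; ratio undefined")
  p <- if (stats::var(aw) == 0 && stats::var(ak) == 0) {
    if (mw == mk) 1 else 0
  } else {
    stats::t.test(ak, aw, var.equal = TRUE)$p.value
  }
  list(ratio = if (undefined) NA_real_ else mk / mw,
       p_value = p, mean_wt = mw, mean_ko = mk, undefined = undefined)
}

#' Convert an absorbance slope to a molar reaction rate
#'
#' Optional conversion of a coupled-assay slope (dA340/min) to nmol NADH per
#' minute via Beer-Lambert: `rate = |slope| / (epsilon * path) * volume`.
#' Off the main reporting path — activities default to |slope| — because
#' genotype fold changes are scale-free.
#'
#' @param slope absorbance change per minute (sign ignored).
#' @param extinction molar extinction coefficient of NADH at 340 nm
#'   (default 6220 /M/cm).
#' @param path_length_cm optical path length in cm.
#' @param volume_ml reaction volume in mL.
#' @param stoichiometry NADH molecules turned over per product molecule of
#'   the reaction being reported (2 for the aldolase-coupled PFK cascade,
#'   where each fructose bisphosphate yields two triose phosphates).
#' @return Rate in nmol/min.
#' @export
slope_to_rate <- function(slope, extinction = 6220, path_length_cm = 1,
                          volume_ml = 0.5, stoichiometry = 1) {
  if (extinction <= 0 || path_length_cm <= 0 || volume_ml <= 0 ||
      stoichiometry <= 0)
    stop("conversion constants must be positive")
  abs(slope) / (extinction * path_length_cm) * (volume_ml / 1000) /
    stoichiometry * 1e9
}

#' Read / write kinetic traces as CSV
#'
#' Long format: `time_min`, `a340`, `embryo_id`, `genotype`.
#'
#' @param path CSV path.
#' @return A data.frame of traces.
#' @export
read_kinetic_traces <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time_min", "a340", "embryo_id", "genotype")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("trace file lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' @rdname read_kinetic_traces
#' @param traces data.frame of traces.
#' @export
write_kinetic_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
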