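#' Ordinary least-squares slope of a fluorescence curve
#'
#' Fits value ~ time by OLS over the points falling inside the window
#' (default the first 3 h, matching regression over the standard assay
#' duration).  Slope is in fluorescence units per minute.
#'
#' @param curve Data.frame with columns `time_min` and `value` for one
#'   replicate curve.
#' @param window Numeric length-2 vector, inclusive time window in minutes.
#' @return List with `slope`, `intercept` and `r2`.
#' @export
fit_slope <- function(curve, window = c(0, 180)) {
  sel <- curve$time_min >= window[1] & curve$time_min <= window[2]
  if (sum(sel) < 2L) {
    stop("insufficient data: need >= 2 points inside window [",
         window[1], ", ", window[2], "] min")
  }
  fit <- lm(value ~ time_min, data = curve[sel, , drop = FALSE])
  # exact lines trigger a benign "essentially perfect fit" warning
  ss <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = ss$r.squared)
}

#' Endpoint fluorescence of a curve
#'
#' Returns the value at the sampling time nearest to `t` (default 3 h);
#' equidistant samples resolve to the earlier one.
#'
#' @param curve Data.frame with columns `time_min` and `value`.
#' @param t Target time in minutes (default 180).
#' @param tol Maximum distance in minutes between `t` and the nearest sample
#'   (default 5, one sampling interval).
#' @return The fluorescence value at the nearest sample.
#' @export
endpoint <- function(curve, t = 180, tol = 5) {
  d <- abs(curve$time_min - t)
  i <- which.min(d)  # ties resolve to the earlier (first) sample
  if (d[i] > tol) {
    stop("missing endpoint: no sample within ", tol, " min of t = ", t,
         " min (nearest is ", curve$time_min[i], " min)")
  }
  curve$value[i]
}

# metric per replicate curve; curves identified by (sample, crrna, replicate)
metric_by_curve <- function(curves, metric = c("endpoint", "slope"),
                            t = 180, tol = 5, window = c(0, 180)) {
  metric <- match.arg(metric)
  key <- interaction(curves$sample, curves$crrna, curves$replicate,
                     drop = TRUE)
  vapply(split(curves, key), function(cc) {
    cc <- cc[order(cc$time_min), , drop = FALSE]
    if (metric == "endpoint") endpoint(cc, t, tol) else
      fit_slope(cc, window)$slope
  }, numeric(1))
}

#' Cross-activator specificity fold of one crRNA
#'
#' Mean metric over reactions spiked with the matched activator divided by
#' the mean over reactions spiked with the mismatched activator (e.g. a
#' mutant-detecting crRNA against mutant vs WT activator).  A fold of 1
#' means no discrimination.
#'
#' @param curves Long-format data.frame with columns `time_min`, `value`,
#'   `crrna`, `replicate` and an activator label column (`activator` if
#'   present, else `sample`).
#' @param crrna crRNA label to evaluate.
#' @param matched_activator,mismatched_activator Activator labels.
#' @param metric `"endpoint"` or `"slope"`.
#' @param eps Smallest admissible mismatched-mean denominator.
#' @param ... Passed to the metric (`t`, `tol`, `window`).
#' @return Positive numeric fold.
#' @export
specificity_fold <- function(curves, crrna, matched_activator,
                             mismatched_activator,
                             metric = c("endpoint", "slope"),
                             eps = 1e-9, ...) {
  metric <- match.arg(metric)
  act_col <- if (!is.null(curves$activator)) "activator" else "sample"
  sub <- curves[curves$crrna == crrna, , drop = FALSE]
  sub$sample <- sub[[act_col]]
  m_matched <- metric_by_curve(
    sub[sub[[act_col]] == matched_activator, , drop = FALSE], metric, ...)
  m_mis <- metric_by_curve(
    sub[sub[[act_col]] == mismatched_activator, , drop = FALSE], metric, ...)
  if (length(m_matched) == 0L || length(m_mis) == 0L) {
    stop("need replicate curves for both activator conditions")
  }
  denom <- mean(m_mis)
  if (denom <= eps) {
    stop("undefined ratio: mismatched-activator mean ", denom,
         " <= eps = ", eps)
  }
  mean(m_matched) / denom
}

#' Ratio score and zygosity call for one sample
#'
#' The ratio score is the mean metric of the mutant-detecting crRNA
#' reactions divided by the mean metric of the WT-detecting reactions.
#' Samples with a ratio of at least `r_hi` (default 5) are called homozygous
#' mutant, samples at or below `r_lo` (default 0.1) homozygous WT, and
#' everything between heterozygous; a ratio near 1 means both crRNAs
#' contribute equally.  A heterozygous call whose ratio falls at or beyond
#' the allelic-balance band edges (default `(1/2, 2)`, open interval, so a
#' ratio of exactly 0.5 -- a cell line with one mutant and two WT copies --
#' is flagged) is marked as imbalanced, consistent with a sample carrying
#' unequal allele copy numbers.  The
#' estimated mutant-allele fraction is `ratio / (1 + ratio)` (0.5 at ratio
#' 1).
#'
#' @param sample_curves Long-format data.frame for one sample with columns
#'   `time_min`, `value`, `sample`, `crrna`, `role` (`"mutant_detecting"`,
#'   `"wt_detecting"`, curves with other roles are ignored) and `replicate`.
#' @param metric `"endpoint"` (default) or `"slope"`.
#' @param r_hi Homozygous-mutant threshold (default 5).
#' @param r_lo Homozygous-WT threshold (default 0.1).
#' @param imbalance Length-2 band of ratios considered allelically balanced
#'   for heterozygous calls (default `c(0.5, 2)`).
#' @param eps Smallest admissible WT-mean denominator.
#' @param ... Passed to the metric (`t`, `tol`, `window`).
#' @return One-row data.frame: `sample`, `ratio`, `metric`, `call`,
#'   `imbalance_flag`, `est_mut_fraction`.
#' @export
ratio_score <- function(sample_curves, metric = c("endpoint", "slope"),
                        r_hi = 5, r_lo = 0.1, imbalance = c(0.5, 2),
                        eps = 1e-9, ...) {
  metric <- match.arg(metric)
  mut <- sample_curves[sample_curves$role == "mutant_detecting", ,
                       drop = FALSE]
  wt <- sample_curves[sample_curves$role == "wt_detecting", , drop = FALSE]
  if (nrow(mut) == 0L || nrow(wt) == 0L) {
    stop("need >= 1 mutant-detecting and >= 1 wt-detecting replicate")
  }
  m_mut <- mean(metric_by_curve(mut, metric, ...))
  m_wt <- mean(metric_by_curve(wt, metric, ...))
  if (m_wt <= eps) {
    stop("undefined ratio: wt-detecting mean ", m_wt, " <= eps = ", eps)
  }
  ratio <- m_mut / m_wt
  call <- if (ratio >= r_hi) "homozygous_mutant" else
    if (ratio <= r_lo) "homozygous_wt" else "heterozygous"
  flag <- call == "heterozygous" &&
    (ratio <= imbalance[1] || ratio >= imbalance[2])
  data.frame(sample = as.character(sample_curves$sample[1L]), ratio = ratio,
             metric = metric, call = call, imbalance_flag = flag,
             est_mut_fraction = ratio / (1 + ratio),
             stringsAsFactors = FALSE)
}

#' Zygosity calls for every sample on a plate
#'
#' Applies [ratio_score()] per sample; samples whose curves all have role
#' `"control"` are skipped.
#'
#' @param curves Long-format plate table (see [ratio_score()]).
#' @param ... Passed to [ratio_score()].
#' @return Data.frame, one row per called sample.
#' @export
call_zygosity <- function(curves, ...) {
  keep <- curves[curves$role %in% c("mutant_detecting", "wt_detecting"), ,
                 drop = FALSE]
  calls <- lapply(split(keep, keep$sample, drop = TRUE), ratio_score, ...)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Is a sample's signal above background?
#'
#' A 3-standard-deviation rule against blank (water) replicates: the sample
#' mean metric must exceed the blank mean plus three blank SDs.
#'
#' @param sample_curves Curves for the sample (long format).
#' @param blank_curves Curves for >= 2 blank replicates.
#' @param metric `"endpoint"` or `"slope"`.
#' @param ... Passed to the metric.
#' @return Logical.
#' @export
above_background <- function(sample_curves, blank_curves,
                             metric = c("endpoint", "slope"), ...) {
  metric <- match.arg(metric)
  m_blank <- metric_by_curve(blank_curves, metric, ...)
  if (length(m_blank) < 2L) {
    stop("need >= 2 blank replicates to estimate background spread")
  }
  m_sample <- metric_by_curve(sample_curves, metric, ...)
  mean(m_sample) > mean(m_blank) + 3 * sd(m_blank)
}

#' Read a long-format fluorescence plate table
#'
#' @param path Path to a tab-separated file with columns `time_min`,
#'   `value`, `sample`, `crrna`, `role`, `replicate`.
#' @return Data.frame.
#' @export
read_plate <- function(path) {
  df <- read_tsv(path)
  need <- c("time_min", "value", "sample", "crrna", "role", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("plate table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}
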