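#' Internal-standard normalization with log10 transform
#'
#' Divides every intensity by the sample's internal-standard intensity,
#' scales the ratio up by `scale_factor` to avoid negative logs, and log10
#' transforms. The standard row is removed from the result. This is the
#' GC-MS-style normalization: ratios to a spiked-in standard (e.g. 13C
#' sorbitol), scaled by a factor of 3000 before the log.
#'
#' For designs with several spiked standards, pass all their ids: the
#' per-sample reference is then the geometric mean of the standards.
#'
#' @param table An [intensity_table()] on the linear scale.
#' @param standard_id Metabolite id(s) of the internal standard(s); each must
#'   be observed (non-missing, positive) in every sample.
#' @param scale_factor Positive multiplier applied to the ratio before the
#'   log; default 3000.
#' @return A log10-scale [intensity_table()] without the standard row(s).
#' @export
normalize_internal_standard <- function(table, standard_id,
                                        scale_factor = 3000) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "linear")
    stop("internal-standard normalization expects a linear-scale table")
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      scale_factor <= 0)
    stop("`scale_factor` must be a positive number")
  missing_std <- setdiff(standard_id, rownames(table$values))
  if (length(missing_std))
    stop("standard not present in table: ", paste(missing_std, collapse = ", "))
  std <- table$values[standard_id, , drop = FALSE]
  bad <- colnames(std)[apply(std, 2, function(v) anyNA(v))]
  if (length(bad))
    stop("internal standard missing in sample(s): ",
         paste(bad, collapse = ", "))
  zero <- colnames(std)[apply(std, 2, function(v) any(v <= 0))]
  if (length(zero))
    stop("internal standard has zero intensity in sample(s): ",
         paste(zero, collapse = ", "))
  # geometric mean collapses to the single standard when only one is given
  ref <- exp(colMeans(log(std)))
  keep <- setdiff(rownames(table$values), standard_id)
  v <- log10(scale_factor * sweep(table$values[keep, , drop = FALSE], 2, ref, "/"))
  intensity_table(v, table$samples, scale = "log10")
}

#' Filter metabolites by missingness
#'
#' Removes metabolites whose fraction of missing (non-detected) values
#' reaches `max_missing_fraction`. The default 0.5 implements the rule that
#' a metabolite detected in less than half of the samples is excluded
#' (equivalently: >= 50% missing values are filtered out). When
#' `stratify_by` names a metadata column (e.g. `"tissue"`), the fraction is
#' computed within each stratum and a metabolite is dropped as soon as it
#' fails in any stratum; analyses that treat strata fully separately should
#' instead subset the table per stratum first, as [run_pipeline()] does.
#'
#' @param table An [intensity_table()].
#' @param max_missing_fraction Threshold in (0, 1]; a metabolite with
#'   missing fraction `>=` this value is removed.
#' @param stratify_by Optional name of a sample-metadata column.
#' @return The filtered [intensity_table()]. Emits a warning (not an error)
#'   if no metabolite survives.
#' @export
filter_missingness <- function(table, max_missing_fraction = 0.5,
                               stratify_by = NULL) {
  stopifnot(inherits(table, "intensity_table"))
  if (!is.numeric(max_missing_fraction) || max_missing_fraction <= 0 ||
      max_missing_fraction > 1)
    stop("`max_missing_fraction` must be in (0, 1]")
  miss <- is.na(table$values)
  if (is.null(stratify_by)) {
    frac <- rowMeans(miss)
    drop <- frac >= max_missing_fraction
  } else {
    if (!stratify_by %in% names(table$samples))
      stop("no metadata column called `", stratify_by, "`")
    strata <- split(seq_len(ncol(miss)), table$samples[[stratify_by]])
    drop <- Reduce(`|`, lapply(strata, function(j)
      rowMeans(miss[, j, drop = FALSE]) >= max_missing_fraction))
  }
  if (all(drop))
    warning("all metabolites removed by the missingness filter")
  table[!drop, ]
}

#' Upper-quartile normalization (log scale)
#'
#' Subtracts, per sample, the 75th percentile of the non-missing log
#' intensities, so that after normalization every sample's upper quartile is
#' zero. On the linear scale this is division by the upper quartile; the
#' operation is performed on the log scale where the pipeline's statistics
#' live. Idempotent.
#'
#' @param table A log-scale [intensity_table()].
#' @return The normalized [intensity_table()].
#' @export
upper_quartile_normalize <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  assert_log_scale(table, "upper_quartile_normalize()")
  nobs <- colSums(!is.na(table$values))
  if (any(nobs < 4))
    stop("sample(s) with fewer than 4 observed metabolites: ",
         paste(colnames(table$values)[nobs < 4], collapse = ", "))
  uq <- apply(table$values, 2, stats::quantile, probs = 0.75, na.rm = TRUE)
  out <- table
  out$values <- sweep(table$values, 2, uq, "-")
  out
}

#' Detect outlier samples by PCA
#'
#' Runs a principal component analysis of the samples (stats::prcomp on the
#' sample-by-metabolite matrix, centered) and reports samples whose score on
#' PC1 or PC2 lies more than `sd_threshold` standard deviations from that
#' component's mean. Detection only: removing the samples is a separate,
#' explicit subsetting step, so the exclusion list is always visible in the
#' analysis code. One pass, no re-iteration.
#'
#' Metabolites with any missing value are excluded from the PCA input by
#' default (`impute = "exclude"`); `impute = "mean"` mean-imputes them
#' instead, which keeps information when missingness is widespread.
#'
#' @param table A log-scale [intensity_table()] with at least 4 samples.
#' @param sd_threshold Score threshold in standard deviations; default 3.
#' @param impute `"exclude"` (default) or `"mean"`.
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(table, sd_threshold = 3,
                                   impute = c("exclude", "mean")) {
  stopifnot(inherits(table, "intensity_table"))
  impute <- match.arg(impute)
  if (ncol(table$values) < 4)
    stop("PCA outlier detection needs at least 4 samples")
  v <- table$values
  if (impute == "exclude") {
    v <- v[stats::complete.cases(v), , drop = FALSE]
    if (nrow(v) < 2)
      stop("fewer than 2 complete metabolites; consider impute = \"mean\"")
  } else {
    rm_ <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- rm_[idx[, 1]]
    v <- v[!is.na(rowMeans(v)), , drop = FALSE]
  }
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  flagged <- rep(FALSE, ncol(table$values))
  for (j in seq_len(k)) {
    s <- pc$x[, j]
    z <- (s - mean(s)) / stats::sd(s)
    flagged <- flagged | abs(z) > sd_threshold
  }
  colnames(table$values)[flagged]
}

#' Drop samples from a table
#'
#' Companion to [detect_outlier_samples()]: explicit removal of named
#' samples.
#'
#' @param table An [intensity_table()].
#' @param sample_ids Character vector of sample ids to remove.
#' @return The reduced [intensity_table()].
#' @export
drop_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "intensity_table"))
  unknown <- setdiff(sample_ids, colnames(table$values))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  table[, setdiff(colnames(table$values), sample_ids)]
}

#' Flag metabolites confounded by measurement run order
#'
#' Fits, per metabolite, a support vector regression (Gaussian/radial
#' kernel, via e1071) of intensity on the sample run order and returns the
#' metabolites whose fitted trend explains at least `r2_threshold` of the
#' variance. Such peaks drift with instrument state rather than biology and
#' are excluded from analysis; flagging returns the set, exclusion is an
#' explicit subsetting step.
#'
#' Run-order indices are standardized and the kernel width is set by the
#' median pairwise-distance heuristic (`gamma = 1 / (2 * median(dist)^2)`);
#' the epsilon-tube is 0.01 and the cost 10, so a smooth noiseless trend is
#' captured while white noise is almost never flagged at the default
#' threshold. A constant metabolite has R-squared defined as 0.
#'
#' @param table An [intensity_table()] whose metadata has `run_order` for
#'   every sample.
#' @param r2_threshold Fraction of variance the run-order trend must explain
#'   for a metabolite to be flagged; default 0.3.
#' @param min_obs Minimum non-missing values needed to fit; metabolites with
#'   fewer are never flagged. Default 8.
#' @return Character vector of flagged metabolite ids.
#' @export
flag_run_order_confounded <- function(table, r2_threshold = 0.3,
                                      min_obs = 8) {
  stopifnot(inherits(table, "intensity_table"))
  ro <- table$samples$run_order
  if (is.null(ro) || anyNA(ro))
    stop("run_order must be present for all samples")
  x_all <- (ro - mean(ro)) / stats::sd(ro)
  flagged <- character()
  for (m in rownames(table$values)) {
    y <- table$values[m, ]
    ok <- !is.na(y)
    if (sum(ok) < min_obs) next
    y0 <- y[ok]
    if (stats::sd(y0) == 0) next  # constant: R^2 := 0
    x0 <- x_all[ok]
    gamma <- 1 / (2 * stats::median(stats::dist(x0))^2)
    fit <- e1071::svm(x = matrix(x0), y = y0, kernel = "radial",
                      gamma = gamma, epsilon = 0.01, cost = 10,
                      scale = FALSE)
    r2 <- 1 - sum((y0 - stats::predict(fit))^2) / sum((y0 - mean(y0))^2)
    if (r2 >= r2_threshold) flagged <- c(flagged, m)
  }
  flagged
}
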