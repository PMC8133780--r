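#' Metabolite-by-sample intensity table
#'
#' The central container of the package: a numeric matrix of metabolite
#' intensities (rows = metabolites, columns = samples) together with
#' per-sample metadata and a scale flag. Missing (undetected) entries are
#' stored as `NA`; the missingness mask is therefore `is.na(values(x))`.
#'
#' @param values Numeric matrix, metabolites in rows (rownames are metabolite
#'   ids), samples in columns (colnames are sample ids). `NA` marks a
#'   non-detected metabolite in that sample. On the linear scale all
#'   observed values must be non-negative.
#' @param samples `data.frame` of sample metadata with at least columns
#'   `sample_id` (unique, matching `colnames(values)`) and `group`
#'   (species or genotype, non-empty). Optional columns: `tissue`, `age`,
#'   `run_order` (non-negative integer), `batch`.
#' @param scale One of `"linear"`, `"log10"`, `"log2"`; the scale the
#'   values are on. All statistical routines require a log scale.
#'
#' @return An object of class `intensity_table`.
#' @examples
#' vals <- matrix(10^rnorm(12, 4), 3, 4,
#'                dimnames = list(paste0("m", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    group = rep(c("a", "b"), each = 2))
#' intensity_table(vals, meta, scale = "linear")
#' @export
intensity_table <- function(values, samples, scale = c("linear", "log10", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop("`values` must have metabolite rownames")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0)
      stop("`values` must have sample colnames")
    colnames(values) <- character(0)
  }
  if (!is.data.frame(samples) || !all(c("sample_id", "group") %in% names(samples)))
    stop("`samples` must be a data.frame with columns `sample_id` and `group`")
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique")
  if (any(!nzchar(samples$group)) || anyNA(samples$group))
    stop("every sample needs a non-empty group label")
  if (ncol(values) != nrow(samples) ||
      !identical(colnames(values), samples$sample_id))
    stop("column names of `values` must equal `samples$sample_id`, in order")
  if (anyDuplicated(rownames(values)))
    stop("metabolite ids must be unique")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop("linear-scale intensities must be non-negative")
  if ("run_order" %in% names(samples)) {
    ro <- samples$run_order
    if (any(!is.na(ro) & (ro < 0 | ro != round(ro))))
      stop("`run_order` must be non-negative integers")
  }
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, scale = scale),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d metabolites x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

#' Accessors for intensity tables
#'
#' @param x An `intensity_table`.
#' @return `values()` the numeric matrix (NA = missing); `sample_meta()` the
#'   sample metadata `data.frame`; `table_scale()` the scale flag;
#'   `metabolite_ids()` / `sample_ids()` the row/column names.
#' @name accessors
NULL

#' @rdname accessors
#' @export
values <- function(x) x$values

#' @rdname accessors
#' @export
sample_meta <- function(x) x$samples

#' @rdname accessors
#' @export
table_scale <- function(x) x$scale

#' @rdname accessors
#' @export
metabolite_ids <- function(x) rownames(x$values)

#' @rdname accessors
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an intensity table
#'
#' @param x An `intensity_table`.
#' @param i Metabolite index (ids, integers or logical).
#' @param j Sample index (ids, integers or logical).
#' @param ... Ignored.
#' @param drop Ignored; dimensions are always kept.
#' @export
`[.intensity_table` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  if (is.logical(j)) j <- which(j)
  intensity_table(v, x$samples[j, , drop = FALSE], x$scale)
}

# internal: stop unless the table is on a log scale
assert_log_scale <- function(table, what) {
  if (table$scale == "linear")
    stop(sprintf("%s requires a log-scale table; got linear. %s", what,
                 "Apply normalize_internal_standard() or log-transform first."),
         call. = FALSE)
  invisible(TRUE)
}
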