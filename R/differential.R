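#' Per-metabolite two-group differential test
#'
#' For every metabolite with enough observations in both groups, computes
#' the average-log fold change (mean of group A log intensities minus mean
#' of group B log intensities) and a two-sided p-value from Student's/Welch
#' t-test or the Wilcoxon rank-sum test. Missing values are handled by
#' pairwise deletion: each metabolite is tested on its observed values only,
#' with no imputation.
#'
#' The t branch uses Welch's unequal-variance statistic by default
#' (`var_equal = TRUE` gives the pooled classical form). If both groups are
#' constant with equal values, the test is degenerate and p is defined as 1;
#' constant groups with different values give p at machine epsilon.
#'
#' @param table A log-scale [intensity_table()].
#' @param group_a,group_b Group labels; `log_fc` is A minus B.
#' @param test `"t"` or `"wilcoxon"`.
#' @param alpha Significance cutoff used only to set the `direction` column.
#' @param adjust `"none"` or `"BH"` (Benjamini-Hochberg across all tested
#'   metabolites). When `"BH"`, `direction` is called on the adjusted p.
#' @param min_group_n Minimum non-missing observations per group for a
#'   metabolite to be tested (default 3); smaller metabolites are skipped
#'   and listed in the `"skipped"` attribute with the reason.
#' @param var_equal For the t branch, pool variances (classical Student)
#'   instead of Welch.
#' @return A `data.frame` (one row per tested metabolite) with columns
#'   `metabolite_id`, `log_fc`, `p_value`, `adj_p` (NA when
#'   `adjust = "none"`), `direction` (`"up"`, `"down"`, `"none"`), `n_a`,
#'   `n_b`.
#' @export
diff_test <- function(table, group_a, group_b, test = c("t", "wilcoxon"),
                      alpha = 0.05, adjust = c("none", "BH"),
                      min_group_n = 3, var_equal = FALSE) {
  stopifnot(inherits(table, "intensity_table"))
  assert_log_scale(table, "diff_test()")
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  groups <- table$samples$group
  for (g in c(group_a, group_b))
    if (!g %in% groups) stop("unknown group label: ", g)
  ja <- which(groups == group_a)
  jb <- which(groups == group_b)
  ids <- rownames(table$values)
  out <- vector("list", length(ids))
  skipped <- list()
  for (i in seq_along(ids)) {
    a <- table$values[i, ja]; a <- a[!is.na(a)]
    b <- table$values[i, jb]; b <- b[!is.na(b)]
    if (length(a) < min_group_n || length(b) < min_group_n) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        metabolite_id = ids[i],
        reason = sprintf("n_a=%d, n_b=%d below min_group_n=%d",
                         length(a), length(b), min_group_n))
      next
    }
    lfc <- mean(a) - mean(b)
    p <- if (test == "t") two_sample_t_p(a, b, var_equal) else {
      suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
    }
    out[[i]] <- data.frame(metabolite_id = ids[i], log_fc = lfc, p_value = p,
                           n_a = length(a), n_b = length(b))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(metabolite_id = character(), log_fc = double(),
                      p_value = double(), n_a = integer(), n_b = integer())
  }
  res$adj_p <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else
    NA_real_
  crit <- if (adjust == "BH") res$adj_p else res$p_value
  res$direction <- ifelse(crit < alpha & res$log_fc > 0, "up",
                          ifelse(crit < alpha & res$log_fc < 0, "down",
                                 "none"))
  res <- res[, c("metabolite_id", "log_fc", "p_value", "adj_p", "direction",
                 "n_a", "n_b")]
  rownames(res) <- NULL
  if (length(skipped)) {
    sk <- do.call(rbind, skipped)
    message(nrow(sk), " metabolite(s) skipped (too few observations)")
    attr(res, "skipped") <- sk
  }
  res
}

# internal: two-sided two-sample t-test p with defined degenerate cases
two_sample_t_p <- function(a, b, var_equal = FALSE) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(1)
    return(.Machine$double.eps)
  }
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' Lineage-specific metabolite calls across three groups
#'
#' A metabolite is called specific to the focal group when it differs
#' significantly, and in the same direction, between the focal group and
#' each of the two outgroups, while the two outgroups do not differ
#' significantly from each other. With species as groups (e.g. human vs
#' chimpanzee and macaque) this isolates changes that occurred on the focal
#' lineage.
#'
#' Significance is the unadjusted two-sided p at `alpha` (default 0.05),
#' matching a per-tissue screening use; pass the result of [diff_test()]
#' with `adjust = "BH"` semantics through `alpha` on adjusted values if a
#' corrected screen is wanted.
#'
#' @param table A log-scale [intensity_table()] containing all three groups.
#' @param focal,out1,out2 Distinct group labels.
#' @param alpha Significance cutoff for all three pairwise tests.
#' @param test,min_group_n Passed to [diff_test()].
#' @return A `data.frame` with per-metabolite columns `log_fc_f1`, `p_f1`
#'   (focal vs out1), `log_fc_f2`, `p_f2` (focal vs out2), `p_out`
#'   (out1 vs out2) and the logical `is_focal_specific`.
#' @export
lineage_specific <- function(table, focal, out1, out2, alpha = 0.05,
                             test = "t", min_group_n = 3) {
  labs <- c(focal, out1, out2)
  if (anyDuplicated(labs)) stop("focal and outgroup labels must be distinct")
  d1 <- diff_test(table, focal, out1, test = test, alpha = alpha,
                  min_group_n = min_group_n)
  d2 <- diff_test(table, focal, out2, test = test, alpha = alpha,
                  min_group_n = min_group_n)
  d12 <- diff_test(table, out1, out2, test = test, alpha = alpha,
                   min_group_n = min_group_n)
  ids <- Reduce(intersect, list(d1$metabolite_id, d2$metabolite_id,
                                d12$metabolite_id))
  i1 <- match(ids, d1$metabolite_id)
  i2 <- match(ids, d2$metabolite_id)
  i12 <- match(ids, d12$metabolite_id)
  res <- data.frame(
    metabolite_id = ids,
    log_fc_f1 = d1$log_fc[i1], p_f1 = d1$p_value[i1],
    log_fc_f2 = d2$log_fc[i2], p_f2 = d2$p_value[i2],
    p_out = d12$p_value[i12])
  res$is_focal_specific <- res$p_f1 < alpha & res$p_f2 < alpha &
    sign(res$log_fc_f1) == sign(res$log_fc_f2) & res$p_out >= alpha
  res
}

#' Correlation of fold changes between two strata
#'
#' Pearson correlation of per-metabolite log fold changes computed in two
#' strata (e.g. two brain regions, or two ages), over the metabolites
#' tested in both. Used to ask whether concentration differences replicate
#' across tissues.
#'
#' @param diffs_a,diffs_b Results of [diff_test()] on the two strata.
#' @return A list with `r` (Pearson correlation), `p` (two-sided), and `n`
#'   (size of the metabolite intersection).
#' @export
cross_stratum_correlation <- function(diffs_a, diffs_b) {
  ids <- intersect(diffs_a$metabolite_id, diffs_b$metabolite_id)
  if (length(ids) < 3)
    stop("need at least 3 shared metabolites; got ", length(ids))
  x <- diffs_a$log_fc[match(ids, diffs_a$metabolite_id)]
  y <- diffs_b$log_fc[match(ids, diffs_b$metabolite_id)]
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids))
}
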