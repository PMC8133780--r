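#' Permutation null for the count of significant metabolites
#'
#' Estimates how surprising the observed number of nominally significant
#' metabolites is under the null of exchangeable group labels. On the true
#' labels, `observed_count` is the number of metabolites whose two-sided
#' t-test p falls strictly below `alpha_inner` (default 0.05). Group labels
#' are then shuffled `B` times preserving group sizes, the count recomputed
#' each time, and the permutation p-value estimated with the add-one rule
#'
#' \deqn{p = (1 + \#\{null \ge observed\}) / (1 + B),}
#'
#' which treats the identity labelling as one more draw from the null and
#' can never return 0. When the design admits fewer distinct label
#' assignments than `B` (e.g. 4 vs 4 samples: 70 assignments), the test
#' enumerates all assignments exactly instead of sampling, with a warning;
#' the reported p is then `#{assignments >= observed} / #assignments`,
#' which includes the identity and is the exact analogue of the add-one
#' estimator.
#'
#' The set of eligible metabolites (enough observations per group on the
#' true labels) is fixed before permuting, so observed and null counts are
#' over the same metabolites. Samples are processed in sample-id order, so
#' the result is invariant to the column order of the input for a fixed
#' seed.
#'
#' @param table A log-scale [intensity_table()].
#' @param group_a,group_b Group labels.
#' @param alpha_inner Inner t-test cutoff; a metabolite counts when
#'   `p < alpha_inner` (strict). Default 0.05.
#' @param B Number of label permutations, at least 100; default 1000.
#' @param seed Integer seed; mandatory, every run is reproducible.
#' @param min_group_n Eligibility threshold on non-missing observations per
#'   group (true labels); default 3.
#' @return An object of class `permutation_result`: a list with
#'   `observed_count`, `null_counts` (length `B`), `p_value`,
#'   `alpha_inner`, `B`, `seed`, and `exhaustive` (logical).
#' @export
permutation_count_test <- function(table, group_a, group_b,
                                   alpha_inner = 0.05, B = 1000, seed,
                                   min_group_n = 3) {
  stopifnot(inherits(table, "intensity_table"))
  assert_log_scale(table, "permutation_count_test()")
  if (missing(seed)) stop("`seed` is required for reproducibility")
  if (B < 100) stop("B must be at least 100")
  groups <- table$samples$group
  for (g in c(group_a, group_b))
    if (!g %in% groups) stop("unknown group label: ", g)
  keep <- groups %in% c(group_a, group_b)
  X <- table$values[, keep, drop = FALSE]
  lab <- groups[keep]
  # canonical sample order: invariance to input column order
  ord <- order(colnames(X))
  X <- X[, ord, drop = FALSE]
  lab <- lab[ord]
  n <- ncol(X)
  na_count <- length(which(lab == group_a))
  # eligibility on true labels, fixed for all permutations
  ok_a <- rowSums(!is.na(X[, lab == group_a, drop = FALSE])) >= min_group_n
  ok_b <- rowSums(!is.na(X[, lab == group_b, drop = FALSE])) >= min_group_n
  X <- X[ok_a & ok_b, , drop = FALSE]
  if (nrow(X) == 0) stop("no eligible metabolites")

  idx_a_obs <- which(lab == group_a)
  observed <- count_signif(X, idx_a_obs, alpha_inner)

  n_assign <- choose(n, na_count)
  exhaustive <- n_assign <= B
  if (exhaustive && n_assign < B)
    warning(sprintf(
      "only %d distinct label assignments; enumerating exhaustively instead of sampling %d",
      n_assign, B))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (exhaustive) {
    assigns <- utils::combn(n, na_count)
    null_counts <- apply(assigns, 2, function(ia) count_signif(X, ia, alpha_inner))
    p <- mean(null_counts >= observed)
    B_used <- n_assign
  } else {
    null_counts <- if (!anyNA(X)) {
      count_signif_batch(X, n, na_count, B, alpha_inner)
    } else {
      vapply(seq_len(B), function(b)
        count_signif(X, sample.int(n, na_count), alpha_inner), numeric(1))
    }
    p <- (1 + sum(null_counts >= observed)) / (1 + B)
    B_used <- B
  }
  structure(list(observed_count = observed, null_counts = as.integer(null_counts),
                 p_value = p, alpha_inner = alpha_inner, B = B_used,
                 seed = seed, exhaustive = exhaustive),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: %d significant metabolites (inner alpha %.3g)\n",
    x$observed_count, x$alpha_inner))
  cat(sprintf("  p = %.4g  (%s%d label assignments, seed %d)\n", x$p_value,
              if (x$exhaustive) "all " else "", x$B, x$seed))
  invisible(x)
}

# internal: number of rows with Welch p < alpha for one A/B split.
# Rows where a permuted group has < 2 observations, or where both groups are
# constant, never count as significant unless means differ with zero variance.
count_signif <- function(X, idx_a, alpha) {
  A <- X[, idx_a, drop = FALSE]
  Bm <- X[, -idx_a, drop = FALSE]
  na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(Bm))
  m1 <- rowMeans(A, na.rm = TRUE); m2 <- rowMeans(Bm, na.rm = TRUE)
  v1 <- row_var(A, m1, na); v2 <- row_var(Bm, m2, nb)
  p <- welch_p(m1, m2, v1, v2, na, nb)
  sum(p < alpha & na >= 2 & nb >= 2, na.rm = TRUE)
}

# internal: all-B-permutations-at-once counter for complete (no-NA) matrices,
# via two matrix products (sums and sums of squares against 0/1 indicators)
count_signif_batch <- function(X, n, na_count, B, alpha) {
  Z <- matrix(0, n, B)
  for (b in seq_len(B)) Z[sample.int(n, na_count), b] <- 1
  X2 <- X * X
  SA <- X %*% Z;  SB <- rowSums(X) - SA
  QA <- X2 %*% Z; QB <- rowSums(X2) - QA
  na <- na_count; nb <- n - na_count
  m1 <- SA / na; m2 <- SB / nb
  v1 <- pmax(QA - SA^2 / na, 0) / (na - 1)
  v2 <- pmax(QB - SB^2 / nb, 0) / (nb - 1)
  se2 <- v1 / na + v2 / nb
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / na)^2 / (na - 1) + (v2 / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- ifelse((m1 - m2)[se2 == 0] == 0, 1, .Machine$double.eps)
  colSums(p < alpha)
}

row_var <- function(M, mu, n) {
  ss <- rowSums(sweep(M, 1, mu, "-")^2, na.rm = TRUE)
  ifelse(n >= 2, ss / (n - 1), NA_real_)
}

welch_p <- function(m1, m2, v1, v2, n1, n2) {
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- !is.na(se2) & se2 == 0
  p[zero] <- ifelse((m1 - m2)[zero] == 0, 1, .Machine$double.eps)
  p
}
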