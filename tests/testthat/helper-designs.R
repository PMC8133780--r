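# Shared fixture builders. Everything is generated in code; no stored data.

# Log-scale intensity table from a plain matrix and a group vector.
make_log_table <- function(vals, groups, run_order = NULL, scale = "log10") {
  vals <- as.matrix(vals)
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("m%02d", seq_len(nrow(vals)))
  colnames(vals) <- sprintf("s%02d", seq_len(ncol(vals)))
  meta <- data.frame(sample_id = colnames(vals), group = groups)
  if (!is.null(run_order)) meta$run_order <- run_order
  intensity_table(vals, meta, scale = scale)
}

# Two-group null design: no effects, no dropout, no drift.
null_design <- function(n_per_group = 10, n_metabolites = 200, seed = 1,
                        groups = c(a = n_per_group, b = n_per_group), ...) {
  simulation_design(groups, n_metabolites = n_metabolites, seed = seed, ...)
}

# Two-group design with one planted pathway effect on the first
# `n_planted` metabolites (pathway "pw1", applied to the first group).
planted_design <- function(n_per_group = 10, n_metabolites = 200,
                           n_planted = 30, effect = 0.4, seed = 1, ...) {
  pa <- stats::setNames(rep("pw1", n_planted), sprintf("m%04d", seq_len(n_planted)))
  grp <- c(a = n_per_group, b = n_per_group)
  simulation_design(grp, n_metabolites = n_metabolites,
                    pathway_assignment = pa,
                    planted_effects = data.frame(pathway_id = "pw1",
                                                 group = "a",
                                                 effect = effect),
                    seed = seed, ...)
}

# Exact two-sided rank-sum p by full enumeration of the label assignments,
# replicating the doubling convention of the exact Mann-Whitney test.
# Independent oracle: never calls wilcox.test or pwilcox.
enumerate_ranksum_p <- function(a, b) {
  nx <- length(a); ny <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  assigns <- utils::combn(nx + ny, nx)
  u_all <- apply(assigns, 2, function(ia) sum(r[ia]) - nx * (nx + 1) / 2)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  p_one <- if (u_obs > nx * ny / 2) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(1, 2 * p_one)
}

# Exact binomial tail by summation of the mass function from binomial
# coefficients (integer arithmetic over 2^n); independent of pbinom.
enumerate_binom_p <- function(n_down, n_total, sidedness) {
  mass <- choose(n_total, 0:n_total) / 2^n_total
  one <- if (n_down > n_total / 2) sum(mass[(n_down + 1):(n_total + 1)]) else
    sum(mass[1:(n_down + 1)])
  if (sidedness == "two_sided") min(1, 2 * one) else one
}

# Permutation count test by direct enumeration with stats::t.test, used as
# the independent oracle for tiny designs.
enumerate_permutation <- function(tab, group_a, group_b, alpha = 0.05) {
  groups <- sample_meta(tab)$group
  keep <- groups %in% c(group_a, group_b)
  X <- values(tab)[, keep, drop = FALSE]
  lab <- groups[keep]
  ord <- order(colnames(X))
  X <- X[, ord, drop = FALSE]; lab <- lab[ord]
  n <- ncol(X); na <- sum(lab == group_a)
  count_for <- function(ia) {
    sum(vapply(seq_len(nrow(X)), function(i)
      stats::t.test(X[i, ia], X[i, -ia])$p.value, numeric(1)) < alpha)
  }
  obs <- count_for(which(lab == group_a))
  all_counts <- apply(utils::combn(n, na), 2, count_for)
  list(observed = obs, p = mean(all_counts >= obs),
       null_counts = all_counts)
}
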