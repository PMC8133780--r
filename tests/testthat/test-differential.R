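test_that("diff_test matches closed-form oracles on tiny inputs", {
  # identical groups: degenerate t defined as p = 1
  tab <- make_log_table(matrix(1, 1, 6), rep(c("a", "b"), each = 3))
  d <- diff_test(tab, "a", "b")
  expect_equal(d$log_fc, 0)
  expect_equal(d$p_value, 1)
  expect_identical(d$direction, "none")

  # A = {2, 2.1, 1.9}, B = {1, 1.1, 0.9}: equal variances 0.01, t = sqrt(150)
  tab2 <- make_log_table(matrix(c(2, 2.1, 1.9, 1, 1.1, 0.9), 1, 6),
                         rep(c("a", "b"), each = 3))
  d2 <- diff_test(tab2, "a", "b")
  expect_equal(d2$log_fc, 1)
  expect_equal(d2$p_value, 2 * pt(-sqrt(150), df = 4), tolerance = 1e-12)
  expect_identical(d2$direction, "up")
  expect_equal(d2$n_a, 3L)

  # Wilcoxon on fully separated {1,2,3} vs {4,5,6}: 2/20 by enumeration
  d3 <- diff_test(make_log_table(matrix(1:6, 1, 6),
                                 rep(c("a", "b"), each = 3)),
                  "a", "b", test = "wilcoxon")
  expect_equal(d3$p_value, enumerate_ranksum_p(1:3, 4:6), tolerance = 1e-12)
  expect_equal(d3$p_value, 0.1, tolerance = 1e-12)
})

test_that("relabeling groups flips log_fc and keeps p", {
  des <- null_design(n_per_group = 6, n_metabolites = 40, seed = 3,
                     dropout_rate = 0.1)
  tab <- simulate_intensity_table(des)$table
  ab <- suppressMessages(diff_test(tab, "a", "b"))
  ba <- suppressMessages(diff_test(tab, "b", "a"))
  expect_equal(ab$log_fc, -ba$log_fc)
  expect_equal(ab$p_value, ba$p_value)
  # and is invariant to sample order
  perm <- sample(seq_len(ncol(values(tab))))
  expect_equal(suppressMessages(diff_test(tab[, perm], "a", "b")), ab)
})

test_that("BH adjustment is monotone and drives the direction call", {
  des <- planted_design(n_per_group = 8, n_metabolites = 100, n_planted = 20,
                        effect = 0.5, seed = 6)
  tab <- simulate_intensity_table(des)$table
  d <- diff_test(tab, "a", "b", adjust = "BH")
  # sorting by raw p never decreases adjusted p (ties allowed)
  expect_true(all(diff(d$adj_p[order(d$p_value)]) >= 0))
  expect_true(all(d$adj_p >= d$p_value))
  expect_true(all(d$direction[d$adj_p >= 0.05] == "none"))
  d_un <- diff_test(tab, "a", "b", adjust = "none")
  expect_true(all(is.na(d_un$adj_p)))
})

test_that("metabolites below the group-size floor are skipped with a reason", {
  v <- matrix(rnorm(12), 2, 6)
  v[2, 1:4] <- NA  # only 2 observed values in total across both groups
  tab <- make_log_table(v, rep(c("a", "b"), each = 3))
  expect_message(d <- diff_test(tab, "a", "b"), "skipped")
  expect_equal(nrow(d), 1)
  expect_match(attr(d, "skipped")$reason, "min_group_n")
  expect_error(diff_test(tab, "a", "zz"), "unknown group")
})

test_that("type-I error of the t branch is nominal on null data", {
  des <- null_design(n_per_group = 10, n_metabolites = 2000, seed = 8)
  tab <- simulate_intensity_table(des)$table
  d <- diff_test(tab, "a", "b")
  expect_lt(abs(mean(d$p_value < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("lineage filter recovers a planted focal shift", {
  pa <- setNames(rep("pw1", 10), sprintf("m%04d", 1:10))
  des <- simulation_design(c(hum = 10, chimp = 10, mac = 10),
                           n_metabolites = 60, pathway_assignment = pa,
                           planted_effects = data.frame(pathway_id = "pw1",
                                                        group = "hum",
                                                        effect = 0.5),
                           seed = 14)
  tab <- simulate_intensity_table(des)$table
  lc <- lineage_specific(tab, "hum", "chimp", "mac")
  planted <- lc$is_focal_specific[lc$metabolite_id %in% names(pa)]
  expect_gte(mean(planted), 0.8)
  expect_lte(mean(lc$is_focal_specific[!lc$metabolite_id %in% names(pa)]),
             0.1)
  expect_error(lineage_specific(tab, "hum", "hum", "mac"), "distinct")
})

test_that("direction mismatch blocks a focal-specific call", {
  # focal clearly above out1 but clearly below out2
  v <- matrix(c(rep(2, 4), rep(0, 4), rep(4, 4)), 1, 12)
  tab <- make_log_table(v + seq(-0.03, 0.03, length.out = 12),
                        rep(c("f", "o1", "o2"), each = 4))
  lc <- lineage_specific(tab, "f", "o1", "o2")
  expect_lt(lc$p_f1, 0.05)
  expect_lt(lc$p_f2, 0.05)
  expect_false(lc$is_focal_specific)
})

test_that("lineage null rate matches the correlated-tests oracle", {
  # The two focal-vs-outgroup statistics share the focal samples, so under
  # the null they are correlated (rho = 1/2) and the joint rate exceeds
  # alpha^2. Oracle: direct Monte Carlo of three independent groups pushed
  # through Welch tests, mirroring the definition but not the implementation.
  n <- 10; alpha <- 0.05
  set.seed(99)
  B <- 60000
  tpair <- function(x, y) {
    vx <- apply(x, 1, var); vy <- apply(y, 1, var)
    se2 <- vx / n + vy / n
    tt <- (rowMeans(x) - rowMeans(y)) / sqrt(se2)
    df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / n)^2 / (n - 1))
    list(p = 2 * pt(-abs(tt), df), s = sign(rowMeans(x) - rowMeans(y)))
  }
  f <- matrix(rnorm(B * n), B); o1 <- matrix(rnorm(B * n), B)
  o2 <- matrix(rnorm(B * n), B)
  r1 <- tpair(f, o1); r2 <- tpair(f, o2); r12 <- tpair(o1, o2)
  oracle <- mean(r1$p < alpha & r2$p < alpha & r1$s == r2$s &
                   r12$p >= alpha)

  des <- null_design(n_per_group = n, n_metabolites = 4000, seed = 15,
                     groups = c(f = n, o1 = n, o2 = n))
  tab <- simulate_intensity_table(des)$table
  lc <- lineage_specific(tab, "f", "o1", "o2", alpha = alpha)
  rate <- mean(lc$is_focal_specific)
  se <- sqrt(oracle * (1 - oracle) / 4000)
  expect_lt(abs(rate - oracle), 4 * se)
  # and the rate sits well above the independence heuristic alpha^2
  expect_gt(oracle, 2 * alpha^2)
})

test_that("cross-stratum correlation handles identity, negation, attenuation", {
  des <- planted_design(n_per_group = 6, n_metabolites = 50, seed = 4)
  d <- diff_test(simulate_intensity_table(des)$table, "a", "b")
  expect_equal(cross_stratum_correlation(d, d)$r, 1)
  neg <- d; neg$log_fc <- -neg$log_fc
  expect_equal(cross_stratum_correlation(d, neg)$r, -1)
  expect_equal(cross_stratum_correlation(d, d)$n, nrow(d))
  expect_error(cross_stratum_correlation(d[1:2, ], d[1:2, ]), "at least 3")

  # shared true effects + independent noise attenuate r to
  # tau^2 / (tau^2 + sigma^2)
  set.seed(44)
  m <- 800; tau <- 0.3; sig <- 0.1
  true_d <- rnorm(m, 0, tau)
  da <- data.frame(metabolite_id = sprintf("m%03d", 1:m),
                   log_fc = true_d + rnorm(m, 0, sig))
  db <- data.frame(metabolite_id = sprintf("m%03d", 1:m),
                   log_fc = true_d + rnorm(m, 0, sig))
  r <- cross_stratum_correlation(da, db)$r
  expect_equal(r, tau^2 / (tau^2 + sig^2), tolerance = 0.03)
})
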