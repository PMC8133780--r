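make_diffs <- function(ids, log_fc, p) {
  data.frame(metabolite_id = ids, log_fc = log_fc, p_value = p,
             adj_p = NA_real_, direction = "none",
             n_a = 5L, n_b = 5L)
}

test_that("Fisher combination matches closed forms", {
  map <- pathway_map(data.frame(metabolite_id = c("x", "y", "z"),
                                pathway_id = c("p1", "p2", "p2")))
  # k = 1: Fisher's method is the identity
  d1 <- make_diffs("x", -1, 0.05)
  res1 <- pathway_cumulative_p(d1, map, "down", min_metabolites = 1)
  expect_equal(res1$combined_p, 0.05, tolerance = 1e-12)
  # k = 2, both p = 0.1: chi-squared(4) tail at -2 * 2 * log(0.1)
  d2 <- make_diffs(c("x", "y", "z"), c(-1, -1, -1), c(0.5, 0.1, 0.1))
  res2 <- pathway_cumulative_p(d2, map, "down", min_metabolites = 1)
  p2 <- res2$combined_p[res2$pathway_id == "p2"]
  expect_equal(p2, pchisq(-4 * log(0.1), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # all member p-values 1 combine to 1
  d3 <- make_diffs(c("y", "z"), c(-1, -1), c(1, 1))
  res3 <- pathway_cumulative_p(d3, map, "down", min_metabolites = 1)
  expect_equal(res3$combined_p[res3$pathway_id == "p2"], 1, tolerance = 1e-9)
})

test_that("direction stratification and the member floor drop pathways", {
  map <- pathway_map(data.frame(metabolite_id = c("x", "y", "z"),
                                pathway_id = c("p1", "p2", "p2")))
  d <- make_diffs(c("x", "y", "z"), c(1, -1, 1), c(0.01, 0.01, 0.01))
  res_down <- pathway_cumulative_p(d, map, "down", min_metabolites = 1)
  expect_setequal(res_down$pathway_id, "p2")   # only y goes down
  expect_equal(res_down$n_detected, 2)
  expect_equal(res_down$n_direction, 1)
  res_up2 <- pathway_cumulative_p(d, map, "up", min_metabolites = 2)
  expect_false("p2" %in% res_up2$pathway_id)   # only one up member
  expect_false("p1" %in% res_up2$pathway_id)
})

test_that("planted pathway suppression is called enriched", {
  pa <- setNames(rep("pw1", 10), sprintf("m%04d", 1:10))
  des <- simulation_design(c(a = 10, b = 10), n_metabolites = 120,
                           pathway_assignment = pa,
                           planted_effects = data.frame(pathway_id = "pw1",
                                                        group = "a",
                                                        effect = -0.4),
                           seed = 61)
  tab <- simulate_intensity_table(des)$table
  d <- diff_test(tab, "a", "b")
  mem <- data.frame(metabolite_id = sprintf("m%04d", 1:120),
                    pathway_id = c(rep("pw1", 10),
                                   rep(c("q1", "q2", "q3", "q4", "q5"), 22)))
  map <- pathway_map(mem, purine_flag = sprintf("m%04d", 1:10))
  res <- pathway_cumulative_p(d, map, "down", cutoff = 0.01)
  expect_true(res$enriched[res$pathway_id == "pw1"])
  expect_equal(res$pathway_id[1], "pw1")  # sorted by combined p
  expect_lte(sum(res$enriched), 1)
})

test_that("pb_vs_rest detects a planted purine suppression", {
  pa <- setNames(rep("pb", 10), sprintf("m%04d", 1:10))
  des <- simulation_design(c(a = 10, b = 10), n_metabolites = 210,
                           pathway_assignment = pa,
                           planted_effects = data.frame(pathway_id = "pb",
                                                        group = "a",
                                                        effect = -0.5),
                           seed = 62)
  d <- diff_test(simulate_intensity_table(des)$table, "a", "b")
  mem <- data.frame(metabolite_id = sprintf("m%04d", 1:210),
                    pathway_id = c(rep("pb", 10), rep("other", 200)))
  map <- pathway_map(mem, purine_flag = sprintf("m%04d", 1:10))
  res <- pb_vs_rest(d, map)
  expect_lt(res$p, 0.01)
  expect_equal(res$median_shift, -0.5, tolerance = 0.15)
  expect_equal(res$n_pb, 10)
  expect_equal(res$n_other, 200)
})

test_that("pb_vs_rest degenerate and error cases", {
  mem <- data.frame(metabolite_id = sprintf("m%02d", 1:12),
                    pathway_id = c(rep("pb", 4), rep("other", 8)))
  map <- pathway_map(mem, purine_flag = sprintf("m%02d", 1:4))
  # flagged values are a pure relabeling of a subset of the others
  d <- make_diffs(sprintf("m%02d", 1:12), rep(c(0.1, 0.2, -0.1, -0.2), 3),
                  runif(12))
  res <- pb_vs_rest(d, map)
  expect_equal(res$median_shift, 0)
  map2 <- pathway_map(mem, purine_flag = sprintf("m%02d", 1:2))
  expect_error(pb_vs_rest(d, map2), "at least 3")
})

test_that("pb_vs_rest p is invariant under common monotone transforms", {
  set.seed(63)
  mem <- data.frame(metabolite_id = sprintf("m%03d", 1:100),
                    pathway_id = c(rep("pb", 8), rep("other", 92)))
  map <- pathway_map(mem, purine_flag = sprintf("m%03d", 1:8))
  lfc <- c(rnorm(8, -0.4, 0.1), rnorm(92, 0, 0.2))
  d <- make_diffs(mem$metabolite_id, lfc, runif(100))
  d_tr <- d; d_tr$log_fc <- exp(2 * d$log_fc) + 5  # strictly increasing
  expect_equal(pb_vs_rest(d, map)$p, pb_vs_rest(d_tr, map)$p,
               tolerance = 1e-12)
})

test_that("direction binomial agrees with mass-function enumeration to n = 20", {
  for (n in 1:20) {
    for (k in 0:n) {
      for (s in c("one_sided", "two_sided")) {
        expect_equal(direction_binomial(k, n, s)$p_value,
                     enumerate_binom_p(k, n, s), tolerance = 1e-12,
                     info = sprintf("n=%d k=%d %s", n, k, s))
      }
    }
  }
  expect_equal(direction_binomial(5, 10, "two_sided")$p_value, 1)
  expect_error(direction_binomial(11, 10, "one_sided"), "n_down")
})

test_that("null flagged sets give roughly uniform pb_vs_rest p-values", {
  ps <- vapply(1:60, function(s) {
    des <- null_design(n_per_group = 6, n_metabolites = 60, seed = 200 + s)
    d <- diff_test(simulate_intensity_table(des)$table, "a", "b")
    mem <- data.frame(metabolite_id = sprintf("m%04d", 1:60),
                      pathway_id = c(rep("pb", 8), rep("other", 52)))
    map <- pathway_map(mem, purine_flag = sprintf("m%04d", 1:8))
    pb_vs_rest(d, map)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2) # not inflated far beyond nominal
  expect_gt(median(ps), 0.2)       # and not degenerate
})
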