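#' Direction-stratified pathway aggregation
#'
#' Scores each pathway by combining the per-metabolite difference p-values
#' of its detected members that changed in the requested direction. The
#' default combiner is Fisher's method: with k member p-values, the
#' statistic \eqn{-2\sum \ln p_i} is referred to a chi-squared distribution
#' with 2k degrees of freedom; its upper tail is the pathway's cumulative
#' p-value. A hypergeometric over-representation p (direction-consistent
#' members vs the detected background) is reported alongside as `hyper_p`.
#'
#' @param diffs Result of [diff_test()] on the contrast of interest.
#' @param map A [pathway_map()].
#' @param direction `"up"` or `"down"`: which sign of `log_fc` a member
#'   must have to contribute.
#' @param min_metabolites Minimum number of direction-consistent detected
#'   members for a pathway to be scored (default 2); pathways with none are
#'   always omitted.
#' @param cutoff Enrichment cutoff on the combined p; default 0.01.
#' @return A `data.frame` with one row per scored pathway: `pathway_id`,
#'   `pathway_name`, `n_detected` (detected members), `n_direction`
#'   (direction-consistent members, the ones combined), `combined_p`
#'   (Fisher), `hyper_p`, `direction`, `enriched`.
#' @export
pathway_cumulative_p <- function(diffs, map, direction = c("down", "up"),
                                 min_metabolites = 2, cutoff = 0.01) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "pathway_map"), min_metabolites >= 1)
  mem <- map$membership[map$membership$metabolite_id %in% diffs$metabolite_id, ]
  idx <- match(mem$metabolite_id, diffs$metabolite_id)
  mem$p <- diffs$p_value[idx]
  mem$consistent <- if (direction == "down") diffs$log_fc[idx] < 0 else
    diffs$log_fc[idx] > 0
  n_bg <- length(unique(mem$metabolite_id))
  n_bg_dir <- length(unique(mem$metabolite_id[mem$consistent]))
  rows <- lapply(split(mem, mem$pathway_id), function(pw) {
    sub <- pw[pw$consistent, ]
    k <- nrow(sub)
    if (k < min_metabolites) return(NULL)
    stat <- -2 * sum(log(sub$p))
    data.frame(pathway_id = pw$pathway_id[1],
               pathway_name = pw$pathway_name[1],
               n_detected = nrow(pw), n_direction = k,
               combined_p = stats::pchisq(stat, df = 2 * k,
                                          lower.tail = FALSE),
               hyper_p = stats::phyper(k - 1, n_bg_dir, n_bg - n_bg_dir,
                                       nrow(pw), lower.tail = FALSE),
               direction = direction)
  })
  res <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(res))
    return(data.frame(pathway_id = character(), pathway_name = character(),
                      n_detected = integer(), n_direction = integer(),
                      combined_p = double(), hyper_p = double(),
                      direction = character(), enriched = logical()))
  res$enriched <- res$combined_p < cutoff
  rownames(res) <- NULL
  res[order(res$combined_p), ]
}

#' Purine-biosynthesis versus other pathways
#'
#' Compares the distribution of log fold changes of the purine-biosynthesis
#' metabolites (the `purine_flag` set of the map) against all other
#' annotated, detected metabolites with a two-sided Wilcoxon rank-sum test.
#' A negative median shift means purine-biosynthesis metabolites are lower
#' in group A of the contrast than other metabolites are.
#'
#' @param diffs Result of [diff_test()].
#' @param map A [pathway_map()] with at least 3 flagged metabolites among
#'   the tested ones.
#' @return A list: `p` (Wilcoxon two-sided), `median_shift` (median flagged
#'   `log_fc` minus median of the rest), `n_pb`, `n_other`.
#' @export
pb_vs_rest <- function(diffs, map) {
  stopifnot(inherits(map, "pathway_map"))
  annotated <- unique(map$membership$metabolite_id)
  d <- diffs[diffs$metabolite_id %in% annotated, ]
  flagged <- d$metabolite_id %in% map$purine_flag
  if (sum(flagged) < 3)
    stop("need at least 3 purine-flagged metabolites among the results; got ",
         sum(flagged))
  if (sum(!flagged) < 1)
    stop("no non-flagged annotated metabolites to compare against")
  x <- d$log_fc[flagged]; y <- d$log_fc[!flagged]
  w <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(p = w$p.value,
       median_shift = stats::median(x) - stats::median(y),
       n_pb = sum(flagged), n_other = sum(!flagged))
}

#' Exact binomial test for the direction of change
#'
#' Tests whether metabolites go down (or up) more often than an even coin
#' would predict: `n_down` decreases among `n_total` detected metabolites
#' against success probability 0.5. The one-sided p is the exact tail in
#' the direction of the observed majority; the two-sided p doubles it,
#' capped at 1. Sidedness has no default: printed values in this literature
#' mix both conventions, so the caller must say which is meant.
#'
#' @param n_down Number of metabolites with lower level (0..`n_total`).
#' @param n_total Number of detected metabolites, at least 1.
#' @param sidedness `"one_sided"` or `"two_sided"`.
#' @return A list: `n_total`, `n_down`, `sidedness`, `p_value`.
#' @examples
#' direction_binomial(10, 12, "two_sided")$p_value # 0.0386..., prints as 0.04
#' direction_binomial(9, 10, "one_sided")$p_value  # 11/1024 = 0.0107...
#' @export
direction_binomial <- function(n_down, n_total,
                               sidedness = c("one_sided", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (n_total < 1 || n_down < 0 || n_down > n_total)
    stop("need 0 <= n_down <= n_total and n_total >= 1")
  one <- if (n_down > n_total / 2) {
    stats::pbinom(n_down - 1, n_total, 0.5, lower.tail = FALSE)
  } else {
    stats::pbinom(n_down, n_total, 0.5)
  }
  p <- if (sidedness == "two_sided") min(1, 2 * one) else one
  list(n_total = as.integer(n_total), n_down = as.integer(n_down),
       sidedness = sidedness, p_value = p)
}
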