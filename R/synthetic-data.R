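#' Specify a synthetic metabolomics study design
#'
#' Collects everything [simulate_intensity_table()] needs: group sizes,
#' tissues, the metabolite-to-pathway assignment, planted pathway-level
#' effects, and the nuisance structure (detection dropout, run-order drift,
#' outlier samples). Defaults emulate a two-genotype rodent study with
#' moderate biological noise; see the package vignette for the reasoning
#' behind each default.
#'
#' @param groups Named integer vector of samples per group, e.g.
#'   `c(hum = 10, wt = 10)`; every group needs at least 2 samples.
#' @param n_metabolites Number of metabolites.
#' @param tissues Character vector of tissue labels; each group is measured
#'   in every tissue with `groups` samples per cell. Default one tissue.
#' @param pathway_assignment Named character vector mapping metabolite ids
#'   to pathway ids (at most one pathway per metabolite); metabolites not
#'   named are unannotated. Default: none.
#' @param planted_effects `data.frame` with columns `pathway_id`, `group`,
#'   `effect`: a log10 shift added to that group's true mean for every
#'   metabolite of the pathway. Default: none.
#' @param dropout_rate Fraction of entries set missing, in `[0, 1]`.
#' @param dropout_mode `"mcar"` (missing completely at random, default) or
#'   `"censor"` (the lowest-intensity entries are the missing ones,
#'   emulating a detection limit).
#' @param drift_amplitude Amplitude (log10 units) of a smooth run-order
#'   trend added to a subset of metabolites; 0 disables drift.
#' @param drift_fraction Fraction of metabolites carrying the trend;
#'   default 0.2.
#' @param n_outliers Number of samples shifted globally to emulate failed
#'   preparations; default 0.
#' @param outlier_shift Size of the outlier shift in units of the
#'   between-sample noise SD; default 5 (comfortably beyond a 3-SD
#'   screening rule).
#' @param noise_sd Between-sample biological + technical SD on the log10
#'   scale; default 0.2.
#' @param baseline_mean,baseline_sd Hyperdistribution of per-metabolite
#'   mean log10 intensities; defaults 4 and 1.
#' @param tissue_sd SD of per-metabolite tissue offsets (log10); default
#'   0.2, 0 when only one tissue.
#' @param seed Integer seed; identical designs give bit-identical tables.
#' @return A `simulation_design` list, validated.
#' @export
simulation_design <- function(groups, n_metabolites,
                              tissues = "tissue1",
                              pathway_assignment = character(),
                              planted_effects = NULL,
                              dropout_rate = 0, dropout_mode = c("mcar", "censor"),
                              drift_amplitude = 0, drift_fraction = 0.2,
                              n_outliers = 0, outlier_shift = 5,
                              noise_sd = 0.2,
                              baseline_mean = 4, baseline_sd = 1,
                              tissue_sd = if (length(tissues) > 1) 0.2 else 0,
                              seed = 1) {
  dropout_mode <- match.arg(dropout_mode)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a named vector of group sizes")
  if (any(groups < 2)) stop("every group needs at least 2 samples")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("`dropout_rate` must be in [0, 1]")
  if (n_metabolites < 1) stop("need at least 1 metabolite")
  mets <- sprintf("m%04d", seq_len(n_metabolites))
  if (length(pathway_assignment)) {
    if (is.null(names(pathway_assignment)))
      stop("`pathway_assignment` must be named by metabolite id")
    if (anyDuplicated(names(pathway_assignment)))
      stop("each metabolite maps to at most one pathway")
    if (!all(names(pathway_assignment) %in% mets))
      stop("pathway_assignment names must be metabolite ids (m0001 ...)")
  }
  if (!is.null(planted_effects)) {
    need <- c("pathway_id", "group", "effect")
    if (!is.data.frame(planted_effects) ||
        !all(need %in% names(planted_effects)))
      stop("`planted_effects` needs columns pathway_id, group, effect")
    if (!all(planted_effects$group %in% names(groups)))
      stop("planted_effects reference unknown groups")
    if (!all(planted_effects$pathway_id %in% pathway_assignment))
      stop("planted_effects reference pathways with no assigned metabolites")
  }
  structure(list(groups = groups, n_metabolites = n_metabolites,
                 metabolites = mets, tissues = tissues,
                 pathway_assignment = pathway_assignment,
                 planted_effects = planted_effects,
                 dropout_rate = dropout_rate, dropout_mode = dropout_mode,
                 drift_amplitude = drift_amplitude,
                 drift_fraction = drift_fraction,
                 n_outliers = n_outliers, outlier_shift = outlier_shift,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, tissue_sd = tissue_sd,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate an intensity table with known ground truth
#'
#' Draws per-metabolite baseline log10 intensities from a wide
#' hyperdistribution, adds planted group effects, Gaussian between-sample
#' noise, an optional smooth run-order trend (a random sum of 1-3
#' sinusoids) on a subset of metabolites, global shifts for designated
#' outlier samples, and detection dropout. Ground truth (true group means,
#' affected metabolites, drift metabolites, outlier samples) is returned
#' alongside, so recovery by the downstream statistics can be verified.
#'
#' @param design A [simulation_design()].
#' @param output_scale `"log10"` (default, the analysis scale) or
#'   `"linear"` (values exponentiated, e.g. to exercise
#'   [normalize_internal_standard()]).
#' @return A list with `table` (an [intensity_table()]; metadata columns
#'   `sample_id`, `group`, `tissue`, `run_order`) and `truth` (a list:
#'   `true_group_means` metabolite-by-group matrix of log10 means,
#'   `affected_metabolites`, `drift_metabolites`, `outlier_samples`).
#' @export
simulate_intensity_table <- function(design, output_scale = c("log10", "linear")) {
  stopifnot(inherits(design, "simulation_design"))
  output_scale <- match.arg(output_scale)
  d <- design
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(d$seed)

  meta <- expand.grid(rep_id = seq_len(max(d$groups)),
                      group = names(d$groups), tissue = d$tissues,
                      stringsAsFactors = FALSE)
  meta <- meta[meta$rep_id <= d$groups[meta$group], ]
  meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  meta$run_order <- sample.int(nrow(meta))
  meta <- meta[, c("sample_id", "group", "tissue", "run_order")]
  n_samp <- nrow(meta)
  m <- d$n_metabolites

  baseline <- stats::rnorm(m, d$baseline_mean, d$baseline_sd)
  true_means <- matrix(baseline, m, length(d$groups),
                       dimnames = list(d$metabolites, names(d$groups)))
  affected <- character()
  if (!is.null(d$planted_effects)) {
    for (i in seq_len(nrow(d$planted_effects))) {
      pw <- d$planted_effects$pathway_id[i]
      g <- d$planted_effects$group[i]
      mem <- names(d$pathway_assignment)[d$pathway_assignment == pw]
      true_means[mem, g] <- true_means[mem, g] + d$planted_effects$effect[i]
      affected <- union(affected, mem)
    }
  }
  tissue_off <- matrix(stats::rnorm(m * length(d$tissues), 0, d$tissue_sd),
                       m, length(d$tissues),
                       dimnames = list(d$metabolites, d$tissues))

  vals <- true_means[, meta$group, drop = FALSE] +
    tissue_off[, meta$tissue, drop = FALSE] +
    matrix(stats::rnorm(m * n_samp, 0, d$noise_sd), m, n_samp)
  colnames(vals) <- meta$sample_id

  drift_mets <- character()
  if (d$drift_amplitude > 0 && d$drift_fraction > 0) {
    n_drift <- max(1, round(d$drift_fraction * m))
    drift_mets <- sort(sample(d$metabolites, n_drift))
    x <- meta$run_order / n_samp
    for (mm in drift_mets) {
      k <- sample(1:3, 1)
      trend <- rowSums(vapply(seq_len(k), function(j)
        stats::runif(1, 0.5, 1) *
          sin(2 * pi * (stats::runif(1, 0.5, 1.5) * x + stats::runif(1))),
        numeric(n_samp)))
      trend <- trend / max(abs(trend)) * d$drift_amplitude
      vals[mm, ] <- vals[mm, ] + trend
    }
  }

  outliers <- character()
  if (d$n_outliers > 0) {
    outliers <- sort(sample(meta$sample_id, d$n_outliers))
    shift <- d$outlier_shift * d$noise_sd *
      sample(c(-1, 1), d$n_outliers, replace = TRUE)
    vals[, outliers] <- sweep(vals[, outliers, drop = FALSE], 2, shift, "+")
  }

  if (d$dropout_rate > 0) {
    if (d$dropout_mode == "mcar") {
      miss <- matrix(stats::runif(m * n_samp) < d$dropout_rate, m, n_samp)
    } else {
      miss <- vals <= stats::quantile(vals, d$dropout_rate)
    }
    vals[miss] <- NA_real_
  }

  scale <- "log10"
  if (output_scale == "linear") {
    vals <- 10^vals
    scale <- "linear"
  }
  list(table = intensity_table(vals, meta, scale = scale),
       truth = list(true_group_means = true_means,
                    affected_metabolites = sort(affected),
                    drift_metabolites = drift_mets,
                    outlier_samples = outliers))
}

#' Simulate a two-state thermal melt curve
#'
#' Samples a two-state unfolding sigmoid at 1 degree steps over the scanned
#' range, with Gaussian noise on the signal. The fraction folded is
#' `1 / (1 + exp(slope * (T - midpoint)))`, so the noiseless curve crosses
#' 50% folded exactly at the midpoint.
#'
#' @param midpoint Melting midpoint, degrees C; must lie inside the scanned
#'   range.
#' @param slope Transition steepness, 1/degree C; must be positive.
#' @param noise_sd Gaussian noise SD in signal (ellipticity) units.
#' @param seed Optional integer seed.
#' @param t_min,t_max Scanned range, degrees C; defaults 50 and 80.
#' @param folded_signal,unfolded_signal Plateau signals (mdeg ellipticity
#'   at 222 nm); defaults -20 and -4.
#' @return `data.frame` with columns `temperature` and `signal`.
#' @export
simulate_melt_curve <- function(midpoint, slope = 0.8, noise_sd = 0,
                                seed = NULL, t_min = 50, t_max = 80,
                                folded_signal = -20, unfolded_signal = -4) {
  if (slope <= 0) stop("`slope` must be positive")
  if (midpoint <= t_min || midpoint >= t_max)
    stop(sprintf("midpoint %.1f outside the scanned range (%g, %g)",
                 midpoint, t_min, t_max))
  temps <- seq(t_min, t_max, by = 1)
  frac <- 1 / (1 + exp(slope * (temps - midpoint)))
  sig <- unfolded_signal + (folded_signal - unfolded_signal) * frac
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
  }
  data.frame(temperature = temps, signal = sig)
}
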