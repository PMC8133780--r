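#' Run the full comparative-metabolomics pipeline
#'
#' Sequences the published analysis order — normalization, missingness
#' filtering, PCA outlier exclusion, per-metabolite testing, permutation
#' count test, pathway statistics — independently within each stratum
#' (typically tissue), and writes all outputs plus a machine-readable run
#' manifest to `out_dir`. Identical config and seed give byte-identical
#' outputs.
#'
#' The config is a named list (or a YAML file with the same structure):
#' \describe{
#'   \item{input}{`table`, `meta` (TSV paths), optional `pathway_map`
#'     (TSV path), `scale` (`"linear"`, `"log10"`, `"log2"`; default
#'     `"log10"`). Ignored when `table`/`map` objects are passed directly.}
#'   \item{contrast}{Two group labels (`group_a`, `group_b`), or three
#'     (`focal`, `out1`, `out2`) — with three, the lineage-specific filter
#'     is run and the two outgroups are pooled into one label for the
#'     permutation and pathway statistics.}
#'   \item{stratify_by}{Metadata column analyzed separately (e.g.
#'     `"tissue"`); omit for a single stratum.}
#'   \item{normalization}{Optional: `standard_id` and `scale_factor` for
#'     internal-standard normalization of a linear-scale table;
#'     `upper_quartile: true` to upper-quartile normalize.}
#'   \item{thresholds}{`alpha` (0.05), `alpha_inner` (0.05), `B` (1000),
#'     `pathway_cutoff` (0.01), `max_missing` (0.5), `outlier_sd` (3),
#'     `test` (`"t"`), `adjust` (`"none"`), `pathway_direction`
#'     (`"down"`).}
#'   \item{seed}{Integer; per-stratum seeds are derived from it.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if absent).
#' @param table Optionally, an [intensity_table()] to use instead of
#'   reading `config$input`.
#' @param map Optionally, a [pathway_map()].
#' @return Invisibly, a list of per-stratum results (`diff`, `permutation`,
#'   `pathways`, `pb_vs_rest`, `lineage`, `outliers`) plus the manifest.
#' @export
run_pipeline <- function(config, out_dir, table = NULL, map = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- apply_config_defaults(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (is.null(table)) {
    table <- read_intensity_table(cfg$input$table, cfg$input$meta,
                                  scale = cfg$input$scale)
  }
  if (is.null(map) && !is.null(cfg$input$pathway_map))
    map <- read_pathway_map(cfg$input$pathway_map)

  th <- cfg$thresholds
  contrast <- unlist(cfg$contrast, use.names = FALSE)
  if (!length(contrast) %in% 2:3)
    stop("contrast must name two or three groups")

  strata <- if (is.null(cfg$stratify_by)) list(all = table) else {
    col <- cfg$stratify_by
    if (!col %in% names(table$samples))
      stop("no metadata column called `", col, "`")
    lv <- sort(unique(table$samples[[col]]))
    stats::setNames(lapply(lv, function(l)
      table[, table$samples[[col]] == l]), lv)
  }

  results <- list()
  summary_lines <- character()
  for (si in seq_along(strata)) {
    stratum <- names(strata)[si]
    tab <- strata[[si]]
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("stage `%s` failed in stratum `%s`: %s", name, stratum,
                     conditionMessage(e)), call. = FALSE))
    }
    if (tab$scale == "linear") {
      if (is.null(cfg$normalization$standard_id))
        stop("linear-scale input needs normalization$standard_id")
      tab <- stage("normalize", normalize_internal_standard(
        tab, cfg$normalization$standard_id,
        cfg$normalization$scale_factor %||% 3000))
    }
    tab <- stage("filter_missingness",
                 filter_missingness(tab, th$max_missing))
    if (isTRUE(cfg$normalization$upper_quartile))
      tab <- stage("upper_quartile", upper_quartile_normalize(tab))
    outliers <- stage("outliers",
                      detect_outlier_samples(tab, th$outlier_sd))
    if (length(outliers)) tab <- drop_samples(tab, outliers)

    lineage <- NULL
    if (length(contrast) == 3) {
      lineage <- stage("lineage", lineage_specific(
        tab, contrast[1], contrast[2], contrast[3], alpha = th$alpha,
        test = th$test))
      write_tsv(lineage, file.path(out_dir,
                                   sprintf("lineage_%s.tsv", stratum)))
      # pool the outgroups for the two-group statistics
      pooled <- tab$samples$group
      pooled[pooled %in% contrast[2:3]] <- "outgroup"
      tab$samples$group <- pooled
      ga <- contrast[1]; gb <- "outgroup"
    } else {
      ga <- contrast[1]; gb <- contrast[2]
    }

    diffs <- stage("diff_test", suppressMessages(diff_test(
      tab, ga, gb, test = th$test, alpha = th$alpha, adjust = th$adjust)))
    write_tsv(diffs, file.path(out_dir, sprintf("diff_%s.tsv", stratum)))

    stratum_seed <- (cfg$seed + si) %% .Machine$integer.max
    perm <- stage("permutation", suppressWarnings(permutation_count_test(
      tab, ga, gb, alpha_inner = th$alpha_inner, B = th$B,
      seed = stratum_seed)))
    write_json_file(perm[c("observed_count", "p_value", "alpha_inner", "B",
                           "seed", "exhaustive", "null_counts")],
                    file.path(out_dir, sprintf("permutation_%s.json", stratum)))

    pw <- NULL; pb <- NULL
    if (!is.null(map)) {
      pw <- stage("pathway", pathway_cumulative_p(
        diffs, map, direction = th$pathway_direction,
        cutoff = th$pathway_cutoff))
      write_tsv(pw, file.path(out_dir, sprintf("pathways_%s.tsv", stratum)))
      n_flagged <- sum(diffs$metabolite_id %in% map$purine_flag)
      if (n_flagged >= 3) {
        pb <- stage("pb_vs_rest", pb_vs_rest(diffs, map))
        write_json_file(pb, file.path(out_dir,
                                      sprintf("pb_vs_rest_%s.json", stratum)))
      }
    }
    results[[stratum]] <- list(diff = diffs, permutation = perm,
                               pathways = pw, pb_vs_rest = pb,
                               lineage = lineage, outliers = outliers)
    summary_lines <- c(summary_lines, sprintf(
      "%s: %d metabolites tested, %d outliers removed, %d significant (perm p = %.4g)%s",
      stratum, nrow(diffs), length(outliers), perm$observed_count,
      perm$p_value,
      if (!is.null(pb)) sprintf(", purine-vs-rest p = %.4g", pb$p) else ""))
  }

  manifest <- list(
    package = "purinedelta",
    version = as.character(utils::packageVersion("purinedelta")),
    seed = cfg$seed, contrast = as.list(contrast),
    stratify_by = cfg$stratify_by, thresholds = th,
    normalization = cfg$normalization, strata = names(strata))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(c(results, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_config_defaults <- function(config) {
  th <- config$thresholds %||% list()
  config$thresholds <- list(
    alpha = th$alpha %||% 0.05,
    alpha_inner = th$alpha_inner %||% 0.05,
    B = th$B %||% 1000,
    pathway_cutoff = th$pathway_cutoff %||% 0.01,
    max_missing = th$max_missing %||% 0.5,
    outlier_sd = th$outlier_sd %||% 3,
    test = th$test %||% "t",
    adjust = th$adjust %||% "none",
    pathway_direction = th$pathway_direction %||% "down")
  config$input <- config$input %||% list()
  config$input$scale <- config$input$scale %||% "log10"
  if (is.null(config$seed)) stop("config needs a `seed`")
  config$seed <- as.integer(config$seed)
  config
}

# internal: deterministic JSON writer
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
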