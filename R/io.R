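#' Read an intensity table and its sample metadata from TSV
#'
#' The intensity file has metabolites in rows and samples in columns, a first
#' column `metabolite_id`, and an empty cell or `NA` for a missing value.
#' The metadata file has one row per sample with at least `sample_id` and
#' `group`; optional `tissue`, `age`, `run_order`, `batch`.
#'
#' @param path Path to the intensity TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @param scale Scale flag of the stored values (`"linear"`, `"log10"`,
#'   `"log2"`).
#' @param sep Field separator; tab by default, use `","` for CSV.
#' @return An [intensity_table()].
#' @export
read_intensity_table <- function(path, meta_path, scale = "linear", sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           na.strings = c("NA", ""), stringsAsFactors = FALSE,
                           comment.char = "")
  if (names(raw)[1] != "metabolite_id")
    stop("first column of the intensity file must be `metabolite_id`")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- raw$metabolite_id
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            na.strings = c("NA", ""), stringsAsFactors = FALSE)
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata is missing entries for some samples in the intensity file")
  intensity_table(vals, meta, scale)
}

#' Write an intensity table and its sample metadata to TSV
#'
#' Missing values are written as empty cells. `write_intensity_table()` and
#' [read_intensity_table()] round-trip values, mask and metadata exactly
#' (values are serialized at full double precision).
#'
#' @param x An [intensity_table()].
#' @param path Output path for the intensity TSV.
#' @param meta_path Output path for the metadata TSV.
#' @return Invisibly, `x`.
#' @export
write_intensity_table <- function(x, path, meta_path) {
  df <- data.frame(metabolite_id = rownames(x$values),
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(x$samples, meta_path)
  invisible(x)
}

# internal: deterministic TSV writer (full precision, no quoting surprises)
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- ""
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Metabolite-to-pathway annotation map
#'
#' Holds pathway membership for annotated metabolites plus the restrictive
#' purine-biosynthesis metabolite set used by [pb_vs_rest()]. A metabolite
#' may belong to several pathways. The purine flag is data, not code: it is
#' supplied in the map file, so alternative curated definitions of the
#' pathway can be swapped in without touching the package.
#'
#' @param membership `data.frame` with columns `metabolite_id`, `pathway_id`
#'   and optionally `pathway_name`.
#' @param purine_flag Character vector of metabolite ids constituting the
#'   purine-biosynthesis set; must be a subset of the metabolites in
#'   `membership`.
#' @return An object of class `pathway_map`.
#' @export
pathway_map <- function(membership, purine_flag = character()) {
  need <- c("metabolite_id", "pathway_id")
  if (!is.data.frame(membership) || !all(need %in% names(membership)))
    stop("`membership` needs columns metabolite_id and pathway_id")
  membership$metabolite_id <- as.character(membership$metabolite_id)
  membership$pathway_id <- as.character(membership$pathway_id)
  if (!"pathway_name" %in% names(membership))
    membership$pathway_name <- membership$pathway_id
  purine_flag <- as.character(purine_flag)
  if (!all(purine_flag %in% membership$metabolite_id))
    stop("purine_flag must be a subset of the annotated metabolites")
  pn <- membership$pathway_name[!duplicated(membership$pathway_id)]
  names(pn) <- membership$pathway_id[!duplicated(membership$pathway_id)]
  structure(list(membership = membership[, c("metabolite_id", "pathway_id",
                                             "pathway_name")],
                 pathway_names = pn, purine_flag = purine_flag),
            class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat(sprintf("pathway_map: %d metabolites, %d pathways, %d purine-flagged\n",
              length(unique(x$membership$metabolite_id)),
              length(x$pathway_names), length(x$purine_flag)))
  invisible(x)
}

#' Read or write a pathway map TSV
#'
#' File columns: `metabolite_id`, `pathway_id`, `pathway_name`,
#' `purine_flag` (0/1; 1 marks membership of the restrictive
#' purine-biosynthesis set).
#'
#' @param path Path to the TSV.
#' @return `read_pathway_map()` returns a [pathway_map()].
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  flag <- if ("purine_flag" %in% names(df))
    unique(df$metabolite_id[df$purine_flag == 1]) else character()
  pathway_map(df, flag)
}

#' @rdname read_pathway_map
#' @param map A [pathway_map()] to serialize.
#' @export
write_pathway_map <- function(map, path) {
  df <- map$membership
  df$purine_flag <- as.integer(df$metabolite_id %in% map$purine_flag)
  write_tsv(df, path)
  invisible(map)
}

#' Bundled synthetic pathway map
#'
#' Loads the KEGG-style metabolite-to-pathway fixture shipped with the
#' package (`inst/extdata/pathway_map_synthetic.tsv`). The purine
#' metabolite names are the field's standard vocabulary; the membership
#' table itself is a synthetic curation for examples and tests, not a
#' database export.
#'
#' @return A [pathway_map()].
#' @export
example_pathway_map <- function() {
  read_pathway_map(system.file("extdata", "pathway_map_synthetic.tsv",
                               package = "purinedelta", mustWork = TRUE))
}
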