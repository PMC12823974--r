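# Tabular IO: count tables, nutrient tables, taxonomy maps, network and
# report export. All files are tab-delimited UTF-8 with one header row;
# feature tables are written features-in-rows (the common amplicon
# convention) but held internally as sites x features matrices.

#' Construct a feature count table
#'
#' @param counts numeric matrix, sites in rows, features in columns, with
#'   row and column names; no negative values, no duplicated identifiers.
#' @param marker_group one of "16S", "ITS", "phoD".
#' @param raw logical; `TRUE` for integer read counts, `FALSE` for
#'   rarefaction-averaged (real-valued) tables.
#' @return object of class `count_table`: a list with elements `counts`,
#'   `marker_group`, `raw`.
#' @export
count_table <- function(counts, marker_group, raw = TRUE) {
  marker_group <- match.arg(marker_group, MARKER_GROUPS)
  counts <- as.matrix(counts)
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("count table needs feature identifiers (column names)")
  if (is.null(rownames(counts)))
    stop("count table needs site identifiers (row names)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate site identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) && length(counts) > 0)
    stop("count table cells must be numeric")
  if (length(counts) > 0 && anyNA(counts))
    stop("count table contains missing values")
  if (length(counts) > 0 && any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance for feature '%s' at site '%s'",
                 colnames(counts)[bad[2]], rownames(counts)[bad[1]]))
  }
  if (raw && length(counts) > 0 && any(counts != floor(counts))) {
    bad <- which(counts != floor(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("raw count table must be integer-valued; feature '%s', site '%s'",
                 colnames(counts)[bad[2]], rownames(counts)[bad[1]]))
  }
  structure(list(counts = counts, marker_group = marker_group, raw = raw),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s: %d sites x %d features (%s)\n",
              x$marker_group, nrow(x$counts), ncol(x$counts),
              if (x$raw) "raw counts" else "rarefied means"))
  invisible(x)
}

#' Number of sites / features of a count table
#' @param x a `count_table`
#' @return integer
#' @export
n_sites <- function(x) nrow(x$counts)

#' @rdname n_sites
#' @export
n_features <- function(x) ncol(x$counts)

#' Write a count table (features in rows)
#'
#' @param x a `count_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(feature_id = colnames(x$counts),
                   t(x$counts), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table (features in rows, sites in columns)
#'
#' The first column must be `feature_id`; the remaining columns are site
#' identifiers. Malformed cells are rejected, naming the offending feature
#' and site, rather than coerced.
#'
#' @param path input file
#' @param marker_group one of "16S", "ITS", "phoD"
#' @param raw expect integer counts (default `TRUE`)
#' @return a `count_table`; column (site) order is preserved
#' @export
read_count_table <- function(path, marker_group, raw = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 1 || names(df)[1] != "feature_id")
    stop("first column must be 'feature_id': ", path)
  features <- df[[1]]
  sites <- names(df)[-1]
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(features),
              dimnames = list(sites, features))
  for (j in seq_along(sites)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric cell for feature '%s' at site '%s'",
                   features[bad[1]], sites[j]))
    m[j, ] <- v
  }
  count_table(m, marker_group, raw = raw)
}

#' Construct a soil nutrient table
#'
#' Validates that all seven nutrient-cycling variables are present and
#' derives the two stoichiometric ratios `tn_tp` (TN/TP) and `nmin_ap`
#' (net N mineralization / available P).
#'
#' @param df data.frame with columns `site_id`, `TN`, `NAG`, `net_Nmin`,
#'   `N_inorg`, `TP`, `AP`, `AKP`
#' @return data.frame of class `nutrient_table` with derived ratio columns
#' @export
nutrient_table <- function(df) {
  vars <- unlist(np_variable_families(), use.names = FALSE)
  if (!"site_id" %in% names(df)) stop("missing variable: site_id")
  for (v in vars) if (!v %in% names(df)) stop("missing variable: ", v)
  if (anyDuplicated(df$site_id))
    stop("duplicate site identifiers in nutrient table")
  for (v in vars) {
    if (!is.numeric(df[[v]])) stop("non-numeric nutrient column: ", v)
    if (anyNA(df[[v]])) stop("missing values in nutrient column: ", v)
  }
  bad <- df$site_id[df$TP <= 0 | df$AP <= 0]
  if (length(bad))
    stop("TP and AP must be positive (ratios undefined) at site(s): ",
         paste(bad, collapse = ", "))
  df <- df[, c("site_id", vars)]
  df$tn_tp <- df$TN / df$TP
  df$nmin_ap <- df$net_Nmin / df$AP
  class(df) <- c("nutrient_table", "data.frame")
  df
}

#' Read / write a nutrient table
#' @param path tab-delimited file with columns `site_id` plus the seven
#'   nutrient variables
#' @return a `nutrient_table`
#' @export
read_nutrients <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nutrient_table(read.delim(path, check.names = FALSE))
}

#' @rdname read_nutrients
#' @param n a `nutrient_table`
#' @export
write_nutrients <- function(n, path) {
  vars <- unlist(np_variable_families(), use.names = FALSE)
  write.table(n[, c("site_id", vars)], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")

#' Read / write a taxonomy map
#'
#' Maps each feature to the seven ranks kingdom through species.
#' Unresolved ranks use the placeholder convention
#' `unclassified_<nearest named rank>`.
#'
#' @param path tab-delimited file with columns `feature_id`, `kingdom`,
#'   `phylum`, `class`, `order`, `family`, `genus`, `species`
#' @return data.frame of class `taxonomy_map`
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  taxonomy_map(read.delim(path, check.names = FALSE,
                          colClasses = "character"))
}

#' @rdname read_taxonomy
#' @param df data.frame with the taxonomy columns
#' @export
taxonomy_map <- function(df) {
  need <- c("feature_id", TAX_RANKS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing taxonomy column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature identifiers in taxonomy")
  df <- df[, need]
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' @rdname read_taxonomy
#' @param tax a `taxonomy_map`
#' @export
write_taxonomy <- function(tax, path) {
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a signed network
#'
#' `edge_tsv` writes one row per edge with columns `taxon_a`, `taxon_b`,
#' `r`, `sign`, `p_adj`; `graphml` writes the full graph (node group tags
#' and edge attributes included) for generic graph software.
#'
#' @param net a `signed_network` (see [build_network()])
#' @param path output file
#' @param format "graphml" or "edge_tsv"
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  stopifnot(inherits(net, "signed_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    write.table(network_edges(net), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Edge and node tables of a signed network
#' @param net a `signed_network`
#' @return data.frame (one row per edge / per node)
#' @export
network_edges <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0)
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      r = numeric(), sign = character(), p_adj = numeric()))
  ends <- igraph::as_edgelist(g)
  data.frame(taxon_a = ends[, 1], taxon_b = ends[, 2],
             r = igraph::E(g)$r, sign = igraph::E(g)$sign,
             p_adj = igraph::E(g)$p_adj)
}

#' @rdname network_edges
#' @export
network_nodes <- function(net) {
  g <- net$graph
  data.frame(taxon = igraph::V(g)$name, group = igraph::V(g)$group)
}

#' Write a pipeline report
#'
#' Serializes the report both machine-readably (`report.json`) and as
#' tab-delimited tables (site labels, taxon labels, regression, enrichment
#' and node-centrality tables) under `dir`.
#'
#' @param report a report list as returned by [run_pipeline()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "string")
  write.table(report$site_labels, file.path(dir, "site_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (rank in names(report$ranks)) {
    rk <- report$ranks[[rank]]
    for (nm in c("taxon_labels", "regression", "enrichment")) {
      if (!is.null(rk[[nm]]) && nrow(rk[[nm]]))
        write.table(rk[[nm]], file.path(dir, paste0(rank, "_", nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (which in c("coupled", "decoupled")) {
      cent <- rk$networks[[which]]$centrality
      if (!is.null(cent) && nrow(cent))
        write.table(cent,
                    file.path(dir, paste0(rank, "_", which, "_nodes.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
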