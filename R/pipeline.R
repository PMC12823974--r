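# End-to-end orchestration: preprocess each marker group, classify sites
# and taxa at phylum and genus ranks, run the net-Nmin/AP regression and
# coupled-site enrichment, and build the paired coupled/decoupled signed
# networks with metrics and keystones. Deterministic given (config, seed).

#' Pipeline configuration
#'
#' Either point `paths` at an on-disk dataset (three count tables,
#' taxonomy, nutrients, as written by [write_dataset()]) or supply a
#' [generator_config()] in `generator` to run on synthetic data. All of
#' the method's thresholds are surfaced here with their standard
#' defaults: 0.001% global floor, rarefaction to 90% of the minimum depth
#' averaged over 100 draws, 10% prevalence (16S/phoD), 10 reads (ITS),
#' 0.1% major-taxon cutoff, site thresholds TN/TP > 3 and net-Nmin/AP >
#' 0.16, alpha 0.05, |r| > 0.6 network edges, keystone score >= 1.
#'
#' @param paths named list with `counts_16S`, `counts_ITS`, `counts_phoD`,
#'   `taxonomy`, `nutrients` (analysis mode), or `NULL`
#' @param generator a [generator_config()] (generator mode), or `NULL`
#' @param ranks taxonomic ranks to analyse (default both)
#' @param global_floor,rarefy_fraction,rarefy_reps,prevalence_min,
#'   min_total_count,major_abund preprocessing parameters
#' @param tn_tp_min,nmin_ap_min site classification thresholds
#' @param alpha significance level used throughout
#' @param bonferroni_family "global" or "per_taxon" (see
#'   [correlate_taxa()])
#' @param r_min,occupancy_min,keystone_threshold network parameters
#' @param out_dir directory for intermediates and the report, or `NULL`
#' @param seed integer seed for rarefaction (and generation in generator
#'   mode)
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(paths = NULL, generator = NULL,
                            ranks = c("phylum", "genus"),
                            global_floor = 1e-5, rarefy_fraction = 0.9,
                            rarefy_reps = 100, prevalence_min = 0.10,
                            min_total_count = 10, major_abund = 0.001,
                            tn_tp_min = 3, nmin_ap_min = 0.16,
                            alpha = 0.05, bonferroni_family = "global",
                            r_min = 0.6, occupancy_min = 0.5,
                            keystone_threshold = 1,
                            out_dir = NULL, seed = 1) {
  if (is.null(paths) == is.null(generator))
    stop("configuration error: supply exactly one of paths or generator")
  if (!is.null(paths)) {
    need <- c("counts_16S", "counts_ITS", "counts_phoD", "taxonomy",
              "nutrients")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("configuration error: missing path(s): ",
                           paste(miss, collapse = ", "))
    absent <- !vapply(paths[need], file.exists, logical(1))
    if (any(absent)) stop("configuration error: file(s) not found: ",
                          paste(unlist(paths[need])[absent], collapse = ", "))
  }
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_config"))
  ranks <- match.arg(ranks, c("phylum", "genus"), several.ok = TRUE)
  for (v in c(global_floor, rarefy_fraction, prevalence_min, major_abund,
              alpha, r_min, occupancy_min))
    if (v <= 0 || v > 1) stop("configuration error: proportions must be in (0,1]")
  if (tn_tp_min <= 0 || nmin_ap_min <= 0)
    stop("configuration error: site thresholds must be positive")
  structure(list(paths = paths, generator = generator, ranks = ranks,
                 global_floor = global_floor,
                 rarefy_fraction = rarefy_fraction,
                 rarefy_reps = rarefy_reps, prevalence_min = prevalence_min,
                 min_total_count = min_total_count,
                 major_abund = major_abund, tn_tp_min = tn_tp_min,
                 nmin_ap_min = nmin_ap_min, alpha = alpha,
                 bonferroni_family = bonferroni_family, r_min = r_min,
                 occupancy_min = occupancy_min,
                 keystone_threshold = keystone_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full N-P coupling analysis
#'
#' Stages, per rank: preprocessing of each marker group (fixed order:
#' global floor, averaged rarefaction, prevalence/count retention,
#' aggregation, major-taxon selection), site classification, taxon
#' correlation screening and labelling, net-Nmin/AP regression and
#' coupled-site enrichment for the coupled taxa, then coupled and
#' decoupled signed networks with topology metrics and keystone scoring.
#' When `config$out_dir` is set, intermediates, network exports and the
#' report are written there.
#'
#' @param config a [pipeline_config()]
#' @return report list: `site_labels`, per-rank results under `ranks`
#'   (taxon labels, label counts, regression, enrichment, networks with
#'   metrics/centrality), and `provenance` (seed, package version, config)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$generator)) {
    ds <- generate_dataset(config$generator)
    counts <- ds$counts; tax <- ds$taxonomy; nutrients <- ds$nutrients
    if (!is.null(config$out_dir))
      write_dataset(ds, file.path(config$out_dir, "synthetic_data"))
  } else {
    counts <- list(
      "16S" = read_count_table(config$paths$counts_16S, "16S"),
      "ITS" = read_count_table(config$paths$counts_ITS, "ITS"),
      "phoD" = read_count_table(config$paths$counts_phoD, "phoD"))
    tax <- read_taxonomy(config$paths$taxonomy)
    nutrients <- read_nutrients(config$paths$nutrients)
  }
  for (grp in names(counts)) {
    miss <- setdiff(rownames(counts[[grp]]$counts), nutrients$site_id)
    if (length(miss))
      stop("stage classify_sites: nutrient table missing site(s): ",
           paste(miss, collapse = ", "))
  }

  site_labels <- classify_sites(nutrients, config$tn_tp_min,
                                config$nmin_ap_min)
  report <- list(
    site_labels = site_labels,
    n_coupled_sites = sum(site_labels$label == "coupled"),
    ranks = list(),
    provenance = list(seed = config$seed,
                      package_version = as.character(packageVersion("npnet")),
                      config = config[setdiff(names(config),
                                              c("paths", "generator",
                                                "out_dir"))]))

  for (rank in config$ranks) {
    agg <- list()
    for (k in seq_along(MARKER_GROUPS)) {
      grp <- MARKER_GROUPS[k]
      agg[[grp]] <- preprocess_group(
        counts[[grp]], tax, rank,
        global_floor = config$global_floor,
        rarefy_fraction = config$rarefy_fraction,
        rarefy_reps = config$rarefy_reps,
        prevalence_min = config$prevalence_min,
        min_total_count = config$min_total_count,
        major_abund = config$major_abund,
        seed = sub_seed(config$seed, 100 + k))
    }
    pooled <- combine_groups(agg)
    records <- correlate_taxa(pooled, nutrients, alpha = config$alpha,
                              family = config$bonferroni_family)
    labels <- classify_taxa(records)
    label_counts <- table(factor(labels$label, levels = COUPLING_LABELS),
                          pooled$taxa$marker_group[match(labels$taxon,
                                                         pooled$taxa$taxon)])
    regression <- regress_vs_nmin_ap(pooled, nutrients, labels,
                                     alpha = config$alpha)
    enrichment <- if (report$n_coupled_sites > 0 &&
                      report$n_coupled_sites < nrow(site_labels))
      test_enrichment(pooled, site_labels, labels, alpha = config$alpha)
    else NULL

    networks <- list()
    for (which in c("coupled", "decoupled")) {
      cand <- suppressWarnings(
        select_candidates(pooled, labels, which,
                          major_abund = config$major_abund,
                          occupancy_min = config$occupancy_min))
      if (length(cand) < 2) {
        networks[[which]] <- list(candidates = cand, network = NULL,
                                  metrics = NULL, centrality = NULL)
        next
      }
      net <- build_network(pooled, cand, r_min = config$r_min,
                           alpha = config$alpha)
      cent <- if (length(cand) >= 3)
        centrality_keystones(net, config$keystone_threshold) else NULL
      networks[[which]] <- list(candidates = cand, network = net,
                                metrics = network_metrics(net),
                                centrality = cent)
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        base <- file.path(config$out_dir, paste0(rank, "_", which))
        write_network(net, paste0(base, "_network.graphml"), "graphml")
        write_network(net, paste0(base, "_edges.tsv"), "edge_tsv")
      }
    }

    report$ranks[[rank]] <- list(
      taxon_labels = labels[, c("taxon", "label", "n_sig_N", "n_sig_P")],
      label_counts = as.data.frame.matrix(label_counts),
      n_major_taxa = nrow(labels),
      regression = regression, enrichment = enrichment,
      networks = lapply(networks, function(nw) {
        nw$network <- NULL  # graphs are exported separately, not serialized
        nw
      }))
  }
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}
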