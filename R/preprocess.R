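# Feature-table preprocessing: global abundance floor, averaged
# rarefaction, marker-group-specific prevalence/count retention,
# taxonomic aggregation to relative abundance, and major-taxon selection.
# The pipeline applies them in exactly that order.

#' Remove globally rare features
#'
#' Drops features whose summed count is below `floor` as a fraction of the
#' grand total (default 0.001%). The inequality is strict: a feature
#' sitting exactly at the floor is retained.
#'
#' @param t a raw `count_table`
#' @param floor proportion of the grand total (default 1e-5)
#' @return filtered `count_table`
#' @export
filter_global_floor <- function(t, floor = 1e-5) {
  stopifnot(inherits(t, "count_table"))
  grand <- sum(t$counts)
  if (grand == 0) stop("grand total is zero; cannot apply abundance floor")
  keep <- colSums(t$counts) / grand >= floor
  count_table(t$counts[, keep, drop = FALSE], t$marker_group, raw = t$raw)
}

#' Averaged rarefaction of a count table
#'
#' Evenly resamples each site, without replacement, to a common depth
#' `D = floor(fraction x minimum site depth)` and averages `reps`
#' independent draws. Each draw is multivariate hypergeometric (sequential
#' conditional [stats::rhyper()] sampling, vectorised across replicates),
#' so every replicate's site total is exactly `D`, and therefore so is
#' every averaged row sum.
#'
#' @param t a raw `count_table`; every site depth must be >= 1
#' @param fraction proportion of the minimum site depth (default 0.9)
#' @param reps number of resampling replicates (default 100)
#' @param seed integer seed driving all draws
#' @return a `count_table` with `raw = FALSE` holding per-cell means
#' @export
rarefy_average <- function(t, fraction = 0.9, reps = 100, seed = 1) {
  stopifnot(inherits(t, "count_table"), reps >= 1)
  depths <- rowSums(t$counts)
  if (any(depths < 1)) stop("every site needs depth >= 1 for rarefaction")
  D <- floor(fraction * min(depths))
  if (D == 0) stop("rarefaction depth is zero")
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- matrix(0, nrow(t$counts), ncol(t$counts),
                dimnames = dimnames(t$counts))
  for (i in seq_len(nrow(t$counts))) {
    x <- t$counts[i, ]
    n_rem <- sum(x)                 # balls left in the urn (scalar)
    d_rem <- rep.int(D, reps)       # draws left, per replicate
    acc <- numeric(length(x))
    for (j in seq_along(x)) {
      if (x[j] == 0) { next }
      if (n_rem == x[j]) { take <- d_rem }
      else take <- rhyper(reps, m = x[j], n = n_rem - x[j], k = d_rem)
      acc[j] <- sum(take)
      d_rem <- d_rem - take
      n_rem <- n_rem - x[j]
    }
    out[i, ] <- acc / reps
  }
  count_table(out, t$marker_group, raw = FALSE)
}

#' Marker-group-specific feature retention
#'
#' 16S and phoD features must be present (abundance > 0) in at least
#' `ceil(prevalence_min x n_sites)` sites; ITS features must carry at
#' least `min_total_count` reads summed over all sites.
#'
#' @param t a `count_table` (raw or rarefied)
#' @param prevalence_min minimum fraction of sites (default 0.10)
#' @param min_total_count minimum summed count for ITS (default 10)
#' @return filtered `count_table`
#' @export
filter_prevalence <- function(t, prevalence_min = 0.10, min_total_count = 10) {
  stopifnot(inherits(t, "count_table"))
  keep <- switch(t$marker_group,
    "16S" = , "phoD" =
      colSums(t$counts > 0) >= ceiling(prevalence_min * nrow(t$counts)),
    "ITS" = colSums(t$counts) >= min_total_count,
    stop("unknown marker group: ", t$marker_group))
  count_table(t$counts[, keep, drop = FALSE], t$marker_group, raw = t$raw)
}

#' Aggregate features to a taxonomic rank as relative abundance
#'
#' Sums member features per site at the requested rank, then converts to
#' relative abundance within the marker group (each site row sums to 1).
#' Unclassified placeholders aggregate under their placeholder name.
#'
#' @param t a `count_table`
#' @param tax a `taxonomy_map` resolving every feature of `t`
#' @param rank "phylum" or "genus"
#' @return object of class `aggregated_table`: list with `abund` (sites x
#'   taxa relative abundance matrix), `rank`, and `taxa` (data.frame with
#'   `taxon`, `marker_group`, `mean_ra`, `occurrence`)
#' @export
aggregate_taxa <- function(t, tax, rank = c("phylum", "genus")) {
  stopifnot(inherits(t, "count_table"), inherits(tax, "taxonomy_map"))
  rank <- match.arg(rank)
  feats <- colnames(t$counts)
  idx <- match(feats, tax$feature_id)
  if (anyNA(idx))
    stop("feature(s) absent from taxonomy: ",
         paste(feats[is.na(idx)], collapse = ", "))
  labels <- tax[[rank]][idx]
  agg <- t(rowsum(t(t$counts), group = labels, reorder = TRUE))
  totals <- rowSums(agg)
  if (any(totals == 0)) stop("site with zero total abundance: ",
                             rownames(agg)[totals == 0][1])
  ra <- agg / totals
  structure(list(
    abund = ra, rank = rank,
    taxa = data.frame(taxon = colnames(ra),
                      marker_group = t$marker_group,
                      mean_ra = colMeans(ra),
                      occurrence = colSums(ra > 0),
                      row.names = NULL)),
    class = "aggregated_table")
}

#' @export
print.aggregated_table <- function(x, ...) {
  cat(sprintf("<aggregated_table> rank %s: %d sites x %d taxa (%s)\n",
              x$rank, nrow(x$abund), ncol(x$abund),
              paste(unique(x$taxa$marker_group), collapse = "+")))
  invisible(x)
}

#' Keep major taxa
#'
#' Retains taxa whose mean relative abundance across sites exceeds
#' `major_abund` (strict; default 0.1%). Relative abundances are not
#' re-normalised, so they remain interpretable within the marker group.
#'
#' @param a an `aggregated_table`
#' @param major_abund mean relative-abundance cutoff (default 0.001)
#' @return filtered `aggregated_table`
#' @export
select_major <- function(a, major_abund = 0.001) {
  stopifnot(inherits(a, "aggregated_table"))
  keep <- a$taxa$mean_ra > major_abund
  structure(list(abund = a$abund[, a$taxa$taxon[keep], drop = FALSE],
                 rank = a$rank, taxa = a$taxa[keep, , drop = FALSE]),
            class = "aggregated_table")
}

#' Pool aggregated tables from several marker groups
#'
#' Joins by site (all tables must cover the same sites) and concatenates
#' taxa. Relative abundances stay normalised within each marker group,
#' mirroring the fact that the groups are separate sequencing universes.
#'
#' @param tables list of `aggregated_table`s at one rank
#' @return pooled `aggregated_table`
#' @export
combine_groups <- function(tables) {
  stopifnot(length(tables) >= 1)
  rank <- tables[[1]]$rank
  sites <- rownames(tables[[1]]$abund)
  for (tb in tables) {
    stopifnot(inherits(tb, "aggregated_table"))
    if (!identical(tb$rank, rank)) stop("tables aggregated at different ranks")
    if (!setequal(rownames(tb$abund), sites))
      stop("tables cover different site sets")
  }
  mats <- lapply(tables, function(tb) tb$abund[sites, , drop = FALSE])
  abund <- do.call(cbind, mats)
  taxa <- do.call(rbind, lapply(tables, `[[`, "taxa"))
  if (anyDuplicated(taxa$taxon))
    stop("taxon name collision across marker groups: ",
         paste(unique(taxa$taxon[duplicated(taxa$taxon)]), collapse = ", "))
  structure(list(abund = abund, rank = rank, taxa = taxa),
            class = "aggregated_table")
}

#' Run the fixed preprocessing chain for one marker group
#'
#' Order is fixed: global floor, averaged rarefaction, prevalence/count
#' retention, aggregation, major-taxon selection.
#'
#' @param t raw `count_table`
#' @param tax `taxonomy_map`
#' @param rank "phylum" or "genus"
#' @param global_floor,rarefy_fraction,rarefy_reps,prevalence_min,
#'   min_total_count,major_abund see the individual steps
#' @param seed seed for the rarefaction draws
#' @return an `aggregated_table` of major taxa
#' @export
preprocess_group <- function(t, tax, rank,
                             global_floor = 1e-5, rarefy_fraction = 0.9,
                             rarefy_reps = 100, prevalence_min = 0.10,
                             min_total_count = 10, major_abund = 0.001,
                             seed = 1) {
  t <- filter_global_floor(t, global_floor)
  t <- rarefy_average(t, rarefy_fraction, rarefy_reps, seed)
  t <- filter_prevalence(t, prevalence_min, min_total_count)
  a <- aggregate_taxa(t, tax, rank)
  select_major(a, major_abund)
}
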