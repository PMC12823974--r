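# Signed co-occurrence networks over coupled or decoupled taxa: candidate
# selection, FDR-filtered Pearson edge construction, topology metrics
# (connectance, positive:negative edge ratio, edge-type composition) and
# composite-score keystone detection.

#' Select network candidate taxa
#'
#' Candidates for the requested network are taxa with the matching
#' coupling label class (`coupled_positive`/`coupled_negative` for the
#' coupled network; `decoupled_N`/`decoupled_P` for the decoupled one),
#' mean relative abundance strictly above `major_abund`, and occurrence in
#' strictly more than `occupancy_min` of the sites. `inconsistent` and
#' `none` taxa never enter either network.
#'
#' @param a a pooled `aggregated_table` (all marker groups, one rank)
#' @param labels output of [classify_taxa()] on the same table
#' @param which "coupled" or "decoupled"
#' @param major_abund mean relative-abundance cutoff (default 0.001)
#' @param occupancy_min occupancy fraction cutoff, strict (default 0.5)
#' @return character vector of candidate taxon names
#' @export
select_candidates <- function(a, labels, which = c("coupled", "decoupled"),
                              major_abund = 0.001, occupancy_min = 0.5) {
  stopifnot(inherits(a, "aggregated_table"),
            inherits(labels, "coupling_labels"))
  which <- match.arg(which)
  wanted <- if (which == "coupled")
    c("coupled_positive", "coupled_negative")
  else c("decoupled_N", "decoupled_P")
  lab <- labels$label[match(a$taxa$taxon, labels$taxon)]
  n_sites <- nrow(a$abund)
  keep <- !is.na(lab) & lab %in% wanted &
    a$taxa$mean_ra > major_abund &
    a$taxa$occurrence / n_sites > occupancy_min
  cand <- a$taxa$taxon[keep]
  if (length(cand) == 0)
    warning("empty candidate set for the ", which, " network")
  cand
}

#' Build a signed co-occurrence network
#'
#' Computes all pairwise Pearson correlations among candidate taxa across
#' all sites, Benjamini-Hochberg adjusts the two-sided p-values over the
#' full set of computable pairs, and keeps edges with |r| > `r_min` and
#' adjusted p < `alpha`. Edge sign is the sign of r. All candidates stay
#' in the node set, including isolated ones; pairs involving a
#' constant-abundance taxon are non-computable and excluded from the BH
#' family.
#'
#' @param a an `aggregated_table` holding the candidates' abundances
#' @param candidates character vector of taxon names (>= 2); needs >= 4
#'   sites
#' @param r_min correlation magnitude threshold, strict (default 0.6)
#' @param alpha significance level on BH-adjusted p (default 0.05)
#' @return object of class `signed_network`: list with `graph` (an igraph
#'   with vertex attrs `name`, `group` and edge attrs `r`, `sign`,
#'   `p_adj`), `params`, and `tests` (the full pair-test table)
#' @export
build_network <- function(a, candidates, r_min = 0.6, alpha = 0.05) {
  stopifnot(inherits(a, "aggregated_table"))
  if (length(candidates) < 2) stop("need at least 2 candidate taxa")
  if (nrow(a$abund) < 4) stop("need at least 4 sites")
  miss <- setdiff(candidates, colnames(a$abund))
  if (length(miss)) stop("candidate(s) absent from table: ",
                         paste(miss, collapse = ", "))
  x <- a$abund[, candidates, drop = FALSE]
  pairs <- t(combn(length(candidates), 2))
  tests <- data.frame(
    taxon_a = candidates[pairs[, 1]], taxon_b = candidates[pairs[, 2]],
    r = NA_real_, p_raw = NA_real_, computable = TRUE)
  for (k in seq_len(nrow(pairs))) {
    xi <- x[, pairs[k, 1]]; xj <- x[, pairs[k, 2]]
    if (sd(xi) == 0 || sd(xj) == 0) { tests$computable[k] <- FALSE; next }
    ct <- suppressWarnings(
      cor.test(xi, xj, method = "pearson", alternative = "two.sided"))
    tests$r[k] <- unname(ct$estimate)
    tests$p_raw[k] <- ct$p.value
  }
  tests$p_adj <- NA_real_
  tests$p_adj[tests$computable] <-
    p.adjust(tests$p_raw[tests$computable], method = "BH")
  keep <- tests$computable & abs(tests$r) > r_min & tests$p_adj < alpha
  edges <- tests[keep, c("taxon_a", "taxon_b", "r", "p_adj")]
  edges$sign <- ifelse(edges$r > 0, "+", "-")

  group <- a$taxa$marker_group[match(candidates, a$taxa$taxon)]
  vertices <- data.frame(
    name = candidates,
    group = vapply(group, marker_node_group, character(1)))
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_a", "taxon_b", "r", "sign", "p_adj")],
    directed = FALSE, vertices = vertices)
  structure(list(graph = g,
                 params = list(r_min = r_min, alpha = alpha),
                 tests = tests),
            class = "signed_network")
}

#' Assemble a signed network from explicit node and edge tables
#'
#' Constructor used for desk calculations and tests (e.g. reproducing
#' topology metrics from published node/edge counts without abundance
#' data).
#'
#' @param nodes data.frame with columns `name` and `group` (one of
#'   "bacteria", "fungi", "phoD")
#' @param edges data.frame with columns `taxon_a`, `taxon_b`, `r`,
#'   `p_adj` (optional columns default to r = sign and p_adj = 0)
#' @param params list of construction parameters (optional)
#' @return a `signed_network`
#' @export
signed_network <- function(nodes, edges = NULL, params = list()) {
  if (is.null(edges) || nrow(edges) == 0)
    edges <- data.frame(taxon_a = character(), taxon_b = character(),
                        r = numeric(), p_adj = numeric())
  if (is.null(edges$p_adj)) edges$p_adj <- rep(0, nrow(edges))
  edges$sign <- ifelse(edges$r > 0, "+", "-")
  if (any(edges$r == 0)) stop("edge with r = 0 has no sign")
  if (is.null(nodes$group)) nodes$group <- "bacteria"
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_a", "taxon_b", "r", "sign", "p_adj")],
    directed = FALSE, vertices = nodes)
  if (any(igraph::which_loop(g))) stop("self-edges are not allowed")
  if (any(igraph::which_multiple(g))) stop("duplicate edges are not allowed")
  structure(list(graph = g, params = params,
                 tests = NULL),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network> %d nodes, %d edges (%d +, %d -)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(igraph::E(x$graph)$sign == "+"),
              sum(igraph::E(x$graph)$sign == "-")))
  invisible(x)
}

#' Topology metrics of a signed network
#'
#' Connectance is realized edges over all possible undirected edges,
#' `n_edges / (n_nodes (n_nodes - 1) / 2)`, reported at full precision
#' together with its 2-decimal display rounding. The positive:negative
#' edge ratio is `Inf` when there are positive but no negative edges and
#' `NA` for an empty edge set. Edge-type composition counts edges by node
#' group pair (B = bacteria, F = fungi, P = phoD).
#'
#' @param net a `signed_network` with >= 2 nodes
#' @return list with `n_nodes`, `n_edges`, `connectance`,
#'   `connectance_display`, `pos_edges`, `neg_edges`, `pos_neg_ratio`,
#'   `edge_types` (named counts B-B, B-F, B-P, F-F, F-P, P-P),
#'   `frac_bacterial_edges`
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  g <- net$graph
  nv <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (nv < 2) stop("need at least 2 nodes for topology metrics")
  pos <- sum(igraph::E(g)$sign == "+")
  neg <- ne - pos
  ratio <- if (ne == 0) NA_real_ else if (neg == 0) Inf else pos / neg

  code <- c(bacteria = "B", fungi = "F", phoD = "P")
  types <- c("B-B" = 0L, "B-F" = 0L, "B-P" = 0L,
             "F-F" = 0L, "F-P" = 0L, "P-P" = 0L)
  frac_b <- NA_real_
  if (ne > 0) {
    ends <- igraph::as_edgelist(g)
    grp <- setNames(igraph::V(g)$group, igraph::V(g)$name)
    a <- code[grp[ends[, 1]]]; b <- code[grp[ends[, 2]]]
    key <- paste(pmin(a, b), pmax(a, b), sep = "-")
    tab <- table(key)
    types[names(tab)] <- as.integer(tab)
    frac_b <- sum(a == "B" | b == "B") / ne
  }
  list(n_nodes = nv, n_edges = ne,
       connectance = ne / (nv * (nv - 1) / 2),
       connectance_display = round(ne / (nv * (nv - 1) / 2), 2),
       pos_edges = pos, neg_edges = neg, pos_neg_ratio = ratio,
       edge_types = types, frac_bacterial_edges = frac_b)
}

#' Node centralities and composite-score keystone taxa
#'
#' Degree, harmonic closeness (normalized by n-1) and betweenness
#' (normalized by (n-1)(n-2)/2) are computed on the unweighted, unsigned
#' skeleton. Each metric is standardized across the network's nodes
#' (sample standard deviation; a zero-variance metric gives all-zero
#' z-scores). The composite keystone score is
#' `z_degree + z_closeness - z_betweenness`; nodes at or above
#' `keystone_threshold` are flagged keystones. Per-node positive and
#' negative edge tallies are reported alongside.
#'
#' @param net a `signed_network` with >= 3 nodes
#' @param keystone_threshold composite-score cutoff (default 1)
#' @return data.frame with `taxon`, `group`, `degree`, `closeness`,
#'   `betweenness`, `z_degree`, `z_closeness`, `z_betweenness`,
#'   `combined_score`, `keystone`, `pos_edges`, `neg_edges`
#' @export
centrality_keystones <- function(net, keystone_threshold = 1) {
  stopifnot(inherits(net, "signed_network"))
  g <- net$graph
  nv <- igraph::vcount(g)
  if (nv < 3) stop("need at least 3 nodes for centrality scoring")
  deg <- igraph::degree(g)
  clo <- igraph::harmonic_centrality(g, normalized = TRUE, weights = NA)
  btw <- igraph::betweenness(g, normalized = TRUE, weights = NA)
  zscore <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  zd <- zscore(deg); zc <- zscore(clo); zb <- zscore(btw)
  combined <- zd + zc - zb

  pos_cnt <- setNames(rep(0L, nv), igraph::V(g)$name)
  neg_cnt <- pos_cnt
  if (igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g)
    s <- igraph::E(g)$sign
    for (side in 1:2) {
      tp <- table(ends[s == "+", side])
      tn <- table(ends[s == "-", side])
      pos_cnt[names(tp)] <- pos_cnt[names(tp)] + as.integer(tp)
      neg_cnt[names(tn)] <- neg_cnt[names(tn)] + as.integer(tn)
    }
  }
  data.frame(taxon = igraph::V(g)$name, group = igraph::V(g)$group,
             degree = as.numeric(deg), closeness = as.numeric(clo),
             betweenness = as.numeric(btw),
             z_degree = as.numeric(zd), z_closeness = as.numeric(zc),
             z_betweenness = as.numeric(zb),
             combined_score = as.numeric(combined),
             keystone = as.numeric(combined) >= keystone_threshold,
             pos_edges = as.integer(pos_cnt), neg_edges = as.integer(neg_cnt),
             row.names = NULL)
}
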