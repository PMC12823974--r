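# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (textbook formulas, double loops, matrix powers) so
# they cannot share a code path with the package implementation.

# textbook Pearson correlation with two-sided t-test p-value
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  r <- num / den
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Bonferroni, longhand
oracle_bonferroni <- function(p) pmin(1, p * length(p))

# Degree, harmonic closeness (normalized by n-1) and betweenness
# (normalized by (n-1)(n-2)/2) from an adjacency matrix, using matrix
# powers: (A^k)[s,t] counts length-k walks, and walks of geodesic length
# are exactly the geodesics, so distances and path counts both come from
# the power sequence rather than from any graph library.
oracle_centrality <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  pow <- vector("list", n - 1)
  M <- diag(n)
  for (k in seq_len(n - 1)) {
    M <- M %*% A
    pow[[k]] <- M
    D[D == Inf & M > 0] <- k
  }
  harm <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sum(1 / d[is.finite(d)])
  }, numeric(1)) / (n - 1)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    d <- D[s, t]
    if (!is.finite(d) || d < 2) next
    sigma <- pow[[d]][s, t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      d1 <- D[s, v]; d2 <- D[v, t]
      if (is.finite(d1) && is.finite(d2) && d1 + d2 == d && d1 > 0 && d2 > 0)
        btw[v] <- btw[v] + pow[[d1]][s, v] * pow[[d2]][v, t] / sigma
    }
  }
  list(degree = rowSums(A), closeness = harm,
       betweenness = btw / ((n - 1) * (n - 2) / 2))
}

# adjacency matrix of the graph encoded by `mask` over the C(n,2) pairs
mask_to_adjacency <- function(mask, n) {
  A <- matrix(0, n, n)
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  for (e in seq_len(nrow(pairs))) {
    if (bitwAnd(mask, bitwShiftL(1, e - 1)) != 0) {
      A[pairs[e, 1], pairs[e, 2]] <- 1
      A[pairs[e, 2], pairs[e, 1]] <- 1
    }
  }
  A
}

# signed_network from an adjacency matrix (all edges positive)
adjacency_to_network <- function(A) {
  n <- nrow(A)
  nm <- sprintf("t%02d", seq_len(n))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- data.frame(taxon_a = nm[idx[, 1]], taxon_b = nm[idx[, 2]],
                      r = rep(0.9, nrow(idx)), p_adj = rep(0, nrow(idx)))
  signed_network(data.frame(name = nm, group = "bacteria"), edges)
}

# a bare-structure network with the requested node count and numbers of
# positive and negative edges (edges fill lexicographic pair order)
make_topology <- function(n_nodes, pos, neg, groups = NULL) {
  nm <- sprintf("t%02d", seq_len(n_nodes))
  if (is.null(groups)) groups <- rep("bacteria", n_nodes)
  pairs <- t(utils::combn(n_nodes, 2))[seq_len(pos + neg), , drop = FALSE]
  edges <- data.frame(taxon_a = nm[pairs[, 1]], taxon_b = nm[pairs[, 2]],
                      r = c(rep(0.9, pos), rep(-0.9, neg)),
                      p_adj = 0)
  signed_network(data.frame(name = nm, group = groups), edges)
}

# aggregated_table directly from a sites x taxa abundance matrix
make_aggregated <- function(mat, rank = "genus", marker_group = "16S") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("S%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("tax%02d", seq_len(ncol(mat)))
  structure(list(abund = mat, rank = rank,
                 taxa = data.frame(taxon = colnames(mat),
                                   marker_group = marker_group,
                                   mean_ra = colMeans(mat),
                                   occurrence = colSums(mat > 0),
                                   row.names = NULL)),
            class = "aggregated_table")
}

# minimal nutrient table with chosen stoichiometric ratios per site; the
# remaining variables get mild deterministic gradients so nothing is
# constant
make_nutrients <- function(tn_tp, nmin_ap, tp = NULL, ap = NULL) {
  n <- length(tn_tp)
  if (is.null(tp)) tp <- rep(1, n)
  if (is.null(ap)) ap <- rep(10, n)
  i <- seq_len(n)
  nutrient_table(data.frame(
    site_id = sprintf("S%02d", i),
    TN = tn_tp * tp, NAG = 20 + 0.3 * i, net_Nmin = nmin_ap * ap,
    N_inorg = 15 + 0.2 * (i %% 5), TP = tp, AP = ap,
    AKP = 8 + 0.1 * ((i * 3) %% 7)))
}

# hand-rolled correlation_records row set for classifier rule tests
make_records <- function(df) {
  fam <- npnet::np_variable_families()
  df$family <- ifelse(df$variable %in% fam$N, "N", "P")
  df$p_raw <- df$p_adj
  df$computable <- TRUE
  class(df) <- c("correlation_records", "data.frame")
  df
}
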