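# Candidate selection, FDR-filtered signed edges, topology metrics and
# composite-score keystones, each against independent brute-force oracles.

test_that("candidate selection filters on label, abundance and occupancy", {
  # 35 sites; occupancy strictly > half (18/35 in, 17/35 out)
  m <- matrix(0, nrow = 35, ncol = 4)
  m[1:18, 1] <- 0.3; m[1:17, 2] <- 0.3; m[1:18, 3] <- 0.3; m[1:18, 4] <- 0.3
  a <- make_aggregated(m)
  lab <- classify_taxa(make_records(data.frame(
    taxon = c("tax01", "tax01", "tax02", "tax02", "tax03", "tax03",
              "tax04", "tax04"),
    variable = rep(c("TN", "TP"), 4),
    r = c(0.8, 0.7, 0.8, 0.7, 0.8, -0.7, -0.6, 0.1),
    p_adj = c(rep(0.001, 7), 0.9),
    significant = c(rep(TRUE, 7), FALSE))))
  expect_equal(lab$label, c("coupled_positive", "coupled_positive",
                            "inconsistent", "decoupled_N"))
  expect_equal(select_candidates(a, lab, "coupled"), "tax01")
  expect_equal(select_candidates(a, lab, "decoupled"), "tax04")
  # inconsistent taxa never enter either network; low occupancy excluded
  expect_false("tax03" %in% c(select_candidates(a, lab, "coupled"),
                              select_candidates(a, lab, "decoupled")))
  lab$label[2] <- "none"
  expect_warning(sel <- select_candidates(a, lab, "decoupled",
                                          occupancy_min = 0.99),
                 "empty candidate set")
  expect_length(sel, 0)
})

test_that("edges require |r| > 0.6 and BH-adjusted p < 0.05, sign = sign(r)", {
  set.seed(77)
  n <- 30
  base <- rnorm(n)
  m <- cbind(t1 = base + rnorm(n, 0, 0.3),         # strongly + correlated
             t2 = base + rnorm(n, 0, 0.3),
             t3 = -base + rnorm(n, 0, 0.3),        # strongly - correlated
             t4 = rnorm(n),                        # independent
             t5 = rep(0.5, n))                     # constant
  m <- m - min(m) + 0.01
  a <- make_aggregated(m)
  net <- build_network(a, colnames(m), r_min = 0.6, alpha = 0.05)
  ed <- network_edges(net)
  key <- paste(ed$taxon_a, ed$taxon_b)
  expect_true(all(c("t1 t2", "t1 t3", "t2 t3") %in% key))
  expect_equal(ed$sign[key == "t1 t2"], "+")
  expect_equal(ed$sign[key == "t1 t3"], "-")
  expect_true(all(abs(ed$r) > 0.6 & ed$p_adj < 0.05))
  # constant taxon: kept as an isolated node, tests non-computable
  expect_true("t5" %in% network_nodes(net)$taxon)
  expect_equal(igraph::degree(net$graph)["t5"], c(t5 = 0))
  expect_false(any(net$tests$computable[net$tests$taxon_a == "t5" |
                                          net$tests$taxon_b == "t5"]))
  # two identical abundance vectors correlate at 1 and are joined
  a2 <- make_aggregated(cbind(x = m[, 1], y = m[, 1], z = m[, 4]))
  ed2 <- network_edges(build_network(a2, c("x", "y", "z")))
  expect_equal(ed2$r[ed2$taxon_a == "x" & ed2$taxon_b == "y"], 1)
})

test_that("edge sets match a brute-force double-loop recomputation", {
  for (s in c(31, 32)) {
    ds <- generate_dataset(generator_config(seed = s))
    a <- combine_groups(lapply(names(ds$counts), function(g)
      preprocess_group(ds$counts[[g]], ds$taxonomy, "genus",
                       seed = s * 10)))
    cand <- colnames(a$abund)[seq_len(15)]
    net <- build_network(a, cand, r_min = 0.6, alpha = 0.05)
    ed <- network_edges(net)
    got <- sort(paste(pmin(ed$taxon_a, ed$taxon_b),
                      pmax(ed$taxon_a, ed$taxon_b)))

    res <- list()
    for (i in 1:14) for (j in (i + 1):15) {
      x <- a$abund[, cand[i]]; y <- a$abund[, cand[j]]
      if (sd(x) == 0 || sd(y) == 0) next
      o <- oracle_pearson(x, y)
      res[[paste(i, j)]] <- data.frame(a = cand[i], b = cand[j],
                                       r = o$r, p = o$p)
    }
    res <- do.call(rbind, res)
    res$p_adj <- oracle_bh(res$p)
    want <- res[abs(res$r) > 0.6 & res$p_adj < 0.05, ]
    expect_equal(got, sort(paste(pmin(want$a, want$b),
                                 pmax(want$a, want$b))))
  }
})

test_that("topology metrics follow the connectance and ratio definitions", {
  # 14 nodes, 8 edges: connectance 8/91 displays as 0.09
  mt <- network_metrics(make_topology(14, pos = 5, neg = 3))
  expect_equal(mt$connectance, 8 / 91)
  expect_equal(mt$connectance_display, 0.09)
  expect_equal(mt$pos_edges + mt$neg_edges, mt$n_edges)
  # complete 2-node graph
  expect_equal(network_metrics(make_topology(2, 1, 0))$connectance, 1)
  # 150 positive / 24 negative
  expect_equal(network_metrics(make_topology(64, 150, 24))$pos_neg_ratio, 6.25)
  # no negative edges: Inf sentinel, serialized as "Inf"
  mt0 <- network_metrics(make_topology(5, 4, 0))
  expect_identical(mt0$pos_neg_ratio, Inf)
  expect_error(network_metrics(make_topology(14, 5, 3)$graph), "signed_network")
})

test_that("edge-type composition tracks marker groups", {
  grp <- c("bacteria", "bacteria", "fungi", "phoD")
  nm <- sprintf("t%02d", 1:4)
  edges <- data.frame(taxon_a = nm[c(1, 1, 1, 3, 2)],
                      taxon_b = nm[c(2, 3, 4, 4, 3)],
                      r = c(0.9, 0.9, -0.9, 0.9, 0.9), p_adj = 0)
  net <- signed_network(data.frame(name = nm, group = grp), edges)
  mt <- network_metrics(net)
  expect_equal(unname(mt$edge_types[c("B-B", "B-F", "B-P", "F-P")]),
               c(1L, 2L, 1L, 1L))
  expect_equal(sum(mt$edge_types), mt$n_edges)
  expect_equal(mt$frac_bacterial_edges, 4 / 5)
})

test_that("the 5-node star's centre is the lone keystone at score 1.789", {
  nm <- sprintf("t%02d", 1:5)
  edges <- data.frame(taxon_a = nm[1], taxon_b = nm[2:5], r = 0.9, p_adj = 0)
  net <- signed_network(data.frame(name = nm, group = "bacteria"), edges)
  cent <- centrality_keystones(net)
  centre <- cent[cent$taxon == "t01", ]
  expect_equal(centre$z_degree, 1.7889, tolerance = 1e-4)
  expect_equal(centre$z_closeness, 1.7889, tolerance = 1e-4)
  expect_equal(centre$z_betweenness, 1.7889, tolerance = 1e-4)
  expect_equal(centre$combined_score, 1.7889, tolerance = 1e-4)
  expect_true(centre$keystone)
  expect_false(any(cent$keystone[cent$taxon != "t01"]))
  expect_equal(centre$pos_edges, 4L)
  expect_equal(cent$pos_edges + cent$neg_edges, cent$degree)
})

test_that("symmetric graphs yield zero scores; isolated nodes never lead", {
  # complete 4-node graph: identical nodes, all z = 0, no keystones
  cent <- centrality_keystones(make_topology(4, 6, 0))
  expect_equal(cent$combined_score, rep(0, 4))
  expect_false(any(cent$keystone))
  # isolated node alongside a connected pair
  nm <- sprintf("t%02d", 1:3)
  net <- signed_network(data.frame(name = nm, group = "bacteria"),
                        data.frame(taxon_a = "t01", taxon_b = "t02",
                                   r = 0.9, p_adj = 0))
  cent2 <- centrality_keystones(net)
  iso <- cent2[cent2$taxon == "t03", ]
  expect_equal(iso$degree, 0)
  expect_equal(iso$closeness, 0)
  expect_equal(iso$betweenness, 0)
  expect_false(iso$keystone)
})

test_that("centralities match the matrix-power oracle on small graphs", {
  # exhaustive over all 4-node graphs, plus fixed-seed 5/6-node samples
  for (mask in 0:63) {
    A <- mask_to_adjacency(mask, 4)
    cent <- centrality_keystones(adjacency_to_network(A))
    orc <- oracle_centrality(A)
    expect_equal(cent$degree, unname(orc$degree))
    expect_equal(cent$closeness, orc$closeness, tolerance = 1e-12)
    expect_equal(cent$betweenness, orc$betweenness, tolerance = 1e-12)
  }
  set.seed(99)
  for (n in 5:6) for (mask in sample(0:(2^choose(n, 2) - 1), 40)) {
    A <- mask_to_adjacency(mask, n)
    cent <- centrality_keystones(adjacency_to_network(A))
    orc <- oracle_centrality(A)
    expect_equal(cent$closeness, orc$closeness, tolerance = 1e-12)
    expect_equal(cent$betweenness, orc$betweenness, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabelling; edge removal
           shrinks connectance and degrees", {
  net <- make_topology(7, pos = 6, neg = 2)
  cent <- centrality_keystones(net)
  # relabel: reverse names
  ed <- network_edges(net)
  relabel <- setNames(sprintf("z%02d", 7:1), sprintf("t%02d", 1:7))
  ed$taxon_a <- relabel[ed$taxon_a]; ed$taxon_b <- relabel[ed$taxon_b]
  net2 <- signed_network(data.frame(name = unname(relabel),
                                    group = "bacteria"), ed)
  cent2 <- centrality_keystones(net2)
  cent2 <- cent2[match(relabel[cent$taxon], cent2$taxon), ]
  expect_equal(cent2$combined_score, cent$combined_score)
  expect_equal(cent2$keystone, cent$keystone)
  mt <- network_metrics(net)
  expect_equal(network_metrics(net2)$connectance, mt$connectance)
  # remove one edge
  net3 <- signed_network(data.frame(name = sprintf("t%02d", 1:7),
                                    group = "bacteria"),
                         network_edges(net)[-1, ])
  expect_lt(network_metrics(net3)$connectance, mt$connectance)
  expect_true(all(centrality_keystones(net3)$degree <= cent$degree))
})
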