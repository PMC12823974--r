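#!/usr/bin/env Rscript
# Stage 4: signed co-occurrence networks. At each rank, taxa labelled
# coupled (resp. decoupled) that are major (> 0.1% mean) and occur in
# more than half the sites become network candidates; edges are Pearson
# correlations with |r| > 0.6 and BH-adjusted p < 0.05. Reports
# connectance, positive:negative edge ratio, edge-type composition and
# composite-score keystone taxa, and exports the graphs.

suppressPackageStartupMessages(library(npnet))

data_dir <- "results/synthetic_study/data"
out_dir <- "results/synthetic_study"
tax <- read_taxonomy(file.path(data_dir, "taxonomy.tsv"))
nutrients <- read_nutrients(file.path(data_dir, "nutrients.tsv"))

for (rank in c("phylum", "genus")) {
  agg <- lapply(c("16S", "ITS", "phoD"), function(grp) {
    t0 <- read_count_table(file.path(data_dir,
                                     paste0("counts_", grp, ".tsv")), grp)
    preprocess_group(t0, tax, rank,
                     seed = 101 + match(grp, c("16S", "ITS", "phoD")))
  })
  pooled <- combine_groups(agg)
  labels <- classify_taxa(correlate_taxa(pooled, nutrients))

  for (which in c("coupled", "decoupled")) {
    cand <- select_candidates(pooled, labels, which)
    if (length(cand) < 3) {
      cat(sprintf("%s %s network: only %d candidate(s), skipped\n",
                  rank, which, length(cand)))
      next
    }
    net <- build_network(pooled, cand)
    mt <- network_metrics(net)
    cent <- centrality_keystones(net)
    base <- file.path(out_dir, paste0(rank, "_", which))
    write_network(net, paste0(base, "_edges.tsv"), "edge_tsv")
    write_network(net, paste0(base, "_network.graphml"), "graphml")
    write.table(cent, paste0(base, "_nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    cat(sprintf("\n%s %s network: %d nodes, %d edges (connectance %.2f)\n",
                rank, which, mt$n_nodes, mt$n_edges, mt$connectance))
    cat(sprintf("  +:- edges %d:%d (ratio %s); edges touching bacteria: %.0f%%\n",
                mt$pos_edges, mt$neg_edges,
                format(round(mt$pos_neg_ratio, 2)),
                100 * mt$frac_bacterial_edges))
    ks <- cent[cent$keystone, ]
    if (nrow(ks))
      cat(sprintf("  keystone %s (score %.2f, %d+/%d- edges)\n",
                  ks$taxon, ks$combined_score, ks$pos_edges, ks$neg_edges))
    else cat("  no keystone taxa at threshold 1\n")
  }
}
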