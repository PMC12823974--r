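#!/usr/bin/env Rscript
# Stage 2: preprocessing. For each marker group: drop features below the
# 0.001% global abundance floor, rarefy to 90% of the minimum depth
# averaged over 100 draws, apply the marker-specific retention rule (10%
# prevalence for 16S/phoD, >= 10 reads for ITS), aggregate to phylum and
# genus relative abundance, and keep major taxa (mean > 0.1%). Writes the
# pooled major-taxon tables.

suppressPackageStartupMessages(library(npnet))

data_dir <- "results/synthetic_study/data"
out_dir <- "results/synthetic_study"
tax <- read_taxonomy(file.path(data_dir, "taxonomy.tsv"))

for (rank in c("phylum", "genus")) {
  agg <- list()
  for (grp in c("16S", "ITS", "phoD")) {
    t0 <- read_count_table(file.path(data_dir,
                                     paste0("counts_", grp, ".tsv")), grp)
    t1 <- filter_global_floor(t0, 1e-5)
    t2 <- rarefy_average(t1, fraction = 0.9, reps = 100,
                         seed = 101 + match(grp, c("16S", "ITS", "phoD")))
    t3 <- filter_prevalence(t2)
    a <- select_major(aggregate_taxa(t3, tax, rank), 0.001)
    cat(sprintf("%-6s %-5s features %3d -> floor %3d -> retained %3d -> %2d major %s\n",
                rank, grp, n_features(t0), n_features(t1), n_features(t3),
                nrow(a$taxa), rank))
    agg[[grp]] <- a
  }
  pooled <- combine_groups(agg)
  tab <- data.frame(taxon = pooled$taxa$taxon,
                    marker_group = pooled$taxa$marker_group,
                    mean_ra = pooled$taxa$mean_ra,
                    occurrence = pooled$taxa$occurrence,
                    t(pooled$abund), check.names = FALSE)
  write.table(tab, file.path(out_dir, paste0("major_", rank, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote major-taxon relative-abundance tables to", out_dir, "\n")
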