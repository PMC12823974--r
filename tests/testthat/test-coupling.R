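# Site labels, correlation screening, the sign-consistency classifier,
# the net-Nmin/AP regression and coupled-site enrichment.

test_that("sites are coupled only when both ratios strictly clear thresholds", {
  nut <- make_nutrients(tn_tp = c(4.7, 3.0, 5.0, 2.0),
                        nmin_ap = c(0.20, 0.20, 0.10, 0.10))
  cls <- classify_sites(nut)
  expect_equal(cls$label, c("coupled", "decoupled", "decoupled", "decoupled"))
  expect_equal(cls$tn_tp[1], 4.7)
})

test_that("correlation records behave like Pearson: perfect, anti, adjusted", {
  nut <- make_nutrients(tn_tp = runif(10, 1, 6), nmin_ap = runif(10, 0, 0.3),
                        tp = runif(10, 0.05, 0.2), ap = runif(10, 5, 20))
  x <- cbind(0.4 * nut$TN,                 # exactly proportional to TN
             max(nut$TN) + 1 - nut$TN,     # r = -1 with TN
             rep(0.1, 10))                 # constant: non-computable
  a <- make_aggregated(x)
  rec <- correlate_taxa(a, nut)
  r1 <- rec[rec$taxon == "tax01" & rec$variable == "TN", ]
  expect_equal(r1$r, 1)
  expect_lt(r1$p_raw, 1e-12)
  expect_equal(rec$r[rec$taxon == "tax02" & rec$variable == "TN"], -1)
  expect_false(any(rec$computable[rec$taxon == "tax03"]))
  # Bonferroni invariant: p_adj = min(1, p_raw * m) with m the computable
  # family size (constant taxon excluded)
  comp <- rec[rec$computable, ]
  expect_equal(comp$p_adj, pmin(1, comp$p_raw * nrow(comp)))
})

test_that("the per-taxon Bonferroni sensitivity mode adjusts over 7 tests", {
  nut <- make_nutrients(tn_tp = runif(12, 1, 6), nmin_ap = runif(12, 0, 0.3),
                        tp = runif(12, 0.05, 0.2), ap = runif(12, 5, 20))
  set.seed(5)
  a <- make_aggregated(matrix(rexp(12 * 4), nrow = 12))
  rec <- correlate_taxa(a, nut, family = "per_taxon")
  one <- rec[rec$taxon == "tax02", ]
  expect_equal(one$p_adj, pmin(1, one$p_raw * 7))
})

test_that("classifier applies the sign-consistency rules", {
  rec <- make_records(data.frame(
    taxon = c("A", "A", "B", "C", "C", "D"),
    variable = c("TN", "TP", "NAG", "TN", "TP", "AKP"),
    r = c(0.70, 0.65, -0.62, 0.70, -0.65, 0.1),
    p_adj = c(0.001, 0.002, 0.004, 0.001, 0.002, 0.9),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)))
  lab <- classify_taxa(rec)
  expect_equal(lab$label[lab$taxon == "A"], "coupled_positive")
  expect_equal(lab$label[lab$taxon == "B"], "decoupled_N")
  expect_equal(lab$label[lab$taxon == "C"], "inconsistent")
  expect_equal(lab$label[lab$taxon == "D"], "none")
  # partition: every taxon gets exactly one label
  expect_setequal(lab$taxon, c("A", "B", "C", "D"))
  expect_equal(anyDuplicated(lab$taxon), 0)
})

test_that("raising alpha only moves taxa away from 'none', never back", {
  ds <- generate_dataset(generator_config(seed = 21))
  a <- combine_groups(lapply(names(ds$counts), function(g)
    preprocess_group(ds$counts[[g]], ds$taxonomy, "genus", seed = 210)))
  ordered_labels <- function(alpha)
    classify_taxa(correlate_taxa(a, ds$nutrients, alpha = alpha))
  lo <- ordered_labels(0.01)
  hi <- ordered_labels(0.20)
  stopifnot(identical(lo$taxon, hi$taxon))
  # taxa labelled at low alpha stay labelled at high alpha
  expect_true(all(hi$label[lo$label != "none"] != "none"))
})

test_that("labels agree with a double-loop textbook recomputation", {
  ds <- generate_dataset(generator_config(
    seed = 22, n_taxa_per_group = c("16S" = 40, "ITS" = 16, "phoD" = 12)))
  a <- combine_groups(lapply(names(ds$counts), function(g)
    preprocess_group(ds$counts[[g]], ds$taxonomy, "genus", seed = 220)))
  a$abund <- a$abund[, seq_len(min(20, ncol(a$abund)))]
  a$taxa <- a$taxa[seq_len(ncol(a$abund)), ]
  rec <- correlate_taxa(a, ds$nutrients, alpha = 0.05)
  lab <- classify_taxa(rec)

  # independent oracle: double loop, textbook sums formula, longhand
  # Bonferroni over the computable family, then the labelling rules
  fam <- np_variable_families()
  vars <- unlist(fam, use.names = FALSE)
  nut <- as.matrix(ds$nutrients[match(rownames(a$abund),
                                      ds$nutrients$site_id), vars])
  res <- list()
  for (tx in colnames(a$abund)) for (v in vars) {
    x <- a$abund[, tx]
    if (sd(x) == 0) next
    o <- oracle_pearson(x, nut[, v])
    res[[paste(tx, v)]] <- data.frame(taxon = tx, variable = v,
                                      r = o$r, p = o$p)
  }
  res <- do.call(rbind, res)
  res$p_adj <- oracle_bonferroni(res$p)
  res$sig <- res$p_adj < 0.05
  for (tx in unique(res$taxon)) {
    s <- res[res$taxon == tx & res$sig, ]
    nN <- sum(s$variable %in% fam$N); nP <- sum(s$variable %in% fam$P)
    want <- if (nN > 0 && nP > 0) {
      if (all(s$r > 0)) "coupled_positive"
      else if (all(s$r < 0)) "coupled_negative" else "inconsistent"
    } else if (nN > 0) "decoupled_N" else if (nP > 0) "decoupled_P" else "none"
    expect_equal(lab$label[lab$taxon == tx], want, label = tx)
  }
  # and the record-level numbers match the oracle
  merged <- merge(rec[rec$computable, ], res, by = c("taxon", "variable"))
  expect_equal(merged$r.x, merged$r.y, tolerance = 1e-12)
  expect_equal(merged$p_raw, merged$p, tolerance = 1e-12)
})

test_that("independent taxa survive Bonferroni screening (type-I control)", {
  # 200 fixed-seed null communities (no planted structure at all): at
  # alpha 0.05 at most ~5% of datasets may show any significant record
  hits <- 0
  for (s in 1:200) {
    ds <- generate_dataset(generator_config(
      seed = 5000 + s,
      n_taxa_per_group = c("16S" = 24, "ITS" = 12, "phoD" = 12),
      fraction_coupled = 0, fraction_decoupled_N = 0,
      fraction_decoupled_P = 0))
    a <- combine_groups(lapply(names(ds$counts), function(g)
      preprocess_group(ds$counts[[g]], ds$taxonomy, "genus", seed = s)))
    if (any(correlate_taxa(a, ds$nutrients)$significant)) hits <- hits + 1
  }
  expect_lte(hits / 200, 0.05)
})

test_that("the net-Nmin/AP regression is exact on noiseless input", {
  nut <- make_nutrients(tn_tp = runif(8, 1, 6),
                        nmin_ap = seq(0.02, 0.30, length.out = 8))
  a <- make_aggregated(cbind(0.01 * nut$nmin_ap + 0.002,
                             rexp(8)))
  rec <- make_records(data.frame(
    taxon = c("tax01", "tax01", "tax02"), variable = c("TN", "TP", "TN"),
    r = c(0.9, 0.9, 0.1), p_adj = c(0.001, 0.001, 0.9),
    significant = c(TRUE, TRUE, FALSE)))
  lab <- classify_taxa(rec)
  out <- suppressWarnings(regress_vs_nmin_ap(a, nut, lab))  # exact fit
  expect_equal(out$taxon, "tax01")  # 'none' taxa are out of scope
  expect_equal(out$slope, 0.01, tolerance = 1e-10)
  expect_equal(out$intercept, 0.002, tolerance = 1e-10)
  expect_equal(out$r_squared, 1, tolerance = 1e-10)
  expect_true(out$significant)
})

test_that("planted coupled taxa show significant positive nmin/AP slopes", {
  ds <- generate_dataset(generator_config(seed = 23, target_r = 0.9))
  a <- combine_groups(lapply(names(ds$counts), function(g)
    preprocess_group(ds$counts[[g]], ds$taxonomy, "genus", seed = 230)))
  lab <- classify_taxa(correlate_taxa(a, ds$nutrients))
  out <- regress_vs_nmin_ap(a, ds$nutrients, lab)
  gt <- truth_genus_labels(ds$truth)
  pos <- out[out$taxon %in% gt$genus[gt$planted_label == "coupled_positive"], ]
  expect_gt(nrow(pos), 0)
  expect_gt(mean(pos$significant & pos$slope > 0), 0.8)
})

test_that("enrichment ranks coupled sites above decoupled ones", {
  nut <- make_nutrients(tn_tp = c(rep(5, 6), rep(1.5, 8)),
                        nmin_ap = c(rep(0.3, 6), rep(0.05, 8)))
  sites <- classify_sites(nut)
  sep <- c(runif(6, 0.6, 1), runif(8, 0, 0.4))    # complete separation
  same <- rep(c(0.2, 0.3), 7)                     # identical distributions
  a <- make_aggregated(matrix(c(sep, same), ncol = 2))
  rec <- make_records(data.frame(
    taxon = rep(c("tax01", "tax02"), each = 2),
    variable = rep(c("TN", "TP"), 2),
    r = 0.8, p_adj = 0.001, significant = TRUE))
  lab <- classify_taxa(rec)
  out <- test_enrichment(a, sites, lab)
  expect_true(out$enriched[out$taxon == "tax01"])
  expect_false(out$enriched[out$taxon == "tax02"])
  # complete separation gives the smallest attainable p for these sizes
  ref <- wilcox.test(sep[1:6], sep[7:14], alternative = "greater",
                     exact = FALSE, correct = TRUE)$p.value
  expect_equal(out$p[out$taxon == "tax01"], ref)

  all_coupled <- classify_sites(make_nutrients(tn_tp = rep(5, 14),
                                               nmin_ap = rep(0.3, 14)))
  expect_error(test_enrichment(a, all_coupled, lab), "nonempty")
})
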