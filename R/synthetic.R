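# Synthetic community generator. Produces site x feature count tables for
# the three marker groups, a taxonomy map, a nutrient table spanning both
# sides of the TN/TP and net-Nmin/AP coupling thresholds, and a truth
# sidecar with the planted per-taxon labels, so the whole downstream chain
# is testable without sequencing data.
#
# Planted structure: each synthetic genus carries one label. Features of a
# "coupled" genus get a latent abundance that responds linearly to a
# standardized mix of two anchor nutrient variables (one N-cycling, one
# P-cycling, chosen as the most-correlated cross-family pair so that a
# dual-anchor correlation of target_r is geometrically attainable), plus
# Gaussian noise scaled so the expected Pearson correlation with each
# anchor is +-target_r; "decoupled" genera anchor on a single variable of
# one family; "none" genera are independent of all variables. Site read
# depths are drawn uniformly from depth_range and counts allocated by
# multinomial sampling of the latent proportions, so column sums equal the
# drawn depths exactly.

#' Configuration for the synthetic community generator
#'
#' Defaults emulate the study design the pipeline targets: 35 sites of
#' which 10 are N-P coupled, three marker groups, per-sample depths in the
#' observed 16S range, and planted taxon-nutrient correlations of
#' magnitude `target_r`.
#'
#' @param n_sites number of sites (default 35)
#' @param n_taxa_per_group named counts of features per marker group
#' @param fraction_coupled,fraction_decoupled_N,fraction_decoupled_P
#'   proportions of genera planted with each label (nonnegative, sum <= 1;
#'   the remainder are label "none")
#' @param coupled_negative_share share of coupled genera with negative-sign
#'   correlations (default 0.25; most coupled taxa relate positively)
#' @param target_r planted correlation magnitude in (0,1)
#' @param depth_range min/max total reads per site
#' @param n_coupled_sites number of sites drawn above both nutrient
#'   thresholds (TN/TP > 3 and net-Nmin/AP > 0.16)
#' @param noise_sd lognormal dispersion of feature abundance about its
#'   latent mean
#' @param enrich_boost multiplicative abundance boost of coupled-positive
#'   taxa in coupled sites (default 3)
#' @param seed integer seed; all randomness derives from it
#' @return a validated list of class `generator_config`
#' @export
generator_config <- function(n_sites = 35,
                             n_taxa_per_group = c("16S" = 120, "ITS" = 80,
                                                  "phoD" = 40),
                             fraction_coupled = 0.12,
                             fraction_decoupled_N = 0.10,
                             fraction_decoupled_P = 0.10,
                             coupled_negative_share = 0.25,
                             target_r = 0.85,
                             depth_range = c(35454, 64657),
                             n_coupled_sites = 10,
                             noise_sd = 0.5,
                             enrich_boost = 3,
                             seed = 1) {
  fr <- c(fraction_coupled, fraction_decoupled_N, fraction_decoupled_P)
  if (any(fr < 0) || sum(fr) > 1)
    stop("configuration error: planted fractions must be nonnegative and sum <= 1")
  if (n_coupled_sites > n_sites)
    stop("configuration error: n_coupled_sites exceeds n_sites")
  if (length(depth_range) != 2 || depth_range[1] < 1 ||
      depth_range[2] < depth_range[1])
    stop("configuration error: depth_range must be [min >= 1, max >= min]")
  if (target_r <= 0 || target_r >= 1)
    stop("configuration error: target_r must be in (0,1)")
  if (!all(MARKER_GROUPS %in% names(n_taxa_per_group)))
    stop("configuration error: n_taxa_per_group needs entries 16S, ITS, phoD")
  structure(list(n_sites = n_sites,
                 n_taxa_per_group = n_taxa_per_group[MARKER_GROUPS],
                 fraction_coupled = fraction_coupled,
                 fraction_decoupled_N = fraction_decoupled_N,
                 fraction_decoupled_P = fraction_decoupled_P,
                 coupled_negative_share = coupled_negative_share,
                 target_r = target_r,
                 depth_range = depth_range,
                 n_coupled_sites = n_coupled_sites,
                 noise_sd = noise_sd,
                 enrich_boost = enrich_boost,
                 seed = as.integer(seed)),
            class = "generator_config")
}

site_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Generate a synthetic soil nutrient table
#'
#' Draws the seven nutrient-cycling variables from two lognormal latent
#' factors (an N-status and a P-status factor, elevated at coupled sites)
#' so that N-cycling variables cluster together more tightly than they do
#' with P-cycling ones. Exactly `n_coupled_sites` sites satisfy both
#' TN/TP > 3 and net-Nmin/AP > 0.16; every other site fails at least one
#' threshold (enforced by redrawing the offending ratio when the latent
#' draw lands on the wrong side).
#'
#' @param config a [generator_config()]
#' @return a `nutrient_table` for `config$n_sites` sites
#' @export
generate_nutrients <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(sub_seed(config$seed, 1))
  n <- config$n_sites
  coupled <- rep(FALSE, n)
  coupled[sample.int(n, config$n_coupled_sites)] <- TRUE

  # P-status latent and P-cycling variables
  TP <- 0.09 * exp(rnorm(n, 0, 0.35) + 0.35 * coupled)       # % mass
  AP <- 95 * TP * exp(rnorm(n, 0, 0.30))                     # mg/kg
  AKP <- 0.8 * AP * exp(rnorm(n, 0, 0.25))                   # umol/g/h

  # N-cycling variables ride on the TN/TP stoichiometric ratio
  ratio1 <- ifelse(coupled, exp(rnorm(n, log(4.5), 0.25)),
                            exp(rnorm(n, log(1.6), 0.45)))
  TN <- ratio1 * TP                                          # % mass
  NAG <- 45 * TN * exp(rnorm(n, 0, 0.25))                    # nmol/g/h
  N_inorg <- 28 * TN * exp(rnorm(n, 0, 0.25))                # mg/kg
  ratio2 <- ifelse(coupled, exp(rnorm(n, log(0.25), 0.25)),
                            exp(rnorm(n, log(0.07), 0.50)))
  net_Nmin <- ratio2 * AP                                    # mg/kg/28d

  # enforce the site-class postcondition exactly
  for (i in seq_len(n)) {
    if (coupled[i]) {
      if (TN[i] / TP[i] <= 3) TN[i] <- TP[i] * runif(1, 3.2, 6.2)
      if (net_Nmin[i] / AP[i] <= 0.16)
        net_Nmin[i] <- AP[i] * runif(1, 0.18, 0.40)
    } else if (TN[i] / TP[i] > 3 && net_Nmin[i] / AP[i] > 0.16) {
      if (runif(1) < 0.5) TN[i] <- TP[i] * runif(1, 0.6, 2.8)
      else net_Nmin[i] <- AP[i] * runif(1, 0.02, 0.13)
    }
  }
  nutrient_table(data.frame(site_id = site_ids(n), TN = TN, NAG = NAG,
                            net_Nmin = net_Nmin, N_inorg = N_inorg,
                            TP = TP, AP = AP, AKP = AKP))
}

# Site profile for coupled taxa: f = (1 +- tau (w1 zN + w2 zP))+ x B,
# with anchor weights (w1, w2) solved so the expected correlation of the
# noisy latent abundance f (1 + nu e) with each standardized anchor equals
# sgn * r_target. B carries the coupled-site enrichment boost, so its
# class-axis signal is compensated rather than distorting the target.
solve_coupled_profile <- function(zN, zP, B, tau, nu, r_target, sgn) {
  f_of <- function(w)
    pmax(0.05, 1 + sgn * tau * (w[1] * zN + w[2] * zP)) * B
  cor_exp <- function(f, z)
    cov(f, z) / sqrt((var(f) + nu^2 * mean(f^2)) * var(z))
  # small-norm regularisation: large weights solve the correlation target
  # too, but through a truncation-dominated spiky profile that would let
  # planted taxa consume whole sites
  obj <- function(w)
    (cor_exp(f_of(w), zN) - sgn * r_target)^2 +
    (cor_exp(f_of(w), zP) - sgn * r_target)^2 +
    1e-4 * sum(w^2) + sum(pmax(0, abs(w) - 2)^2)
  fit <- optim(c(0.3, 0.3), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  f_of(fit$par)
}

# genus sizes of 4-5 features summing exactly to n (all >= 3)
genus_sizes <- function(n) {
  n_gen <- n %/% 4
  sizes <- rep(4L, n_gen)
  extra <- n - 4L * n_gen
  if (extra > 0) sizes[seq_len(extra)] <- 5L
  sizes
}

#' Generate synthetic count tables with planted taxon-nutrient structure
#'
#' @param config a [generator_config()]
#' @param nutrients a `nutrient_table` covering the configured sites,
#'   normally from [generate_nutrients()]
#' @return list with `counts` (named list of three raw `count_table`s),
#'   `taxonomy` (a `taxonomy_map`) and `truth` (list with per-feature
#'   planted labels, per-site true coupling labels, and the seed)
#' @export
generate_counts <- function(config, nutrients) {
  stopifnot(inherits(config, "generator_config"),
            inherits(nutrients, "nutrient_table"))
  n <- config$n_sites
  if (nrow(nutrients) != n)
    stop("nutrient table does not cover the configured sites")
  fam <- np_variable_families()
  vars <- unlist(fam, use.names = FALSE)
  Z <- scale(as.matrix(nutrients[, vars]))
  coupled_site <- nutrients$tn_tp > 3 & nutrients$nmin_ap > 0.16

  # most-correlated N/P anchor pair: a taxon can correlate at r with both
  # anchors only if r <= sqrt((1 + rho)/2), so the pair with the largest
  # cross-family rho gives the planted target the most headroom
  cross <- cor(Z)[fam$N, fam$P]
  best <- which(cross == max(cross), arr.ind = TRUE)[1, ]
  best_N <- fam$N[best[1]]; best_P <- fam$P[best[2]]
  rho_best <- max(cross)

  counts <- list(); tax <- list(); truth <- list()
  for (k in seq_along(MARKER_GROUPS)) {
    grp <- MARKER_GROUPS[k]
    set.seed(sub_seed(config$seed, 10 + k))
    n_feat <- config$n_taxa_per_group[[grp]]
    sizes <- genus_sizes(n_feat)
    n_gen <- length(sizes)
    genus_of <- rep(seq_len(n_gen), times = sizes)

    # one planted label per genus
    n_c <- round(config$fraction_coupled * n_gen)
    n_dn <- round(config$fraction_decoupled_N * n_gen)
    n_dp <- round(config$fraction_decoupled_P * n_gen)
    n_cneg <- round(config$coupled_negative_share * n_c)
    lab <- rep("none", n_gen)
    ord <- sample.int(n_gen)
    lab[ord[seq_len(n_c - n_cneg)]] <- "coupled_positive"
    if (n_cneg > 0) lab[ord[n_c - n_cneg + seq_len(n_cneg)]] <- "coupled_negative"
    if (n_dn > 0) lab[ord[n_c + seq_len(n_dn)]] <- "decoupled_N"
    if (n_dp > 0) lab[ord[n_c + n_dn + seq_len(n_dp)]] <- "decoupled_P"
    is_coupled_lab <- lab %in% c("coupled_positive", "coupled_negative")
    anchor_N <- ifelse(lab == "decoupled_N",
                       sample(fam$N, n_gen, replace = TRUE), NA)
    anchor_P <- ifelse(lab == "decoupled_P",
                       sample(fam$P, n_gen, replace = TRUE), NA)
    anchor_N[is_coupled_lab] <- best_N
    anchor_P[is_coupled_lab] <- best_P
    gsign <- ifelse(lab == "coupled_negative", -1,
             ifelse(lab == "none", 0,
             ifelse(lab == "coupled_positive", 1,
                    sample(c(-1, 1), n_gen, replace = TRUE))))

    # Latent abundance per feature. Coupled taxa follow a shared site
    # profile whose anchor weights are solved so the expected Pearson
    # correlation of the final profile (enrichment boost included) with
    # each anchor equals target_r; decoupled taxa use the closed-form
    # single-anchor construction; "none" taxa are pure noise.
    nu <- 0.15  # residual feature-level dispersion of planted taxa
    boost_vec <- config$enrich_boost ^ coupled_site
    f_pos <- solve_coupled_profile(Z[, best_N], Z[, best_P], boost_vec,
                                   config$noise_sd, nu, config$target_r, 1)
    f_neg <- solve_coupled_profile(Z[, best_N], Z[, best_P], rep(1, n),
                                   config$noise_sd, nu, config$target_r, -1)
    latent <- matrix(0, n, n_feat)
    base <- numeric(n_feat)
    for (j in seq_len(n_feat)) {
      g <- genus_of[j]
      planted <- lab[g] != "none"
      base[j] <- if (planted) exp(rnorm(1, 0, 0.4)) else exp(rnorm(1, 0, 1.3))
      eps <- rnorm(n)
      latent[, j] <- if (!planted) {
        base[j] * pmax(0.05, 1 + config$noise_sd * eps)
      } else if (lab[g] == "coupled_positive") {
        base[j] * f_pos * pmax(0.05, 1 + nu * eps)
      } else if (lab[g] == "coupled_negative") {
        base[j] * f_neg * pmax(0.05, 1 + nu * eps)
      } else {
        za <- Z[, if (lab[g] == "decoupled_N") anchor_N[g] else anchor_P[g]]
        b <- min(0.995, config$target_r)
        x <- gsign[g] * b * za + sqrt(1 - b^2) * eps
        base[j] * pmax(0.05, 1 + config$noise_sd * x)
      }
    }

    depths <- floor(runif(n, config$depth_range[1], config$depth_range[2] + 1))
    cm <- matrix(0L, n, n_feat)
    for (i in seq_len(n))
      cm[i, ] <- as.integer(rmultinom(1, depths[i], latent[i, ] / sum(latent[i, ])))

    feat_ids <- sprintf("%s_asv%03d", grp, seq_len(n_feat))
    gen_names <- sprintf("%s_gen%02d", grp, seq_len(n_gen))
    n_phy <- ceiling(n_gen / 5)
    phy_of <- rep(seq_len(n_phy), each = 5, length.out = n_gen)
    phy_names <- sprintf("%s_phy%02d", grp, seq_len(n_phy))
    dimnames(cm) <- list(site_ids(n), feat_ids)
    counts[[grp]] <- count_table(cm, grp, raw = TRUE)

    genus <- gen_names[genus_of]
    phylum <- phy_names[phy_of[genus_of]]
    species <- sprintf("%s_sp", feat_ids)
    # a slice of unplanted features keeps only a genus-level placeholder name
    placeholder <- lab[genus_of] == "none" & (seq_len(n_feat) %% 7 == 0)
    species[placeholder] <- paste0("unclassified_", genus[placeholder])
    tax[[grp]] <- data.frame(
      feature_id = feat_ids,
      kingdom = if (grp == "ITS") "Fungi" else "Bacteria",
      phylum = phylum, class = paste0(phylum, "_c"),
      order = paste0(phylum, "_o"), family = paste0(genus, "_fam"),
      genus = genus, species = species)

    truth[[grp]] <- data.frame(
      feature_id = feat_ids, marker_group = grp, genus = genus,
      planted_label = lab[genus_of],
      target_r = ifelse(lab[genus_of] == "none", 0, config$target_r),
      anchor_N = anchor_N[genus_of], anchor_P = anchor_P[genus_of])
  }

  list(counts = counts,
       taxonomy = taxonomy_map(do.call(rbind, tax)),
       truth = list(features = do.call(rbind, truth),
                    sites = data.frame(site_id = nutrients$site_id,
                                       coupled = coupled_site),
                    seed = config$seed))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: nutrients, the three count tables, taxonomy and
#' truth from one config. Identical (config, seed) give bit-identical
#' output.
#'
#' @param config a [generator_config()]
#' @return list with `nutrients`, `counts`, `taxonomy`, `truth`
#' @export
generate_dataset <- function(config) {
  nutrients <- generate_nutrients(config)
  g <- generate_counts(config, nutrients)
  list(nutrients = nutrients, counts = g$counts, taxonomy = g$taxonomy,
       truth = g$truth)
}

#' Planted label of each synthetic genus
#' @param truth the `truth` element of [generate_dataset()] output
#' @return data.frame with columns `genus`, `planted_label`
#' @export
truth_genus_labels <- function(truth) {
  unique(truth$features[, c("genus", "planted_label")])
}

#' Write a synthetic dataset to disk
#'
#' Writes the same tab-delimited formats the pipeline reads, plus truth
#' sidecars (`truth_features.tsv` with feature_id, planted_label, target_r;
#' `truth_sites.tsv` with the true site coupling labels).
#'
#' @param dataset output of [generate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (grp in names(dataset$counts))
    write_count_table(dataset$counts[[grp]],
                      file.path(dir, paste0("counts_", grp, ".tsv")))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_nutrients(dataset$nutrients, file.path(dir, "nutrients.tsv"))
  write.table(dataset$truth$features[, c("feature_id", "planted_label",
                                         "target_r")],
              file.path(dir, "truth_features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$sites, file.path(dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
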