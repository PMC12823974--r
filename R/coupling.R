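# Site and taxon N-P coupling classification: stoichiometric site labels,
# sign-consistent Bonferroni-screened taxon-nutrient correlations, the
# net-Nmin/AP regression for coupled taxa, and coupled-site enrichment.

#' Classify sites as N-P coupled or decoupled
#'
#' A site is coupled when both stoichiometric ratios clear their
#' thresholds strictly: TN/TP > `tn_tp_min` and net-Nmin/AP >
#' `nmin_ap_min`. Every other site is decoupled (N and P cycling
#' asynchronous, or both too slow).
#'
#' @param n a `nutrient_table`
#' @param tn_tp_min TN/TP threshold (default 3)
#' @param nmin_ap_min net-Nmin/AP threshold (default 0.16)
#' @return data.frame with `site_id`, `tn_tp`, `nmin_ap`, `label`
#' @export
classify_sites <- function(n, tn_tp_min = 3, nmin_ap_min = 0.16) {
  stopifnot(inherits(n, "nutrient_table"))
  data.frame(site_id = n$site_id, tn_tp = n$tn_tp, nmin_ap = n$nmin_ap,
             label = ifelse(n$tn_tp > tn_tp_min & n$nmin_ap > nmin_ap_min,
                            "coupled", "decoupled"))
}

#' Correlate taxa with the N- and P-cycling variables
#'
#' Pearson correlation of each taxon's relative abundance with each of the
#' seven nutrient variables (two-sided test), Bonferroni-adjusted. The
#' default family is all computable taxon-by-variable tests in the table
#' (one marker-group/rank analysis); `family = "per_taxon"` adjusts over
#' the 7 variables of each taxon instead, as a sensitivity mode.
#' Constant abundance vectors are flagged non-computable and excluded from
#' the family size.
#'
#' @param a an `aggregated_table` (>= 3 sites)
#' @param n a `nutrient_table` covering the same sites
#' @param alpha significance level on adjusted p (default 0.05)
#' @param family "global" (default) or "per_taxon" Bonferroni family
#' @return data.frame of class `correlation_records`: `taxon`, `variable`,
#'   `family` (N/P), `r`, `p_raw`, `p_adj`, `significant`, `computable`
#' @export
correlate_taxa <- function(a, n, alpha = 0.05,
                           family = c("global", "per_taxon")) {
  stopifnot(inherits(a, "aggregated_table"), inherits(n, "nutrient_table"))
  family <- match.arg(family)
  sites <- rownames(a$abund)
  idx <- match(sites, n$site_id)
  if (anyNA(idx)) stop("nutrient table missing site(s): ",
                       paste(sites[is.na(idx)], collapse = ", "))
  if (length(sites) < 3) stop("need at least 3 sites for correlation")
  fam <- np_variable_families()
  vars <- unlist(fam, use.names = FALSE)
  vfam <- ifelse(vars %in% fam$N, "N", "P")
  nut <- as.matrix(n[idx, vars])

  taxa <- colnames(a$abund)
  rec <- expand.grid(variable = vars, taxon = taxa,
                     stringsAsFactors = FALSE)[, c("taxon", "variable")]
  rec$family <- vfam[match(rec$variable, vars)]
  rec$r <- NA_real_; rec$p_raw <- NA_real_
  rec$computable <- TRUE
  for (i in seq_len(nrow(rec))) {
    x <- a$abund[, rec$taxon[i]]
    y <- nut[, rec$variable[i]]
    if (sd(x) == 0 || sd(y) == 0) { rec$computable[i] <- FALSE; next }
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    rec$r[i] <- unname(ct$estimate)
    rec$p_raw[i] <- ct$p.value
  }
  rec$p_adj <- NA_real_
  if (family == "global") {
    comp <- rec$computable
    rec$p_adj[comp] <- p.adjust(rec$p_raw[comp], method = "bonferroni")
  } else {
    for (tx in taxa) {
      sel <- rec$taxon == tx & rec$computable
      rec$p_adj[sel] <- p.adjust(rec$p_raw[sel], method = "bonferroni")
    }
  }
  rec$significant <- rec$computable & rec$p_adj < alpha
  attr(rec, "alpha") <- alpha
  class(rec) <- c("correlation_records", "data.frame")
  rec
}

COUPLING_LABELS <- c("coupled_positive", "coupled_negative", "decoupled_N",
                     "decoupled_P", "inconsistent", "none")

#' Label taxa as coupled or decoupled from their correlation records
#'
#' A taxon is `coupled_positive`/`coupled_negative` when it has at least
#' one significant correlation with each variable family and all its
#' significant correlations share one sign; `decoupled_N`/`decoupled_P`
#' when significant in exactly one family; `inconsistent` when significant
#' in both families with mixed signs; `none` otherwise. Every taxon gets
#' exactly one label.
#'
#' @param records output of [correlate_taxa()] for one marker-group/rank
#'   family
#' @return data.frame of class `coupling_labels` with `taxon`, `label`,
#'   `n_sig_N`, `n_sig_P`; the records are attached as attribute
#'   `"records"`
#' @export
classify_taxa <- function(records) {
  stopifnot(inherits(records, "correlation_records"))
  taxa <- unique(records$taxon)
  lab <- character(length(taxa))
  nN <- integer(length(taxa)); nP <- integer(length(taxa))
  for (i in seq_along(taxa)) {
    s <- records[records$taxon == taxa[i] & records$significant, ]
    nN[i] <- sum(s$family == "N"); nP[i] <- sum(s$family == "P")
    lab[i] <- if (nN[i] > 0 && nP[i] > 0) {
      if (all(s$r > 0)) "coupled_positive"
      else if (all(s$r < 0)) "coupled_negative"
      else "inconsistent"
    } else if (nN[i] > 0) "decoupled_N"
    else if (nP[i] > 0) "decoupled_P"
    else "none"
  }
  out <- data.frame(taxon = taxa, label = lab, n_sig_N = nN, n_sig_P = nP)
  attr(out, "records") <- records
  class(out) <- c("coupling_labels", "data.frame")
  out
}

#' Regress coupled-taxon abundances on net-Nmin/AP
#'
#' Ordinary least squares of relative abundance on the net-Nmin/AP ratio,
#' for coupled taxa only, with Bonferroni adjustment over the number of
#' coupled taxa tested.
#'
#' @param a an `aggregated_table`
#' @param n a `nutrient_table` covering the same sites
#' @param labels output of [classify_taxa()]
#' @param alpha significance level on adjusted p (default 0.05)
#' @return data.frame with `taxon`, `slope`, `intercept`, `r_squared`,
#'   `p_raw`, `p_adj`, `significant`
#' @export
regress_vs_nmin_ap <- function(a, n, labels, alpha = 0.05) {
  stopifnot(inherits(a, "aggregated_table"), inherits(n, "nutrient_table"),
            inherits(labels, "coupling_labels"))
  sites <- rownames(a$abund)
  if (length(sites) < 3) stop("need at least 3 sites for regression")
  idx <- match(sites, n$site_id)
  if (anyNA(idx)) stop("nutrient table missing site(s): ",
                       paste(sites[is.na(idx)], collapse = ", "))
  ratio <- n$nmin_ap[idx]
  coupled <- labels$taxon[labels$label %in% c("coupled_positive",
                                              "coupled_negative")]
  out <- data.frame(taxon = coupled, slope = NA_real_, intercept = NA_real_,
                    r_squared = NA_real_, p_raw = NA_real_)
  for (i in seq_along(coupled)) {
    fit <- lm(a$abund[, coupled[i]] ~ ratio)
    sm <- summary(fit)
    out$slope[i] <- coef(fit)[["ratio"]]
    out$intercept[i] <- coef(fit)[["(Intercept)"]]
    out$r_squared[i] <- sm$r.squared
    out$p_raw[i] <- sm$coefficients["ratio", "Pr(>|t|)"]
  }
  out$p_adj <- p.adjust(out$p_raw, method = "bonferroni")
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Test coupled-taxon enrichment in coupled sites
#'
#' One-sided Mann-Whitney rank test (coupled sites > decoupled sites) of
#' each coupled taxon's relative abundance, Benjamini-Hochberg adjusted
#' across the taxa tested. Normal approximation with continuity
#' correction throughout (abundances may tie at zero).
#'
#' @param a an `aggregated_table`
#' @param sites output of [classify_sites()]; both classes must be
#'   nonempty
#' @param labels output of [classify_taxa()]
#' @param alpha significance level on adjusted p (default 0.05)
#' @return data.frame with `taxon`, `mean_coupled`, `mean_decoupled`, `p`,
#'   `p_adj`, `enriched`
#' @export
test_enrichment <- function(a, sites, labels, alpha = 0.05) {
  stopifnot(inherits(a, "aggregated_table"),
            inherits(labels, "coupling_labels"))
  idx <- match(rownames(a$abund), sites$site_id)
  if (anyNA(idx)) stop("site labels missing site(s): ",
                       paste(rownames(a$abund)[is.na(idx)], collapse = ", "))
  cls <- sites$label[idx]
  if (!any(cls == "coupled") || !any(cls == "decoupled"))
    stop("both site classes must be nonempty for the enrichment test")
  coupled <- labels$taxon[labels$label %in% c("coupled_positive",
                                              "coupled_negative")]
  out <- data.frame(taxon = coupled, mean_coupled = NA_real_,
                    mean_decoupled = NA_real_, p = NA_real_)
  for (i in seq_along(coupled)) {
    x <- a$abund[cls == "coupled", coupled[i]]
    y <- a$abund[cls == "decoupled", coupled[i]]
    out$mean_coupled[i] <- mean(x)
    out$mean_decoupled[i] <- mean(y)
    out$p[i] <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                            correct = TRUE)$p.value
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$enriched <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}
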