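# Fisher-exact enrichment of model-selected sites across annotation features.

#' Fisher's exact test for a 2x2 table
#'
#' Table layout: rows are selected / background, columns are has-feature /
#' lacks-feature, i.e. `a` = selected with feature, `b` = selected without,
#' `c` = background with, `d` = background without. The null distribution is
#' hypergeometric; the two-sided p-value sums the probabilities of all
#' tables (at fixed margins) no more probable than the observed one, and
#' `p_greater` is the upper tail P(X >= a). Probabilities are computed in
#' log space so extreme tables do not underflow.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with `odds_ratio` (sample odds ratio; `NaN` when a margin is
#'   zero), `p_two_sided`, `p_greater`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  m <- a + c      # feature-positive total
  n <- b + d      # feature-negative total
  k <- a + b      # selected total
  if (m == 0 || n == 0 || k == 0 || (c + d) == 0)
    return(list(odds_ratio = NaN, p_two_sided = 1, p_greater = 1,
                note = "zero margin: no contrast"))
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(a, m, n, k, log = TRUE)
  # "no more probable than observed" with the usual relative tolerance
  p_two <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  p_greater <- stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p_two_sided = min(p_two, 1), p_greater = p_greater)
}

#' Enrichment of selected sites across annotation features
#'
#' Tests whether the model's selected (nonzero-coefficient) sites are
#' enriched, relative to all sites available to the model at training, for:
#' SNP-class probes; among CpG probes, a SNP in the probe body / CpG site /
#' single-base-extension site (`snp_in_probe`) and known mQTL status; each
#' chromosome versus the rest; and each CpG-island relation level versus the
#' rest. One Fisher exact test per feature level; no multiple-testing
#' correction is applied to the 0.05 significance flag, but a
#' Benjamini-Hochberg column is emitted for transparency.
#'
#' @param model an `ethnicity_model`.
#' @param ann annotation data.frame covering all model sites.
#' @return data.frame with one row per feature: cell counts, odds ratio,
#'   two-sided and upper-tail p-values, BH-adjusted p, significance flag.
#' @export
enrichment_report <- function(model, ann) {
  background <- model$model_sites
  sel <- selected_sites(model)
  if (length(sel) == 0) {
    message("model has no selected sites; empty enrichment report")
    return(data.frame())
  }
  idx <- match(background, ann$site_id)
  if (anyNA(idx))
    stop(sprintf("annotation missing %d model site(s)", sum(is.na(idx))))
  ann_bg <- ann[idx, , drop = FALSE]
  in_sel <- background %in% sel
  is_cpg <- ann_bg$probe_class == "CpG"

  one_test <- function(feature_name, has, subset = rep(TRUE, length(background))) {
    has <- has & subset
    has[is.na(has)] <- FALSE
    a <- sum(in_sel & has & subset)
    b <- sum(in_sel & !has & subset)
    c_ <- sum(!in_sel & has & subset)
    d <- sum(!in_sel & !has & subset)
    ft <- fisher_exact_2x2(a, b, c_, d)
    data.frame(feature = feature_name, a = a, b = b, c = c_, d = d,
               odds_ratio = ft$odds_ratio, p_two_sided = ft$p_two_sided,
               p_greater = ft$p_greater, stringsAsFactors = FALSE)
  }

  rows <- list(one_test("snp_probe", ann_bg$probe_class == "SNP"))
  if ("snp_in_probe" %in% names(ann_bg))
    rows <- c(rows, list(one_test("snp_in_probe", ann_bg$snp_in_probe, is_cpg)))
  else warning("annotation lacks snp_in_probe; skipped")
  if ("mqtl" %in% names(ann_bg))
    rows <- c(rows, list(one_test("mqtl", ann_bg$mqtl, is_cpg)))
  else warning("annotation lacks mqtl; skipped")
  if ("chromosome" %in% names(ann_bg)) {
    for (chr in intersect(c(as.character(1:22), "X", "Y"), unique(ann_bg$chromosome)))
      rows <- c(rows, list(one_test(paste0("chr", chr), ann_bg$chromosome == chr)))
  }
  if ("island_relation" %in% names(ann_bg)) {
    for (lev in intersect(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
                          unique(ann_bg$island_relation)))
      rows <- c(rows, list(one_test(paste0("island_", lev), ann_bg$island_relation == lev)))
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_two_sided, method = "BH")
  out$significant <- out$p_two_sided < 0.05
  rownames(out) <- NULL
  out
}
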