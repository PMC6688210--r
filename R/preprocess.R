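# QC / filtering cascade for methylation beta matrices.
# Order follows array-processing practice: platform overlap -> probe quality ->
# imputation -> cross-hybridizing / non-variable removal -> sample QC (sex
# concordance, inter-array correlation) -> BMIQ normalization.

filter_step <- function(step, kind, ids, params = list()) {
  list(step = step, kind = kind, n_removed = length(ids),
       ids = as.character(ids), params = params)
}

#' Default preprocessing configuration
#'
#' All thresholds default to the standard values used for Infinium placental
#' array processing: a site is dropped when more than `max_fail_fraction` of
#' samples fail it (detection p > `detect_thresh` or bead count <
#' `min_beads`), samples need a mean inter-array correlation of at least
#' `min_interarray_r`, and missing values are imputed from the `knn_k`
#' nearest sites.
#'
#' @param max_fail_fraction site dropped iff failing fraction strictly exceeds this.
#' @param detect_thresh detection p-value above which a measurement fails.
#' @param min_beads bead count below which a measurement fails.
#' @param knn_k neighbours for KNN imputation.
#' @param min_interarray_r minimum mean inter-array Pearson correlation.
#' @param bmiq_enabled run beta-mixture quantile normalization.
#' @param bmiq_min_probes minimum probes per design type for BMIQ.
#' @param platform_overlap,quality_filter,impute,flagged_sites,sex_check,interarray
#'   logical switches for the individual cascade steps.
#' @param drop_flags annotation flags whose sites are removed.
#' @return a named list of settings.
#' @export
preprocess_config <- function(max_fail_fraction = 0.01, detect_thresh = 0.01,
                              min_beads = 3, knn_k = 10, min_interarray_r = 0.95,
                              bmiq_enabled = TRUE, bmiq_min_probes = 500,
                              platform_overlap = TRUE, quality_filter = TRUE,
                              impute = TRUE, flagged_sites = TRUE,
                              sex_check = TRUE, interarray = TRUE,
                              drop_flags = c("cross_hybridizing", "nonvariable")) {
  as.list(environment())
}

#' Restrict a beta matrix to sites present on both array platforms
#'
#' Keeps only sites flagged `on_epic` in the annotation, so that models are
#' portable between the 450K and EPIC platforms. SNP-class probes are
#' retained like any other site (their genetic signal is the point).
#'
#' @param bm a [beta_matrix]
#' @param ann annotation data.frame (see [read_annotation()]).
#' @return list with elements `bm` and `report` (a filter step record).
#' @export
restrict_to_platform_overlap <- function(bm, ann) {
  idx <- match(site_ids(bm), ann$site_id)
  if (anyNA(idx)) {
    missing_ids <- site_ids(bm)[is.na(idx)]
    stop(sprintf("unannotated site(s): %s%s",
                 paste(utils::head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) sprintf(" (+%d more)", length(missing_ids) - 5) else ""))
  }
  keep <- ann$on_epic[idx]
  dropped <- site_ids(bm)[!keep]
  list(bm = bm_subset(bm, sites = keep),
       report = filter_step("platform_overlap", "sites", dropped))
}

#' Remove sites with too many failed measurements
#'
#' A measurement fails iff its detection p-value exceeds `detect_thresh` or
#' its bead count is strictly below `min_beads`. A site is removed iff its
#' failing-sample fraction strictly exceeds `max_fail_fraction` (the "greater
#' than 1 percent" rule). Failed measurements on surviving sites are set to
#' missing so that imputation can replace them. Absent layers contribute no
#' failures; with neither layer present the step is a no-op with a warning.
#'
#' @inheritParams restrict_to_platform_overlap
#' @param max_fail_fraction,detect_thresh,min_beads see [preprocess_config()].
#' @return list with elements `bm` and `report`.
#' @export
filter_poor_quality_sites <- function(bm, max_fail_fraction = 0.01,
                                      detect_thresh = 0.01, min_beads = 3) {
  if (is.null(bm$detection_p) && is.null(bm$bead_count)) {
    warning("no detection_p or bead_count layer present; quality filter is a no-op")
    return(list(bm = bm, report = filter_step("quality_filter", "sites", character(0),
                                              list(note = "no QC layers"))))
  }
  fails <- matrix(FALSE, nrow(bm$beta), ncol(bm$beta), dimnames = dimnames(bm$beta))
  if (!is.null(bm$detection_p)) fails <- fails | (bm$detection_p > detect_thresh)
  if (!is.null(bm$bead_count)) fails <- fails | (bm$bead_count < min_beads)
  fails[is.na(fails)] <- FALSE
  frac <- rowMeans(fails)
  drop <- frac > max_fail_fraction
  dropped <- site_ids(bm)[drop]
  beta <- bm$beta
  beta[fails] <- NA
  kept <- !drop
  out <- beta_matrix(beta[kept, , drop = FALSE],
                     if (!is.null(bm$detection_p)) bm$detection_p[kept, , drop = FALSE],
                     if (!is.null(bm$bead_count)) bm$bead_count[kept, , drop = FALSE])
  list(bm = out,
       report = filter_step("quality_filter", "sites", dropped,
                            list(max_fail_fraction = max_fail_fraction,
                                 detect_thresh = detect_thresh, min_beads = min_beads)))
}

#' KNN imputation of missing beta values
#'
#' Each missing measurement is replaced by the mean of the `k` nearest sites'
#' values at that sample. Nearness between two sites is the Euclidean
#' distance over the samples observed in both, scaled by
#' `sqrt(shared / total)` so that distances are comparable across missingness
#' patterns (a site pair sharing few samples is not spuriously close).
#' Observed values are never altered.
#'
#' @inheritParams restrict_to_platform_overlap
#' @param k number of neighbouring sites to average.
#' @return a [beta_matrix] with no missing values.
#' @export
impute_knn <- function(bm, k = 10) {
  beta <- bm$beta
  if (!anyNA(beta)) return(bm)
  all_missing <- rowSums(!is.na(beta)) == 0
  if (any(all_missing))
    stop(sprintf("site(s) with all values missing cannot be imputed: %s",
                 paste(utils::head(site_ids(bm)[all_missing], 5), collapse = ", ")))
  n_sites <- nrow(beta)
  if (k > n_sites - 1) {
    warning(sprintf("k = %d exceeds available sites; using all %d other sites", k, n_sites - 1))
    k <- n_sites - 1
  }
  n_samp <- ncol(beta)
  miss_rows <- which(rowSums(is.na(beta)) > 0)
  obs <- !is.na(beta)
  for (i in miss_rows) {
    xi <- beta[i, ]
    oi <- obs[i, ]
    # shared observed counts and scaled distances to every other site
    shared <- obs %*% oi                       # n_sites x 1
    diffs <- sweep(beta, 2, xi)
    diffs[!obs | matrix(!oi, n_sites, n_samp, byrow = TRUE)] <- 0
    ss <- rowSums(diffs^2)
    # sqrt(shared/total) scaling <=> distance computed as sqrt(total * mean sq diff)
    d <- sqrt(ss / pmax(shared[, 1], 1) * n_samp)
    d[i] <- Inf
    d[shared[, 1] == 0] <- Inf
    for (j in which(is.na(beta[i, ]))) {
      cand <- which(obs[, j] & is.finite(d))
      if (length(cand) == 0)
        stop(sprintf("no neighbour with an observed value for site %s, sample %s",
                     rownames(beta)[i], colnames(beta)[j]))
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      beta[i, j] <- mean(beta[nb, j])
    }
  }
  beta_matrix(beta, bm$detection_p, bm$bead_count)
}

#' Remove annotation-flagged sites
#'
#' Drops sites carrying any of the listed annotation flags (by default
#' cross-hybridizing probes and tissue-specific non-variable sites).
#' SNP-class probes are exempt from the `nonvariable` flag: their trimodal,
#' genotype-driven signal is exactly what downstream models exploit.
#'
#' @inheritParams restrict_to_platform_overlap
#' @param drop character vector of logical annotation columns.
#' @return list with elements `bm` and `report`.
#' @export
remove_flagged_sites <- function(bm, ann, drop = c("cross_hybridizing", "nonvariable")) {
  idx <- match(site_ids(bm), ann$site_id)
  flagged <- rep(FALSE, nrow(bm$beta))
  is_snp <- !is.na(idx) & ann$probe_class[idx] == "SNP"
  for (fl in drop) {
    v <- ann[[fl]][idx]
    v[is.na(v)] <- FALSE
    if (fl == "nonvariable") v[is_snp] <- FALSE
    flagged <- flagged | v
  }
  dropped <- site_ids(bm)[flagged]
  list(bm = bm_subset(bm, sites = !flagged),
       report = filter_step("flagged_sites", "sites", dropped, list(flags = drop)))
}

#' Infer sample sex from sex-chromosome methylation
#'
#' Average-linkage hierarchical clustering (Euclidean distance) on the
#' betas of chromosome X/Y sites, cut at two clusters; the cluster with the
#' higher mean chrY methylation is labelled male. When a reported sex is
#' supplied, a concordance flag is returned per sample so that callers can
#' drop mismatches.
#'
#' @inheritParams restrict_to_platform_overlap
#' @param reported_sex optional character vector ("M"/"F"/NA) aligned with samples.
#' @return data.frame with `sample_id`, `inferred_sex`, `reported_sex`, `concordant`.
#' @export
infer_sex <- function(bm, ann, reported_sex = NULL) {
  idx <- match(site_ids(bm), ann$site_id)
  chr <- ann$chromosome[idx]
  sex_sites <- which(chr %in% c("X", "Y"))
  if (length(sex_sites) < 2) stop("need at least 2 sex-chromosome sites to infer sex")
  if (ncol(bm$beta) < 2) stop("need at least 2 samples to infer sex")
  m <- t(bm$beta[sex_sites, , drop = FALSE])   # samples x sex sites
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  cl <- stats::cutree(hc, k = 2)
  y_sites <- which(chr[sex_sites] == "Y")
  if (length(y_sites) == 0) {
    warning("no chrY sites present; sex labels assigned by chrX mean (lower = male)")
    x_mean <- tapply(rowMeans(m), cl, mean)
    male_cluster <- as.integer(names(which.min(x_mean)))
    inferred <- ifelse(cl == male_cluster, "M", "F")
  } else {
    y_by_sample <- rowMeans(m[, y_sites, drop = FALSE])
    y_mean <- tapply(y_by_sample, cl, mean)
    if (diff(range(y_mean)) < 0.2) {
      # degenerate: the two clusters show no chrY dimorphism (e.g. a
      # single-sex cohort); assign every sample by its global chrY level
      warning("samples do not separate into two sex clusters; assigning all by chrY level")
      inferred <- ifelse(y_by_sample > 0.45, "M", "F")
    } else {
      male_cluster <- as.integer(names(which.max(y_mean)))
      inferred <- ifelse(cl == male_cluster, "M", "F")
    }
  }
  if (is.null(reported_sex)) reported_sex <- rep(NA_character_, ncol(bm$beta))
  concordant <- ifelse(is.na(reported_sex), NA, inferred == reported_sex)
  data.frame(sample_id = sample_ids(bm), inferred_sex = unname(inferred),
             reported_sex = reported_sex, concordant = concordant,
             stringsAsFactors = FALSE)
}

#' Filter samples by mean inter-array correlation
#'
#' For each sample, the mean Pearson correlation of its beta vector with
#' every other sample (pairwise-complete observations); samples whose mean
#' correlation falls strictly below `min_r` are removed.
#'
#' @inheritParams restrict_to_platform_overlap
#' @param min_r removal threshold on the mean correlation.
#' @return list with `bm`, `mean_r` (named vector), `report`.
#' @export
interarray_correlation_filter <- function(bm, min_r = 0.95) {
  n <- ncol(bm$beta)
  if (n < 3) stop("need at least 3 samples for a stable mean inter-array correlation")
  cc <- stats::cor(bm$beta, use = "pairwise.complete.obs")
  diag(cc) <- NA
  mean_r <- rowMeans(cc, na.rm = TRUE)
  drop <- mean_r < min_r
  if (all(drop))
    stop(sprintf("all samples fall below min_r = %g (mean inter-array r range %.3f-%.3f); threshold unsuitable for these data",
                 min_r, min(mean_r), max(mean_r)))
  dropped <- sample_ids(bm)[drop]
  list(bm = bm_subset(bm, samples = !drop),
       mean_r = mean_r,
       report = filter_step("interarray_correlation", "samples", dropped,
                            list(min_r = min_r)))
}

#' Run the full preprocessing cascade
#'
#' Executes, in order: platform-overlap restriction, probe quality filter,
#' KNN imputation, flagged-site removal, sex-concordance sample removal,
#' inter-array correlation sample removal, and BMIQ normalization. Each step
#' can be switched off via the config; the filter report records every step
#' in execution order with the exact ids removed.
#'
#' @inheritParams restrict_to_platform_overlap
#' @param sheet sample sheet data.frame (see [read_sample_sheet()]); may be
#'   `NULL`, in which case the sex-concordance step is skipped.
#' @param config list from [preprocess_config()].
#' @return list with `bm` (analysis-ready [beta_matrix]), `sheet` (restricted
#'   to surviving samples), and `reports` (list of filter step records).
#' @export
run_preprocess <- function(bm, ann, sheet = NULL, config = preprocess_config()) {
  reports <- list()
  if (isTRUE(config$platform_overlap)) {
    st <- restrict_to_platform_overlap(bm, ann)
    bm <- st$bm; reports <- c(reports, list(st$report))
  }
  if (isTRUE(config$quality_filter)) {
    has_layers <- !is.null(bm$detection_p) || !is.null(bm$bead_count)
    if (has_layers) {
      st <- filter_poor_quality_sites(bm, config$max_fail_fraction,
                                      config$detect_thresh, config$min_beads)
      bm <- st$bm; reports <- c(reports, list(st$report))
    }
  }
  if (isTRUE(config$impute) && anyNA(bm$beta)) {
    bm <- impute_knn(bm, k = config$knn_k)
    reports <- c(reports, list(filter_step("knn_imputation", "sites", character(0),
                                           list(k = config$knn_k))))
  }
  if (isTRUE(config$flagged_sites)) {
    st <- remove_flagged_sites(bm, ann, drop = config$drop_flags)
    bm <- st$bm; reports <- c(reports, list(st$report))
  }
  # outlier arrays are removed before the sex-concordance clustering so a
  # noise sample cannot distort the two sex clusters
  if (isTRUE(config$interarray) && ncol(bm$beta) >= 3) {
    st <- interarray_correlation_filter(bm, min_r = config$min_interarray_r)
    bm <- st$bm; reports <- c(reports, list(st$report))
  }
  if (isTRUE(config$sex_check) && !is.null(sheet)) {
    idx <- match(sample_ids(bm), sheet$sample_id)
    rep_sex <- sheet$reported_sex[idx]
    sex <- tryCatch(infer_sex(bm, ann, reported_sex = rep_sex),
                    error = function(e) NULL)
    if (!is.null(sex)) {
      mism <- !is.na(sex$concordant) & !sex$concordant
      reports <- c(reports, list(filter_step("sex_concordance", "samples",
                                             sex$sample_id[mism])))
      if (any(mism)) bm <- bm_subset(bm, samples = !mism)
    }
  }
  if (isTRUE(config$bmiq_enabled)) {
    bm <- bmiq_normalize(bm, ann, min_probes = config$bmiq_min_probes)
    reports <- c(reports, list(filter_step("bmiq", "sites", character(0),
                                           list(min_probes = config$bmiq_min_probes))))
  }
  if (!is.null(sheet))
    sheet <- sheet[match(sample_ids(bm), sheet$sample_id), , drop = FALSE]
  list(bm = bm, sheet = sheet, reports = reports)
}

#' Render a filter report as a data.frame
#' @param reports list of filter step records from [run_preprocess()].
#' @return data.frame with step, kind, n_removed.
#' @export
filter_report_table <- function(reports) {
  data.frame(step = vapply(reports, `[[`, "", "step"),
             kind = vapply(reports, `[[`, "", "kind"),
             n_removed = vapply(reports, `[[`, 0L, "n_removed"),
             stringsAsFactors = FALSE)
}
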