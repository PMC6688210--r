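# PCA variance-explained framework for comparing population-structure
# inference methods on method-specific site subsets.

#' Standardize beta values per site
#'
#' Subtracts the across-sample mean and divides by the across-sample SD for
#' each site; zero-variance sites are dropped with a warning.
#'
#' @param bm a [beta_matrix] or sites x samples matrix.
#' @param sites optional character vector restricting to a site subset.
#' @return standardized sites x samples matrix.
#' @export
standardize_betas <- function(bm, sites = NULL) {
  m <- if (inherits(bm, "beta_matrix")) bm$beta else as.matrix(bm)
  if (!is.null(sites)) {
    sites <- intersect(sites, rownames(m))
    if (length(sites) == 0) stop("empty site set after intersection with matrix")
    m <- m[sites, , drop = FALSE]
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  zero <- !is.finite(sdv) | sdv < 1e-12
  if (any(zero)) {
    warning(sprintf("%d zero-variance site(s) dropped before standardization", sum(zero)))
    m <- m[!zero, , drop = FALSE]; mu <- mu[!zero]; sdv <- sdv[!zero]
  }
  if (nrow(m) == 0) stop("no variable sites to standardize")
  sweep(sweep(m, 1, mu), 1, sdv, "/")
}

#' Principal component scores of samples
#'
#' PCA with sites as variables (covariance of the standardized matrix).
#' Components are ordered by decreasing explained variance; the sign of each
#' component is fixed so the loading element with the largest magnitude is
#' positive.
#'
#' @param std_matrix standardized sites x samples matrix
#'   (see [standardize_betas()]).
#' @param n_components number of PCs to return (clamped to what the data
#'   supports, with a warning).
#' @return list with `scores` (samples x PCs), `loadings` (sites x PCs), and
#'   `var_explained` (fraction of total variance per returned PC).
#' @export
pca_scores <- function(std_matrix, n_components = 10) {
  x <- t(std_matrix)                       # samples x sites
  max_pc <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_pc) {
    warning(sprintf("n_components clamped from %d to %d", n_components, max_pc))
    n_components <- max_pc
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    top <- which.max(abs(loadings[, i]))
    if (loadings[top, i] < 0) {
      loadings[, i] <- -loadings[, i]
      scores[, i] <- -scores[, i]
    }
  }
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       var_explained = var_explained[seq_len(k)])
}

#' Variance in a principal component explained by a covariate
#'
#' Ordinary least-squares regression of each PC on the covariate. A factor
#' (or character) covariate is expanded to indicator variables in one joint
#' model; a matrix covariate (e.g. two ancestry coordinates) enters as a
#' joint model; a numeric vector enters as a simple regression.
#'
#' @param pc_scores samples x PCs matrix.
#' @param covariate numeric vector, factor/character vector, or numeric
#'   matrix aligned with the samples.
#' @return named numeric vector of R-squared values, one per PC, in \[0,1\].
#'   A constant covariate yields 0 with a warning.
#' @export
variance_explained <- function(pc_scores, covariate) {
  pc_scores <- as.matrix(pc_scores)
  if (is.character(covariate)) covariate <- factor(covariate)
  X <- if (is.factor(covariate)) {
    if (nlevels(droplevels(covariate)) < 2) NULL
    else stats::model.matrix(~ droplevels(covariate))[, -1, drop = FALSE]
  } else {
    cm <- as.matrix(covariate)
    keep <- apply(cm, 2, function(v) stats::sd(v) > 1e-12)
    if (!any(keep)) NULL else cm[, keep, drop = FALSE]
  }
  if (is.null(X)) {
    warning("constant covariate: R-squared undefined, returning 0")
    return(stats::setNames(rep(0, ncol(pc_scores)), colnames(pc_scores)))
  }
  r2 <- apply(pc_scores, 2, function(pc) {
    fit <- stats::lm(pc ~ X)
    summary(fit)$r.squared
  })
  stats::setNames(r2, colnames(pc_scores))
}

#' Nested CpG site sets by distance to the nearest genetic variant
#'
#' Set `d` contains every CpG site whose `dist_to_variant` annotation is at
#' most `d` bp; the sets are nested (0 within 1 within 2 ... within 50).
#'
#' @param ann annotation data.frame with a `dist_to_variant` column.
#' @param distances distance cutoffs in bp.
#' @return named list of site-id vectors (`snp_adjacent_d<d>`).
#' @export
barfield_distance_sets <- function(ann, distances = c(0, 1, 2, 5, 10, 50)) {
  if (!"dist_to_variant" %in% names(ann))
    stop("annotation lacks dist_to_variant")
  cpg <- ann$probe_class == "CpG"
  out <- lapply(distances, function(d)
    ann$site_id[cpg & !is.na(ann$dist_to_variant) & ann$dist_to_variant <= d])
  stats::setNames(out, paste0("snp_adjacent_d", distances))
}

#' Default site-set registry
#'
#' Builds the standard named subsets used for method comparison: the 59-SNP
#' probe set, the variant-distance sets, and (when a fitted model is given)
#' the classifier-selected sites.
#'
#' @param ann annotation data.frame.
#' @param model optional `ethnicity_model` contributing its selected sites.
#' @return named list of site-id vectors.
#' @export
default_site_sets <- function(ann, model = NULL) {
  reg <- c(list(snp59 = ann$site_id[ann$probe_class == "SNP"]),
           barfield_distance_sets(ann))
  if (!is.null(model)) reg$classifier_selected <- selected_sites(model)
  bad <- vapply(reg, function(s) length(setdiff(s, ann$site_id)) > 0, TRUE)
  if (any(bad))
    stop(sprintf("site set(s) with unannotated sites: %s",
                 paste(names(reg)[bad], collapse = ", ")))
  reg
}

#' Compare site subsets by PCA variance explained
#'
#' For every registered site set and every cohort: standardize betas within
#' the cohort, compute the top PCs, and regress each PC on self-reported
#' ethnicity (indicator encoding, one joint model), on each available
#' covariate, and — when ancestry coordinates are supplied — on each single
#' coordinate and on coordinates 1+2 jointly. For the classifier-derived
#' set, per-cohort held-out models (e.g. from [lodocv()]) should be supplied
#' so a cohort is never scored on sites selected using its own samples.
#'
#' @param bm a [beta_matrix].
#' @param ann annotation data.frame.
#' @param sheet sample sheet (provides `dataset_id`, `reported_ethnicity`,
#'   covariate columns).
#' @param registry named list of site-id vectors (see [default_site_sets()]).
#' @param ancestry optional samples x coordinates matrix of genetic-ancestry
#'   coordinates (rownames = sample ids).
#' @param lodocv_models optional named list (by dataset id) of
#'   `ethnicity_model`s; adds a `classifier_selected` set per cohort using
#'   the model trained with that cohort held out.
#' @param covariates character vector of sheet columns to test.
#' @param n_components PCs per site set.
#' @return data.frame with columns `cohort`, `site_set`, `pc`, `covariate`,
#'   `r2`, `var_explained`.
#' @export
compare_methods <- function(bm, ann, sheet, registry, ancestry = NULL,
                            lodocv_models = NULL, covariates = character(0),
                            n_components = 10) {
  rows <- list()
  for (d in unique(sheet$dataset_id)) {
    samp <- intersect(sheet$sample_id[sheet$dataset_id == d], sample_ids(bm))
    if (length(samp) < 3) next
    bm_d <- bm_subset(bm, samples = sample_ids(bm) %in% samp)
    sheet_d <- sheet[match(sample_ids(bm_d), sheet$sample_id), , drop = FALSE]
    reg_d <- registry
    if (!is.null(lodocv_models) && d %in% names(lodocv_models))
      reg_d$classifier_selected <- selected_sites(lodocv_models[[d]])
    for (set_name in names(reg_d)) {
      sites <- intersect(reg_d[[set_name]], site_ids(bm_d))
      if (length(sites) == 0) {
        warning(sprintf("site set '%s' empty in cohort %s; skipped", set_name, d))
        next
      }
      std <- suppressWarnings(standardize_betas(bm_d, sites))
      k_d <- min(n_components, ncol(std) - 1, nrow(std))
      if (k_d < n_components)
        warning(sprintf("site set '%s' in cohort %s supports only %d PCs", set_name, d, k_d))
      pcs <- suppressWarnings(pca_scores(std, k_d))
      tests <- list()
      eth <- sheet_d$reported_ethnicity
      if (sum(!is.na(eth)) >= 3 && length(unique(stats::na.omit(eth))) >= 2)
        tests$ethnicity <- factor(eth)
      for (cv in covariates)
        if (cv %in% names(sheet_d)) tests[[cv]] <- sheet_d[[cv]]
      if (!is.null(ancestry)) {
        anc <- ancestry[match(sample_ids(bm_d), rownames(ancestry)), , drop = FALSE]
        if (!anyNA(anc)) {
          for (j in seq_len(ncol(anc)))
            tests[[paste0("ancestry_coord", j)]] <- anc[, j]
          if (ncol(anc) >= 2)
            tests$ancestry_joint12 <- anc[, 1:2, drop = FALSE]
        }
      }
      for (tn in names(tests)) {
        cov <- tests[[tn]]
        ok <- if (is.matrix(cov)) rowSums(is.na(cov)) == 0 else !is.na(cov)
        if (sum(ok) < 3) next
        sc <- pcs$scores[ok, , drop = FALSE]
        cv_ok <- if (is.matrix(cov)) cov[ok, , drop = FALSE] else cov[ok]
        r2 <- suppressWarnings(variance_explained(sc, cv_ok))
        rows[[length(rows) + 1]] <- data.frame(
          cohort = d, site_set = set_name, pc = seq_along(r2),
          covariate = tn, r2 = unname(r2),
          var_explained = pcs$var_explained[seq_along(r2)],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
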