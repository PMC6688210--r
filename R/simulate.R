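# Seeded generator of population-structured methylation cohorts with ground
# truth. Three ancestral populations with Balding-Nichols-differentiated
# allele frequencies drive trimodal SNP-probe betas and genotype-shifted
# mQTL CpGs; cohort batch effects and measurement noise act on the logit
# scale; QC defects (failed detections, low bead counts, noise samples, sex
# mislabels) are planted with exact bookkeeping.

#' Simulation configuration
#'
#' Defaults describe a five-cohort placental methylation study of three
#' ancestral populations at continental-scale differentiation (Fst 0.15),
#' with 59 genotyping (SNP) probes, 200 mQTL CpGs, 5000 background CpGs,
#' and a full complement of planted QC defects.
#'
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param n_snp_probes,n_mqtl_cpgs,n_background_cpgs site counts by role.
#' @param n_nonvariable,n_crosshyb,n_sexchr further site counts
#'   (non-variable, cross-hybridizing, sex-chromosome).
#' @param n_off_epic background sites flagged as absent from the EPIC array.
#' @param mqtl_effect per-allele shift of mQTL CpG means, logit scale.
#' @param n_cohorts,cohort_sizes cohort structure (sizes recycled).
#' @param batch_sd SD of per-site, per-cohort batch shifts, logit scale.
#' @param admixed_fraction fraction of samples with Dirichlet-drawn admixture.
#' @param admix_concentration Dirichlet concentration for admixed samples.
#' @param noise_sd measurement noise SD, logit scale.
#' @param n_failed_detection_sites,n_lowbead_sites sites planted to exceed
#'   the 1 percent failing-sample rule via detection p / bead count.
#' @param n_scattered_failures single failing measurements scattered on
#'   otherwise-clean sites (below the removal rule, so they get imputed).
#' @param n_noise_samples samples replaced by uniform noise (low inter-array
#'   correlation).
#' @param n_sex_mislabels samples whose reported sex is flipped in the sheet.
#' @param seed integer seed; identical seeds reproduce identical cohorts.
#' @return a named list of settings.
#' @export
simulation_config <- function(fst = 0.15, n_snp_probes = 59, n_mqtl_cpgs = 200,
                              n_background_cpgs = 5000, n_nonvariable = 300,
                              n_crosshyb = 100, n_sexchr = 40, n_off_epic = 50,
                              mqtl_effect = 0.15, n_cohorts = 5,
                              cohort_sizes = c(48, 44, 40, 36, 32),
                              batch_sd = 0.3, admixed_fraction = 0.1,
                              admix_concentration = c(1, 1, 1), noise_sd = 0.05,
                              n_failed_detection_sites = 10, n_lowbead_sites = 5,
                              n_scattered_failures = 30, n_noise_samples = 2,
                              n_sex_mislabels = 1, seed = 1) {
  cfg <- as.list(environment())
  counts <- cfg[grep("^n_", names(cfg))]
  if (any(unlist(counts) < 0)) stop("site/sample counts must be >= 0")
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  if (admixed_fraction < 0 || admixed_fraction > 1)
    stop("admixed_fraction must be in [0, 1]")
  n_defect <- n_failed_detection_sites + n_lowbead_sites + n_scattered_failures +
    n_off_epic
  if (n_defect > n_background_cpgs)
    stop("more planted defects than background sites")
  cfg
}

#' Balding-Nichols allele frequencies
#'
#' Ancestral frequencies are Uniform(0.1, 0.9); each population's frequency
#' is drawn independently from Beta(p(1-F)/F, (1-p)(1-F)/F), so the
#' across-population variance of the frequency is F p (1 - p).
#'
#' @param n_variants number of variants.
#' @param fst differentiation parameter in (0, 1).
#' @param n_populations number of populations.
#' @return list with `ancestral` (length `n_variants`) and `freq`
#'   (variants x populations matrix).
#' @export
draw_allele_frequencies <- function(n_variants, fst, n_populations = 3) {
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  p <- stats::runif(n_variants, 0.1, 0.9)
  shape <- (1 - fst) / fst
  freq <- vapply(seq_len(n_populations), function(k)
    stats::rbeta(n_variants, p * shape, (1 - p) * shape), numeric(n_variants))
  list(ancestral = p, freq = freq)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate population-structured methylation cohorts
#'
#' Generates a complete study: beta matrix with detection-p and bead-count
#' layers, sample sheet, site annotation, and a ground-truth record (true
#' admixture proportions, genotypes, sexes, site roles, planted defects).
#' Pure samples have one-hot admixture; admixed samples draw proportions
#' from a Dirichlet. Genotypes are Binomial(2, q . p_pop); SNP-probe betas
#' cluster trimodally at 0.05 / 0.5 / 0.95 (SD 0.03); mQTL CpGs shift by
#' `mqtl_effect` per alternate allele on the logit scale; cohort batch
#' shifts and measurement noise also act on the logit scale. The hard truth
#' label is `Mixed` when the largest admixture proportion is below 0.75,
#' mirroring the classifier's ambiguity rule.
#'
#' @param config a [simulation_config()].
#' @return list with `bm` ([beta_matrix]), `sheet`, `ann`, `truth`.
#' @export
simulate_cohorts <- function(config = simulation_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  pops <- ethnicity_classes()
  sizes <- rep_len(config$cohort_sizes, config$n_cohorts)
  n <- sum(sizes)
  cohort <- rep(paste0("C", seq_len(config$n_cohorts)), sizes)
  sample_id <- sprintf("S%04d", seq_len(n))

  # --- admixture proportions ---
  assigned <- unlist(lapply(sizes, function(s) pops[rep_len(1:3, s)]))
  admixed <- stats::runif(n) < config$admixed_fraction
  q <- matrix(0, n, 3, dimnames = list(sample_id, pops))
  for (i in seq_len(n)) {
    q[i, ] <- if (admixed[i]) rdirichlet1(config$admix_concentration)
              else as.numeric(pops == assigned[i])
  }
  true_label <- ifelse(apply(q, 1, max) < 0.75, "Mixed", pops[max.col(q)])
  reported <- pops[max.col(q, ties.method = "first")]
  sex <- sample(c("M", "F"), n, replace = TRUE)

  # --- site roles ---
  roles <- c(rep("snp_probe", config$n_snp_probes),
             rep("mqtl", config$n_mqtl_cpgs),
             rep("background", config$n_background_cpgs),
             rep("nonvariable", config$n_nonvariable),
             rep("crosshyb", config$n_crosshyb),
             rep("sexchr", config$n_sexchr))
  p_sites <- length(roles)
  site_id <- character(p_sites)
  site_id[roles == "snp_probe"] <- sprintf("rs%05d", seq_len(config$n_snp_probes))
  site_id[roles != "snp_probe"] <- sprintf("cg%06d", seq_len(sum(roles != "snp_probe")))

  # --- genotypes for snp probes and mQTL CpGs ---
  n_var <- config$n_snp_probes + config$n_mqtl_cpgs
  af <- draw_allele_frequencies(n_var, config$fst)
  dose <- q %*% t(af$freq)                     # n x n_var expected allele freq
  geno <- matrix(stats::rbinom(n * n_var, 2, t(dose)), nrow = n_var, ncol = n)
  variant_sites <- site_id[roles %in% c("snp_probe", "mqtl")]
  dimnames(geno) <- list(variant_sites, sample_id)

  # --- batch and noise (logit scale) ---
  batch <- matrix(stats::rnorm(p_sites * config$n_cohorts, 0, config$batch_sd),
                  p_sites, config$n_cohorts)
  cohort_idx <- match(cohort, paste0("C", seq_len(config$n_cohorts)))

  beta <- matrix(NA_real_, p_sites, n, dimnames = list(site_id, sample_id))
  snp_means <- c(`0` = 0.05, `1` = 0.5, `2` = 0.95)
  is_snp <- roles == "snp_probe"
  beta[is_snp, ] <- clip01(snp_means[as.character(geno[seq_len(config$n_snp_probes), ])] +
                             stats::rnorm(config$n_snp_probes * n, 0, 0.03))

  is_mqtl <- roles == "mqtl"
  mqtl_mu <- stats::runif(config$n_mqtl_cpgs, 0.2, 0.8)
  g_mqtl <- geno[config$n_snp_probes + seq_len(config$n_mqtl_cpgs), , drop = FALSE]
  eta <- stats::qlogis(mqtl_mu) + g_mqtl * config$mqtl_effect +
    batch[is_mqtl, cohort_idx, drop = FALSE] +
    stats::rnorm(config$n_mqtl_cpgs * n, 0, config$noise_sd)
  beta[is_mqtl, ] <- stats::plogis(eta)

  draw_bg_mu <- function(k) {
    comp <- sample(1:3, k, replace = TRUE)
    mu <- numeric(k)
    mu[comp == 1] <- stats::rbeta(sum(comp == 1), 0.5, 5)
    mu[comp == 2] <- stats::rbeta(sum(comp == 2), 5, 5)
    mu[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 0.5)
    pmin(pmax(mu, 0.01), 0.99)
  }
  for (role in c("background", "crosshyb")) {
    ix <- roles == role
    k <- sum(ix)
    mu <- draw_bg_mu(k)
    eta <- stats::qlogis(mu) + batch[ix, cohort_idx, drop = FALSE] +
      stats::rnorm(k * n, 0, config$noise_sd)
    beta[ix, ] <- stats::plogis(eta)
  }
  ix <- roles == "nonvariable"
  if (any(ix)) {
    mu <- draw_bg_mu(sum(ix))
    beta[ix, ] <- clip01(mu + stats::rnorm(sum(ix) * n, 0, 0.005))
  }
  ix_sex <- which(roles == "sexchr")
  sex_chr <- rep(c("X", "Y"), length.out = length(ix_sex))
  for (jj in seq_along(ix_sex)) {
    mu <- if (sex_chr[jj] == "Y") ifelse(sex == "M", 0.8, 0.1)
          else ifelse(sex == "M", 0.8, 0.5)
    beta[ix_sex[jj], ] <- clip01(mu + stats::rnorm(n, 0, 0.03))
  }

  # --- QC layers and planted defects ---
  detection_p <- matrix(stats::runif(p_sites * n, 0, 0.005), p_sites, n,
                        dimnames = dimnames(beta))
  bead_count <- matrix(sample(5:25, p_sites * n, replace = TRUE), p_sites, n,
                       dimnames = dimnames(beta))
  bg_pool <- which(roles == "background")
  n_planted <- config$n_off_epic + config$n_failed_detection_sites +
    config$n_lowbead_sites + config$n_scattered_failures
  planted <- sample(bg_pool, n_planted)
  take <- function(k) {
    out <- planted[seq_len(k)]
    planted <<- planted[-seq_len(k)]
    out
  }
  off_epic_idx <- take(config$n_off_epic)
  fail_min <- floor(0.01 * n) + 1         # strictly more than 1% of samples
  failed_idx <- take(config$n_failed_detection_sites)
  for (i in failed_idx) {
    cells <- sample(n, fail_min + sample(0:2, 1))
    detection_p[i, cells] <- stats::runif(length(cells), 0.02, 0.5)
  }
  lowbead_idx <- take(config$n_lowbead_sites)
  for (i in lowbead_idx) {
    cells <- sample(n, fail_min + sample(0:2, 1))
    bead_count[i, cells] <- sample(0:2, length(cells), replace = TRUE)
  }
  scattered_idx <- take(config$n_scattered_failures)
  scattered_cells <- cbind(site = scattered_idx, sample = sample(n, length(scattered_idx), replace = TRUE))
  for (r in seq_len(nrow(scattered_cells)))
    detection_p[scattered_cells[r, 1], scattered_cells[r, 2]] <- stats::runif(1, 0.02, 0.5)

  noise_samples <- if (config$n_noise_samples > 0) sample(n, config$n_noise_samples) else integer(0)
  for (j in noise_samples) beta[, j] <- stats::runif(p_sites)
  mislabel_pool <- setdiff(seq_len(n), noise_samples)
  sex_mislabels <- if (config$n_sex_mislabels > 0)
    sample(mislabel_pool, config$n_sex_mislabels) else integer(0)
  reported_sex <- sex
  reported_sex[sex_mislabels] <- ifelse(sex[sex_mislabels] == "M", "F", "M")

  # --- annotation ---
  chromosome <- sample(as.character(1:22), p_sites, replace = TRUE)
  chromosome[ix_sex] <- sex_chr
  snp_in_probe <- rep(FALSE, p_sites)
  mqtl_rows <- which(is_mqtl)
  snp_in_probe[sample(mqtl_rows, floor(length(mqtl_rows) / 2))] <- TRUE
  snp_in_probe[sample(bg_pool, max(1, floor(0.02 * length(bg_pool))))] <- TRUE
  dist_to_variant <- rep(NA_real_, p_sites)
  dist_to_variant[is_snp] <- 0
  dist_to_variant[snp_in_probe] <- 0
  linked_no_snp <- is_mqtl & !snp_in_probe
  dist_to_variant[linked_no_snp] <- sample(c(1, 2, 5, 10, 50), sum(linked_no_snp), replace = TRUE)
  far_bg <- roles == "background" & is.na(dist_to_variant) & stats::runif(p_sites) < 0.1
  dist_to_variant[far_bg] <- sample(c(1, 2, 5, 10, 50), sum(far_bg), replace = TRUE)
  on_epic <- rep(TRUE, p_sites)
  on_epic[off_epic_idx] <- FALSE
  ann <- data.frame(
    site_id = site_id,
    probe_class = ifelse(is_snp, "SNP", "CpG"),
    design_type = sample(c("I", "II"), p_sites, replace = TRUE, prob = c(0.28, 0.72)),
    chromosome = chromosome,
    island_relation = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
                             p_sites, replace = TRUE,
                             prob = c(0.31, 0.13, 0.10, 0.05, 0.04, 0.37)),
    on_epic = on_epic,
    cross_hybridizing = roles == "crosshyb",
    nonvariable = roles == "nonvariable",
    snp_in_probe = snp_in_probe,
    dist_to_variant = dist_to_variant,
    mqtl = as.logical(is_mqtl),
    stringsAsFactors = FALSE)

  sheet <- data.frame(
    sample_id = sample_id,
    dataset_id = cohort,
    reported_ethnicity = reported,
    reported_sex = reported_sex,
    gestational_age = round(stats::rnorm(n, 38.5, 2), 1),
    array_row = sample(1:6, n, replace = TRUE),
    stringsAsFactors = FALSE)

  truth_samples <- data.frame(
    sample_id = sample_id, cohort = cohort,
    q_African = q[, "African"], q_Asian = q[, "Asian"], q_Caucasian = q[, "Caucasian"],
    true_label = true_label, admixed = admixed, sex = sex,
    noise_sample = seq_len(n) %in% noise_samples,
    sex_mislabeled = seq_len(n) %in% sex_mislabels,
    stringsAsFactors = FALSE)
  truth_sites <- data.frame(
    site_id = site_id, role = roles,
    failed_detection = seq_len(p_sites) %in% failed_idx,
    low_bead = seq_len(p_sites) %in% lowbead_idx,
    scattered_failure = seq_len(p_sites) %in% scattered_idx,
    off_epic = seq_len(p_sites) %in% off_epic_idx,
    stringsAsFactors = FALSE)

  bm <- beta_matrix(beta, detection_p = detection_p, bead_count = bead_count)
  truth <- list(samples = truth_samples, sites = truth_sites,
                genotypes = geno, allele_freq = af,
                scattered_cells = scattered_cells, config = config)
  list(bm = bm, sheet = sheet, ann = ann, truth = truth)
}
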