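# Shared fixtures: all built in code at test time.

# A reduced study: 3 cohorts, 102 samples, ~610 sites. Big enough for the
# QC cascade and classifier to behave, small enough for fast tests.
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    n_background_cpgs = 400, n_mqtl_cpgs = 60, n_snp_probes = 40,
    n_nonvariable = 50, n_crosshyb = 30, n_sexchr = 30, n_off_epic = 10,
    n_cohorts = 3, cohort_sizes = c(36, 34, 32),
    n_failed_detection_sites = 4, n_lowbead_sites = 2,
    n_scattered_failures = 8, n_noise_samples = 1, n_sex_mislabels = 1,
    seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Coarse tuning grid for tests that exercise the tuning machinery without
# needing the full default grid.
tiny_grid <- function(folds = 3, repeats = 1) {
  hyper_grid(alphas = c(0.1, 0.5), lambdas = c(0.2, 0.02, 0.002),
             cv_folds = folds, cv_repeats = repeats)
}

# BMIQ off (too few probes per design type in the reduced fixture) and an
# inter-array threshold adapted to the fixture's higher fraction of
# genotype-driven sites (a uniform-noise array still sits near r = 0).
fast_pp <- function(...) preprocess_config(bmiq_enabled = FALSE,
                                           min_interarray_r = 0.8, ...)

# Tiny labelled matrix with real class signal at two sites.
toy_classification_data <- function(n_per = 12, p_noise = 6, seed = 11) {
  set.seed(seed)
  classes <- c("African", "Asian", "Caucasian")
  n <- 3 * n_per
  y <- rep(classes, each = n_per)
  centers <- rbind(c(0.2, 0.8), c(0.5, 0.2), c(0.8, 0.5))
  x <- matrix(runif((p_noise + 2) * n), p_noise + 2, n)
  for (i in 1:2)
    x[i, ] <- pmin(pmax(centers[match(y, classes), i] + rnorm(n, 0, 0.05), 0), 1)
  dimnames(x) <- list(paste0("cg", seq_len(nrow(x))), sprintf("s%03d", seq_len(n)))
  list(x = x, y = y)
}

# Minimal annotation for hand-built matrices.
toy_annotation <- function(site_ids, probe_class = "CpG", design_type = "II",
                           chromosome = "1", on_epic = TRUE,
                           cross_hybridizing = FALSE, nonvariable = FALSE,
                           snp_in_probe = FALSE, dist_to_variant = NA,
                           mqtl = FALSE, island_relation = "OpenSea") {
  data.frame(site_id = site_ids, probe_class = probe_class,
             design_type = design_type, chromosome = chromosome,
             island_relation = island_relation, on_epic = on_epic,
             cross_hybridizing = cross_hybridizing, nonvariable = nonvariable,
             snp_in_probe = snp_in_probe, dist_to_variant = dist_to_variant,
             mqtl = mqtl, stringsAsFactors = FALSE)
}

rand_bm <- function(p = 10, n = 6, seed = 3, ...) {
  set.seed(seed)
  b <- matrix(runif(p * n), p, n,
              dimnames = list(sprintf("cg%03d", 1:p), sprintf("s%02d", 1:n)))
  beta_matrix(b, ...)
}

# Independent proximal-gradient minimizer of the penalized multinomial
# objective (standardized scale). Used as a brute-force oracle; shares no
# code with the fitting path.
prox_grad_multinomial <- function(x, y, alpha, lambda, iters = 20000, step = 0.5) {
  xs <- t(x)
  ctr <- colMeans(xs)
  scl <- apply(xs, 2, sd)
  z <- sweep(sweep(xs, 2, ctr), 2, scl, "/")
  classes <- sort(unique(y))
  Y <- sapply(classes, function(cl) as.numeric(y == cl))
  n <- nrow(z); p <- ncol(z); K <- length(classes)
  B0 <- rep(0, K); B <- matrix(0, p, K)
  for (it in seq_len(iters)) {
    eta <- sweep(z %*% B, 2, B0, "+")
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta); P <- P / rowSums(P)
    G <- crossprod(z, P - Y) / n
    B0 <- B0 - step * colMeans(P - Y)
    Bt <- B - step * (G + lambda * (1 - alpha) * B)
    B <- sign(Bt) * pmax(abs(Bt) - step * lambda * alpha, 0)
  }
  eta <- sweep(z %*% B, 2, B0, "+")
  eta <- eta - apply(eta, 1, max)
  lp <- eta - log(rowSums(exp(eta)))
  obj <- -mean(lp[Y == 1]) + lambda * sum((1 - alpha) / 2 * B^2 + alpha * abs(B))
  list(objective = obj, B0 = B0, B = B)
}
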