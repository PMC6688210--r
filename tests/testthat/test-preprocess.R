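test_that("platform-overlap restriction keeps exactly the on-EPIC sites", {
  bm <- rand_bm(10, 4)
  ann <- toy_annotation(site_ids(bm), on_epic = c(rep(FALSE, 4), rep(TRUE, 6)))
  out <- restrict_to_platform_overlap(bm, ann)
  expect_equal(nrow(out$bm$beta), 6)
  expect_equal(out$report$n_removed, 4)
  # all on-EPIC -> identity
  ann2 <- toy_annotation(site_ids(bm))
  out2 <- restrict_to_platform_overlap(bm, ann2)
  expect_equal(out2$bm$beta, bm$beta)
  # SNP probes are never dropped here if on the overlap
  ann3 <- toy_annotation(site_ids(bm), probe_class = "SNP")
  expect_equal(nrow(restrict_to_platform_overlap(bm, ann3)$bm$beta), 10)
  # unannotated sites are a hard error listing ids
  expect_error(restrict_to_platform_overlap(bm, ann[-1, ]), "cg001")
})

test_that("site failure uses strictly-greater-than-1% and strict bead/detection bounds", {
  p <- 3; n <- 100
  det <- matrix(0, p, n); bead <- matrix(10, p, n)
  det[1, 1:2] <- 0.5              # 2% failing -> removed
  det[2, 1] <- 0.5                # exactly 1% -> kept, value masked
  b <- matrix(runif(p * n), p, n)
  dimnames(b) <- dimnames(det) <- dimnames(bead) <-
    list(paste0("cg", 1:p), paste0("s", 1:n))
  bm <- beta_matrix(b, detection_p = det, bead_count = bead)
  out <- filter_poor_quality_sites(bm)
  expect_equal(out$report$ids, "cg1")
  expect_true(is.na(out$bm$beta["cg2", "s1"]))
  expect_false(anyNA(out$bm$beta["cg3", ]))
  # boundary: bead_count == 3 and detection_p == 0.01 do not fail
  bead2 <- matrix(3, p, n, dimnames = dimnames(b))
  det2 <- matrix(0.01, p, n, dimnames = dimnames(b))
  out2 <- filter_poor_quality_sites(beta_matrix(b, detection_p = det2, bead_count = bead2))
  expect_equal(out2$report$n_removed, 0)
  expect_false(anyNA(out2$bm$beta))
  # no QC layers -> warning no-op
  expect_warning(out3 <- filter_poor_quality_sites(beta_matrix(b)), "no-op")
  expect_equal(out3$bm$beta, b)
})

test_that("quality filter removes exactly the planted defective sites", {
  sim <- simulate_cohorts(small_sim_config(seed = 4))
  out <- filter_poor_quality_sites(sim$bm)
  planted <- sim$truth$sites$site_id[sim$truth$sites$failed_detection |
                                       sim$truth$sites$low_bead]
  expect_setequal(out$report$ids, planted)
  # scattered single failures are masked, not removed
  sc <- sim$truth$scattered_cells
  sc_ids <- sim$truth$sites$site_id[sc[, "site"]]
  expect_true(all(sc_ids %in% site_ids(out$bm)))
  expect_true(all(is.na(out$bm$beta[cbind(sc_ids, sample_ids(out$bm)[sc[, "sample"]])])))
})

test_that("KNN imputation fills missing cells from the nearest sites only", {
  # hand case: k = 1, nearest site by Euclidean distance determines the value
  b <- rbind(cg1 = c(0.10, 0.20, NA),
             cg2 = c(0.11, 0.21, 0.40),
             cg3 = c(0.90, 0.80, 0.70))
  colnames(b) <- paste0("s", 1:3)
  out <- impute_knn(beta_matrix(b), k = 1)
  expect_equal(out$beta["cg1", "s3"], 0.40)
  # observed values untouched; k = 2 averages both neighbours
  out2 <- impute_knn(beta_matrix(b), k = 2)
  expect_equal(out2$beta["cg1", "s3"], mean(c(0.40, 0.70)))
  expect_equal(out2$beta[-1, ], b[-1, ])
  expect_equal(out2$beta["cg1", 1:2], b["cg1", 1:2])
  # no missing -> identity
  bm <- rand_bm(5, 4)
  expect_identical(impute_knn(bm, k = 3)$beta, bm$beta)
  # k larger than available sites clamps with a warning
  expect_warning(out3 <- impute_knn(beta_matrix(b), k = 10), "exceeds")
  expect_false(anyNA(out3$beta))
  # all-missing site is an error
  b2 <- b; b2["cg1", ] <- NA
  expect_error(impute_knn(beta_matrix(b2)), "all values missing")
})

test_that("flagged-site removal uses set semantics and exempts SNP probes from nonvariable", {
  bm <- rand_bm(12, 4)
  ids <- site_ids(bm)
  ann <- toy_annotation(ids,
                        probe_class = c(rep("CpG", 10), "SNP", "SNP"),
                        cross_hybridizing = c(rep(TRUE, 5), rep(FALSE, 7)),
                        nonvariable = c(rep(FALSE, 4), TRUE, TRUE, TRUE, TRUE,
                                        FALSE, FALSE, TRUE, FALSE))
  # 5 crosshyb + 4 nonvariable CpGs with one overlap -> 8 removed once
  # each; the nonvariable SNP probe (11th) is exempt
  out <- remove_flagged_sites(bm, ann)
  expect_equal(out$report$n_removed, 8)
  expect_true(ids[11] %in% site_ids(out$bm))
  # planted nonvariable set exactly recovered on simulated data
  sim <- simulate_cohorts(small_sim_config(seed = 9))
  out2 <- remove_flagged_sites(sim$bm, sim$ann)
  planted <- sim$truth$sites$site_id[sim$truth$sites$role %in% c("crosshyb", "nonvariable")]
  expect_setequal(out2$report$ids, planted)
})

test_that("sex is inferred by clustering sex-chromosome betas", {
  set.seed(21)
  n <- 24
  sex <- rep(c("M", "F"), each = n / 2)
  ids <- paste0("s", 1:n)
  y_sites <- matrix(rnorm(8 * n, ifelse(sex == "M", 0.8, 0.1), 0.03), 8, n, byrow = TRUE)
  x_sites <- matrix(rnorm(8 * n, ifelse(sex == "M", 0.8, 0.5), 0.03), 8, n, byrow = TRUE)
  auto <- matrix(runif(10 * n), 10, n)
  b <- pmin(pmax(rbind(y_sites, x_sites, auto), 0), 1)
  dimnames(b) <- list(paste0("cg", 1:26), ids)
  ann <- toy_annotation(rownames(b),
                        chromosome = c(rep("Y", 8), rep("X", 8), rep("3", 10)))
  res <- infer_sex(beta_matrix(b), ann, reported_sex = sex)
  expect_equal(res$inferred_sex, sex)
  expect_true(all(res$concordant))
  # one flipped report is flagged, and only that one
  flipped <- sex; flipped[5] <- "F"
  res2 <- infer_sex(beta_matrix(b), ann, reported_sex = flipped)
  expect_equal(which(!res2$concordant), 5L)
  # all one sex -> degenerate warning, but labels still by chrY level
  bb <- b[, sex == "M"]
  expect_warning(res3 <- infer_sex(beta_matrix(bb), ann, reported_sex = rep("M", ncol(bb))),
                 "do not separate")
  expect_true(all(res3$inferred_sex == "M"))
  # too few sex-chromosome sites is an error
  expect_error(infer_sex(beta_matrix(b[20:26, ]), ann[20:26, ]), "sex-chromosome")
})

test_that("inter-array correlation filter removes only the outlier array", {
  set.seed(31)
  base <- runif(300)
  # 6 near-identical arrays + 1 uniform-noise outlier: with so few arrays
  # the outlier drags every mean down, so the cutoff is set accordingly
  b <- sapply(1:6, function(i) pmin(pmax(base + rnorm(300, 0, 0.01), 0), 1))
  b <- cbind(b, runif(300))
  dimnames(b) <- list(paste0("cg", 1:300), paste0("s", 1:7))
  out <- interarray_correlation_filter(beta_matrix(b), min_r = 0.8)
  expect_equal(out$report$ids, "s7")
  expect_lt(out$mean_r["s7"], 0.3)
  expect_true(all(out$mean_r[1:6] > 0.8))
  # at a realistic cohort size the default 0.95 cutoff isolates the outlier
  b2 <- sapply(1:30, function(i) pmin(pmax(base + rnorm(300, 0, 0.01), 0), 1))
  b2 <- cbind(b2, runif(300))
  dimnames(b2) <- list(paste0("cg", 1:300), paste0("s", 1:31))
  out_big <- interarray_correlation_filter(beta_matrix(b2))
  expect_equal(out_big$report$ids, "s31")
  # identical samples: mean r = 1, none removed
  b2 <- matrix(rep(runif(50), 4), 50, 4,
               dimnames = list(paste0("cg", 1:50), paste0("s", 1:4)))
  out2 <- interarray_correlation_filter(beta_matrix(b2))
  expect_equal(out2$report$n_removed, 0)
  expect_equal(unname(out2$mean_r), rep(1, 4))
  # threshold 0 removes nothing even for the outlier
  expect_equal(interarray_correlation_filter(beta_matrix(b), min_r = 0)$report$n_removed, 0)
  expect_error(interarray_correlation_filter(beta_matrix(b[, 1:2, drop = FALSE])),
               "at least 3")
})

test_that("the full cascade removes exactly the planted defects and is idempotent", {
  sim <- simulate_cohorts(small_sim_config(seed = 2))
  pp <- run_preprocess(sim$bm, sim$ann, sim$sheet, fast_pp())
  tab <- filter_report_table(pp$reports)
  truth <- sim$truth
  expected_sites <- c(
    platform_overlap = sum(truth$sites$off_epic),
    quality_filter = sum(truth$sites$failed_detection | truth$sites$low_bead),
    flagged_sites = sum(truth$sites$role %in% c("crosshyb", "nonvariable")))
  for (st in names(expected_sites))
    expect_equal(tab$n_removed[tab$step == st], unname(expected_sites[st]), label = st)
  noise_ids <- truth$samples$sample_id[truth$samples$noise_sample]
  mislabel_ids <- truth$samples$sample_id[truth$samples$sex_mislabeled]
  get_ids <- function(step) pp$reports[[which(tab$step == step)]]$ids
  expect_setequal(get_ids("interarray_correlation"), noise_ids)
  expect_setequal(get_ids("sex_concordance"), mislabel_ids)
  expect_equal(ncol(pp$bm$beta),
               nrow(sim$sheet) - length(noise_ids) - length(mislabel_ids))
  expect_false(anyNA(pp$bm$beta))
  # every removed id appears in exactly one step
  all_ids <- unlist(lapply(pp$reports, `[[`, "ids"))
  expect_equal(anyDuplicated(all_ids), 0L)
  # idempotence: re-running the cascade removes nothing further
  bm2 <- beta_matrix(pp$bm$beta)
  pp2 <- run_preprocess(bm2, sim$ann, pp$sheet, fast_pp())
  expect_equal(dim(pp2$bm$beta), dim(pp$bm$beta))
  expect_true(all(filter_report_table(pp2$reports)$n_removed == 0))
})

test_that("a config disabling all steps is the identity", {
  sim <- simulate_cohorts(small_sim_config(seed = 6))
  cfg <- preprocess_config(platform_overlap = FALSE, quality_filter = FALSE,
                           impute = FALSE, flagged_sites = FALSE,
                           sex_check = FALSE, interarray = FALSE,
                           bmiq_enabled = FALSE)
  pp <- run_preprocess(sim$bm, sim$ann, sim$sheet, cfg)
  expect_identical(pp$bm$beta, sim$bm$beta)
  expect_length(pp$reports, 0)
})

test_that("a defect-free matrix passes the cascade untouched", {
  sim <- simulate_cohorts(small_sim_config(
    seed = 8, n_failed_detection_sites = 0, n_lowbead_sites = 0,
    n_scattered_failures = 0, n_noise_samples = 0, n_sex_mislabels = 0,
    n_off_epic = 0, n_crosshyb = 0, n_nonvariable = 0))
  pp <- run_preprocess(sim$bm, sim$ann, sim$sheet, fast_pp())
  expect_true(all(filter_report_table(pp$reports)$n_removed == 0))
  expect_equal(dim(pp$bm$beta), dim(sim$bm$beta))
})
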