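test_that("a dominating penalty recovers the empirical class priors", {
  set.seed(7)
  y <- c(rep("African", 4), rep("Asian", 2), rep("Caucasian", 2))
  x <- matrix(runif(24), 3, 8,
              dimnames = list(paste0("cg", 1:3), paste0("s", 1:8)))
  fit <- suppressWarnings(fit_ethnicity_model(x, y, alpha = 0.5, lambda = 1e3))
  expect_true(all(fit$coefficients == 0))
  probs <- predict_probabilities(fit, x)
  expect_equal(unname(probs),
               matrix(rep(c(0.5, 0.25, 0.25), each = 8), 8, 3),
               tolerance = 1e-6)
})

test_that("the fitted solution attains the penalized-objective optimum", {
  set.seed(42)
  n <- 30; p <- 5
  x <- matrix(runif(n * p), p, n,
              dimnames = list(paste0("cg", 1:p), paste0("s", 1:n)))
  y <- rep(c("African", "Asian", "Caucasian"), each = 10)
  for (pars in list(c(0.5, 0.05), c(0.2, 0.01))) {
    fit <- fit_ethnicity_model(x, y, alpha = pars[1], lambda = pars[2])
    oracle <- prox_grad_multinomial(x, y, alpha = pars[1], lambda = pars[2])
    obj_fit <- methylancestry:::penalized_objective(fit, x, y)
    expect_lt(abs(obj_fit - oracle$objective), 1e-4)
  }
})

test_that("lambda = 0 reproduces the unpenalized multinomial fit", {
  skip_if_not_installed("nnet")
  toy <- toy_classification_data(n_per = 15, p_noise = 2, seed = 13)
  fit <- fit_ethnicity_model(toy$x, toy$y, alpha = 0.5, lambda = 0)
  df <- data.frame(y = factor(toy$y, levels = fit$classes), t(toy$x))
  nn <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 2000, reltol = 1e-14)
  p_nn <- predict(nn, df, type = "probs")
  p_fit <- predict_probabilities(fit, toy$x)
  expect_lt(max(abs(p_fit - p_nn[, fit$classes])), 1e-3)
})

test_that("probabilities follow the softmax of the linear predictors", {
  # hand-built one-site model: intercepts 0, coefficients (2, 0, -2), x = 0.5
  coefs <- matrix(c(2, 0, -2), 1, 3,
                  dimnames = list("cg1", c("African", "Asian", "Caucasian")))
  m <- methylancestry:::new_ethnicity_model(
    classes = c("African", "Asian", "Caucasian"),
    intercepts = c(African = 0, Asian = 0, Caucasian = 0),
    coefficients = coefs, alpha = 0.5, lambda = 0.1,
    center = c(cg1 = 0), scale = c(cg1 = 1))
  x <- matrix(0.5, 1, 1, dimnames = list("cg1", "s1"))
  p <- predict_probabilities(m, x)
  expect_equal(unname(p[1, ]), exp(c(1, 0, -1)) / sum(exp(c(1, 0, -1))),
               tolerance = 1e-12)
  expect_equal(unname(round(p[1, ], 4)), c(0.6652, 0.2447, 0.0900))
  # equal intercepts, zero coefficients -> uniform
  m0 <- methylancestry:::new_ethnicity_model(
    classes = m$classes, intercepts = m$intercepts,
    coefficients = coefs * 0, alpha = 0.5, lambda = 0.1,
    center = c(cg1 = 0), scale = c(cg1 = 1))
  expect_equal(unname(predict_probabilities(m0, x)[1, ]), rep(1 / 3, 3))
})

test_that("prediction is invariant to input site order and checks for missing sites", {
  toy <- toy_classification_data()
  fit <- fit_ethnicity_model(toy$x, toy$y, alpha = 0.5, lambda = 0.02)
  perm <- sample(nrow(toy$x))
  expect_identical(predict_probabilities(fit, toy$x),
                   predict_probabilities(fit, toy$x[perm, , drop = FALSE]))
  expect_error(predict_probabilities(fit, toy$x[-1, , drop = FALSE]), "cg1")
})

test_that("probabilities are invariant to a constant shift of all linear predictors", {
  toy <- toy_classification_data()
  fit <- fit_ethnicity_model(toy$x, toy$y, alpha = 0.5, lambda = 0.02)
  shifted <- fit
  shifted$intercepts <- fit$intercepts + 5
  expect_equal(predict_probabilities(shifted, toy$x),
               predict_probabilities(fit, toy$x), tolerance = 1e-12)
})

test_that("ethnicity calls apply the strictly-below-threshold ambiguity rule", {
  probs <- rbind(s1 = c(0.80, 0.10, 0.10),
                 s2 = c(0.50, 0.30, 0.20),
                 s3 = c(0.75, 0.15, 0.10))
  colnames(probs) <- c("African", "Asian", "Caucasian")
  calls <- call_ethnicity(probs, threshold = 0.75)
  expect_equal(calls$predicted, c("African", "Ambiguous", "African"))
  expect_equal(calls$threshold, rep(0.75, 3))
  # exact tie broken by fixed class order, with a log message
  tie <- matrix(c(0.4, 0.4, 0.2), 1, dimnames = list("t", colnames(probs)))
  expect_message(ct <- call_ethnicity(tie, threshold = 0.3), "tie")
  expect_equal(ct$predicted, "African")
  # probabilities must sum to 1
  bad <- matrix(c(0.5, 0.3, 0.1), 1, dimnames = list("b", colnames(probs)))
  expect_error(call_ethnicity(bad), "sum to 1")
})

test_that("selected-site count is non-increasing in lambda", {
  toy <- toy_classification_data(n_per = 20, p_noise = 10, seed = 19)
  lams <- c(0.001, 0.01, 0.05, 0.2, 1)
  counts <- vapply(lams, function(l)
    length(selected_sites(fit_ethnicity_model(toy$x, toy$y, alpha = 0.5, lambda = l))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("tuning is deterministic, honours single-point grids, and prefers signal", {
  toy <- toy_classification_data(n_per = 10, p_noise = 4, seed = 23)
  g1 <- hyper_grid(alphas = 0.3, lambdas = 0.05, cv_folds = 3, cv_repeats = 1)
  t1 <- tune_hyperparameters(toy$x, toy$y, g1, seed = 5)
  expect_equal(t1$alpha, 0.3)
  expect_equal(t1$lambda, 0.05)
  g2 <- hyper_grid(alphas = c(0.1, 0.5), lambdas = c(1e3, 0.01),
                   cv_folds = 3, cv_repeats = 2)
  ta <- tune_hyperparameters(toy$x, toy$y, g2, seed = 5)
  tb <- tune_hyperparameters(toy$x, toy$y, g2, seed = 5)
  expect_identical(ta$cv_table, tb$cv_table)
  # on separable data the small-lambda point beats the intercept-only point
  expect_equal(ta$lambda, 0.01)
  ll <- ta$cv_table
  expect_lt(min(ll$logLoss[ll$lambda == 0.01]), min(ll$logLoss[ll$lambda == 1e3]))
  # class smaller than fold count is an actionable error
  expect_error(tune_hyperparameters(toy$x[, 1:12], toy$y[1:12],
                                    hyper_grid(alphas = 0.5, lambdas = 0.1, cv_folds = 11)),
               "fewer folds")
})

test_that("permuted labels drop CV accuracy to the majority-class frequency", {
  toy <- toy_classification_data(n_per = 20, p_noise = 6, seed = 29)
  set.seed(101)
  y_perm <- sample(toy$y)
  g <- hyper_grid(alphas = 0.5, lambdas = c(0.2, 0.02), cv_folds = 5, cv_repeats = 2)
  tt <- tune_hyperparameters(toy$x, y_perm, g, seed = 7)
  majority <- max(table(y_perm)) / length(y_perm)
  expect_lt(max(tt$cv_table$accuracy), majority + 0.05)
})

test_that("the end-to-end pipeline trains a reproducible model with selected sites", {
  sim <- simulate_cohorts(small_sim_config(seed = 1))
  cfg <- list(preprocess = fast_pp(), grid = tiny_grid())
  m1 <- fit_ethnicity_pipeline(sim$bm, sim$ann, sim$sheet, cfg, seed = 1)
  expect_s3_class(m1, "ethnicity_model")
  expect_gt(length(selected_sites(m1)), 0)
  m2 <- fit_ethnicity_pipeline(sim$bm, sim$ann, sim$sheet, cfg, seed = 1)
  expect_identical(selected_sites(m1), selected_sites(m2))
  expect_identical(m1$coefficients, m2$coefficients)
  # preprocessing record is embedded
  expect_true(is.data.frame(m1$preprocessing_record$steps))
  # all-missing labels are an error
  sheet_na <- sim$sheet
  sheet_na$reported_ethnicity <- NA_character_
  expect_error(fit_ethnicity_pipeline(sim$bm, sim$ann, sheet_na, cfg, seed = 1),
               "no labels")
})

test_that("model methods print, summarize, and expose coefficients", {
  toy <- toy_classification_data()
  fit <- fit_ethnicity_model(toy$x, toy$y, alpha = 0.5, lambda = 0.02)
  expect_output(print(fit), "elastic-net|Elastic-net")
  expect_output(print(summary(fit)), "selected")
  cf <- coef(fit)
  expect_equal(rownames(cf)[1], "(Intercept)")
  expect_equal(dim(cf), c(nrow(toy$x) + 1, 3))
  cls <- predict(fit, toy$x, type = "class")
  expect_true(all(cls$predicted %in% c(fit$classes, "Ambiguous")))
})
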