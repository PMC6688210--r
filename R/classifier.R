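# Penalized multinomial ethnicity classifier.
#
# The model is symmetric-softmax multinomial logistic regression with an
# elastic-net penalty, fit by coordinate descent (glmnet). Features (sites)
# are standardized internally using training means/SDs; coefficients are
# returned on the original beta scale. The penalized objective is
#   -(1/N) sum_i log softmax_{y_i}(b0_c + b_c . x_i)
#     + lambda * sum_c [ (1-alpha)/2 ||b_c||_2^2 + alpha ||b_c||_1 ]
# with intercepts unpenalized and the L1 term ungrouped across classes.

new_ethnicity_model <- function(classes, intercepts, coefficients, alpha, lambda,
                                center, scale, threshold = 0.75,
                                preprocessing_record = NULL, tuning = NULL) {
  structure(
    list(classes = classes, intercepts = intercepts, coefficients = coefficients,
         model_sites = rownames(coefficients), alpha = alpha, lambda = lambda,
         center = center, scale = scale, threshold = threshold,
         preprocessing_record = preprocessing_record, tuning = tuning),
    class = "ethnicity_model")
}

#' Selected (nonzero-coefficient) sites of a fitted model
#' @param model an `ethnicity_model`.
#' @return character vector of site ids with a nonzero coefficient in at
#'   least one class.
#' @export
selected_sites <- function(model) {
  model$model_sites[rowSums(model$coefficients != 0) > 0]
}

standardize_fit <- function(xs) {
  ctr <- colMeans(xs)
  scl <- apply(xs, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl,
       x = sweep(sweep(xs, 2, ctr), 2, scl, "/"))
}

canonical_class_order <- function(labels) {
  canon <- ethnicity_classes()
  c(intersect(canon, labels), sort(setdiff(labels, canon)))
}

# lambda path ending exactly at the requested lambda, for a stable
# warm-started coordinate-descent solution at a single penalty value.
lambda_path <- function(lambda) {
  if (lambda <= 0) return(c(exp(seq(log(0.5), log(1e-4), length.out = 15)), 0))
  top <- max(lambda * 200, 0.5)
  exp(seq(log(top), log(lambda), length.out = 25))
}

#' Fit the elastic-net multinomial ethnicity model
#'
#' @param x numeric matrix of beta values, sites x samples (rownames = site
#'   ids), or a [beta_matrix]; no missing values.
#' @param y per-sample class labels (character or factor). Every class
#'   present must have at least 2 samples.
#' @param alpha elastic-net mixing parameter in (0, 1].
#' @param lambda penalty strength, >= 0.
#' @param threshold ambiguity threshold stored with the model (see
#'   [call_ethnicity()]).
#' @param preprocessing_record optional record of the filtering applied to
#'   the training matrix, embedded for provenance.
#' @param tuning optional tuning record (see [tune_hyperparameters()]).
#' @return an object of class `ethnicity_model` with per-class intercepts and
#'   a sites x classes coefficient matrix on the original beta scale.
#' @examples
#' sim <- simulate_cohorts(simulation_config(n_background_cpgs = 100,
#'   n_mqtl_cpgs = 20, n_snp_probes = 20, cohort_sizes = c(30, 30),
#'   n_cohorts = 2, seed = 7))
#' fit <- fit_ethnicity_model(sim$bm$beta, sim$sheet$reported_ethnicity,
#'                            alpha = 0.5, lambda = 0.05)
#' fit
#' @export
fit_ethnicity_model <- function(x, y, alpha = 0.5, lambda = 0.05,
                                threshold = 0.75, preprocessing_record = NULL,
                                tuning = NULL) {
  if (inherits(x, "beta_matrix")) x <- x$beta
  if (anyNA(x) || any(!is.finite(x))) stop("x contains missing or non-finite values")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  y <- as.character(y)
  if (length(y) != ncol(x)) stop("length(y) must equal ncol(x) (samples)")
  if (anyNA(y)) stop("y contains missing labels")
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 classes present to fit")
  if (any(tab < 2))
    stop(sprintf("class with fewer than 2 samples: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  classes <- canonical_class_order(names(tab))
  yf <- factor(y, levels = classes)
  xs <- t(x)                                   # samples x sites
  std <- standardize_fit(xs)
  path <- lambda_path(lambda)
  fit <- glmnet::glmnet(std$x, yf, family = "multinomial", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        type.multinomial = "ungrouped",
                        thresh = 1e-10, maxit = 1e6)
  cf <- glmnet::coef.glmnet(fit, s = lambda, exact = FALSE)
  p <- nrow(x)
  coefs <- matrix(0, p, length(classes), dimnames = list(rownames(x), classes))
  icpt <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    v <- as.numeric(cf[[cl]])
    b_std <- v[-1]
    # back-transform to the original beta scale
    coefs[, cl] <- b_std / std$scale
    icpt[cl] <- v[1] - sum(b_std * std$center / std$scale)
  }
  new_ethnicity_model(classes, icpt, coefs, alpha, lambda,
                      center = std$center, scale = std$scale,
                      threshold = threshold,
                      preprocessing_record = preprocessing_record,
                      tuning = tuning)
}

# Penalized objective of a model on (x, y), evaluated on the internal
# standardized scale (the scale on which the penalty is applied in fitting).
penalized_objective <- function(model, x, y) {
  if (inherits(x, "beta_matrix")) x <- x$beta
  xs <- t(x[model$model_sites, , drop = FALSE])
  z <- sweep(sweep(xs, 2, model$center), 2, model$scale, "/")
  b_std <- model$coefficients * model$scale
  icpt_std <- model$intercepts + colSums(model$coefficients * model$center)
  eta <- sweep(z %*% b_std, 2, icpt_std, "+")
  eta <- eta - apply(eta, 1, max)
  logp <- eta - log(rowSums(exp(eta)))
  yi <- match(as.character(y), model$classes)
  nll <- -mean(logp[cbind(seq_along(yi), yi)])
  pen <- model$lambda * sum((1 - model$alpha) / 2 * b_std^2 + model$alpha * abs(b_std))
  nll + pen
}

#' Predicted class probabilities
#'
#' @param model an `ethnicity_model`.
#' @param x sites x samples matrix or [beta_matrix] containing every model
#'   site (extra sites are ignored; site order is irrelevant).
#' @return samples x classes matrix of probabilities (rows sum to 1).
#' @export
predict_probabilities <- function(model, x) {
  if (inherits(x, "beta_matrix")) x <- x$beta
  miss <- setdiff(model$model_sites, rownames(x))
  if (length(miss) > 0)
    stop(sprintf("input is missing %d model site(s): %s%s", length(miss),
                 paste(utils::head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) ", ..." else ""))
  xm <- x[model$model_sites, , drop = FALSE]
  if (anyNA(xm) || any(!is.finite(xm))) stop("input contains missing or non-finite values")
  eta <- t(xm) %*% model$coefficients
  eta <- sweep(eta, 2, model$intercepts, "+")
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  rownames(p) <- colnames(x)
  p
}

#' @export
predict.ethnicity_model <- function(object, newdata, type = c("response", "class"),
                                    threshold = NULL, ...) {
  type <- match.arg(type)
  probs <- predict_probabilities(object, newdata)
  if (type == "response") return(probs)
  if (is.null(threshold)) threshold <- object$threshold
  call_ethnicity(probs, threshold = threshold)
}

#' Threshold class probabilities into ethnicity calls
#'
#' The call is the highest-probability class when that probability is at
#' least `threshold` (a maximum of exactly `threshold` is called, not
#' Ambiguous); otherwise the sample is called `Ambiguous`. Exact ties are
#' broken by the fixed class order (African < Asian < Caucasian) and logged.
#'
#' @param probs samples x classes matrix (or data.frame) of probabilities;
#'   each row must sum to 1 within 1e-6.
#' @param threshold ambiguity cutoff in \[0, 1\].
#' @return data.frame with `sample_id`, one `prob_<class>` column per class,
#'   `predicted`, and `threshold`.
#' @export
call_ethnicity <- function(probs, threshold = 0.75) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) stop("probs must have class names as colnames")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("class probabilities must sum to 1 within 1e-6")
  ord <- canonical_class_order(colnames(probs))
  probs <- probs[, ord, drop = FALSE]
  n <- nrow(probs)
  pred <- character(n)
  for (i in seq_len(n)) {
    mx <- max(probs[i, ])
    if (mx < threshold) {
      pred[i] <- "Ambiguous"
    } else {
      hits <- which(probs[i, ] == mx)
      if (length(hits) > 1)
        message(sprintf("tie at sample %s broken by class order", i))
      pred[i] <- ord[hits[1]]
    }
  }
  out <- data.frame(sample_id = if (!is.null(rownames(probs))) rownames(probs)
                    else as.character(seq_len(n)),
                    stringsAsFactors = FALSE)
  for (cl in ord) out[[paste0("prob_", cl)]] <- unname(probs[, cl])
  out$predicted <- pred
  out$threshold <- threshold
  rownames(out) <- NULL
  out
}

#' Hyperparameter grid for tuning
#'
#' Defaults: 6 alpha values log-spaced over \[0.025, 0.5\] and 8 lambda
#' values log-spaced over \[0.0025, 0.25\], evaluated by 3-times-repeated
#' stratified 5-fold cross-validation with log-loss as the selection metric.
#'
#' @param alphas,lambdas grid values.
#' @param cv_folds,cv_repeats fold count (>= 2) and repeats.
#' @param metric selection metric: `logLoss` (minimized), `accuracy` or
#'   `kappa` (maximized).
#' @return a `hyper_grid` list.
#' @export
hyper_grid <- function(alphas = exp(seq(log(0.025), log(0.5), length.out = 6)),
                       lambdas = exp(seq(log(0.0025), log(0.25), length.out = 8)),
                       cv_folds = 5, cv_repeats = 3,
                       metric = c("logLoss", "accuracy", "kappa")) {
  metric <- match.arg(metric)
  if (length(alphas) == 0 || length(lambdas) == 0) stop("empty hyperparameter grid")
  if (any(alphas <= 0 | alphas > 1)) stop("alphas must lie in (0, 1]")
  if (any(lambdas < 0)) stop("lambdas must be >= 0")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(alphas = sort(alphas), lambdas = sort(lambdas, decreasing = TRUE),
                 cv_folds = cv_folds, cv_repeats = cv_repeats, metric = metric),
            class = "hyper_grid")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune elastic-net hyperparameters by repeated stratified k-fold CV
#'
#' For every (alpha, lambda) grid point the held-out selection metric is
#' averaged over all folds and repeats; the best point is the argmin of
#' log-loss (or argmax of accuracy/kappa). Deterministic given `seed`.
#'
#' @param x sites x samples matrix or [beta_matrix]; no missing values.
#' @param y per-sample labels.
#' @param grid a [hyper_grid()].
#' @param seed integer seed controlling fold assignment.
#' @return list with `alpha`, `lambda`, and `cv_table` (one row per grid
#'   point with mean logLoss, accuracy and kappa).
#' @export
tune_hyperparameters <- function(x, y, grid = hyper_grid(), seed = 1) {
  if (inherits(x, "beta_matrix")) x <- x$beta
  y <- as.character(y)
  tab <- table(y)
  if (any(tab < grid$cv_folds))
    stop(sprintf("class '%s' has fewer samples (%d) than cv_folds (%d); use fewer folds",
                 names(tab)[which.min(tab)], min(tab), grid$cv_folds))
  classes <- canonical_class_order(names(tab))
  yf <- factor(y, levels = classes)
  xs <- t(x)
  n_lam <- length(grid$lambdas)
  n_alp <- length(grid$alphas)
  ll_sum <- acc_sum <- kap_sum <- matrix(0, n_alp, n_lam)
  n_eval <- 0
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (r in seq_len(grid$cv_repeats)) {
    fold <- stratified_folds(y, grid$cv_folds)
    for (f in seq_len(grid$cv_folds)) {
      tr <- fold != f
      std <- standardize_fit(xs[tr, , drop = FALSE])
      xte <- sweep(sweep(xs[!tr, , drop = FALSE], 2, std$center), 2, std$scale, "/")
      yte <- yf[!tr]
      for (a in seq_len(n_alp)) {
        # ranking grid points only: a looser convergence threshold suffices
        fit <- glmnet::glmnet(std$x, yf[tr], family = "multinomial",
                              alpha = grid$alphas[a], lambda = grid$lambdas,
                              standardize = FALSE, type.multinomial = "ungrouped",
                              thresh = 1e-7, maxit = 1e6)
        pr <- predict(fit, xte, s = grid$lambdas, type = "response")
        for (l in seq_len(n_lam)) {
          p <- pr[, , l, drop = TRUE]
          if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, dimnames(pr)[[2]]))
          p <- p[, classes, drop = FALSE]
          pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
          truth_idx <- match(as.character(yte), classes)
          ll_sum[a, l] <- ll_sum[a, l] + -mean(log(pc[cbind(seq_along(truth_idx), truth_idx)]))
          calls <- classes[max.col(p, ties.method = "first")]
          acc_sum[a, l] <- acc_sum[a, l] + mean(calls == as.character(yte))
          kap_sum[a, l] <- kap_sum[a, l] + cohens_kappa(as.character(yte), calls, classes)
        }
      }
      n_eval <- n_eval + 1
    }
  }
  cv <- expand.grid(lambda = grid$lambdas, alpha = grid$alphas)[, 2:1]
  cv$logLoss <- as.vector(t(ll_sum)) / n_eval
  cv$accuracy <- as.vector(t(acc_sum)) / n_eval
  cv$kappa <- as.vector(t(kap_sum)) / n_eval
  best <- if (grid$metric == "logLoss") which.min(cv$logLoss) else which.max(cv[[grid$metric]])
  list(alpha = cv$alpha[best], lambda = cv$lambda[best], cv_table = cv)
}

#' Fit the full training pipeline: preprocess, tune, fit
#'
#' Runs the QC cascade on the training matrix, drops samples without a
#' reported ethnicity, tunes (alpha, lambda) by repeated stratified CV, and
#' fits the final model at the selected point. The preprocessing record is
#' embedded in the model so predictions can validate input compatibility.
#'
#' @param bm a [beta_matrix].
#' @param ann annotation data.frame.
#' @param sheet sample sheet data.frame.
#' @param config list with optional entries `preprocess` (see
#'   [preprocess_config()]), `grid` (see [hyper_grid()]), `threshold`.
#' @param seed integer seed for tuning.
#' @return an `ethnicity_model`.
#' @export
fit_ethnicity_pipeline <- function(bm, ann, sheet, config = list(), seed = 1) {
  pp_config <- config$preprocess %||% preprocess_config()
  grid <- config$grid %||% hyper_grid()
  threshold <- config$threshold %||% 0.75
  pp <- run_preprocess(bm, ann, sheet, pp_config)
  labelled <- !is.na(pp$sheet$reported_ethnicity)
  if (!any(labelled)) stop("no labels to train on: all reported ethnicities missing")
  x <- pp$bm$beta[, labelled, drop = FALSE]
  y <- pp$sheet$reported_ethnicity[labelled]
  tuned <- tune_hyperparameters(x, y, grid, seed = seed)
  record <- list(steps = filter_report_table(pp$reports),
                 n_sites = nrow(x), n_samples = ncol(x),
                 config = pp_config)
  fit_ethnicity_model(x, y, alpha = tuned$alpha, lambda = tuned$lambda,
                      threshold = threshold, preprocessing_record = record,
                      tuning = tuned)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ethnicity_model <- function(x, ...) {
  cat("Elastic-net multinomial ethnicity classifier\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  alpha = %.4g, lambda = %.4g, ambiguity threshold = %.2f\n",
              x$alpha, x$lambda, x$threshold))
  cat(sprintf("  %d model sites, %d selected (nonzero in >= 1 class)\n",
              length(x$model_sites), length(selected_sites(x))))
  invisible(x)
}

#' @export
summary.ethnicity_model <- function(object, ...) {
  sel <- selected_sites(object)
  per_class <- colSums(object$coefficients != 0)
  out <- list(classes = object$classes, alpha = object$alpha,
              lambda = object$lambda, threshold = object$threshold,
              n_model_sites = length(object$model_sites),
              n_selected = length(sel), nonzero_per_class = per_class,
              preprocessing = object$preprocessing_record$steps)
  class(out) <- "summary.ethnicity_model"
  out
}

#' @export
print.summary.ethnicity_model <- function(x, ...) {
  cat("Elastic-net multinomial ethnicity classifier\n")
  cat(sprintf("  alpha = %.4g, lambda = %.4g, threshold = %.2f\n",
              x$alpha, x$lambda, x$threshold))
  cat(sprintf("  model sites: %d; selected: %d\n", x$n_model_sites, x$n_selected))
  cat("  nonzero coefficients per class:\n")
  print(x$nonzero_per_class)
  if (!is.null(x$preprocessing)) {
    cat("  preprocessing steps:\n")
    print(x$preprocessing)
  }
  invisible(x)
}

#' @export
coef.ethnicity_model <- function(object, nonzero = FALSE, ...) {
  cf <- rbind(`(Intercept)` = object$intercepts, object$coefficients)
  if (nonzero)
    cf <- cf[c(TRUE, rowSums(object$coefficients != 0) > 0), , drop = FALSE]
  cf
}

#' @export
plot.ethnicity_model <- function(x, n = 20, ...) {
  sel <- selected_sites(x)
  if (length(sel) == 0) {
    warning("no selected sites to plot")
    return(invisible(NULL))
  }
  mag <- apply(abs(x$coefficients[sel, , drop = FALSE]), 1, max)
  top <- utils::head(sel[order(-mag)], n)
  graphics::barplot(t(x$coefficients[top, , drop = FALSE]), beside = TRUE,
                    las = 2, cex.names = 0.6, legend.text = x$classes,
                    ylab = "coefficient (beta scale)",
                    main = sprintf("Top %d selected sites", length(top)), ...)
  invisible(x)
}
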