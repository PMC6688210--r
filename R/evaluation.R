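# Classification metrics, leave-one-dataset-out cross-validation, the
# ambiguity-threshold sweep, and paired-classifier comparison.

cohens_kappa <- function(truth, calls, levels = NULL) {
  if (is.null(levels)) levels <- union(unique(truth), unique(calls))
  tab <- table(factor(truth, levels = levels), factor(calls, levels = levels))
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) return(ifelse(p_o >= 1, 1, 0))
  (p_o - p_e) / (1 - p_e)
}

#' Classification performance metrics
#'
#' Computes overall accuracy (with `Ambiguous` calls counted as incorrect,
#' and also excluding them), Cohen's kappa, per-class positive predictive
#' value and macro PPV, per-class accuracy (recall), log-loss (when
#' probabilities are supplied; probabilities are clipped to
#' \[1e-15, 1 - 1e-15\]), the truth-by-call confusion matrix, and an optional
#' per-dataset breakdown.
#'
#' @param truth character vector of true class labels.
#' @param calls character vector of calls (classes and possibly `Ambiguous`).
#' @param probs optional samples x classes probability matrix for log-loss.
#' @param dataset optional per-sample dataset labels for a breakdown.
#' @return a list of class `evaluation_report`.
#' @export
compute_metrics <- function(truth, calls, probs = NULL, dataset = NULL) {
  truth <- as.character(truth)
  calls <- as.character(calls)
  if (length(truth) != length(calls)) stop("truth and calls length mismatch")
  known <- c(ethnicity_classes(), "Ambiguous")
  unknown <- setdiff(unique(calls), union(known, unique(truth)))
  if (length(unknown) > 0)
    stop(sprintf("unknown call label(s): %s", paste(unknown, collapse = ", ")))
  classes <- canonical_class_order(union(unique(truth),
                                         setdiff(unique(calls), "Ambiguous")))
  call_levels <- c(classes, if ("Ambiguous" %in% calls) "Ambiguous")
  n <- length(truth)
  confusion <- table(truth = factor(truth, levels = classes),
                     call = factor(calls, levels = call_levels))
  accuracy <- mean(calls == truth)
  non_amb <- calls != "Ambiguous"
  accuracy_excluding_ambiguous <-
    if (any(non_amb)) mean(calls[non_amb] == truth[non_amb]) else NA_real_
  kappa <- cohens_kappa(truth, calls, levels = union(classes, call_levels))
  ppv <- vapply(classes, function(cl) {
    called <- calls == cl
    if (!any(called)) return(NA_real_)
    sum(truth[called] == cl) / sum(called)
  }, 0)
  per_class_accuracy <- vapply(classes, function(cl) {
    is_cl <- truth == cl
    if (!any(is_cl)) return(NA_real_)
    mean(calls[is_cl] == cl)
  }, 0)
  log_loss <- NA_real_
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    pc <- pmin(pmax(probs[, classes, drop = FALSE], 1e-15), 1 - 1e-15)
    idx <- match(truth, classes)
    log_loss <- -mean(log(pc[cbind(seq_len(n), idx)]))
  }
  by_dataset <- NULL
  if (!is.null(dataset)) {
    by_dataset <- lapply(split(seq_len(n), dataset), function(ix)
      compute_metrics(truth[ix], calls[ix],
                      probs = if (!is.null(probs)) probs[ix, , drop = FALSE]))
  }
  structure(list(n = n, accuracy = accuracy,
                 accuracy_excluding_ambiguous = accuracy_excluding_ambiguous,
                 kappa = kappa, ppv = ppv, macro_ppv = mean(ppv, na.rm = TRUE),
                 per_class_accuracy = per_class_accuracy, log_loss = log_loss,
                 fraction_ambiguous = mean(calls == "Ambiguous"),
                 confusion = confusion, by_dataset = by_dataset),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d samples\n", x$n))
  cat(sprintf("  accuracy: %.3f (excluding Ambiguous: %.3f)\n",
              x$accuracy, x$accuracy_excluding_ambiguous))
  cat(sprintf("  kappa: %.3f  macro PPV: %.3f  logLoss: %.3f  ambiguous: %.1f%%\n",
              x$kappa, x$macro_ppv, x$log_loss, 100 * x$fraction_ambiguous))
  cat("  confusion (truth x call):\n")
  print(x$confusion)
  invisible(x)
}

# BMIQ applied to held-out samples: a per-sample transform, so no training
# information leaks into the test set.
prepare_test_matrix <- function(bm, ann, model, pp_config) {
  if (isTRUE(pp_config$bmiq_enabled))
    bm <- suppressWarnings(bmiq_normalize(bm, ann, min_probes = pp_config$bmiq_min_probes))
  bm
}

#' Leave-one-dataset-out cross-validation
#'
#' For every dataset (cohort) in the sample sheet, the entire training
#' pipeline — QC cascade, hyperparameter tuning, final fit — is run on the
#' remaining datasets only, and the resulting model classifies the held-out
#' dataset. Held-out samples receive only per-sample normalization (BMIQ),
#' so no quantity derived from the held-out cohort influences its own
#' training. Aggregate metrics pool every held-out prediction.
#'
#' @param bm a [beta_matrix] covering all cohorts.
#' @param ann annotation data.frame.
#' @param sheet sample sheet with at least 2 distinct `dataset_id`s.
#' @param config pipeline config as in [fit_ethnicity_pipeline()].
#' @param seed integer seed (tuning folds).
#' @return list with `per_dataset` (named list of `evaluation_report`s),
#'   `aggregate` (`evaluation_report`), `predictions` (data.frame of every
#'   held-out call), and `models` (named list of `ethnicity_model`s).
#' @export
lodocv <- function(bm, ann, sheet, config = list(), seed = 1) {
  datasets <- unique(sheet$dataset_id)
  if (length(datasets) < 2) stop("LODOCV needs at least 2 datasets")
  pp_config <- config$preprocess %||% preprocess_config()
  threshold <- config$threshold %||% 0.75
  preds <- list()
  models <- list()
  for (d in datasets) {
    test_samples <- intersect(sheet$sample_id[sheet$dataset_id == d], sample_ids(bm))
    train_samples <- intersect(sheet$sample_id[sheet$dataset_id != d], sample_ids(bm))
    if (length(test_samples) == 0) stop(sprintf("held-out dataset '%s' is empty", d))
    bm_train <- bm_subset(bm, samples = sample_ids(bm) %in% train_samples)
    sheet_train <- sheet[sheet$dataset_id != d, , drop = FALSE]
    model <- fit_ethnicity_pipeline(bm_train, ann, sheet_train, config, seed = seed)
    models[[d]] <- model
    bm_test <- bm_subset(bm, samples = sample_ids(bm) %in% test_samples)
    bm_test <- prepare_test_matrix(bm_test, ann, model, pp_config)
    probs <- predict_probabilities(model, bm_test)
    calls <- call_ethnicity(probs, threshold = threshold)
    calls$dataset_id <- d
    idx <- match(calls$sample_id, sheet$sample_id)
    calls$truth <- sheet$reported_ethnicity[idx]
    preds[[d]] <- calls
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  labelled <- !is.na(predictions$truth)
  prob_cols <- grep("^prob_", names(predictions), value = TRUE)
  probs_all <- as.matrix(predictions[, prob_cols])
  colnames(probs_all) <- sub("^prob_", "", prob_cols)
  aggregate <- compute_metrics(predictions$truth[labelled],
                               predictions$predicted[labelled],
                               probs = probs_all[labelled, , drop = FALSE])
  per_dataset <- lapply(split(which(labelled), predictions$dataset_id[labelled]),
                        function(ix) compute_metrics(predictions$truth[ix],
                                                     predictions$predicted[ix],
                                                     probs = probs_all[ix, , drop = FALSE]))
  list(per_dataset = per_dataset, aggregate = aggregate,
       predictions = predictions, models = models)
}

#' Sweep the ambiguity threshold
#'
#' @param probs samples x classes probability matrix.
#' @param truth true class labels.
#' @param thresholds cutoffs to evaluate.
#' @return data.frame with one row per threshold: accuracy (Ambiguous
#'   counted incorrect), kappa, and the ambiguous fraction (non-decreasing
#'   in the threshold).
#' @export
threshold_sweep <- function(probs, truth, thresholds = seq(0.5, 0.95, by = 0.05)) {
  out <- lapply(thresholds, function(th) {
    calls <- call_ethnicity(probs, threshold = th)
    data.frame(threshold = th,
               accuracy = mean(calls$predicted == truth),
               kappa = cohens_kappa(truth, calls$predicted),
               fraction_ambiguous = mean(calls$predicted == "Ambiguous"))
  })
  do.call(rbind, out)
}

#' McNemar comparison of two classifiers on the same samples
#'
#' Correctness is call == truth. `b` counts samples A got right and B got
#' wrong, `c` the reverse. The continuity-corrected statistic
#' (|b - c| - 1)^2 / (b + c) is referred to a chi-square with 1 df; when
#' b + c < 25 the exact two-sided binomial test is used instead.
#'
#' @param truth true labels.
#' @param calls_a,calls_b the two classifiers' calls.
#' @return list with `b`, `c`, `statistic`, `p_value`, `method`.
#' @export
mcnemar_compare <- function(truth, calls_a, calls_b) {
  if (length(truth) != length(calls_a) || length(truth) != length(calls_b))
    stop("truth, calls_a, calls_b must be aligned")
  ok_a <- calls_a == truth
  ok_b <- calls_b == truth
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0)
    return(list(b = b, c = cc, statistic = 0, p_value = 1,
                method = "degenerate (no discordant pairs)"))
  if (b + cc < 25) {
    p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
    return(list(b = b, c = cc, statistic = (abs(b - cc) - 1)^2 / (b + cc),
                p_value = p, method = "exact binomial"))
  }
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  list(b = b, c = cc, statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       method = "continuity-corrected chi-square")
}
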