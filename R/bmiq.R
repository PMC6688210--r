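# Beta-mixture quantile normalization (BMIQ).
#
# Infinium arrays mix two probe chemistries whose beta-value distributions
# differ systematically: type II probes are compressed relative to type I.
# BMIQ fits, per sample, a three-state beta mixture (unmethylated /
# hemimethylated / methylated) to each design type and maps type II values
# onto the type I distribution by quantile transformation. Here the map is
# the full mixture-CDF transform x' = F_I^{-1}(F_II(x)), which is monotone
# (so within-sample ranks among type II probes are preserved) and reduces to
# the identity when the two distributions coincide.

BMIQ_EPS <- 1e-6

# Method-of-moments beta parameters from a weighted mean/variance. Shapes
# are floored just above 1: each methylation state is a peak, so U-shaped
# components are disallowed (they absorb tail mass and wreck the CDF fit).
mom_beta <- function(m, v) {
  m <- min(max(m, 1e-3), 1 - 1e-3)
  v <- max(min(v, m * (1 - m) * 0.99), 1e-6)
  common <- m * (1 - m) / v - 1
  c(a = max(m * common, 1.001), b = max((1 - m) * common, 1.001))
}

# EM fit of a K=3 beta mixture; init by quantile thirds. For speed the
# parameters are estimated on a deterministic quantile-thinned subsample
# (every value when n <= fit_cap); convergence is declared when the mean
# log-likelihood change drops below `tol` or the parameters stop moving
# (the moment-matched M-step can cycle at machine-level amplitudes).
fit_beta_mixture3 <- function(x, max_iter = 100, tol = 1e-6, fit_cap = 2000) {
  x <- pmin(pmax(x, BMIQ_EPS), 1 - BMIQ_EPS)
  if (length(x) > fit_cap) {
    xs <- sort(x)
    x <- xs[round(seq(1, length(xs), length.out = fit_cap))]
  }
  n <- length(x)
  lx <- log(x)
  l1x <- log1p(-x)
  qs <- stats::quantile(x, c(1 / 3, 2 / 3))
  grp <- 1L + (x > qs[1]) + (x > qs[2])
  w <- as.numeric(table(factor(grp, levels = 1:3))) / n
  pars <- t(vapply(1:3, function(k) {
    xk <- x[grp == k]
    if (length(xk) < 2) xk <- x
    mom_beta(mean(xk), max(stats::var(xk), 1e-6))
  }, c(a = 0, b = 0)))
  ll_old <- -Inf
  dens <- matrix(0, n, 3)
  for (it in seq_len(max_iter)) {
    for (k in 1:3)
      dens[, k] <- exp(log(w[k]) + (pars[k, 1] - 1) * lx + (pars[k, 2] - 1) * l1x -
                         lbeta(pars[k, 1], pars[k, 2]))
    tot <- rowSums(dens)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- dens / tot
    w <- colMeans(r)
    w <- pmax(w, 1e-6); w <- w / sum(w)
    pars_old <- pars
    for (k in 1:3) {
      rk <- r[, k]
      sk <- sum(rk)
      mk <- sum(rk * x) / sk
      vk <- sum(rk * (x - mk)^2) / sk
      pars[k, ] <- mom_beta(mk, vk)
    }
    if (is.finite(ll_old) &&
        (abs(ll - ll_old) / n < tol ||
         max(abs(pars - pars_old) / (abs(pars_old) + 1e-8)) < 1e-5)) break
    ll_old <- ll
  }
  # order states by mean so state 1 = unmethylated, 3 = methylated
  means <- pars[, 1] / (pars[, 1] + pars[, 2])
  ord <- order(means)
  list(w = w[ord], a = pars[ord, 1], b = pars[ord, 2])
}

mixture_cdf <- function(x, fit) {
  out <- numeric(length(x))
  for (k in 1:3) out <- out + fit$w[k] * stats::pbeta(x, fit$a[k], fit$b[k])
  out
}

# Map values from the source mixture onto the target mixture:
# x' = F_target^{-1}(F_source(x)), inverted on a fine grid.
mixture_quantile_map <- function(x, fit_source, fit_target, grid_n = 4001) {
  grid <- seq(BMIQ_EPS, 1 - BMIQ_EPS, length.out = grid_n)
  Ft <- mixture_cdf(grid, fit_target)
  # enforce strict monotonicity for interpolation
  Ft <- cummax(Ft) + seq_along(Ft) * 1e-12
  u <- mixture_cdf(pmin(pmax(x, BMIQ_EPS), 1 - BMIQ_EPS), fit_source)
  out <- stats::approx(Ft, grid, xout = u, rule = 2, ties = "ordered")$y
  pmin(pmax(out, 0), 1)
}

#' Beta-mixture quantile normalization of type II probes
#'
#' Per sample, fits a three-state beta mixture to the type I and type II CpG
#' probe distributions and maps every type II value onto the type I mixture
#' by the monotone quantile transform. Type I values are returned unchanged.
#' SNP-class probes are passed through untouched: their trimodal genotype
#' signal must not be reshaped. If either design type has fewer than
#' `min_probes` CpG probes, the sample matrix is returned unchanged with a
#' warning.
#'
#' @param bm a [beta_matrix] with no missing values.
#' @param ann annotation data.frame with `design_type` and `probe_class`.
#' @param min_probes minimum CpG probes per design type required to fit.
#' @return a normalized [beta_matrix].
#' @export
bmiq_normalize <- function(bm, ann, min_probes = 500) {
  idx <- match(site_ids(bm), ann$site_id)
  cpg <- !is.na(idx) & ann$probe_class[idx] == "CpG"
  t1 <- which(cpg & ann$design_type[idx] == "I")
  t2 <- which(cpg & ann$design_type[idx] == "II")
  if (length(t1) < min_probes || length(t2) < min_probes) {
    warning(sprintf("fewer than %d CpG probes of design type I (%d) or II (%d); BMIQ skipped",
                    min_probes, length(t1), length(t2)))
    return(bm)
  }
  if (anyNA(bm$beta[c(t1, t2), ]))
    stop("BMIQ requires complete data; impute missing values first")
  beta <- bm$beta
  for (j in seq_len(ncol(beta))) {
    fit1 <- fit_beta_mixture3(beta[t1, j])
    fit2 <- fit_beta_mixture3(beta[t2, j])
    beta[t2, j] <- mixture_quantile_map(beta[t2, j], fit2, fit1)
  }
  beta_matrix(beta, bm$detection_p, bm$bead_count)
}
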