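#' Construct a beta matrix container
#'
#' Bundles a sites-by-samples matrix of methylation beta values (methylated
#' fraction, in \[0,1\]) with optional, dimension-aligned detection p-value and
#' bead-count layers. Sites are rows, matching the array-manifest convention.
#'
#' @param beta numeric matrix, sites x samples, values in \[0,1\] or `NA`.
#'   Must carry unique rownames (site ids) and colnames (sample ids).
#' @param detection_p optional numeric matrix of per-measurement detection
#'   p-values in \[0,1\], same dimensions and dimnames as `beta`.
#' @param bead_count optional matrix of non-negative integer bead counts,
#'   same dimensions and dimnames as `beta`.
#' @return an object of class `beta_matrix`: a list with elements `beta`,
#'   `detection_p`, `bead_count`.
#' @examples
#' b <- matrix(runif(6), 3, 2, dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' bm <- beta_matrix(b)
#' dim(bm)
#' @export
beta_matrix <- function(beta, detection_p = NULL, bead_count = NULL) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have rownames (site ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate site ids in beta matrix")
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids in beta matrix")
  rng <- range(beta, na.rm = TRUE)
  if (!all(is.na(beta)) && (rng[1] < 0 || rng[2] > 1))
    stop("beta value out of range [0,1]")
  check_layer <- function(layer, name, lo = 0, hi = Inf) {
    if (is.null(layer)) return(NULL)
    layer <- as.matrix(layer)
    storage.mode(layer) <- "double"
    if (!identical(dim(layer), dim(beta)))
      stop(sprintf("layer '%s' dimensions do not match beta", name))
    if (!identical(dimnames(layer), dimnames(beta)))
      stop(sprintf("layer '%s' site/sample ordering does not match beta", name))
    if (any(layer < lo | layer > hi, na.rm = TRUE))
      stop(sprintf("layer '%s' has values outside [%s, %s]", name, lo, hi))
    layer
  }
  structure(
    list(beta = beta,
         detection_p = check_layer(detection_p, "detection_p", 0, 1),
         bead_count = check_layer(bead_count, "bead_count", 0, Inf)),
    class = "beta_matrix")
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

#' Site and sample identifiers of a beta matrix
#' @param bm a `beta_matrix`
#' @return character vector of ids
#' @export
site_ids <- function(bm) rownames(bm$beta)

#' @rdname site_ids
#' @export
sample_ids <- function(bm) colnames(bm$beta)

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d sites x %d samples\n", nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  layers: beta%s%s\n",
              if (!is.null(x$detection_p)) ", detection_p" else "",
              if (!is.null(x$bead_count)) ", bead_count" else ""))
  nmiss <- sum(is.na(x$beta))
  if (nmiss > 0) cat(sprintf("  missing beta values: %d\n", nmiss))
  invisible(x)
}

#' Subset a beta matrix by sites and/or samples
#'
#' Subsets all layers consistently. Either index may be a character vector of
#' ids, a logical vector, or integer positions.
#'
#' @param bm a `beta_matrix`
#' @param sites,samples indices; `NULL` keeps everything.
#' @return a `beta_matrix`
#' @export
bm_subset <- function(bm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(bm$beta))
  if (is.null(samples)) samples <- seq_len(ncol(bm$beta))
  sub <- function(m) if (is.null(m)) NULL else m[sites, samples, drop = FALSE]
  beta_matrix(sub(bm$beta), sub(bm$detection_p), sub(bm$bead_count))
}
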