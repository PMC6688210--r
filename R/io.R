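# Delimited-text readers/writers for the package's interchange formats.
# Delimiter auto-detected between comma and tab; all files UTF-8.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop(sprintf("empty file: %s", path))
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

read_matrix_file <- function(path, what) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicate site ids in %s file", what))
  if (anyDuplicated(colnames(m)))
    stop(sprintf("duplicate sample ids in %s file", what))
  m
}

#' Read a beta matrix (with optional detection p-value / bead-count layers)
#'
#' Files are delimited tables (comma or tab, auto-detected) with site ids in
#' the first column and sample ids in the header row. Blank cells become
#' missing values. All layers must agree exactly in site and sample ordering.
#'
#' @param path path to the beta-value table.
#' @param detection_path,beadcount_path optional paths to aligned layers.
#' @return a [beta_matrix]
#' @export
read_beta_matrix <- function(path, detection_path = NULL, beadcount_path = NULL) {
  beta <- read_matrix_file(path, "beta")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta value out of range [0,1]")
  read_layer <- function(p, name) {
    if (is.null(p)) return(NULL)
    m <- read_matrix_file(p, name)
    if (!identical(dim(m), dim(beta)) || !identical(dimnames(m), dimnames(beta)))
      stop(sprintf("layer '%s' does not align with the beta matrix (check site/sample order)", name))
    m
  }
  beta_matrix(beta,
              detection_p = read_layer(detection_path, "detection_p"),
              bead_count = read_layer(beadcount_path, "bead_count"))
}

#' Write a beta matrix (and optional layers) to delimited text
#'
#' @param bm a [beta_matrix]
#' @param path output path for the beta layer.
#' @param detection_path,beadcount_path optional output paths for the layers.
#' @param sep field delimiter.
#' @export
write_beta_matrix <- function(bm, path, detection_path = NULL,
                              beadcount_path = NULL, sep = "\t") {
  wr <- function(m, p) {
    df <- data.frame(site_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = sep, quote = FALSE, row.names = FALSE)
  }
  wr(bm$beta, path)
  if (!is.null(detection_path) && !is.null(bm$detection_p))
    wr(bm$detection_p, detection_path)
  if (!is.null(beadcount_path) && !is.null(bm$bead_count))
    wr(bm$bead_count, beadcount_path)
  invisible(path)
}

#' Ethnicity label aliases
#'
#' The declared, versioned mapping from free-text self-reported ethnicity
#' strings to the three class labels. Strings not in this table (and not
#' already a class label) are mapped to missing with a warning.
#' @return named character vector (alias -> class label)
#' @export
ethnicity_aliases <- function() {
  c("African" = "African",
    "Black" = "African",
    "Black/African American" = "African",
    "African American" = "African",
    "Asian" = "Asian",
    "East Asian" = "Asian",
    "South Asian" = "Asian",
    "Caucasian" = "Caucasian",
    "White" = "Caucasian",
    "Caucasian/White" = "Caucasian",
    "European" = "Caucasian")
}

ethnicity_classes <- function() c("African", "Asian", "Caucasian")

normalize_ethnicity <- function(x) {
  al <- ethnicity_aliases()
  out <- unname(al[as.character(x)])
  unknown <- !is.na(x) & x != "" & is.na(out)
  if (any(unknown))
    warning(sprintf("unknown ethnicity strings mapped to missing: %s",
                    paste(unique(x[unknown]), collapse = ", ")))
  out
}

normalize_sex <- function(x) {
  map <- c("M" = "M", "Male" = "M", "male" = "M", "m" = "M",
           "F" = "F", "Female" = "F", "female" = "F", "f" = "F")
  out <- unname(map[as.character(x)])
  unknown <- !is.na(x) & x != "" & is.na(out)
  if (any(unknown))
    warning(sprintf("unknown sex strings mapped to missing: %s",
                    paste(unique(x[unknown]), collapse = ", ")))
  out
}

#' Read a sample sheet
#'
#' CSV/TSV with required columns `sample_id`, `dataset_id`,
#' `reported_ethnicity`, `reported_sex`; any further columns are kept as
#' covariates. Ethnicity strings are normalized through [ethnicity_aliases()];
#' unknown strings become missing with a warning.
#'
#' @param path file path.
#' @return a `data.frame` with normalized columns.
#' @export
read_sample_sheet <- function(path) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  required <- c("sample_id", "dataset_id", "reported_ethnicity", "reported_sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("sample sheet missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  df$sample_id <- as.character(df$sample_id)
  df$dataset_id <- as.character(df$dataset_id)
  df$reported_ethnicity <- normalize_ethnicity(df$reported_ethnicity)
  df$reported_sex <- normalize_sex(df$reported_sex)
  df
}

#' Read a site annotation manifest
#'
#' CSV/TSV with one row per site. Required columns: `site_id`, `probe_class`
#' (CpG/SNP), `design_type` (I/II), `chromosome` (1..22, X, Y),
#' `island_relation` (Island, N_Shore, S_Shore, N_Shelf, S_Shelf, OpenSea),
#' `on_epic`, `cross_hybridizing`, `nonvariable`, `snp_in_probe` (logicals),
#' `dist_to_variant` (non-negative bp or missing), `mqtl` (logical).
#'
#' @param path file path.
#' @return a `data.frame`, one row per site.
#' @export
read_annotation <- function(path) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  required <- c("site_id", "probe_class", "design_type", "chromosome",
                "island_relation", "on_epic", "cross_hybridizing",
                "nonvariable", "snp_in_probe", "dist_to_variant", "mqtl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("annotation missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in annotation")
  chk_enum <- function(x, levels, name) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad))
      stop(sprintf("annotation column '%s' has invalid value(s): %s",
                   name, paste(unique(x[bad]), collapse = ", ")))
  }
  df$chromosome <- as.character(df$chromosome)
  chk_enum(df$probe_class, c("CpG", "SNP"), "probe_class")
  chk_enum(df$design_type, c("I", "II"), "design_type")
  chk_enum(df$chromosome, c(as.character(1:22), "X", "Y"), "chromosome")
  chk_enum(df$island_relation,
           c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
           "island_relation")
  for (col in c("on_epic", "cross_hybridizing", "nonvariable", "snp_in_probe", "mqtl"))
    df[[col]] <- as.logical(df[[col]])
  df$dist_to_variant <- as.numeric(df$dist_to_variant)
  if (any(df$dist_to_variant < 0, na.rm = TRUE))
    stop("dist_to_variant must be non-negative")
  df
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Save / load a fitted ethnicity model
#'
#' Models are serialized as versioned JSON; all numeric fields round-trip at
#' full double precision so a reloaded model reproduces predictions exactly.
#'
#' @param model an `ethnicity_model` (see [fit_ethnicity_model()]).
#' @param path file path (JSON).
#' @return `load_model` returns the `ethnicity_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ethnicity_model"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    classes = model$classes,
    model_sites = model$model_sites,
    intercepts = unname(model$intercepts),
    coefficients = lapply(model$classes, function(cl) unname(model$coefficients[, cl])),
    alpha = model$alpha,
    lambda = model$lambda,
    center = unname(model$center),
    scale = unname(model$scale),
    threshold = model$threshold,
    preprocessing_record = model$preprocessing_record)
  # 17 significant digits: doubles round-trip bit-for-bit through the text
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                      error = function(e) stop(sprintf("cannot parse model file '%s': %s",
                                                       path, conditionMessage(e))))
  if (is.null(payload$schema_version))
    stop("model file has no schema_version field")
  if (!identical(as.character(payload$schema_version), MODEL_SCHEMA_VERSION))
    stop(sprintf("model schema version mismatch: file has '%s', package expects '%s'",
                 payload$schema_version, MODEL_SCHEMA_VERSION))
  p <- length(payload$model_sites)
  coefs <- matrix(0, nrow = p, ncol = length(payload$classes),
                  dimnames = list(payload$model_sites, payload$classes))
  # jsonlite may simplify the per-class list to a classes x sites matrix
  cf <- payload$coefficients
  for (i in seq_along(payload$classes))
    coefs[, i] <- if (is.matrix(cf)) cf[i, ] else cf[[i]]
  new_ethnicity_model(
    classes = payload$classes,
    intercepts = stats::setNames(payload$intercepts, payload$classes),
    coefficients = coefs,
    alpha = payload$alpha,
    lambda = payload$lambda,
    center = stats::setNames(payload$center, payload$model_sites),
    scale = stats::setNames(payload$scale, payload$model_sites),
    threshold = payload$threshold,
    preprocessing_record = payload$preprocessing_record)
}

#' Write a prediction table
#'
#' @param pred a data.frame as returned by [call_ethnicity()].
#' @param path output CSV path.
#' @export
write_predictions <- function(pred, path) {
  utils::write.csv(pred, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
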