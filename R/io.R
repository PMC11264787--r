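# Readers/writers for the tabular interchange formats (TSV matrices, CSV
# phenotype tables, GMT gene sets) and the run configuration.

#' Read a count matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample IDs and the
#' feature IDs in the first column. `orientation = "samples_x_features"`
#' transposes, so the result is always features x samples.
#'
#' @param path file path.
#' @param orientation `"features_x_samples"` (default) or
#'   `"samples_x_features"`.
#' @return integer matrix with dimnames.
#' @export
read_count_matrix <- function(path,
                              orientation = c("features_x_samples",
                                              "samples_x_features")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_mv("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_mv("cannot parse '%s': %s", path, conditionMessage(e)))
  if (!nrow(df) || ncol(df) < 2) stop_mv("'%s' is empty or has no data columns", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop_mv("duplicate feature IDs in '%s'", path)
  if (anyDuplicated(names(df)[-1])) stop_mv("duplicate sample IDs in '%s'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop_mv("non-integer or negative count at row '%s', column '%s' of '%s'",
            rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path)
  storage.mode(m) <- "integer"
  if (orientation == "samples_x_features") m <- t(m)
  m
}

#' Write a count or numeric matrix as TSV
#'
#' @param m matrix with dimnames (features x samples).
#' @param path output path.
#' @param id_col name for the leading ID column, default "feature_id".
#' @export
write_count_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the per-sample phenotype table (CSV)
#'
#' @param path CSV path with a `sample_id` column.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop_mv("phenotype file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop_mv("'%s' lacks a sample_id column", path)
  if (anyDuplicated(df$sample_id)) stop_mv("duplicate sample_ids in '%s'", path)
  if (anyDuplicated(names(df))) stop_mv("duplicate columns in '%s'", path)
  if ("age" %in% names(df) && any(df$age <= 0, na.rm = TRUE))
    stop_mv("non-positive age in '%s'", path)
  df
}

#' @rdname read_sample_table
#' @param df data.frame to write.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (term, description, tab-separated genes).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_mv("malformed GMT line: %s", substr(l, 1, 40))
    stats::setNames(list(f[-(1:2)]), f[1])
  })
  do.call(c, sets)
}

#' @rdname read_gmt
#' @param sets named list of gene sets.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default run configuration
#'
#' All stage parameters with their analysis defaults: scale-free fit target
#' 0.90, minimum module size 5, merge cut height 0.2; module FDR thresholds
#' 0.05 (strict) and 0.1 (lenient); hub thresholds MM > 0.8 and p < 0.05;
#' eQTL cis window 1 Mb, genome-wide alpha 5e-8, clump r2 0.6, lead r2 0.1;
#' mediation bootstrap 1000.
#'
#' @param overrides named list (possibly nested) of values to override.
#' @return validated config list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1,
    network = list(powers = 1:20, target = 0.90, min_size = 5,
                   cut_height = 0.2),
    filter = list(min_mean = 15, min_prop = 0.05),
    association = list(fdr_strict = 0.05, fdr_lenient = 0.1),
    hub = list(mm_thresh = 0.8, p_thresh = 0.05),
    mediation = list(n_boot = 1000),
    eqtl = list(cis_window = 1e6, alpha = 5e-8, r2_locus = 0.6,
                r2_lead = 0.1, n_pc = 10),
    paths = list()
  )
  cfg <- utils::modifyList(cfg, overrides)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  probs <- c(cfg$network$target, cfg$association$fdr_strict,
             cfg$association$fdr_lenient, cfg$hub$mm_thresh,
             cfg$hub$p_thresh, cfg$eqtl$alpha, cfg$eqtl$r2_locus,
             cfg$eqtl$r2_lead, cfg$network$cut_height)
  if (any(probs <= 0 | probs >= 1))
    stop_mv("all probability-type thresholds must lie in (0, 1)")
  if (cfg$eqtl$cis_window <= 0) stop_mv("cis window must be positive")
  if (cfg$network$min_size < 2) stop_mv("minimum module size must be >= 2")
  cfg
}

#' Read / write a run configuration (YAML)
#'
#' The configuration is a plain-text key/value record so a run's parameters
#' travel with its outputs.
#'
#' @param path YAML file path.
#' @return validated config list (merged over the defaults).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_mv("config file not found: %s", path)
  default_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg config list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
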