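#' Write a numeric matrix to the dense TSV container
#'
#' Header row of column names, first column of row names; an optional JSON
#' sidecar (`<path>.meta.json`) records metadata (generator parameters,
#' seeds, alignment flags). Vertex indexing in all containers is 0-based
#' and documented in the sidecar.
#'
#' @param matrix numeric matrix.
#' @param path output path (TSV).
#' @param metadata optional named list serialized to the sidecar.
#' @return the path, invisibly.
#' @export
write_matrix <- function(matrix, path, metadata = NULL) {
  check_matrix(matrix, "matrix")
  rn <- rownames(matrix) %||% sprintf("r%d", seq_len(nrow(matrix)) - 1L)
  cn <- colnames(matrix) %||% sprintf("c%d", seq_len(ncol(matrix)) - 1L)
  fm <- apply(matrix, 2, function(col) sprintf("%.17g", col))
  df <- data.frame(id = rn, fm, check.names = FALSE)
  names(df) <- c("id", cn)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata))
    jsonlite::write_json(metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a numeric matrix from the dense TSV container
#'
#' @param path TSV path written by [write_matrix()] (or any dense TSV with a
#'   header row and a leading row-name column).
#' @return numeric matrix with dimnames; sidecar metadata, if present, is
#'   attached as the `metadata` attribute.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = NA),
    error = function(e) stop_param("malformed matrix container %s: %s",
                                   path, conditionMessage(e)))
  if (ncol(df) < 2) stop_param("malformed matrix container %s: no data columns", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_param("malformed matrix container %s: non-numeric values", path)
  rownames(m) <- df[[1]]
  side <- paste0(path, ".meta.json")
  if (file.exists(side))
    attr(m, "metadata") <- jsonlite::read_json(side, simplifyVector = TRUE)
  m
}

table_schemas <- list(
  cohort = c("scan_id", "individual_id", "cohort_id", "age_years", "sex", "arousal"),
  labels = c("vertex", "network", "parcel", "medial"),
  metrics = c("scan_id", "dispersion", "grange_SA", "grange_VS", "grange_MR",
              "cossim_SA", "cossim_VS", "cossim_MR", "eval1", "eval2", "eval3",
              "mean_degree"),
  scores = c("scan_id"),
  generic = character(0))

#' Read a tidy TSV table with schema validation
#'
#' @param path TSV path.
#' @param kind table kind (`cohort`, `labels`, `metrics`, `scores`,
#'   `generic`); required columns are validated, unknown columns preserved.
#' @return a tibble.
#' @export
read_table <- function(path, kind = "generic") {
  kind <- match.arg(kind, names(table_schemas))
  if (!file.exists(path)) stop_param("no such file: %s", path)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(table_schemas[[kind]], names(tbl))
  if (length(miss))
    stop_param("%s table %s lacks required column(s): %s", kind, path,
               paste(miss, collapse = ", "))
  tbl
}

#' Write a tidy TSV table
#'
#' @param table a data frame or tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Every default matches the study's printed setting where one exists:
#' row-threshold density 0.10, 10 embedding components, 10 template age
#' bins, age-transform exponent 0.5, harmonization bases k_low 4 / k_test 6
#' / k_high 10, 5000 PLS permutations, 20000 posterior draws, percentile
#' bounds 5/95. All overridable via a YAML/JSON config file.
#'
#' @return a named list.
#' @export
default_config <- function() {
  list(
    n_vertices = 400, n_networks = 7, n_parcels = 60, medial_fraction = 0.05,
    density = 0.10, n_components = 10, embed_alpha = 0.5, diffusion_time = 0,
    n_bins = 10, n_keep = 10,
    age_alpha = 0.5, k_low = 4, k_test = 6, k_high = 10, weight_bins = 20,
    n_perm = 5000, n_draws = 20000, percentiles = c(5, 95),
    pls_ages = c(0.5, 2, 10, 25, 40, 80),
    n_genes = 200, frac_coupled = 0.3, n_terms = 24,
    score_beta_grad = 0.3, score_noise_sd = 1,
    seed = 1,
    stages = c("simulate", "gradients", "template", "align", "metrics",
               "trajectories", "associate", "meta_axis", "pls"))
}

#' Read a run configuration (YAML or JSON), merged over the defaults
#'
#' @param path config file path; `NULL` returns the defaults.
#' @return a named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_param("no such config file: %s", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
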