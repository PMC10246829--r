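#' Construct an omics abundance matrix with sample metadata
#'
#' The central data container: a features x samples numeric matrix together
#' with a per-sample metadata table assigning each sample to a population and
#' a role (`"ancestral"` or `"evolved"`). Counts matrices hold non-negative
#' integers; `"log_area"` matrices hold log-transformed normalized peak areas;
#' `"area"` matrices hold raw (positive) normalized areas awaiting the log
#' transform.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row
#'   names are feature ids; column names are sample ids.
#' @param meta Data frame with columns `sample_id`, `population`, `role`,
#'   `replicate`, one row per sample, in the same order as the columns of
#'   `values`.
#' @param value_kind One of `"counts"`, `"log_area"`, `"area"`, `"cpm"`.
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `meta`, `value_kind`.
#' @export
omics_matrix <- function(values, meta, value_kind = c("counts", "log_area", "area", "cpm")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyNA(rownames(values)) || any(rownames(values) == "")) {
    stop("validation error: all features must have non-missing ids (rownames)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("validation error: duplicate feature_ids")
  }
  meta <- validate_sample_meta(meta)
  if (ncol(values) != nrow(meta)) {
    stop("schema error: matrix has ", ncol(values), " samples but metadata has ", nrow(meta))
  }
  if (!is.null(colnames(values)) && !identical(colnames(values), meta$sample_id)) {
    stop("schema error: matrix column names do not match metadata sample_ids (same order required)")
  }
  colnames(values) <- meta$sample_id
  if (value_kind == "counts") {
    if (any(values < 0)) stop("validation error: negative counts")
    if (any(abs(values - round(values)) > 1e-8)) {
      stop("validation error: counts must be integers")
    }
  }
  if (value_kind == "area" && any(values < 0)) {
    stop("validation error: negative normalized areas")
  }
  structure(list(values = values, meta = meta, value_kind = value_kind),
            class = "omics_matrix")
}

#' @keywords internal
validate_sample_meta <- function(meta) {
  req <- c("sample_id", "population", "role", "replicate")
  if (!is.data.frame(meta) || !all(req %in% names(meta))) {
    stop("schema error: metadata needs columns ", paste(req, collapse = ", "))
  }
  meta <- as.data.frame(meta)[, req]
  meta$sample_id <- as.character(meta$sample_id)
  meta$population <- as.character(meta$population)
  meta$role <- as.character(meta$role)
  meta$replicate <- as.integer(meta$replicate)
  if (anyDuplicated(meta$sample_id)) stop("validation error: duplicate sample_ids")
  if (!all(meta$role %in% c("ancestral", "evolved"))) {
    stop("validation error: role must be 'ancestral' or 'evolved'")
  }
  anc_pops <- unique(meta$population[meta$role == "ancestral"])
  if (any(meta$population[meta$role == "evolved"] %in% anc_pops)) {
    stop("validation error: evolved samples must not share the ancestral population label")
  }
  if (any(meta$replicate < 1L, na.rm = TRUE)) {
    stop("validation error: replicate must be a positive integer")
  }
  rownames(meta) <- NULL
  meta
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  pops <- table(x$meta$population)
  cat("populations:", paste(sprintf("%s(%d)", names(pops), pops), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample ids of the evolved populations present in a matrix
#' @param x An `omics_matrix`.
#' @return Character vector of evolved population labels, in metadata order.
#' @export
evolved_populations <- function(x) {
  unique(x$meta$population[x$meta$role == "evolved"])
}

#' @keywords internal
samples_of <- function(x, population = NULL, role = NULL) {
  keep <- rep(TRUE, nrow(x$meta))
  if (!is.null(population)) keep <- keep & x$meta$population %in% population
  if (!is.null(role)) keep <- keep & x$meta$role %in% role
  x$meta$sample_id[keep]
}

#' Read an omics matrix and its sample metadata from TSV files
#'
#' @param path_values TSV file: header row of sample ids, first column of
#'   feature ids.
#' @param path_meta TSV file with columns `sample_id`, `population`, `role`,
#'   `replicate`.
#' @param value_kind Passed to [omics_matrix()].
#' @return A validated [omics_matrix()].
#' @export
read_omics_matrix <- function(path_values, path_meta,
                              value_kind = c("counts", "log_area", "area", "cpm")) {
  value_kind <- match.arg(value_kind)
  tab <- utils::read.delim(path_values, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("schema error: values TSV needs feature id column plus samples")
  if (anyDuplicated(tab[[1L]])) stop("validation error: duplicate feature_ids in ", path_values)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1L]])
  meta <- utils::read.delim(path_meta, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  meta <- validate_sample_meta(meta)
  if (!setequal(colnames(values), meta$sample_id)) {
    missing_m <- setdiff(colnames(values), meta$sample_id)
    missing_v <- setdiff(meta$sample_id, colnames(values))
    stop("schema error: sample_ids differ between matrix and metadata",
         if (length(missing_m)) paste0("; absent from metadata: ", paste(missing_m, collapse = ",")),
         if (length(missing_v)) paste0("; absent from matrix: ", paste(missing_v, collapse = ",")))
  }
  values <- values[, meta$sample_id, drop = FALSE]
  omics_matrix(values, meta, value_kind)
}

#' Write an omics matrix (and optionally its metadata) to TSV
#'
#' Values are written with the `%.17g` format, so a write/read round trip
#' reproduces the matrix bit-exactly.
#'
#' @param x An `omics_matrix`.
#' @param path_values Output TSV path for the matrix.
#' @param path_meta Optional output TSV path for the metadata.
#' @return Invisibly, `x`.
#' @export
write_omics_matrix <- function(x, path_values, path_meta = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  chr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  df <- data.frame(feature_id = rownames(x$values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(x$values))
  utils::write.table(df, path_values, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_meta)) {
    utils::write.table(x$meta, path_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}
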