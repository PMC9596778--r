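#' @keywords internal
"_PACKAGE"

#' Construct a validated expression matrix
#'
#' The package carries expression data as a plain numeric matrix with genes in
#' rows and samples in columns, plus a `scale_tag` attribute recording the
#' measurement scale. Bulk array inputs are expected on the log2 scale;
#' single-cell inputs are raw counts.
#'
#' @param values Numeric matrix, genes x samples, with unique row and column
#'   names and no missing values.
#' @param scale_tag One of `"log2"`, `"linear"`, `"counts"`.
#' @return The matrix with a `scale_tag` attribute, after validation.
#' @export
expression_matrix <- function(values, scale_tag = c("log2", "linear", "counts")) {
  scale_tag <- match.arg(scale_tag)
  values <- as_dense(values)
  validate_expression_matrix(values)
  attr(values, "scale_tag") <- scale_tag
  values
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) stop("expression values must be a matrix", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

validate_expression_matrix <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s' (imputation is not a default)",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]), call. = FALSE)
  }
  invisible(values)
}

scale_tag <- function(x) {
  tag <- attr(x, "scale_tag")
  if (is.null(tag)) "linear" else tag
}

#' Construct a signature collection
#'
#' A named list of gene-ID character vectors. Set names must be unique and
#' within-set duplicates are collapsed.
#'
#' @param gene_sets Named list of character vectors (each of size >= 1).
#' @param source_tag Free-text provenance note.
#' @return Object of class `signature_collection`.
#' @export
signature_collection <- function(gene_sets, source_tag = "") {
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets))))
    stop("every gene set must be named", call. = FALSE)
  if (anyDuplicated(names(gene_sets)))
    stop("duplicate set names: ",
         paste(unique(names(gene_sets)[duplicated(names(gene_sets))]), collapse = ", "), call. = FALSE)
  gene_sets <- lapply(gene_sets, function(g) unique(as.character(g)))
  if (any(lengths(gene_sets) == 0L)) stop("empty gene sets are not allowed", call. = FALSE)
  structure(gene_sets, class = "signature_collection", source_tag = source_tag)
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("signature_collection: %d sets, %d..%d genes each\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Construct a survival table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param time Non-negative follow-up times (units carried in `time_unit`).
#' @param event Event indicator: 1 = recurrence/death observed, 0 = censored.
#' @param time_unit Free-text unit label ("days", "months", ...).
#' @return `data.frame` with columns `sample_id`, `time`, `event` and a
#'   `time_unit` attribute.
#' @export
survival_table <- function(sample_id, time, event, time_unit = "months") {
  sample_id <- as.character(sample_id)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs in survival table", call. = FALSE)
  if (length(time) != length(sample_id) || length(event) != length(sample_id))
    stop("sample_id, time and event must have equal length", call. = FALSE)
  if (anyNA(time) || anyNA(event)) stop("missing survival values", call. = FALSE)
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (observed)", call. = FALSE)
  out <- data.frame(sample_id = sample_id, time = time, event = as.integer(event),
                    stringsAsFactors = FALSE)
  attr(out, "time_unit") <- time_unit
  out
}

#' Bundle expression, survival and metadata for one cohort
#'
#' @param name Cohort name (unique within a multi-cohort collection).
#' @param expression Expression matrix (see [expression_matrix()]).
#' @param survival Survival table (see [survival_table()]); every survival
#'   sample must be present in the expression matrix.
#' @param metadata Optional per-sample `data.frame` keyed by `sample_id`.
#' @return Object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(name, expression, survival, metadata = NULL) {
  validate_expression_matrix(as_dense(expression))
  missing <- setdiff(survival$sample_id, colnames(expression))
  if (length(missing))
    stop("survival samples absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  structure(list(name = as.character(name), expression = expression,
                 survival = survival, metadata = metadata),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset '%s': %d genes x %d samples, %d with survival (%d events)\n",
              x$name, nrow(x$expression), ncol(x$expression),
              nrow(x$survival), sum(x$survival$event)))
  invisible(x)
}
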