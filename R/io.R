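#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are collapsed; duplicate set names or lines with fewer than three
#' fields are errors.
#'
#' @param path Path to a GMT file.
#' @param source_tag Provenance note stored on the collection.
#' @return A [signature_collection()].
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 tab-separated fields", call. = FALSE)
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    dup <- nm[duplicated(nm)][1L]
    stop(sprintf("duplicate set name '%s' (line %d)", dup, which(nm == dup)[2L]), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  signature_collection(sets, source_tag = source_tag)
}

#' Write a signature collection as GMT
#'
#' @param sigs A [signature_collection()].
#' @param path Output path.
#' @param description Description field written on every line.
#' @export
write_gmt <- function(sigs, path, description = "na") {
  stopifnot(inherits(sigs, "signature_collection"))
  lines <- vapply(seq_along(sigs), function(i) {
    paste(c(names(sigs)[i], description, sigs[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("\t", header, fixed = TRUE) && grepl(",", header, fixed = TRUE)) "," else "\t"
}

#' Read a delimited expression table
#'
#' Accepts either orientation and always returns a genes x samples matrix.
#' The delimiter is tab by default with comma auto-detected from the header.
#' Missing or non-numeric cells are errors (reported with coordinates), as is
#' any duplicated ID.
#'
#' @param path Delimited text file with one ID header row and one ID column.
#' @param layout `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param scale_tag Scale of the stored values; see [expression_matrix()].
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` on load (for counts
#'   destined for NES scaling; rank-based enrichment itself is unaffected by
#'   monotone transforms).
#' @return A genes x samples [expression_matrix()].
#' @export
read_expression <- function(path, layout = c("genes_in_rows", "samples_in_rows"),
                            scale_tag = "log2", log2_transform = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  ids <- tab[[1L]]
  body <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(body) <- ids
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                  dimnames = dimnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing cell '%s' at row '%s', column '%s'",
                 body[bad[1L], bad[2L]], rownames(body)[bad[1L]], colnames(body)[bad[2L]]),
         call. = FALSE)
  }
  if (layout == "samples_in_rows") vals <- t(vals)
  if (log2_transform) {
    vals <- log2(vals + 1)
    scale_tag <- "log2"
  }
  expression_matrix(vals, scale_tag = scale_tag)
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' Values are written with 17 significant digits so that a read/write round
#' trip reproduces them to full double precision.
#'
#' @param x Genes x samples matrix.
#' @param path Output path.
#' @param id_column Name of the leading ID column in the header.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  x <- as_dense(x)
  validate_expression_matrix(x)
  header <- paste(c(id_column, colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a MatrixMarket triplet (matrix + features + barcodes)
#'
#' Standard single-cell carrier: a coordinate `.mtx` with sidecar feature and
#' barcode files (one ID per line; for multi-column feature files the first
#' column is taken). Dimensions must agree with the sidecars. All-zero
#' columns (empty cells) are retained and reported via a message.
#'
#' @param matrix_path Path to the MatrixMarket coordinate file.
#' @param features_path Path to the feature (gene) ID file.
#' @param barcodes_path Path to the cell barcode file.
#' @param sparse Keep the loaded matrix sparse (`dgCMatrix`); otherwise dense.
#' @return Genes x cells matrix with `scale_tag = "counts"`.
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path, sparse = TRUE) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.table(features_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  bcs <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[[1L]]
  if (nrow(m) != length(feats))
    stop(sprintf("feature file has %d lines but matrix header declares %d rows",
                 length(feats), nrow(m)), call. = FALSE)
  if (ncol(m) != length(bcs))
    stop(sprintf("barcode file has %d lines but matrix header declares %d columns",
                 length(bcs), ncol(m)), call. = FALSE)
  dimnames(m) <- list(feats, bcs)
  zero_cols <- Matrix::colSums(m != 0) == 0
  if (any(zero_cols))
    message(sum(zero_cols), " all-zero column(s) retained: ",
            paste(utils::head(bcs[zero_cols], 5L), collapse = ", "))
  if (!sparse) {
    out <- expression_matrix(as.matrix(m), scale_tag = "counts")
    return(out)
  }
  validate_expression_matrix_ids(feats, bcs)
  attr(m, "scale_tag") <- "counts"
  m
}

validate_expression_matrix_ids <- function(genes, samples) {
  if (anyDuplicated(genes)) stop("duplicate gene IDs in features file", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicate barcodes", call. = FALSE)
  invisible(TRUE)
}

#' Read a clinical survival TSV
#'
#' Expects columns `sample_id`, `time`, `event` (extra columns are kept as
#' metadata attributes).
#'
#' @param path Delimited clinical table.
#' @param time_unit Unit label carried on the result.
#' @return A [survival_table()].
#' @export
read_survival <- function(path, time_unit = "months") {
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  out <- survival_table(tab$sample_id, tab$time, tab$event, time_unit = time_unit)
  extra <- setdiff(names(tab), need)
  if (length(extra)) attr(out, "metadata") <- tab[, c("sample_id", extra), drop = FALSE]
  out
}

#' Per-signature gene-overlap report
#'
#' Gene-ID matching between expression and signatures is exact-string and
#' case-sensitive; this report is emitted alongside every enrichment run so
#' mapping losses are visible.
#'
#' @param expr Genes x samples matrix.
#' @param sigs A [signature_collection()].
#' @return `data.frame` with columns `signature`, `n_genes`, `n_matched`,
#'   `fraction`.
#' @export
signature_overlap <- function(expr, sigs) {
  genes <- rownames(expr)
  n_matched <- vapply(sigs, function(g) sum(g %in% genes), integer(1L))
  data.frame(signature = names(sigs), n_genes = lengths(sigs),
             n_matched = n_matched, fraction = n_matched / lengths(sigs),
             row.names = NULL, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
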