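#' Average expression within groups of cells
#'
#' Per-gene arithmetic mean within each label (cluster or patient), on
#' whatever scale the input carries. Labels with zero cells are absent from
#' the output and reported via a message. Accepts dense or sparse matrices.
#'
#' @param expr Genes x cells matrix.
#' @param labels Label per cell (length = `ncol(expr)`).
#' @return Genes x labels matrix of group means.
#' @export
average_by_group <- function(expr, labels) {
  if (length(labels) != ncol(expr)) stop("one label per cell required", call. = FALSE)
  if (anyNA(labels)) stop("every cell must be labeled", call. = FALSE)
  if (!is.factor(labels)) labels <- factor(labels)
  empty <- levels(labels)[tabulate(labels, nlevels(labels)) == 0L]
  if (length(empty)) message("label(s) with 0 cells dropped: ", paste(empty, collapse = ", "))
  labels <- droplevels(labels)
  ind <- Matrix::sparseMatrix(i = seq_along(labels), j = as.integer(labels),
                              x = 1, dims = c(length(labels), nlevels(labels)))
  sums <- as.matrix(expr %*% ind)
  means <- sweep(sums, 2L, tabulate(labels, nlevels(labels)), "/")
  colnames(means) <- levels(labels)
  rownames(means) <- rownames(expr)
  means
}

#' Per-cell IRScore with median grouping
#'
#' ssGSEA per cell, by default ranking only the cell's nonzero genes
#' (zero-inflated counts otherwise make full-rank ties dominate the walk);
#' `rank_all_genes = TRUE` ranks the whole gene universe instead. Raw scores
#' are z-scaled to NES across cells, combined by the signed verdict sum, and
#' cells are split at the median score. Signatures with fewer than 2 matched
#' genes among a cell's nonzero ranks contribute a raw score of 0 for that
#' cell (flagged).
#'
#' @param expr Genes x cells matrix (counts or log-normalized).
#' @param sigs A [signature_collection()].
#' @param verdicts Verdict frame as for [compute_irscore()].
#' @param alpha ssGSEA rank-weight exponent.
#' @param rank_all_genes Rank all genes instead of nonzero genes only.
#' @return List with `scores` (an `irscore_table` over cells), `nes`
#'   (signatures x cells), and `n_flagged` (count of (signature, cell) pairs
#'   scored 0 for insufficient nonzero overlap).
#' @export
score_cells <- function(expr, sigs, verdicts, alpha = 0.25, rank_all_genes = FALSE) {
  expr <- as_dense(expr)
  validate_expression_matrix(expr)
  stopifnot(inherits(sigs, "signature_collection"))
  if (rank_all_genes) {
    es <- ssgsea_scores(expr, sigs, alpha = alpha)
  } else {
    es <- ssgsea_nonzero(expr, sigs, alpha = alpha)
  }
  nes <- normalize_to_nes(es)
  scores <- compute_irscore(nes, verdicts)
  list(scores = scores, nes = nes,
       n_flagged = attr(es, "n_flagged") %||% 0L)
}

## ssGSEA restricted, per cell, to that cell's nonzero genes.
ssgsea_nonzero <- function(expr, sigs, alpha = 0.25) {
  keep <- prune_signatures(expr, sigs)
  gene_ids <- rownames(expr)
  scores <- matrix(0, nrow = length(keep$sets), ncol = ncol(expr),
                   dimnames = list(names(keep$sets), colnames(expr)))
  n_flagged <- 0L
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    nz <- which(x > 0)
    N <- length(nz)
    if (N < 3L) { n_flagged <- n_flagged + length(keep$sets); next }
    xv <- x[nz]
    rv <- rank(xv, ties.method = "average")
    w <- abs(rv)^alpha
    ord <- order(-xv, gene_ids[nz])
    pos <- integer(N); pos[ord] <- seq_len(N)
    steps <- N - pos + 1L
    total_steps <- N * (N + 1) / 2
    for (s in seq_along(keep$sets)) {
      hit <- which(nz %in% keep$index[[s]])
      m <- length(hit)
      if (m < 2L || m == N) { n_flagged <- n_flagged + 1L; next }
      hitsum <- sum(w[hit] * steps[hit]) / sum(w[hit])
      misssum <- (total_steps - sum(steps[hit])) / (N - m)
      scores[s, j] <- hitsum - misssum
    }
  }
  out <- enrichment_result(scores, variant = "raw_es", method = "ssgsea_nonzero",
                           overlap = keep$overlap, dropped = keep$dropped)
  attr(out, "n_flagged") <- n_flagged
  out
}

#' Classify cells by CD103/CD39 double positivity
#'
#' DP if both markers exceed the threshold, DN if neither does, SP otherwise.
#' The default markers are the genes encoding CD103 (ITGAE) and CD39
#' (ENTPD1); the default gate treats any detected transcript as expressing
#' (threshold 0 on counts).
#'
#' @param expr Genes x cells matrix.
#' @param marker_a,marker_b Marker gene IDs (must be present in `expr`).
#' @param threshold Positivity gate applied to both markers.
#' @return Factor per cell with levels `DN`, `SP`, `DP`.
#' @export
classify_dp <- function(expr, marker_a = "ITGAE", marker_b = "ENTPD1", threshold = 0) {
  for (mk in c(marker_a, marker_b)) {
    if (!mk %in% rownames(expr)) stop("marker gene absent from matrix: ", mk, call. = FALSE)
  }
  a <- as.numeric(expr[marker_a, ]) > threshold
  b <- as.numeric(expr[marker_b, ]) > threshold
  cls <- ifelse(a & b, "DP", ifelse(!a & !b, "DN", "SP"))
  factor(cls, levels = c("DN", "SP", "DP"))
}

#' Log2 odds ratio with Fisher's exact p for a 2x2 table
#'
#' The odds ratio is `(a d)/(b c)` with the Haldane-Anscombe +0.5 correction
#' applied to all cells only when at least one cell is zero. The two-sided
#' p-value is the conditional hypergeometric (Fisher) probability of tables
#' as or less likely than the observed one, on the uncorrected counts.
#'
#' @param tab 2x2 matrix (or length-4 vector `a, b, c, d`, row-wise) of
#'   nonnegative counts with a positive total.
#' @param correction Haldane-Anscombe constant (default 0.5).
#' @return List with `odds_ratio`, `log2_or`, `p`, `corrected` (whether the
#'   continuity correction was applied).
#' @export
enrichment_odds_ratio <- function(tab, correction = 0.5) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  if (sum(tab) <= 0) stop("empty table", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  corrected <- any(tab == 0)
  if (corrected) { a <- a + correction; b <- b + correction
                   c_ <- c_ + correction; d <- d + correction }
  or <- (a * d) / (b * c_)
  list(odds_ratio = or, log2_or = log2(or),
       p = fisher_p_twosided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
       corrected = corrected)
}

## Two-sided Fisher exact p: sum of hypergeometric probabilities not exceeding
## the observed one (with fisher.test's relative tolerance on "not exceeding").
fisher_p_twosided <- function(a, b, c_, d) {
  m <- a + b          # row-1 margin
  n <- c_ + d         # row-2 margin
  k <- a + c_         # column-1 margin
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' Per-cluster DP-vs-DN enrichment odds ratios
#'
#' For each cluster, the 2x2 table of DP/DN membership in-cluster vs
#' out-of-cluster (SP cells are excluded), with the log2 odds ratio and
#' Fisher's exact p from [enrichment_odds_ratio()].
#'
#' @param dp_class Factor per cell (`DN`/`SP`/`DP`), e.g. from
#'   [classify_dp()].
#' @param cluster Cluster label per cell.
#' @return `data.frame`: `cluster`, `dp_in`, `dn_in`, `dp_out`, `dn_out`,
#'   `log2_or`, `p`.
#' @export
dp_cluster_odds <- function(dp_class, cluster) {
  if (length(dp_class) != length(cluster)) stop("aligned vectors required", call. = FALSE)
  cluster <- factor(cluster)
  dp <- dp_class == "DP"
  dn <- dp_class == "DN"
  rows <- lapply(levels(cluster), function(cl) {
    inc <- cluster == cl
    tab <- matrix(c(sum(dp & inc), sum(dp & !inc),
                    sum(dn & inc), sum(dn & !inc)), 2L, 2L, byrow = TRUE)
    res <- enrichment_odds_ratio(tab)
    data.frame(cluster = cl, dp_in = tab[1, 1], dn_in = tab[2, 1],
               dp_out = tab[1, 2], dn_out = tab[2, 2],
               log2_or = res$log2_or, p = res$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
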