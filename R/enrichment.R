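#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Within each sample genes are ranked by expression; the enrichment score is
#' the sum over the ranked list of the weighted hit CDF minus the uniform
#' miss CDF,
#' \deqn{ES = \sum_{i=1}^{N} [P^w_{hit}(i) - P_{miss}(i)],}
#' where hits (signature genes) are weighted by their rank value raised to
#' `alpha` and misses uniformly. The score depends only on within-sample
#' ranks, so any strictly increasing per-sample transform of the expression
#' leaves it unchanged. Rank values use average ranks for ties; walk order
#' among tied values is by gene ID, making results deterministic.
#'
#' @param expr Genes x samples matrix (any monotone scale).
#' @param sigs A [signature_collection()].
#' @param alpha Rank weighting exponent (default 0.25).
#' @param normalize If `TRUE`, divide all scores by the range
#'   (max - min) of the raw score matrix.
#' @param min_genes Minimum matched genes per signature (default 2;
#'   signatures below it are dropped with a warning).
#' @return Signatures x samples score matrix with attributes `variant`
#'   (`"raw_es"`), `method`, `overlap` (the [signature_overlap()] report) and
#'   `dropped` (signatures with < 2 matched genes).
#' @export
ssgsea_scores <- function(expr, sigs, alpha = 0.25, normalize = FALSE, min_genes = 2L) {
  expr <- as_dense(expr)
  validate_expression_matrix(expr)
  stopifnot(inherits(sigs, "signature_collection"))
  keep <- prune_signatures(expr, sigs, min_genes = min_genes)
  N <- nrow(expr)
  gene_ids <- rownames(expr)

  ## weights = (average rank from bottom)^alpha; walk position 1 = highest value
  rank_vals <- apply(expr, 2L, rank, ties.method = "average")
  w <- abs(rank_vals)^alpha
  ## steps-remaining term: for walk position p (1 = top), N - p + 1
  steps <- apply(expr, 2L, function(x) {
    ord <- order(-x, gene_ids)
    pos <- integer(N)
    pos[ord] <- seq_len(N)
    N - pos + 1L
  })
  total_steps <- N * (N + 1) / 2

  scores <- matrix(NA_real_, nrow = length(keep$sets), ncol = ncol(expr),
                   dimnames = list(names(keep$sets), colnames(expr)))
  for (s in seq_along(keep$sets)) {
    idx <- keep$index[[s]]
    m <- length(idx)
    whit <- w[idx, , drop = FALSE]
    hit <- colSums(whit * steps[idx, , drop = FALSE]) / colSums(whit)
    miss <- (total_steps - colSums(steps[idx, , drop = FALSE])) / (N - m)
    scores[s, ] <- hit - miss
  }
  if (normalize && length(scores)) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  enrichment_result(scores, variant = "raw_es", method = "ssgsea",
                    overlap = keep$overlap, dropped = keep$dropped)
}

#' Gene-set variation analysis (GSVA) scores
#'
#' Per gene, a Gaussian-kernel estimate of the sample-level expression CDF
#' (bandwidth `sd/4`); per sample, genes are ranked by the CDF estimate and
#' converted to the symmetric rank statistic `|N/2 - position|`; a weighted
#' Kolmogorov-Smirnov random walk down the ranked list yields the score as
#' the maximum positive deviation plus the maximum negative deviation (the
#' "mx.diff" convention). Deterministic given the input; requires at least 3
#' samples because the CDF estimate is cross-sample.
#'
#' @inheritParams ssgsea_scores
#' @param tau Weight on the symmetric rank statistic in the walk (default 1).
#' @return Signatures x samples score matrix (attributes as in
#'   [ssgsea_scores()]).
#' @export
gsva_scores <- function(expr, sigs, tau = 1) {
  expr <- as_dense(expr)
  validate_expression_matrix(expr)
  stopifnot(inherits(sigs, "signature_collection"))
  if (ncol(expr) < 3L)
    stop("gsva_scores needs >= 3 samples (cross-sample kernel CDF); use ssgsea_scores",
         call. = FALSE)
  keep <- prune_signatures(expr, sigs)
  N <- nrow(expr)
  n <- ncol(expr)
  gene_ids <- rownames(expr)

  z <- matrix(0, N, n, dimnames = dimnames(expr))
  for (g in seq_len(N)) {
    x <- expr[g, ]
    h <- stats::sd(x) / 4
    if (h == 0) {
      z[g, ] <- 0.5
    } else {
      z[g, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
    }
  }

  scores <- matrix(NA_real_, nrow = length(keep$sets), ncol = n,
                   dimnames = list(names(keep$sets), colnames(expr)))
  member <- matrix(FALSE, N, length(keep$sets))
  for (s in seq_along(keep$sets)) member[keep$index[[s]], s] <- TRUE

  for (j in seq_len(n)) {
    ord <- order(-z[, j], gene_ids)
    r_sym <- abs(N / 2 - seq_len(N))^tau    # symmetric rank statistic along the walk
    memb_ord <- member[ord, , drop = FALSE]
    for (s in seq_along(keep$sets)) {
      hit <- memb_ord[, s]
      m <- sum(hit)
      wh <- r_sym * hit
      walk <- cumsum(wh) / sum(wh) - cumsum(!hit) / (N - m)
      scores[s, j] <- max(0, max(walk)) + min(0, min(walk))
    }
  }
  enrichment_result(scores, variant = "raw_es", method = "gsva",
                    overlap = keep$overlap, dropped = keep$dropped)
}

prune_signatures <- function(expr, sigs, min_genes = 2L) {
  overlap <- signature_overlap(expr, sigs)
  full <- overlap$n_matched == nrow(expr)
  if (any(full))
    stop("signature(s) covering all genes: ",
         paste(overlap$signature[full], collapse = ", "), call. = FALSE)
  too_small <- overlap$n_matched < min_genes
  if (any(too_small))
    warning("dropping signature(s) with < ", min_genes, " matched genes: ",
            paste(overlap$signature[too_small], collapse = ", "), call. = FALSE)
  kept <- which(!too_small)
  if (!length(kept)) stop("no signature has >= 2 matched genes", call. = FALSE)
  sets <- lapply(sigs[kept], function(g) g[g %in% rownames(expr)])
  names(sets) <- names(sigs)[kept]
  index <- lapply(sets, match, table = rownames(expr))
  list(sets = sets, index = index, overlap = overlap,
       dropped = overlap$signature[too_small])
}

enrichment_result <- function(scores, variant, method, overlap = NULL,
                              dropped = character(0), flagged = character(0)) {
  attr(scores, "variant") <- variant
  attr(scores, "method") <- method
  attr(scores, "overlap") <- overlap
  attr(scores, "dropped") <- dropped
  attr(scores, "flagged") <- flagged
  scores
}

#' Scale enrichment scores to NES
#'
#' Per-signature z-scaling across the samples of one cohort:
#' `(x - mean) / sd` with the sample standard deviation (ddof = 1). Rows with
#' zero variance become all-zero and are flagged in the `flagged` attribute.
#' Scaling is always within one cohort; multi-cohort studies scale each
#' cohort separately before any cross-cohort modeling.
#'
#' @param es Signatures x samples raw score matrix.
#' @return Matrix of the same shape with `variant = "nes"`.
#' @export
normalize_to_nes <- function(es) {
  es <- as_dense(es)
  if (ncol(es) < 2L) stop("NES scaling needs >= 2 samples", call. = FALSE)
  mu <- rowMeans(es)
  sd_ <- apply(es, 1L, stats::sd)
  flagged <- rownames(es)[sd_ == 0]
  sd_safe <- ifelse(sd_ == 0, 1, sd_)
  nes <- (es - mu) / sd_safe
  nes[sd_ == 0, ] <- 0
  enrichment_result(nes, variant = "nes",
                    method = attr(es, "method") %||% "unknown",
                    overlap = attr(es, "overlap"),
                    dropped = attr(es, "dropped") %||% character(0),
                    flagged = flagged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
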