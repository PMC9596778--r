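#' Compute the IRScore from NES and signature verdicts
#'
#' The immune-related signature score of a sample is the sum of its NES over
#' the M prognostically good signatures minus the sum over the N
#' prognostically bad signatures:
#' \deqn{IRScore = \sum_{i=1}^{M} NES_i - \sum_{j=1}^{N} NES_j.}
#' Samples are then split into high/low groups at the cohort median (ties at
#' the median go low).
#'
#' @param nes NES matrix (signatures x samples) of the cohort being scored.
#' @param verdicts Verdict `data.frame` (`signature`, `selected`,
#'   `direction`) from [select_signatures()], or any frame with those
#'   columns.
#' @param group If `FALSE`, skip the median split (scores only).
#' @return `data.frame` (class `irscore_table`) with `sample_id`, `irscore`
#'   and (unless `group = FALSE`) `group`; attributes `n_good`, `n_bad`,
#'   `threshold`, `signatures_used`.
#' @export
compute_irscore <- function(nes, verdicts, group = TRUE) {
  sel <- verdicts[verdicts$selected, , drop = FALSE]
  if (!nrow(sel)) stop("no selected signatures (M + N = 0)", call. = FALSE)
  missing <- setdiff(sel$signature, rownames(nes))
  if (length(missing))
    stop("selected signature(s) missing from the NES matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- ifelse(sel$direction == "good", 1, -1)
  score <- as.numeric(crossprod(nes[sel$signature, , drop = FALSE], d))
  names(score) <- colnames(nes)
  out <- data.frame(sample_id = colnames(nes), irscore = score,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (group) {
    grp <- dichotomize_by_median(score)
    out$group <- grp$group
    attr(out, "threshold") <- attr(grp, "threshold")
  }
  attr(out, "n_good") <- sum(sel$direction == "good")
  attr(out, "n_bad") <- sum(sel$direction == "bad")
  attr(out, "signatures_used") <- sel
  class(out) <- c("irscore_table", "data.frame")
  out
}

#' Evaluate survival stratification by IRScore group
#'
#' Kaplan-Meier curves per group, the two-group log-rank test, and the Cox
#' hazard ratio of high vs low with a 95% Wald interval.
#'
#' @param scores An `irscore_table` with a `group` column.
#' @param surv A [survival_table()] for the same samples.
#' @return List with `logrank` (`chi_square`, `p`), `cox` (`cox_result` plus
#'   `ci_low`/`ci_high` on the HR), `km` (list of `km_curve` per group), and
#'   `n_per_group`.
#' @export
evaluate_stratification <- function(scores, surv) {
  if (is.null(scores$group)) stop("scores carry no group column", call. = FALSE)
  if (nlevels(droplevels(scores$group)) < 2L)
    stop("both IRScore groups must be nonempty", call. = FALSE)
  groups <- scores[, c("sample_id", "group")]
  class(groups) <- c("group_assignment", "data.frame")
  lr <- logrank_test(groups, surv)
  cox <- fit_cox_binary(groups, surv)
  cox$ci_low <- exp(cox$log_hr - stats::qnorm(0.975) * cox$se)
  cox$ci_high <- exp(cox$log_hr + stats::qnorm(0.975) * cox$se)
  km <- lapply(split(surv, groups$group[match(surv$sample_id, groups$sample_id)]),
               km_estimate)
  list(logrank = lr, cox = cox, km = km,
       n_per_group = table(groups$group[groups$sample_id %in% surv$sample_id]))
}

#' Associate the IRScore with an external per-sample feature
#'
#' Either a Spearman correlation between IRScore and the feature, or a
#' rank-sum comparison of the feature between the high and low IRScore
#' groups.
#'
#' @param scores An `irscore_table`.
#' @param feature Named numeric vector (names = sample IDs), e.g. the NES of
#'   an angiogenesis or EMT signature.
#' @param mode `"correlation"` or `"group_compare"`.
#' @return For correlation: list `rho`, `p`, `n`. For group comparison: list
#'   `p`, `median_high`, `median_low`, `n`.
#' @export
associate_with_signature <- function(scores, feature,
                                     mode = c("correlation", "group_compare")) {
  mode <- match.arg(mode)
  m <- match(scores$sample_id, names(feature))
  keep <- !is.na(m)
  if (sum(keep) < 4L) stop("fewer than 4 matched samples", call. = FALSE)
  f <- feature[m[keep]]
  if (mode == "correlation") {
    r <- rank_correlation(scores$irscore[keep], f)
    list(rho = r$rho, p = r$p, n = sum(keep))
  } else {
    if (is.null(scores$group)) stop("group_compare mode needs a group column", call. = FALSE)
    g <- scores$group[keep]
    list(p = two_group_test(f, g),
         median_high = stats::median(f[g == "high"]),
         median_low = stats::median(f[g == "low"]),
         n = sum(keep))
  }
}
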