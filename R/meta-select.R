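#' Inverse-variance meta-analysis of per-cohort log hazard ratios
#'
#' Fixed-effect pooling weights each cohort by `1/se^2`; the random-effects
#' model adds the DerSimonian-Laird moment estimate of the between-cohort
#' variance,
#' \deqn{\tau^2 = \max\{0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w)\},}
#' with `Q` the fixed-effect heterogeneity statistic and
#' `I^2 = max(0, (Q - (k-1))/Q) x 100`. The pooled z and two-sided p come
#' from the chosen model; the fixed-effect estimate is always recorded
#' alongside.
#'
#' @param log_hr Per-cohort log hazard ratios.
#' @param se Per-cohort standard errors (all > 0). Non-converged fits must be
#'   excluded upstream.
#' @param model `"random_dl"` (default) or `"fixed"`.
#' @return List of class `meta_result`: `pooled_log_hr`, `pooled_se`,
#'   `pooled_hr`, `z`, `p`, `model`, `Q`, `tau2`, `I2`, `k`, `ci_low`,
#'   `ci_high`, and `fixed` (log HR, SE, p of the fixed-effect pooling).
#' @export
meta_pool <- function(log_hr, se, model = c("random_dl", "fixed")) {
  model <- match.arg(model)
  if (length(log_hr) != length(se)) stop("log_hr and se must have equal length", call. = FALSE)
  ok <- is.finite(log_hr) & is.finite(se) & se > 0
  if (!all(ok)) stop("all inputs must be finite with se > 0 (exclude failed fits upstream)",
                     call. = FALSE)
  k <- length(log_hr)
  if (k < 1L) stop("k = 0 cohorts: nothing to pool", call. = FALSE)

  w <- 1 / se^2
  bF <- sum(w * log_hr) / sum(w)
  seF <- sqrt(1 / sum(w))
  Q <- sum(w * (log_hr - bF)^2)
  df <- k - 1
  tau2 <- if (k > 1L) max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w))) else 0
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0

  if (model == "random_dl") {
    wr <- 1 / (se^2 + tau2)
    b <- sum(wr * log_hr) / sum(wr)
    se_p <- sqrt(1 / sum(wr))
  } else {
    b <- bF
    se_p <- seF
    tau2 <- 0
  }
  z <- b / se_p
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(pooled_log_hr = b, pooled_se = se_p, pooled_hr = exp(b),
                 z = z, p = p, model = model, Q = Q, tau2 = tau2, I2 = I2, k = k,
                 ci_low = exp(b - stats::qnorm(0.975) * se_p),
                 ci_high = exp(b + stats::qnorm(0.975) * se_p),
                 fixed = list(log_hr = bF, se = seF,
                              p = 2 * stats::pnorm(-abs(bF / seF)))),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result (%s, k = %d): HR = %.4g [%.4g, %.4g], p = %.3g, Q = %.3g, tau2 = %.3g, I2 = %.1f%%\n",
              x$model, x$k, x$pooled_hr, x$ci_low, x$ci_high, x$p, x$Q, x$tau2, x$I2))
  invisible(x)
}

#' Per-cohort univariate Cox screening of signature NES
#'
#' For every signature and cohort: samples are split at the cohort's median
#' NES and a two-group Cox model is fit. Signatures whose NES is constant in
#' a cohort (no median split possible) and non-converged fits are recorded
#' with `NA` estimates so they can be excluded from pooling.
#'
#' @param nes_list Named list of NES matrices (signatures x samples), one per
#'   cohort.
#' @param surv_list Named list of [survival_table()]s aligned with `nes_list`.
#' @param ties Tie handling for the Cox fits.
#' @return Long `data.frame`: `cohort`, `signature`, `log_hr`, `se`, `z`,
#'   `p`, `hr`, `n`, `n_events`, `converged`.
#' @export
cohort_signature_cox <- function(nes_list, surv_list, ties = "efron") {
  stopifnot(length(nes_list) == length(surv_list))
  if (is.null(names(nes_list))) names(nes_list) <- paste0("cohort", seq_along(nes_list))
  rows <- list()
  for (ci in seq_along(nes_list)) {
    nes <- nes_list[[ci]]
    surv <- surv_list[[ci]]
    for (s in rownames(nes)) {
      fit <- tryCatch({
        grp <- dichotomize_by_median(nes[s, ])
        fit_cox_binary(grp, surv, ties = ties)
      }, error = function(e) NULL)
      ok <- !is.null(fit) && fit$converged
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = names(nes_list)[ci], signature = s,
        log_hr = if (ok) fit$log_hr else NA_real_,
        se = if (ok) fit$se else NA_real_,
        z = if (ok) fit$z else NA_real_,
        p = if (ok) fit$p else NA_real_,
        hr = if (ok) fit$hr else NA_real_,
        n = if (!is.null(fit)) fit$n else NA_integer_,
        n_events = if (!is.null(fit)) fit$n_events else NA_integer_,
        converged = ok, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pool the per-cohort Cox table and select prognostic signatures
#'
#' Each signature's converged per-cohort estimates are pooled by
#' [meta_pool()]; a signature is selected when its pooled p-value is below
#' `alpha` (raw p, no multiplicity correction by default, matching the
#' screening rule the score was built with; set `fdr = TRUE` for a
#' Benjamini-Hochberg variant). Selected signatures are classified as
#' prognostically `good` (pooled HR < 1) or `bad` (pooled HR > 1).
#'
#' @param cox_table Output of [cohort_signature_cox()].
#' @param model Meta-analysis model passed to [meta_pool()].
#' @param alpha Selection threshold on the pooled p-value (default 0.05).
#' @param fdr Apply Benjamini-Hochberg adjustment before thresholding.
#' @return List with `meta` (per-signature `data.frame`: `signature`, `k`,
#'   `pooled_hr`, `ci_low`, `ci_high`, `p`, `Q`, `tau2`, `I2`, `selected`,
#'   `direction`) and `verdicts` (`signature`, `selected`, `direction`,
#'   `pooled_hr`, `p`), plus summary counts.
#' @export
select_signatures <- function(cox_table, model = "random_dl", alpha = 0.05, fdr = FALSE) {
  sigs <- unique(cox_table$signature)
  rows <- lapply(sigs, function(s) {
    sub <- cox_table[cox_table$signature == s & cox_table$converged &
                       is.finite(cox_table$se), , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(signature = s, k = 0L, pooled_hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        Q = NA_real_, tau2 = NA_real_, I2 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    m <- meta_pool(sub$log_hr, sub$se, model = model)
    data.frame(signature = s, k = m$k, pooled_hr = m$pooled_hr,
               ci_low = m$ci_low, ci_high = m$ci_high, p = m$p,
               Q = m$Q, tau2 = m$tau2, I2 = m$I2, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  n_dropped <- sum(meta$k == 0L)
  if (n_dropped) message(n_dropped, " signature(s) had no converged cohort fits")
  p_use <- if (fdr) stats::p.adjust(meta$p, method = "BH") else meta$p
  meta$selected <- !is.na(p_use) & p_use < alpha
  meta$direction <- ifelse(!meta$selected, "none",
                           ifelse(meta$pooled_hr < 1, "good", "bad"))
  verdicts <- meta[, c("signature", "selected", "direction", "pooled_hr", "p")]
  list(meta = meta, verdicts = verdicts,
       n_selected = sum(meta$selected),
       n_good = sum(meta$direction == "good"),
       n_bad = sum(meta$direction == "bad"))
}
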