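#' Split samples into high/low groups at the median
#'
#' Values strictly greater than the median go to `high`; values at or below
#' the median (including exact-median ties) go to `low`. The threshold is
#' recorded on the result. Requires at least 4 samples and errors when one
#' group would be empty (e.g. a constant vector).
#'
#' @param values Named numeric vector (names = sample IDs).
#' @return `data.frame` (class `group_assignment`) with columns `sample_id`,
#'   `group` (factor `low`/`high`) and a `threshold` attribute.
#' @export
dichotomize_by_median <- function(values) {
  if (is.null(names(values))) stop("values must be named by sample ID", call. = FALSE)
  if (length(values) < 4L) stop("median dichotomization needs >= 4 samples", call. = FALSE)
  if (anyNA(values)) stop("missing values", call. = FALSE)
  med <- stats::median(values)
  grp <- factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
  if (any(tabulate(grp, 2L) == 0L))
    stop("one group is empty after the median split (constant values?)", call. = FALSE)
  out <- data.frame(sample_id = names(values), group = grp,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- med
  class(out) <- c("group_assignment", "data.frame")
  out
}

join_groups_survival <- function(groups, surv) {
  m <- match(surv$sample_id, groups$sample_id)
  keep <- !is.na(m)
  if (!any(keep)) stop("no overlapping samples between groups and survival", call. = FALSE)
  list(time = surv$time[keep], event = surv$event[keep],
       x = as.integer(groups$group[m[keep]] == "high"))
}

## Risk-set bookkeeping shared by the Cox fit and the log-rank test.
## Returns, per distinct event time: d (events), m (events in group 1),
## n (at risk), n1 (at risk in group 1).
risk_table <- function(time, event, x) {
  ord <- order(time)
  t <- time[ord]; d <- event[ord]; x <- x[ord]
  n <- length(t)
  cx <- rev(cumsum(rev(x)))            # group-1 subjects with index >= i
  ut <- unique(t[d == 1])
  first <- findInterval(ut, t, left.open = TRUE) + 1L  # first index with t >= ut
  dk <- vapply(ut, function(u) sum(d[t == u]), numeric(1L))
  mk <- vapply(ut, function(u) sum(d[t == u] * x[t == u]), numeric(1L))
  nk <- n - first + 1
  n1k <- cx[first]
  list(dk = dk, mk = mk, nk = nk, n1k = n1k, n = n, n_events = sum(d))
}

#' Two-group Cox proportional-hazards fit
#'
#' Maximum partial likelihood for a single binary covariate (`high` = 1,
#' `low` = 0) by Newton-Raphson with the Efron (default) or Breslow tie
#' correction; standard error from the observed information. Convergence at
#' `|delta log HR| < 1e-8`, at most 50 iterations. Under a monotone partial
#' likelihood (all events drifting to one arm) the fit is flagged
#' `converged = FALSE`, `log_hr` is reported as a signed infinity and the
#' p-value falls back to the score test at beta = 0.
#'
#' @param groups A `group_assignment` (see [dichotomize_by_median()]).
#' @param surv A [survival_table()].
#' @param ties `"efron"` or `"breslow"`.
#' @return List of class `cox_result`: `log_hr`, `se`, `z`, `p`, `hr`, `n`,
#'   `n_events`, `converged`, `ties_method`, plus `score_chisq`/`score_p`
#'   (score test at beta = 0).
#' @export
fit_cox_binary <- function(groups, surv, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  dat <- join_groups_survival(groups, surv)
  if (!any(dat$event)) stop("no events; Cox fit is undefined", call. = FALSE)
  if (any(!is.finite(dat$time))) stop("non-finite survival times", call. = FALSE)
  rt <- risk_table(dat$time, dat$event, dat$x)

  ## expand Efron correction fractions j/d for each event time
  reps <- if (ties == "efron") rt$dk else rep(1, length(rt$dk))
  k_idx <- rep(seq_along(rt$dk), reps)
  frac <- if (ties == "efron") {
    unlist(lapply(rt$dk, function(d) (seq_len(d) - 1) / d), use.names = FALSE)
  } else rep(0, length(rt$dk))

  score_parts <- function(beta) {
    r <- exp(beta)
    R <- (rt$nk - rt$n1k) + rt$n1k * r        # risk-score sum over risk set
    S <- (rt$dk - rt$mk) + rt$mk * r          # risk-score sum over tied events
    Bx <- rt$n1k * r                          # x-weighted risk-score sum
    Sx <- rt$mk * r
    A <- R[k_idx] - frac * S[k_idx]
    B <- Bx[k_idx] - frac * Sx[k_idx]
    mult <- if (ties == "breslow") rt$dk else rep(1, length(A))
    q <- B / A
    U <- sum(rt$mk) - sum(mult * q)
    I <- sum(mult * q * (1 - q))
    list(U = U, I = I)
  }

  sp0 <- score_parts(0)
  score_chisq <- if (sp0$I > 0) sp0$U^2 / sp0$I else 0
  score_p <- stats::pchisq(score_chisq, df = 1, lower.tail = FALSE)

  beta <- 0
  converged <- FALSE
  for (it in seq_len(50L)) {
    sp <- score_parts(beta)
    if (sp$I <= 1e-12 || !is.finite(sp$U)) break
    step <- sp$U / sp$I
    beta <- beta + step
    if (abs(beta) > 15) break                  # monotone likelihood guard
    if (abs(step) < 1e-8) { converged <- TRUE; break }
  }

  if (converged) {
    se <- 1 / sqrt(score_parts(beta)$I)
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    beta <- sign(if (sp0$U != 0) sp0$U else beta) * Inf
    se <- Inf; z <- NA_real_; p <- score_p
  }
  structure(list(log_hr = beta, se = se, z = z, p = p, hr = exp(beta),
                 n = rt$n, n_events = rt$n_events, converged = converged,
                 ties_method = ties, score_chisq = score_chisq, score_p = score_p),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("cox_result: HR = %.4g (log HR %.4g, SE %.3g), p = %.3g, n = %d (%d events)%s\n",
              x$hr, x$log_hr, x$se, x$p, x$n, x$n_events,
              if (x$converged) "" else " [NOT converged; score-test p]"))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank with the hypergeometric variance at each distinct event
#' time; the statistic is referred to a chi-square with 1 df.
#'
#' @inheritParams fit_cox_binary
#' @return List with `chi_square`, `p`, `observed`, `expected` (group `high`).
#' @export
logrank_test <- function(groups, surv) {
  dat <- join_groups_survival(groups, surv)
  if (!any(dat$event)) stop("no events; log-rank test is undefined", call. = FALSE)
  if (length(unique(dat$x)) < 2L) stop("both groups must be nonempty", call. = FALSE)
  rt <- risk_table(dat$time, dat$event, dat$x)
  E <- rt$dk * rt$n1k / rt$nk
  V <- ifelse(rt$nk > 1,
              rt$dk * (rt$n1k / rt$nk) * (1 - rt$n1k / rt$nk) * (rt$nk - rt$dk) / (rt$nk - 1),
              0)
  O <- sum(rt$mk)
  stat <- if (sum(V) > 0) (O - sum(E))^2 / sum(V) else 0
  list(chi_square = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = sum(E))
}

#' Kaplan-Meier product-limit estimate
#'
#' Censoring at an event time is processed after the events at that time
#' (censored subjects remain in the risk set for that time's factor). The
#' curve starts at (time 0, survival 1) and drops only at event times.
#'
#' @param surv A [survival_table()].
#' @return List of class `km_curve`: `times`, `survival`, `at_risk`, `events`.
#' @export
km_estimate <- function(surv) {
  if (any(surv$time < 0)) stop("negative survival times", call. = FALSE)
  if (!nrow(surv)) stop("empty survival table", call. = FALSE)
  ord <- order(surv$time)
  t <- surv$time[ord]; d <- surv$event[ord]
  n <- length(t)
  ut <- unique(t[d == 1])
  if (!length(ut)) {
    out <- list(times = 0, survival = 1, at_risk = n, events = 0L)
  } else {
    first <- findInterval(ut, t, left.open = TRUE) + 1L
    nk <- n - first + 1
    dk <- vapply(ut, function(u) sum(d[t == u]), numeric(1L))
    surv_prob <- cumprod(1 - dk / nk)
    out <- list(times = c(0, ut), survival = c(1, surv_prob),
                at_risk = c(n, nk), events = c(0L, as.integer(dk)))
  }
  class(out) <- "km_curve"
  out
}

#' Spearman rank correlation
#'
#' Average-rank Spearman rho with the t-approximation p-value.
#'
#' @param x,y Equal-length numeric vectors (n >= 4), neither constant.
#' @return List with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 4L) stop("need >= 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-group rank test
#'
#' Default is the Wilcoxon rank-sum (Mann-Whitney) test with normal
#' approximation and tie correction for independent groups; `paired = TRUE`
#' gives the signed-rank test for genuinely paired inputs. (A signed-rank
#' test requires pairing, so unpaired group comparisons use the rank-sum
#' form.)
#'
#' @param values Numeric vector.
#' @param groups Two-level factor/character vector aligned with `values`.
#' @param paired Use the signed-rank test on paired values.
#' @return Two-sided p-value.
#' @export
two_group_test <- function(values, groups, paired = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  split_v <- split(values, groups)
  if (any(lengths(split_v) < 2L)) stop("each group needs >= 2 values", call. = FALSE)
  if (stats::sd(values) == 0) return(1)
  if (paired) {
    stats::wilcox.test(split_v[[1L]], split_v[[2L]], paired = TRUE, exact = FALSE)$p.value
  } else {
    stats::wilcox.test(split_v[[1L]], split_v[[2L]], exact = FALSE)$p.value
  }
}

#' K-group rank test (Kruskal-Wallis)
#'
#' @param values Numeric vector.
#' @param labels Group labels (>= 2 levels, each with >= 2 values).
#' @return P-value from the Kruskal-Wallis chi-square test.
#' @export
k_group_test <- function(values, labels) {
  labels <- factor(labels)
  if (any(table(labels) < 2L)) stop("each group needs >= 2 values", call. = FALSE)
  stats::kruskal.test(values, labels)$p.value
}
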