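make_groups <- function(ids, x) {
  out <- data.frame(sample_id = ids,
                    group = factor(ifelse(x == 1, "high", "low"),
                                   levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_assignment", "data.frame")
  out
}

test_that("median dichotomization sends exact ties low and records the threshold", {
  g <- dichotomize_by_median(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(attr(g, "threshold"), 2.5)
  expect_identical(g$sample_id[g$group == "high"], c("c", "d"))

  g2 <- dichotomize_by_median(c(a = 1, b = 2, c = 2, d = 3))
  expect_identical(g2$sample_id[g2$group == "high"], "d")

  expect_error(dichotomize_by_median(c(a = 2, b = 2, c = 2, d = 2)), "empty")
  expect_error(dichotomize_by_median(c(a = 1, b = 2, c = 3)), ">= 4")
})

test_that("Cox fit is null under exchangeable duplicated arms", {
  t0 <- c(1, 2, 3, 4, 6, 9)
  e0 <- c(1, 1, 0, 1, 1, 0)
  ids <- sprintf("P%02d", 1:12)
  surv <- survival_table(ids, c(t0, t0), c(e0, e0))
  fit <- fit_cox_binary(make_groups(ids, rep(c(0, 1), each = 6)), surv)
  expect_equal(fit$log_hr, 0)
  expect_equal(fit$p, 1)
})

test_that("Cox estimate matches a dense grid search of the partial likelihood", {
  set.seed(21)
  for (rep_i in 1:3) {
    n <- 8
    time <- sort(sample(1:100, n))          # tie-free
    event <- rbinom(n, 1, 0.8); event[1] <- 1
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    ids <- sprintf("P%d", 1:n)
    surv <- survival_table(ids, time, event)
    fit <- fit_cox_binary(make_groups(ids, x), surv)
    if (!fit$converged) next
    grid <- oracle_grid_cox(time, event, x)
    expect_equal(fit$log_hr, grid, tolerance = 1e-6)
  }
})

test_that("Cox fit agrees with survival::coxph on larger data (both tie methods)", {
  skip_if_not_installed("survival")
  set.seed(22)
  n <- 80
  time <- round(rexp(n, 0.1), 1)            # induces some ties
  event <- rbinom(n, 1, 0.7)
  x <- rbinom(n, 1, 0.5)
  ids <- sprintf("P%d", 1:n)
  surv <- survival_table(ids, time, event)
  for (tm in c("efron", "breslow")) {
    fit <- fit_cox_binary(make_groups(ids, x), surv, ties = tm)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = tm)
    expect_equal(fit$log_hr, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("score test at beta = 0 equals the log-rank chi-square on tie-free data", {
  set.seed(23)
  n <- 30
  time <- sample(seq(0.5, 200, by = 0.5), n)  # distinct times
  event <- rbinom(n, 1, 0.7); event[1] <- 1
  x <- rep(c(0, 1), n / 2)
  ids <- sprintf("P%d", 1:n)
  surv <- survival_table(ids, time, event)
  g <- make_groups(ids, x)
  fit <- fit_cox_binary(g, surv)
  lr <- logrank_test(g, surv)
  expect_equal(fit$score_chisq, lr$chi_square, tolerance = 1e-8)
})

test_that("monotone likelihood is flagged with a signed sentinel and score-test p", {
  ids <- sprintf("P%d", 1:8)
  surv <- survival_table(ids, c(1, 2, 3, 4, 20, 21, 22, 23), c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- fit_cox_binary(make_groups(ids, c(1, 1, 1, 1, 0, 0, 0, 0)), surv)
  expect_false(fit$converged)
  expect_identical(fit$log_hr, Inf)
  expect_equal(fit$p, fit$score_p)
})

test_that("log-rank matches hand-computed O-E and variance terms", {
  # A: 1 (event), 3 (event), 5 (censored); B ('high'): 2 (event), 4 (cens), 6 (event)
  # t=1: d=1 n=6 n_hi=3 -> E=1/2,  V=1/4
  # t=2: d=1 n=5 n_hi=3 -> E=3/5,  V=6/25
  # t=3: d=1 n=4 n_hi=2 -> E=1/2,  V=1/4
  # t=6: d=1 n=1 n_hi=1 -> E=1,    V=0
  # O(high)=2, E=2.6, V=0.74
  ids <- sprintf("P%d", 1:6)
  surv <- survival_table(ids, 1:6, c(1, 1, 1, 0, 0, 1))
  lr <- logrank_test(make_groups(ids, c(0, 1, 0, 1, 0, 1)), surv)
  expect_equal(lr$chi_square, (2 - 2.6)^2 / 0.74, tolerance = 1e-12)
  expect_equal(lr$p, pchisq((2 - 2.6)^2 / 0.74, 1, lower.tail = FALSE))
})

test_that("log-rank is null for identical group compositions and agrees with survdiff", {
  ids <- sprintf("P%d", 1:10)
  t0 <- c(1, 3, 5, 7, 9)
  surv <- survival_table(ids, c(t0, t0), rep(1, 10))
  lr <- logrank_test(make_groups(ids, rep(c(0, 1), each = 5)), surv)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p, 1)

  skip_if_not_installed("survival")
  set.seed(24)
  time <- rexp(40); event <- rbinom(40, 1, 0.8); x <- rep(0:1, 20)
  ids <- sprintf("Q%d", 1:40)
  surv <- survival_table(ids, time, event)
  lr <- logrank_test(make_groups(ids, x), surv)
  ref <- survival::survdiff(survival::Surv(time, event) ~ x)
  expect_equal(lr$chi_square, ref$chisq, tolerance = 1e-8)
})

test_that("log-rank is invariant to strictly increasing time transforms", {
  set.seed(25)
  time <- rexp(30); event <- rbinom(30, 1, 0.7); x <- rep(0:1, 15)
  ids <- sprintf("P%d", 1:30)
  lr1 <- logrank_test(make_groups(ids, x), survival_table(ids, time, event))
  lr2 <- logrank_test(make_groups(ids, x), survival_table(ids, exp(time), event))
  expect_equal(lr1$chi_square, lr2$chi_square, tolerance = 1e-12)
})

test_that("Cox log HR flips sign when group labels are swapped", {
  set.seed(26)
  time <- rexp(40); event <- rbinom(40, 1, 0.8); x <- rbinom(40, 1, 0.5)
  ids <- sprintf("P%d", 1:40)
  surv <- survival_table(ids, time, event)
  f1 <- fit_cox_binary(make_groups(ids, x), surv)
  f2 <- fit_cox_binary(make_groups(ids, 1 - x), surv)
  expect_equal(f1$log_hr, -f2$log_hr, tolerance = 1e-7)
})

test_that("Kaplan-Meier matches closed forms and stays a step function in [0,1]", {
  s <- km_estimate(survival_table(c("a", "b", "c"), 1:3, c(1, 1, 1)))
  expect_equal(s$survival, c(1, 2 / 3, 1 / 3, 0))

  flat <- km_estimate(survival_table(c("a", "b"), c(5, 7), c(0, 0)))
  expect_equal(flat$survival, 1)

  # events at 2 (n=5) and 6 (n=2, after censoring at 3 and 5):
  # S = 4/5, then 4/5 * 1/2
  mixed <- km_estimate(survival_table(sprintf("m%d", 1:5), c(2, 3, 5, 6, 8),
                                      c(1, 0, 0, 1, 0)))
  expect_equal(mixed$survival, c(1, 4 / 5, 4 / 5 * 1 / 2))

  set.seed(27)
  r <- km_estimate(survival_table(sprintf("r%d", 1:50), rexp(50), rbinom(50, 1, 0.6)))
  expect_true(all(diff(r$survival) <= 0))
  expect_true(all(r$survival >= 0 & r$survival <= 1))

  expect_error(km_estimate(survival_table(c("x"), 1, 1)[-1, ]), "empty")
})

test_that("censoring at an event time stays in that time's risk set", {
  skip_if_not_installed("survival")
  surv <- survival_table(sprintf("c%d", 1:6), c(1, 1, 2, 2, 3, 4), c(1, 0, 1, 0, 1, 1))
  km <- km_estimate(surv)
  ref <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  expect_equal(km$survival[-1], ref$surv[ref$n.event > 0], tolerance = 1e-12)
})

test_that("Spearman correlation matches the rank formula and handles edge cases", {
  set.seed(28)
  x <- rnorm(10); y <- rnorm(10)
  r <- rank_correlation(x, y)
  o <- oracle_spearman(x, y)
  expect_equal(r$rho, o$rho, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  expect_equal(rank_correlation(x, x)$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  expect_error(rank_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("rank tests separate shifted groups and agree with exact permutation p", {
  set.seed(29)
  v <- c(rnorm(20), rnorm(20) + 10)
  g <- rep(c("a", "b"), each = 20)
  expect_lt(two_group_test(v, g), 1e-6)
  expect_equal(two_group_test(rep(c(1, 2, 3), 4), rep(c("a", "b"), 6)), 1,
               tolerance = 0.05)

  # tie-free instance vs the full permutation distribution of the rank sum
  set.seed(30)
  v2 <- round(rnorm(20), 6)
  g2 <- rep(c("a", "b"), each = 10)
  p_approx <- two_group_test(v2, g2)
  r <- rank(v2)
  obs <- sum(r[g2 == "a"])
  combos <- combn(20, 10)
  sums <- colSums(matrix(r[combos], nrow = 10))
  p_exact <- mean(abs(sums - sum(r) / 2) >= abs(obs - sum(r) / 2) - 1e-9)
  expect_lt(abs(p_approx - p_exact), 0.01)

  expect_error(two_group_test(1:4, c("a", "a", "a", "b")), ">= 2")
  expect_lt(k_group_test(c(rnorm(5), rnorm(5) + 8, rnorm(5) + 16),
                         rep(1:3, each = 5)), 0.01)
})
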