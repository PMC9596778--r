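random_nes <- function(n_sig, n_samples, seed = 1) {
  x <- random_expr(n_sig, n_samples, seed = seed)
  rownames(x) <- sprintf("SIG%02d", seq_len(n_sig))
  normalize_to_nes(x)
}

random_verdicts <- function(sig_names, seed = 2) {
  set.seed(seed)
  dirs <- sample(c("good", "bad"), length(sig_names), replace = TRUE)
  data.frame(signature = sig_names, selected = TRUE, direction = dirs,
             stringsAsFactors = FALSE)
}

test_that("IRScore equals the signed-direction dot product", {
  nes <- random_nes(10, 20, seed = 3)
  v <- random_verdicts(rownames(nes), seed = 4)
  tab <- compute_irscore(nes, v)
  d <- ifelse(v$direction == "good", 1, -1)
  oracle <- as.numeric(t(nes[v$signature, ]) %*% d)
  expect_equal(tab$irscore, oracle, tolerance = 1e-12)
  expect_equal(attr(tab, "n_good") + attr(tab, "n_bad"), sum(v$selected))

  # two-term closed form
  nes2 <- rbind(GOOD = rep(0.5, 4), BAD = rep(0.2, 4))
  colnames(nes2) <- sprintf("S%d", 1:4)
  v2 <- data.frame(signature = c("GOOD", "BAD"), selected = TRUE,
                   direction = c("good", "bad"), stringsAsFactors = FALSE)
  tab2 <- compute_irscore(nes2, v2, group = FALSE)
  expect_equal(tab2$irscore, rep(0.3, 4))
})

test_that("constant shifts propagate with the signature's sign", {
  nes <- random_nes(6, 15, seed = 5)
  v <- random_verdicts(rownames(nes), seed = 6)
  base <- compute_irscore(nes, v, group = FALSE)
  good_sig <- v$signature[v$direction == "good"][1]
  bad_sig <- v$signature[v$direction == "bad"][1]
  shifted <- nes; shifted[good_sig, ] <- shifted[good_sig, ] + 2.5
  expect_equal(compute_irscore(shifted, v, group = FALSE)$irscore,
               base$irscore + 2.5, tolerance = 1e-12)
  shifted2 <- nes; shifted2[bad_sig, ] <- shifted2[bad_sig, ] + 2.5
  expect_equal(compute_irscore(shifted2, v, group = FALSE)$irscore,
               base$irscore - 2.5, tolerance = 1e-12)
})

test_that("flipping a verdict's direction flips that signature's contribution", {
  nes <- random_nes(5, 12, seed = 7)
  v <- random_verdicts(rownames(nes), seed = 8)
  base <- compute_irscore(nes, v, group = FALSE)
  v2 <- v
  v2$direction[1] <- ifelse(v$direction[1] == "good", "bad", "good")
  flipped <- compute_irscore(nes, v2, group = FALSE)
  sgn <- ifelse(v$direction[1] == "good", 1, -1)
  expect_equal(flipped$irscore, base$irscore - 2 * sgn * nes[v$signature[1], ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the pooled score decomposes into good-only minus bad-only sums", {
  nes <- random_nes(8, 10, seed = 9)
  v <- random_verdicts(rownames(nes), seed = 10)
  all_ <- compute_irscore(nes, v, group = FALSE)$irscore
  vg <- v[v$direction == "good", ]; vb <- v[v$direction == "bad", ]
  good_only <- compute_irscore(nes, vg, group = FALSE)$irscore
  bad_mag <- as.numeric(colSums(nes[vb$signature, , drop = FALSE]))
  expect_equal(all_, good_only - bad_mag, tolerance = 1e-12)
})

test_that("missing selected signatures and degenerate scores error clearly", {
  nes <- random_nes(3, 8, seed = 11)
  v <- data.frame(signature = c("SIG01", "GHOST"), selected = TRUE,
                  direction = c("good", "bad"), stringsAsFactors = FALSE)
  expect_error(compute_irscore(nes, v), "GHOST")

  zero <- matrix(0, 2, 6, dimnames = list(c("A", "B"), sprintf("S%d", 1:6)))
  vz <- data.frame(signature = c("A", "B"), selected = TRUE,
                   direction = c("good", "bad"), stringsAsFactors = FALSE)
  expect_error(compute_irscore(zero, vz), "empty")       # constant scores
  expect_equal(compute_irscore(zero, vz, group = FALSE)$irscore, rep(0, 6))
})

test_that("stratification evaluation returns HR, log-rank p and KM curves", {
  set.seed(12)
  n <- 60
  ids <- sprintf("P%03d", 1:n)
  score <- rnorm(n)
  time <- rexp(n, 0.1 * exp(-0.8 * score))
  event <- as.integer(time <= rexp(n, 0.05))
  surv <- survival_table(ids, time, event)
  tab <- data.frame(sample_id = ids, irscore = score,
                    group = dichotomize_by_median(setNames(score, ids))$group)
  class(tab) <- c("irscore_table", "data.frame")
  ev <- evaluate_stratification(tab, surv)
  expect_lt(ev$cox$hr, 1)           # high score protective by construction
  expect_lt(ev$logrank$p, 0.05)
  expect_named(ev$km, c("low", "high"))
  expect_true(all(ev$km$high$survival <= 1))

  tab$group <- factor(rep("high", n), levels = c("low", "high"))
  expect_error(evaluate_stratification(tab, surv), "nonempty")
})

test_that("feature association recovers self, anti-self and noisy copies", {
  nes <- random_nes(6, 40, seed = 13)
  v <- random_verdicts(rownames(nes), seed = 14)
  tab <- compute_irscore(nes, v)
  self <- setNames(tab$irscore, tab$sample_id)
  expect_equal(associate_with_signature(tab, self)$rho, 1)
  expect_equal(associate_with_signature(tab, -self)$rho, -1)
  set.seed(15)
  noisy <- self + rnorm(length(self), sd = 0.1 * sd(self))
  expect_gt(associate_with_signature(tab, noisy)$rho, 0.9)

  gc <- associate_with_signature(tab, noisy, mode = "group_compare")
  expect_gt(gc$median_high, gc$median_low)
  expect_lt(gc$p, 0.01)
  expect_error(associate_with_signature(tab, self[1:3]), "4 matched")
})
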