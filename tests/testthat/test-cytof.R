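toy_frame <- function(values, markers = "MK1", samples = NULL) {
  m <- matrix(values, ncol = length(markers))
  colnames(m) <- markers
  if (is.null(samples)) samples <- rep("S1", nrow(m))
  cytometry_frame(m, samples)
}

test_that("arcsinh transform matches closed forms and preserves order", {
  fr <- toy_frame(c(0, 5, 10, -2))
  tr <- arcsinh_transform(fr)
  expect_equal(unname(tr$intensities[1, 1]), 0)
  expect_equal(unname(tr$intensities[2, 1]), log(1 + sqrt(2)), tolerance = 1e-12)
  expect_identical(tr$transform_state, "arcsinh")

  set.seed(51)
  x <- sort(runif(50, 0, 100))
  fr2 <- arcsinh_transform(toy_frame(x))
  expect_true(all(diff(fr2$intensities[, 1]) > 0))

  expect_error(arcsinh_transform(tr), "raw-state")
  expect_error(arcsinh_transform(fr, cofactor = 0), "> 0")
})

test_that("arcsinh then rescale is invariant to joint scaling of data and cofactor", {
  set.seed(52)
  x <- rlnorm(200)
  a <- percentile_rescale(arcsinh_transform(toy_frame(x), cofactor = 5))
  b <- percentile_rescale(arcsinh_transform(toy_frame(10 * x), cofactor = 50))
  expect_equal(a$intensities, b$intensities, tolerance = 1e-12)
})

test_that("percentile rescale caps at the 99th percentile and maps to [0,1]", {
  fr <- toy_frame(0:100)
  fr$transform_state <- "arcsinh"   # inject state: testing the rescale arithmetic
  rs <- percentile_rescale(fr)
  # type-7 percentile of 0..100 at 0.99 is 99; floor is 0
  expect_equal(unname(rs$intensities[101, 1]), 1)        # 100 clipped to the cap
  expect_equal(unname(rs$intensities[100, 1]), 1)        # 99 == cap
  expect_equal(unname(rs$intensities[1, 1]), 0)
  expect_equal(unname(rs$intensities[51, 1]), 50 / 99)

  set.seed(53)
  fr2 <- arcsinh_transform(toy_frame(rlnorm(500, sdlog = 2)))
  rs2 <- percentile_rescale(fr2)
  expect_true(all(rs2$intensities >= 0 & rs2$intensities <= 1))

  const <- toy_frame(rep(2, 10)); const$transform_state <- "arcsinh"
  rc <- percentile_rescale(const)
  expect_true(all(rc$intensities == 0))
  expect_identical(rc$flagged_markers, "MK1")
})

test_that("per-sample subsampling is seed-reproducible and respects counts", {
  set.seed(54)
  n_samples <- 5
  fr <- toy_frame(rnorm(n_samples * 1200),
                  samples = rep(sprintf("S%d", 1:n_samples), each = 1200))
  sub1 <- subsample_per_sample(fr, n_per_sample = 1000, seed = 99)
  sub2 <- subsample_per_sample(fr, n_per_sample = 1000, seed = 99)
  expect_identical(attr(sub1, "kept_index"), attr(sub2, "kept_index"))
  expect_identical(as.integer(table(sub1$sample_id)[sprintf("S%d", 1:n_samples)]),
                   rep(1000L, n_samples))
  expect_equal(nrow(sub1$intensities), n_samples * 1000L)

  expect_warning(short <- subsample_per_sample(toy_frame(1:5), 10), "keeping all")
  expect_equal(nrow(short$intensities), 5L)
  empty <- subsample_per_sample(fr, n_per_sample = 0)
  expect_equal(nrow(empty$intensities), 0L)
})

test_that("cluster frequencies sum to one, add over unions, and compare groups", {
  gen <- generate_cytometry(seed = 55)
  res <- cluster_frequency_compare(gen$cluster, gen$frame$sample_id,
                                   gen$sample_groups)
  base <- res$frequencies[, sort(unique(gen$cluster))]
  expect_equal(unname(rowSums(base)), rep(1, nrow(base)), tolerance = 1e-12)

  res_u <- cluster_frequency_compare(gen$cluster, gen$frame$sample_id,
                                     gen$sample_groups,
                                     populations = list(UNION = c("T01", "T02")))
  expect_equal(res_u$frequencies[, "UNION"],
               res_u$frequencies[, "T01"] + res_u$frequencies[, "T02"],
               tolerance = 1e-12)

  one <- cluster_frequency_compare(rep("T01", 40), rep(sprintf("S%d", 1:4), each = 10),
                                   setNames(c("high", "high", "low", "low"),
                                            sprintf("S%d", 1:4)))
  expect_equal(unname(one$frequencies[, "T01"]), rep(1, 4))
  expect_equal(one$comparison$p, 1)

  expect_error(cluster_frequency_compare(gen$cluster, gen$frame$sample_id,
                                         setNames(rep("low", 13),
                                                  unique(gen$frame$sample_id))),
               ">= 2 samples")
})

test_that("cytometry CSV fallback round-trips the frame contract", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("MK1,MK2,sample_id", "1.5,2,SA", "3,4,SA", "5,6,SB"), f)
  fr <- read_cytometry_csv(f)
  expect_identical(fr$markers, c("MK1", "MK2"))
  expect_identical(fr$sample_id, c("SA", "SA", "SB"))
  expect_equal(unname(fr$intensities[1, "MK1"]), 1.5)
  expect_identical(fr$transform_state, "raw")
})
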