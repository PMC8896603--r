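test_that("k-sample AD matches the direct discrete formula on small samples", {
  cases <- list(
    list(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)),
    list(c(1, 1, 2, 3, 5), c(2, 4, 4, 6, 8), c(1, 3, 3, 7, 9)))
  withr::local_seed(55)
  for (i in 1:6) {
    k <- sample(2:4, 1)
    cases[[length(cases) + 1]] <-
      lapply(seq_len(k), function(j) sample(0:20, sample(6:25, 1), replace = TRUE))
  }
  for (cs in cases) {
    expect_equal(suppressWarnings(ad_ksample(cs)),
                 suppressWarnings(ad_naive(cs)), tolerance = 1e-10)
    expect_equal(suppressWarnings(ad_ksample(cs, statistic = "raw")),
                 suppressWarnings(ad_naive(cs, standardized = FALSE)),
                 tolerance = 1e-10)
  }
})

test_that("k-sample AD agrees with independently computed reference values", {
  # midrank-corrected standardized statistics, frozen from an external
  # reference implementation
  expect_equal(ad_ksample(list(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))),
               -1.567750170851398, tolerance = 1e-9)
  expect_equal(ad_ksample(list(c(1, 2, 3, 4, 5, 6, 7, 8),
                               c(3, 3, 5, 9, 10, 11, 2, 6))),
               -0.2680285286057525, tolerance = 1e-9)
  expect_equal(ad_ksample(list(c(1, 1, 2, 3, 5), c(2, 4, 4, 6, 8),
                               c(1, 3, 3, 7, 9))),
               0.26577087575091884, tolerance = 1e-9)
})

test_that("AD statistic grows with separation and ignores within-slide order", {
  sep <- ad_ksample(list(1:20, 1001:1020))
  mixed <- ad_ksample(list(seq(1, 39, by = 2), seq(2, 40, by = 2)))
  expect_gt(sep, mixed)
  withr::local_seed(3)
  s <- list(rpois(50, 10), rpois(60, 12))
  expect_equal(ad_ksample(s), ad_ksample(lapply(s, sample)))
  expect_error(ad_ksample(list(1:5)), "at least 2")
  expect_error(ad_ksample(list(1:5, numeric(0))), "empty")
})

test_that("Otsu threshold separates a bimodal sample and matches brute force", {
  o <- otsu_threshold(c(rep(0, 50), rep(10, 50)))
  expect_gt(o, 0); expect_lt(o, 10)
  v <- c(1, 2, 3, 4, 5, 6, 100, 101, 102)
  expect_equal(otsu_threshold(v, nbins = 64), otsu_naive(v, nbins = 64))
  withr::local_seed(9)
  for (i in 1:10) {
    vals <- switch(1 + i %% 3,
                   rpois(500, 20) + rbinom(500, 1, 0.3) * rpois(500, 200),
                   rlnorm(400, 3, 0.7),
                   runif(300, 0, 50))
    expect_equal(otsu_threshold(vals), otsu_naive(vals))
  }
  expect_error(otsu_threshold(rep(3, 10)),
               class = "slidenorm_degenerate_threshold_error")
})

test_that("Otsu threshold is affine-equivariant", {
  withr::local_seed(10)
  v <- rlnorm(1000, 3, 0.8)
  o <- otsu_threshold(v)
  expect_equal(otsu_threshold(2.5 * v + 7), 2.5 * o + 7, tolerance = 1e-9)
})

test_that("threshold discordance is zero for identical slides and matches enumeration", {
  withr::local_seed(12)
  v <- rlnorm(300, 2, 1)
  tbl <- toy_table(list(s1 = v, s2 = v, s3 = v))
  expect_equal(otsu_discordance(tbl, "ch")$mean, 0)

  tbl2 <- toy_table(list(A = c(0, 0, 10, 10), B = c(0, 0, 4, 10)))
  d <- otsu_discordance(tbl2, "ch", nbins = 16)
  o_c <- otsu_threshold(tbl2$ch, nbins = 16)
  expected <- vapply(split(tbl2$ch, tbl2$slide_id), function(y) {
    o_i <- otsu_threshold(y, nbins = 16)
    mean(abs(as.integer(y > o_i) - as.integer(y > o_c)))
  }, numeric(1))
  expect_equal(d$scores$score, unname(expected))
  expect_equal(d$mean, mean(expected))
})

test_that("duplicating every cell leaves discordance scores unchanged", {
  withr::local_seed(14)
  vals <- list(s1 = rlnorm(100, 2, 1), s2 = rlnorm(80, 2.4, 0.8))
  d1 <- otsu_discordance(toy_table(vals), "ch")
  d2 <- otsu_discordance(toy_table(lapply(vals, rep, times = 2)), "ch")
  expect_equal(d1$scores$score, d2$scores$score)
})

test_that("marker-positive accuracy counts matches against manual labels", {
  withr::local_seed(16)
  tbl <- toy_table(list(s1 = rlnorm(50, 2, 1), s2 = rlnorm(50, 2, 1)))
  o_c <- otsu_threshold(tbl$ch)
  calls <- tbl$ch > o_c
  expect_equal(marker_positive_accuracy(tbl, "ch", labels = calls), 1)
  expect_equal(marker_positive_accuracy(tbl, "ch", labels = !calls), 0)
  labels90 <- calls; labels90[1:10] <- !labels90[1:10]
  expect_equal(marker_positive_accuracy(tbl, "ch", labels = labels90), 0.9)
  expect_error(marker_positive_accuracy(tbl, "ch"), "no manual labels")
})

test_that("variance proportion hits the null and saturation limits", {
  withr::local_seed(18)
  n <- 20 * 500
  slides <- rep(sprintf("s%02d", 1:20), each = 500)
  expect_lt(variance_proportion(rnorm(n, 5), slides), 0.01)
  big <- rnorm(20, 0, 10)[as.integer(factor(slides))] + rnorm(n, 0, 0.1)
  expect_gt(variance_proportion(big, slides), 0.99)
})

test_that("variance proportion recovers a known intraclass correlation", {
  # a single 20-slide draw has slide-sampling SE ~ 0.08, so average replicates
  withr::local_seed(19)
  ests <- vapply(1:5, function(r) {
    slides <- rep(sprintf("s%02d", 1:20), each = 500)
    y <- rnorm(20, 0, 1)[as.integer(factor(slides))] + rnorm(length(slides), 0, 1)
    variance_proportion(y, slides)
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 0.1)
})

test_that("adjusted Rand index matches closed-form and reference values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c("a", "a", "b", "b"), c("x", "x", "y", "y")), 1)
  # partitions {12|34} vs {13|24}: every pair split -> ARI = -1/2 by the formula
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  skip_if_not_installed("mclust")
  withr::local_seed(20)
  for (i in 1:5) {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:3, 200, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})
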