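test_that("standardization matches the hand-worked two-slide example", {
  tbl <- toy_table(list(s1 = c(0, 2), s2 = c(4, 6)))
  std <- combat_standardize(tbl, "ch")
  expect_equal(std$alpha, 3)
  expect_equal(std$sigma, 1)              # sigma2 = (1+1+1+1)/4
  expect_equal(std$z, c(-3, -1, 1, 3))
  expect_equal(std$slide_stats$gamma_hat, c(-2, 2))
})

test_that("identically distributed slides give zero mean effects; degenerate inputs error", {
  tbl <- toy_table(list(s1 = c(1, 2, 3), s2 = c(1, 2, 3)))
  std <- combat_standardize(tbl, "ch")
  expect_equal(std$slide_stats$gamma_hat, c(0, 0))
  expect_error(combat_standardize(toy_table(list(s1 = c(5, 5), s2 = c(5, 5))), "ch"),
               class = "slidenorm_degenerate_channel_error")
  expect_error(combat_standardize(toy_table(list(s1 = c(1, 2))), "ch"),
               class = "slidenorm_batch_design_error")
})

test_that("method-of-moments hyperparameters satisfy the moment identities", {
  hp <- combat_mom_hyperparams(c(-2, 2), c(1, 3))
  expect_equal(hp$gamma_bar, 0)
  expect_equal(hp$tau2_bar, 8)            # sample variance, n-1 denominator
  expect_equal(hp$omega_bar, 4)           # m=2, v=2 -> m^2/v + 2
  expect_equal(hp$beta_bar, 6)            # m*(omega-1)
  expect_equal(hp$beta_bar / (hp$omega_bar - 1), 2)  # implied IG mean = m
  expect_warning(
    hp0 <- combat_mom_hyperparams(c(-1, 1), c(2, 2)),
    class = "slidenorm_noninformative_prior_warning")
  expect_false(hp0$informative_variance_prior)
})

test_that("EB updates shrink toward the prior and reach the naive limits", {
  withr::local_seed(31)
  tbl <- toy_table(lapply(setNames(rnorm(4, 0, 1), paste0("s", 1:4)),
                          function(m) rnorm(40, m, 1)))
  std <- combat_standardize(tbl, "ch")
  gh <- setNames(std$slide_stats$gamma_hat, std$slide_stats$slide_id)
  d2 <- setNames(std$slide_stats$delta2_hat, std$slide_stats$slide_id)
  hp <- combat_mom_hyperparams(gh, d2)
  eb <- combat_eb_iterate(std$z, tbl$slide_id, gh, d2, hp)
  expect_true(eb$converged)
  # shrinkage: gamma* lies between gamma_hat and the prior mean
  expect_true(all(abs(eb$gamma_star - hp$gamma_bar) <= abs(gh - hp$gamma_bar) + 1e-12))
  expect_true(all(eb$delta2_star > 0))
  # tau2 -> Inf limit removes shrinkage
  hp_inf <- hp; hp_inf$tau2_bar <- 1e12
  eb_inf <- combat_eb_iterate(std$z, tbl$slide_id, gh, d2, hp_inf)
  expect_equal(unname(eb_inf$gamma_star), unname(gh), tolerance = 1e-6)
})

test_that("EB fixed point matches an independent slow alternating solver", {
  for (seed in 1:3) {
    withr::local_seed(seed)
    n_slides <- 3
    tbl <- toy_table(lapply(setNames(rnorm(n_slides, 0, 0.8), paste0("s", 1:n_slides)),
                            function(m) rnorm(50, m, runif(1, 0.5, 1.5))))
    std <- combat_standardize(tbl, "ch")
    gh <- setNames(std$slide_stats$gamma_hat, std$slide_stats$slide_id)
    d2 <- setNames(std$slide_stats$delta2_hat, std$slide_stats$slide_id)
    hp <- combat_mom_hyperparams(gh, d2)
    eb <- combat_eb_iterate(std$z, tbl$slide_id, gh, d2, hp, tol = 1e-10,
                            max_iter = 5000)
    ref <- combat_eb_naive(std$z, tbl$slide_id, gh, d2, hp)
    expect_equal(unname(eb$gamma_star), unname(ref$gamma_star), tolerance = 1e-8)
    expect_equal(unname(eb$delta2_star), unname(ref$delta2_star), tolerance = 1e-8)
  }
})

test_that("adjustment with null effects inverts standardization exactly", {
  tbl <- toy_table(list(s1 = c(0, 2), s2 = c(4, 6)))
  std <- combat_standardize(tbl, "ch")
  slides <- std$slide_stats$slide_id
  y <- combat_adjust(std$z, tbl$slide_id,
                     setNames(c(0, 0), slides), setNames(c(1, 1), slides),
                     std$alpha, std$sigma)
  expect_equal(y, tbl$ch)
  expect_error(
    combat_adjust(std$z, tbl$slide_id, setNames(c(0, 0), slides),
                  setNames(c(1, -1), slides), std$alpha, std$sigma),
    class = "slidenorm_internal_error")
})

test_that("a full fit equalizes slide means up to the EB shrinkage residual", {
  tbl <- toy_table(list(s1 = c(0, 2, 1, 3), s2 = c(4, 6, 5, 7)))
  res <- combat_normalize(tbl)
  m <- slide_summary(res$table, "ch")$mu
  f <- res$fit$channels$ch
  st <- f$slide_stats
  # algebraic identity: adjusted slide mean = alpha + sigma*(gamma_hat - gamma*)/delta*
  expected <- f$alpha + f$sigma * (st$gamma_hat - unname(f$gamma_star[st$slide_id])) /
    sqrt(unname(f$delta2_star[st$slide_id]))
  expect_equal(m, expected, tolerance = 1e-10)
  # the raw slide-mean gap (4) is almost entirely removed
  raw_gap <- abs(diff(slide_summary(tbl, "ch")$mu))
  expect_lt(abs(diff(m)), 0.05 * raw_gap)
})

test_that("tables without batch signal pass through nearly unchanged", {
  withr::local_seed(77)
  vals <- rnorm(200, 10, 2)
  tbl <- toy_table(split(vals, rep(paste0("s", 1:4), each = 50)), scale = "log10")
  res <- combat_normalize(tbl)
  expect_equal(res$table$ch, tbl$ch, tolerance = 0.05)
})

test_that("pure batch signal is removed", {
  tbl <- toy_table(list(s1 = rep(1, 30) + rnorm(30, 0, 1e-3),
                        s2 = rep(5, 30) + rnorm(30, 0, 1e-3),
                        s3 = rep(9, 30) + rnorm(30, 0, 1e-3)), scale = "log10")
  res <- suppressWarnings(combat_normalize(tbl))
  expect_lt(diff(range(slide_summary(res$table, "ch")$mu)), 0.01 * diff(range(tbl$ch)))
})

test_that("tidy/glance expose per-slide effects and convergence state", {
  sim <- simulate_table(sim_config(n_slides = 4, cells_per_slide = 60, seed = 13))
  res <- combat_normalize(apply_transform(sim$table, "log10"),
                          use_channels = c("cd3", "cd8"))
  td <- tidy(res$fit)
  expect_equal(nrow(td), 8)  # 4 slides x 2 channels
  expect_true(all(c("gamma_hat", "gamma_star", "delta2_hat", "delta2_star") %in% names(td)))
  gl <- glance(res$fit)
  expect_equal(gl$channel, c("cd3", "cd8"))
  expect_true(all(gl$converged))
  path <- withr::local_tempfile(fileext = ".json")
  write_combat_fit(res$fit, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "\n")))
})
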