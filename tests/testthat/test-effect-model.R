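# direct data builder for model tests: known quadratic + known variance parts
make_quad_data <- function(n_players = 12, n_obs = 24, b = c(100, 2, -0.5),
                           icc_sd = 10, resid_sd = 5, x_sd = 2,
                           time_coef = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(player_id = sprintf("p%02d", 1:n_players),
                   t = 1:n_obs, stringsAsFactors = FALSE)
  ints <- setNames(rnorm(n_players, 0, icc_sd), sprintf("p%02d", 1:n_players))
  d$x <- rnorm(nrow(d), 0, x_sd)
  d$match_time_pct <- pmin(100, pmax(50, rnorm(nrow(d), 85, 8)))
  d$performance_score <- b[1] + b[2] * d$x + b[3] * d$x^2 +
    ints[d$player_id] + time_coef * d$match_time_pct +
    rnorm(nrow(d), 0, resid_sd)
  d$subbed_on <- FALSE
  d$subbed_off <- FALSE
  d$match_id <- sprintf("M%02d", d$t)
  tibble::tibble(d)
}

test_that("single-player fit reduces to the closed-form OLS quadratic", {
  d <- make_quad_data(n_players = 1, n_obs = 60, icc_sd = 0, resid_sd = 5)
  fit <- fit_quadratic_mixed(d, "x", center = 0)
  X <- cbind(1, d$x, d$x^2, d$match_time_pct)
  beta_ols <- drop(solve(t(X) %*% X, t(X) %*% d$performance_score))
  expect_equal(unname(fit$beta), beta_ols, tolerance = 1e-6)
  expect_true("all_random_terms_single_player" %in% fit$dropped)
})

test_that("fixed coefficients are recovered from balanced synthetic data", {
  b <- c(100, 2, -0.5)
  fits <- lapply(1:12, function(s)
    fit_quadratic_mixed(make_quad_data(b = b, seed = s), "x", center = 0))
  est <- t(vapply(fits, function(f) f$beta[c("(Intercept)", "xc", "xc2")],
                  numeric(3)))
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  bias <- colMeans(est) - b
  expect_true(all(abs(bias) < 3 * mc_se + 1e-8))
  expect_true(all(vapply(fits, function(f) f$converged, TRUE)))
  expect_true(all(vapply(fits, function(f) f$varcomp[["residual"]], 0) > 0))
})

test_that("centering the measure elsewhere leaves delta(k) unchanged", {
  d <- make_quad_data(seed = 3)
  f0 <- fit_quadratic_mixed(d, "x", center = 0)
  d2 <- dplyr::mutate(d, x = x + 50)
  f1 <- fit_quadratic_mixed(d2, "x", center = 50)
  e0 <- effect_at_offsets(f0, sd = 2)
  e1 <- effect_at_offsets(f1, sd = 2)
  expect_equal(e0$delta, e1$delta, tolerance = 1e-6)
  expect_equal(e0$cl90, e1$cl90, tolerance = 1e-6)
})

test_that("effect contrasts evaluate the quadratic exactly", {
  f <- fake_fit(b0 = 0, b1 = 2, b2 = -1)
  e <- effect_at_offsets(f, sd = 1)
  expect_equal(e$delta[e$offset == 1], 1)    # f(1) - f(0) for 2x - x^2
  expect_equal(e$delta[e$offset == -1], -3)

  # pure linear case: delta(k) = b1 * k * sd
  f <- fake_fit(b1 = 3, b2 = 0)
  e <- effect_at_offsets(f, sd = 10, offsets = c(-2, -1, 1, 2))
  expect_equal(e$delta, 3 * c(-2, -1, 1, 2) * 10)

  # mean-centered symmetry: delta(+k) + delta(-k) = 2 b2 k^2 sd^2
  f <- fake_fit(b1 = 1.7, b2 = -0.4)
  for (k in c(1, 2)) {
    e <- effect_at_offsets(f, sd = 3, offsets = c(-k, k))
    expect_equal(sum(e$delta), 2 * -0.4 * k^2 * 9, tolerance = 1e-12)
  }

  # b1 = 0 at the mean: both directions give b2 * sd^2
  f <- fake_fit(b1 = 0, b2 = 0.25)
  e <- effect_at_offsets(f, sd = 2, offsets = c(-1, 1))
  expect_equal(e$delta, rep(0.25 * 4, 2))

  expect_error(effect_at_offsets(fake_fit(), sd = 0), "sd")
})

test_that("confidence limits follow the (b1, b2) contrast variance", {
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  Vfull <- diag(1e-9, 3)
  Vfull[2:3, 2:3] <- V
  f <- fake_fit(b1 = 1, b2 = -0.2, V = Vfull, df_resid = 30)
  e <- effect_at_offsets(f, sd = 2, offsets = 1)
  cvec <- c(2, 4)
  expect_equal(e$se, sqrt(drop(t(cvec) %*% V %*% cvec)), tolerance = 1e-12)
  expect_equal(e$cl90, qt(0.95, 30) * e$se, tolerance = 1e-12)
})

test_that("predicted curve traces the fitted quadratic with its maximum", {
  f <- fake_fit(b0 = 0, b1 = 2, b2 = -1)
  cu <- predict_performance_curve(f, sd = 1, grid = -2:2)
  expect_equal(cu$predicted, c(-8, -3, 0, 1, 0))
  # curve maximum at -b1 / (2 b2)
  cu <- predict_performance_curve(f, sd = 1, grid = seq(-2, 2, by = 0.001))
  expect_equal(cu$offset[which.max(cu$predicted)], 1, tolerance = 2e-3)
  # flat when b1 = b2 = 0
  f <- fake_fit(b0 = 50)
  cu <- predict_performance_curve(f, sd = 1)
  expect_true(all(cu$predicted == 50))
})

test_that("simple and complex variants agree without match effects or subs", {
  d <- make_quad_data(n_players = 14, n_obs = 26, seed = 9)
  fs <- fit_quadratic_mixed(d, "x", variant = "simple", center = 0)
  fc <- fit_quadratic_mixed(d, "x", variant = "complex", center = 0)
  for (term in c("xc", "xc2")) {
    se <- sqrt(fs$vcov_fixed[term, term])
    expect_lt(abs(fs$beta[[term]] - fc$beta[[term]]), se)
  }
})

test_that("reliability analysis recovers a planted between-player SD", {
  cfg <- season_config(n_weeks = 24,
                       squad = c(defender = 10, forward = 10,
                                 midfielder = 10, ruck = 5),
                       load_mean = c(defender = 540, forward = 540,
                                     midfielder = 540, ruck = 540),
                       load_within_sd = c(defender = 60, forward = 60,
                                          midfielder = 60, ruck = 60),
                       load_between_sd = 30, problem_prob = 0.1)
  ests <- vapply(1:4, function(s) {
    led <- simulate_squad(cfg, seed = 100 + s)
    obs <- aggregate_week(led$sessions, led$wellness, led$matches,
                          led$roster, led$problems)
    obs$weekly <- global_load(obs)
    reliability_between_sd(obs, "weekly")$between_sd
  }, 0)
  expect_gt(mean(ests), 30 - 3 * sd(ests) / 2 - 5)
  expect_lt(mean(ests), 30 + 3 * sd(ests) / 2 + 5)
})

test_that("a shared seasonal ramp moves the trend, not the player SD", {
  cfg0 <- season_config(squad = c(defender = 10, forward = 10),
                        load_within_sd = c(defender = 60, forward = 60),
                        load_between_sd = 30, problem_prob = 0)
  cfg1 <- do.call(season_config, utils::modifyList(unclass(cfg0),
                                                   list(trend = 8)))
  get_fit <- function(cfg) {
    led <- simulate_squad(cfg, seed = 21)
    obs <- aggregate_week(led$sessions, led$wellness, led$matches,
                          led$roster, led$problems)
    obs$weekly <- global_load(obs)
    reliability_between_sd(obs, "weekly")
  }
  r0 <- get_fit(cfg0)
  r1 <- get_fit(cfg1)
  expect_gt(r1$trend, r0$trend + 4)          # ramp shows up in the trend
  expect_lt(abs(r1$between_sd - r0$between_sd), 12)
})

test_that("degenerate model inputs raise informative errors", {
  d <- make_quad_data(seed = 2)
  expect_error(fit_quadratic_mixed(d[1:5, ], "x"), "10 complete")
  d$x <- 1
  expect_error(fit_quadratic_mixed(d, "x"), "singular design")
  expect_error(fit_quadratic_mixed(dplyr::select(d, -match_time_pct), "x"),
               "missing column")
})
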