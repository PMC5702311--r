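test_that("global load reproduces the worked weighted sum", {
  obs <- make_obs("p1", 1, training_td = 20000, match_td = 12000,
                  training_hvd = 1000, match_hvd = 500,
                  match_work_rate = 150, match_accels = 10,
                  match_decels = 5, wellness_total = 90)
  expect_equal(global_load(obs), 1000)  # 200+180+50+50+50+100+100+270

  expect_equal(global_load(make_obs("p1", 1, wellness_total = 100)), 300)
  expect_equal(global_load(make_obs("p1", 1)), 0)
  # missing match fields count as zero for a non-match week
  expect_equal(global_load(make_obs("p1", 1, training_td = 1000,
                                    wellness_total = 50)),
               10 + 150)
})

test_that("global load is linear in each field with slope equal to its weight", {
  base <- make_obs("p1", 1, training_td = 5000, match_td = 8000,
                   training_hvd = 300, match_hvd = 200, match_work_rate = 140,
                   match_accels = 6, match_decels = 3, wellness_total = 80)
  w <- load_weights()
  cols <- c(training_td = "train_td", match_td = "match_td",
            training_hvd = "train_hvd", match_hvd = "match_hvd",
            match_work_rate = "work_rate", match_accels = "accel",
            match_decels = "decel", wellness_total = "wellness")
  for (col in names(cols)) {
    bumped <- base
    bumped[[col]] <- bumped[[col]] + 7
    expect_equal(global_load(bumped) - global_load(base),
                 7 * w[[cols[[col]]]], tolerance = 1e-12)
  }
})

test_that("negative load inputs are rejected", {
  expect_error(global_load(make_obs("p1", 1, training_td = -5)), "negative")
})

test_that("rolling mean matches hand values and edge conventions", {
  expect_equal(rolling_mean(rep(500, 6), 4), c(NA, NA, NA, 500, 500, 500))
  expect_equal(rolling_mean(c(400, 600, 800), 3), c(NA, NA, 600))
  x <- c(3, 1, 4, 1, 5)
  expect_equal(rolling_mean(x, 1), x)
  expect_error(rolling_mean(x, 0), "positive")
})

test_that("smoothing spec encodes the 1/lambda time-constant convention", {
  expect_equal(vapply(c(0.67, 0.5, 0.33, 0.25),
                      function(l) smoothing_spec(l)$time_constant, 0),
               c(1.5, 2, 3, 4))
  expect_error(smoothing_spec(0), "lambda")
  expect_error(smoothing_spec(1.2), "lambda")
})

test_that("smoothed load follows the recurrence with first-value seeding", {
  expect_equal(smoothed_load(rep(700, 8), 0.33), c(NA, rep(700, 7)))
  expect_equal(smoothed_load(c(400, 600, 800), 0.5), c(NA, 400, 500))
  expect_equal(smoothed_load(c(400, 600, 800, NA), 0.5)[1:3], c(NA, 400, 500))
  expect_equal(tail(smoothed_load(c(400, 600, 800, 0), 0.5), 1), 650)
})

test_that("smoothed load equals the brute-force kernel-sum oracle", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(4:52, 1)
    lam <- sample(c(0.67, 0.5, 0.33, 0.25), 1)
    x <- stats::runif(n, 100, 1000)
    got <- smoothed_load(x, lam)
    want <- oracle_smooth(x, lam)
    expect_lt(max(abs(got - want) / abs(want), na.rm = TRUE), 1e-9)
  }
})

test_that("smoothed load is shift- and scale-equivariant after the seed week", {
  set.seed(7)
  x <- stats::runif(20, 300, 900)
  s <- smoothed_load(x, 0.33)
  expect_equal(smoothed_load(x + 100, 0.33), s + 100)
  expect_equal(smoothed_load(3 * x, 0.33), 3 * s)
})

test_that("gaps restart the smoothing recurrence", {
  x <- c(400, 600, NA, 500, 700, 900)
  s <- smoothed_load(x, 0.5)
  expect_true(is.na(s[3]))
  expect_true(is.na(s[4]))        # run restarts: week 4 is a new seed week
  expect_equal(s[5], 500)         # first value of the new run
  expect_equal(s[6], 0.5 * 700 + 0.5 * 500)
})

test_that("burn-in policy discards the first ceiling(1/lambda) weeks", {
  x <- stats::runif(10, 300, 900)
  s1 <- smoothed_load(x, smoothing_spec(0.25))
  s2 <- smoothed_load(x, smoothing_spec(0.25, init = "burn_in"))
  expect_true(all(is.na(s2[1:4])))
  expect_equal(s2[5:10], s1[5:10])
})

test_that("lag-0 smoothing includes the current week", {
  x <- c(400, 600, 800)
  s <- smoothed_load(x, 0.5, predictor_lag = 0)
  expect_equal(s, c(400, 500, 650))
})

test_that("differential load smooths week-to-week changes", {
  expect_equal(differential_load(rep(650, 6), 0.5), c(NA, rep(0, 5)))
  ramp <- seq(400, 1400, by = 200)
  expect_equal(differential_load(ramp, 0.33), c(NA, rep(200, 5)))
  expect_equal(differential_load(c(400, 600, 700), 0.5), c(NA, 200, 150))
  # shift invariance: differential load ignores the level
  set.seed(8)
  x <- stats::runif(15, 300, 900)
  expect_equal(differential_load(x + 250, 0.33), differential_load(x, 0.33))
})

test_that("monotony and strain match hand computation over 3-week windows", {
  ms <- monotony_strain(c(400, 500, 600))
  expect_equal(ms$monotony[3], 5.0)
  expect_equal(ms$strain[3], 2500)
  ms <- monotony_strain(c(300, 500, 700))
  expect_equal(ms$monotony[3], 2.5)
  expect_equal(ms$strain[3], 1250)
  # zero-SD window is flagged undefined, not infinite
  ms <- monotony_strain(rep(500, 5))
  expect_true(all(is.na(ms$monotony[3:5])))
  # scale invariance of monotony, linear scaling of strain
  x <- c(400, 500, 600, 450, 700)
  expect_equal(monotony_strain(2 * x)$monotony, monotony_strain(x)$monotony)
  expect_equal(monotony_strain(2 * x)$strain, 2 * monotony_strain(x)$strain)
})

test_that("acute:chronic ratio uses the coupled 4-week chronic window", {
  expect_equal(acute_chronic(rep(500, 6))[4:6], rep(1, 3))
  expect_equal(acute_chronic(c(400, 400, 400, 800))[4], 1.6)
  expect_equal(acute_chronic(c(800, 400, 400, 400))[4], 0.8)
  expect_true(is.na(acute_chronic(rep(0, 4))[4]))
  x <- c(400, 500, 600, 450, 700)
  expect_equal(acute_chronic(2 * x), acute_chronic(x))
})

test_that("pooled within-player SD is the df-weighted root mean square", {
  expect_equal(within_player_sd(c(15, 15, 15), c(3, 9, 5)), 15)
  expect_equal(within_player_sd(c(10, 20), c(4, 4)), sqrt(250))
  expect_equal(within_player_sd(c(10, 20), c(9, 1)), sqrt(130))
  expect_error(within_player_sd(c(10, 20), c(0, 0)), "undefined")
})

test_that("kernel-weight fraction equals the explicit partial kernel sum", {
  for (lam in c(0.67, 0.5, 0.33, 0.25)) {
    n <- ceiling(1 / lam)
    expect_equal(ewma_weight_fraction(lam),
                 sum(lam * (1 - lam)^(0:(n - 1))), tolerance = 1e-12)
  }
})

test_that("derive_measures produces the full tidy measure table", {
  led <- simulate_squad(season_config(n_weeks = 8,
                                      squad = c(defender = 2, ruck = 1)),
                        seed = 5)
  obs <- aggregate_week(led$sessions, led$wellness, led$matches, led$roster,
                        led$problems)
  der <- derive_measures(obs)
  expect_setequal(unique(der$measure), measure_names())
  expect_equal(nrow(der), 3 * 8 * length(measure_names()))
  # weekly equals global_load, roll1 equals weekly
  wk <- der[der$measure == "weekly", ]
  r1 <- der[der$measure == "roll1", ]
  expect_equal(wk$value, r1$value)
  expect_equal(sort(wk$value), sort(global_load(obs)))
})
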