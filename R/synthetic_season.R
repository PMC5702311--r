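#' Season-simulation configuration
#'
#' Defaults describe an elite Australian-football squad over a 24-week
#' competitive season: four position groups (13 defenders, 13 forwards, 6
#' midfielders, 3 rucks) with position-specific weekly-load and
#' match-performance levels, player random intercepts, match-to-match
#' residual noise, and a configurable quadratic dependence of performance on
#' a chosen training measure. The default dose-response plants an inverted-U
#' peaking about 0.6 within-player SD below the mean load, so that +1 SD of
#' weekly load costs a defender about 8 performance points while -1 SD is
#' roughly neutral.
#'
#' @param n_weeks season length in weeks.
#' @param squad named integer vector of players per position.
#' @param load_mean,load_within_sd per-position weekly global-load mean and
#'   within-player SD (arbitrary units).
#' @param load_between_sd SD of player mean loads around the position mean.
#' @param perf_mean,perf_within_sd per-position performance mean and
#'   match-to-match residual SD (arbitrary units).
#' @param perf_between_sd SD of player performance intercepts.
#' @param dose list: `measure` (which derived measure drives performance),
#'   `b1`, `b2` (linear/quadratic coefficients on the centered measure).
#' @param time_coef linear effect of %-match-time (per percentage point,
#'   centered at 85).
#' @param match_sd SD of the shared match random effect (0 = none).
#' @param problem_prob probability a player-week is an injury/illness
#'   "problem" week; training fields are then multiplied by
#'   `problem_factor`.
#' @param problem_factor multiplier on training fields in problem weeks.
#' @param sub_on_prob,sub_off_prob per-match substitution probabilities.
#' @param ar_rho lag-1 autocorrelation of weekly load deviations (0 =
#'   independent weeks; smoothed/differential measures are only informative
#'   under temporal structure).
#' @param trend additive linear load trend per week (0 = none).
#' @return list of class `season_config` with all defaults resolved.
#' @export
season_config <- function(
    n_weeks = 24,
    squad = c(defender = 13, forward = 13, midfielder = 6, ruck = 3),
    load_mean = c(defender = 541, forward = 576, midfielder = 560, ruck = 475),
    load_within_sd = c(defender = 138, forward = 144, midfielder = 135,
                       ruck = 98),
    load_between_sd = 34,
    perf_mean = c(defender = 65, forward = 68, midfielder = 101, ruck = 80),
    perf_within_sd = c(defender = 27, forward = 28, midfielder = 27,
                       ruck = 21),
    perf_between_sd = 25,
    dose = list(measure = "weekly", b1 = -0.0333, b2 = -1.94e-4),
    time_coef = 0,
    match_sd = 0,
    problem_prob = 0.08,
    problem_factor = 0.5,
    sub_on_prob = 0.04,
    sub_off_prob = 0.04,
    ar_rho = 0,
    trend = 0) {
  stopifnot(all(squad >= 1), n_weeks >= 1,
            all(load_within_sd >= 0), all(perf_within_sd >= 0),
            load_between_sd >= 0, perf_between_sd >= 0,
            problem_prob >= 0, problem_prob <= 1,
            sub_on_prob >= 0, sub_on_prob + sub_off_prob <= 1,
            abs(ar_rho) < 1)
  structure(as.list(environment()), class = "season_config")
}

# waterfall decomposition of one week's target load into the eight fields;
# the weighted sum of the returned fields equals `target` exactly whenever
# target >= 3 * wellness minimum; shortfalls clip fields at zero (counted by
# the caller). Counts stay integers; distances absorb the remainder.
decompose_load <- function(target, wellness_total, work_rate, accels, decels,
                           weights, has_match) {
  w <- as.numeric(weights)
  names(w) <- names(weights)
  rem <- target - w[["wellness"]] * wellness_total
  clipped <- FALSE
  if (!has_match) {
    work_rate <- NA_real_; accels <- NA_integer_; decels <- NA_integer_
    match_td <- NA_real_; match_hvd <- NA_real_
    hvd_c <- 0.15 * max(rem, 0)
    td_c <- rem - hvd_c
    if (td_c < 0) { clipped <- TRUE; td_c <- 0; hvd_c <- max(rem, 0) }
    train_hvd <- hvd_c / w[["train_hvd"]]
    train_td <- td_c / w[["train_td"]]
    if (train_hvd > train_td) train_hvd <- train_td
  } else {
    # integer/count contributions first, shaved if infeasible
    while (decels > 0 && rem < w[["work_rate"]] * work_rate +
           w[["accel"]] * accels + w[["decel"]] * decels) decels <- decels - 1
    while (accels > 0 && rem < w[["work_rate"]] * work_rate +
           w[["accel"]] * accels + w[["decel"]] * decels) accels <- accels - 1
    fixed_c <- w[["work_rate"]] * work_rate + w[["accel"]] * accels +
      w[["decel"]] * decels
    rem2 <- rem - fixed_c
    if (rem2 < 0) { clipped <- TRUE; work_rate <- max(0, rem / w[["work_rate"]])
      rem2 <- 0 }
    frac <- c(match_td = 0.45, match_hvd = 0.12, train_hvd = 0.13)
    match_td <- frac[["match_td"]] * rem2 / w[["match_td"]]
    match_hvd <- frac[["match_hvd"]] * rem2 / w[["match_hvd"]]
    train_hvd <- frac[["train_hvd"]] * rem2 / w[["train_hvd"]]
    train_td <- (rem2 * (1 - sum(frac))) / w[["train_td"]]
    if (match_hvd > match_td) match_hvd <- match_td  # never triggers at defaults
  }
  list(train_td = train_td, train_hvd = train_hvd, match_td = match_td,
       match_hvd = match_hvd, work_rate = work_rate, accels = accels,
       decels = decels, clipped = clipped)
}

#' Simulate a full synthetic season with known ground truth
#'
#' Draws player mean loads and performance intercepts, weekly load
#' realizations (optionally AR(1)-correlated), decomposes each week's target
#' load into session GPS fields and a 12-item wellness total such that
#' [global_load()] recovers the weekly load exactly, and generates match
#' performance as position mean + player intercept + planted quadratic
#' dose-response in the configured measure + residual. Problem weeks halve
#' the training fields; the recorded weekly load is the realized
#' (post-adjustment) value.
#'
#' @param cfg a [season_config()].
#' @param seed integer RNG seed; the same seed reproduces the season
#'   byte-identically.
#' @param weights the [load_weights()] used for the decomposition contract.
#' @return list: ledger tibbles `sessions`, `wellness`, `matches`, `roster`,
#'   `problems`, plus `truth` (class `ground_truth`): resolved config,
#'   per-player intercepts, per player-week realized loads and measure
#'   values, and the planted dose coefficients.
#' @export
simulate_squad <- function(cfg = season_config(), seed = 1,
                           weights = load_weights()) {
  set.seed(seed)
  positions <- names(cfg$squad)
  players <- tibble::tibble(
    position = rep(positions, cfg$squad),
    player_id = sprintf("%s_%02d", substr(position, 1, 3),
                        unlist(lapply(cfg$squad, seq_len))))
  n_p <- nrow(players)
  players$load_player_mean <- cfg$load_mean[players$position] +
    rnorm(n_p, 0, cfg$load_between_sd)
  players$perf_intercept <- rnorm(n_p, 0, cfg$perf_between_sd)

  n_w <- cfg$n_weeks
  match_eff <- rnorm(n_w, 0, cfg$match_sd)
  ses <- list(); wel <- list(); mat <- list(); wk <- list()
  n_clipped <- 0L
  for (i in seq_len(n_p)) {
    pos <- players$position[i]
    wsd <- cfg$load_within_sd[[pos]]
    # stationary AR(1) deviations with marginal SD = wsd
    e <- rnorm(n_w)
    if (cfg$ar_rho != 0 && n_w > 1) {
      for (t in 2:n_w)
        e[t] <- cfg$ar_rho * e[t - 1] + sqrt(1 - cfg$ar_rho^2) * e[t]
    }
    target <- players$load_player_mean[i] + cfg$trend * seq_len(n_w) + wsd * e
    problem <- rbinom(n_w, 1, cfg$problem_prob) == 1
    items <- matrix(pmin(10L, pmax(1L, round(rnorm(12 * n_w, 6, 1.2)))),
                    nrow = n_w)
    wellness_total <- rowSums(items)
    work_rate <- pmin(200, pmax(100, rnorm(n_w, 150, 10)))
    accels <- rpois(n_w, 5)
    decels <- rpois(n_w, 2)
    u <- stats::runif(n_w)
    sub_on <- u < cfg$sub_on_prob
    sub_off <- !sub_on & u < cfg$sub_on_prob + cfg$sub_off_prob
    mtp <- pmin(100, pmax(40, rnorm(n_w, 85, 8)))
    mtp[sub_on | sub_off] <- pmin(100, pmax(20, rnorm(sum(sub_on | sub_off),
                                                      55, 10)))
    realized <- numeric(n_w)
    for (t in seq_len(n_w)) {
      dc <- decompose_load(max(target[t], 3 * wellness_total[t]),
                           wellness_total[t], work_rate[t], accels[t],
                           decels[t], weights, has_match = TRUE)
      if (dc$clipped || target[t] < 3 * wellness_total[t])
        n_clipped <- n_clipped + 1L
      if (problem[t]) {
        dc$train_td <- dc$train_td * cfg$problem_factor
        dc$train_hvd <- dc$train_hvd * cfg$problem_factor
      }
      realized[t] <- dc$train_td * weights[["train_td"]] +
        dc$match_td * weights[["match_td"]] +
        dc$train_hvd * weights[["train_hvd"]] +
        dc$match_hvd * weights[["match_hvd"]] +
        dc$work_rate * weights[["work_rate"]] +
        dc$accels * weights[["accel"]] + dc$decels * weights[["decel"]] +
        wellness_total[t] * weights[["wellness"]]
      # two main field sessions, two recovery sessions, one match
      shares <- c(0.40, 0.35, 0.15, 0.10)
      hvd_shares <- c(0.7, 0.3, 0, 0)
      ses[[length(ses) + 1]] <- tibble::tibble(
        player_id = players$player_id[i], week_index = t,
        session_kind = c("training", "training", "recovery", "recovery",
                         "match"),
        total_distance = c(dc$train_td * shares, dc$match_td),
        high_velocity_distance = c(dc$train_hvd * hvd_shares, dc$match_hvd),
        avg_speed = c(rep(NA_real_, 4), dc$work_rate),
        high_accel_count = c(rep(NA_integer_, 4), dc$accels),
        high_decel_count = c(rep(NA_integer_, 4), dc$decels))
    }
    wel[[i]] <- tibble::tibble(player_id = players$player_id[i],
                               week_index = seq_len(n_w))
    wel[[i]][paste0("item_", 1:12)] <- as.data.frame(items)
    wel[[i]]$total <- wellness_total
    wk[[i]] <- tibble::tibble(player_id = players$player_id[i],
                              position = pos, week_index = seq_len(n_w),
                              target_load = realized, problem = problem,
                              match_time_pct = mtp, sub_on = sub_on,
                              sub_off = sub_off)
  }
  weekly <- dplyr::bind_rows(wk)

  # measure values driving performance, from the realized loads
  truth_center <- numeric(0)
  if (cfg$dose$measure == "weekly") {
    weekly$x <- weekly$target_load
    truth_center <- cfg$load_mean
  } else {
    der <- dplyr::bind_rows(lapply(split(weekly, weekly$player_id), function(p) {
      p <- p[order(p$week_index), ]
      x <- switch(cfg$dose$measure,
                  roll1 = p$target_load,
                  roll3 = rolling_mean(p$target_load, 3),
                  roll4 = rolling_mean(p$target_load, 4),
                  monotony = monotony_strain(p$target_load)$monotony,
                  strain = monotony_strain(p$target_load)$strain,
                  acwr = acute_chronic(p$target_load),
                  if (startsWith(cfg$dose$measure, "smooth"))
                    smoothed_load(p$target_load,
                                  2 / (2 * as.numeric(sub("smooth", "",
                                                          cfg$dose$measure))))
                  else
                    differential_load(p$target_load,
                                      2 / (2 * as.numeric(sub("diff", "",
                                                              cfg$dose$measure)))))
      p$x <- x
      p
    }))
    weekly <- der
    truth_center <- tapply(weekly$x, weekly$position, mean, na.rm = TRUE)
  }
  weekly <- weekly |> dplyr::arrange(.data$player_id, .data$week_index)

  pm <- match(weekly$player_id, players$player_id)
  center <- truth_center[weekly$position]
  xc <- ifelse(is.na(weekly$x), 0, weekly$x - center)
  perf <- cfg$perf_mean[weekly$position] + players$perf_intercept[pm] +
    cfg$dose$b1 * xc + cfg$dose$b2 * xc^2 +
    cfg$time_coef * (weekly$match_time_pct - 85) +
    match_eff[weekly$week_index] +
    rnorm(nrow(weekly), 0, cfg$perf_within_sd[weekly$position])
  matches <- tibble::tibble(
    player_id = weekly$player_id, week_index = weekly$week_index,
    performance_score = unname(perf),
    match_time_pct = weekly$match_time_pct,
    subbed_on = weekly$sub_on, subbed_off = weekly$sub_off,
    match_id = sprintf("M%02d", weekly$week_index))
  truth <- structure(list(
    config = cfg, players = players,
    weekly = weekly[c("player_id", "position", "week_index", "target_load",
                      "x", "problem")],
    center = truth_center, match_effects = match_eff,
    n_clipped = n_clipped, seed = seed), class = "ground_truth")
  list(sessions = dplyr::bind_rows(ses),
       wellness = dplyr::bind_rows(wel),
       matches = matches,
       roster = players[c("player_id", "position")],
       problems = tibble::tibble(player_id = weekly$player_id,
                                 week_index = weekly$week_index,
                                 problem_flag = weekly$problem),
       truth = truth)
}

#' True dose-response effect of a k-SD offset, from the generator
#'
#' Exact `delta(k) = b1 k s + b2 k² s²` from the planted coefficients, the
#' oracle against which fitted effects are compared. `s` defaults to the
#' configured within-player SD of weekly load for the position.
#'
#' @param truth `ground_truth` from [simulate_squad()].
#' @param k SD offset(s).
#' @param position position group (default defender).
#' @param sd within-player SD to use; default the configured one.
#' @return numeric delta(s), performance units.
#' @export
true_effect_of_offset <- function(truth, k, position = "defender", sd = NULL) {
  cfg <- truth$config
  if (is.null(sd)) sd <- cfg$load_within_sd[[position]]
  cfg$dose$b1 * k * sd + cfg$dose$b2 * (k * sd)^2
}
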