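#' Global-load weighting coefficients
#'
#' The eight coefficients of the weekly global-load score, combining external
#' (GPS) load with the internal (wellness) response. Defaults are the scoring
#' scheme this package implements: training distance per 100 m, match
#' distance per 100 m times 1.5, training high-velocity distance per 20 m,
#' match high-velocity distance per 10 m, match work rate per 3 m·min⁻¹,
#' 10 per high acceleration, 20 per high deceleration, 3 per wellness point.
#'
#' @param w_train_td,w_match_td,w_train_hvd,w_match_hvd,w_work_rate,w_accel,w_decel,w_wellness
#'   weights per unit of the corresponding input field.
#' @return a named numeric vector of class `load_weights`.
#' @export
load_weights <- function(w_train_td = 1 / 100, w_match_td = 1.5 / 100,
                         w_train_hvd = 1 / 20, w_match_hvd = 1 / 10,
                         w_work_rate = 1 / 3, w_accel = 10, w_decel = 20,
                         w_wellness = 3) {
  w <- c(train_td = w_train_td, match_td = w_match_td,
         train_hvd = w_train_hvd, match_hvd = w_match_hvd,
         work_rate = w_work_rate, accel = w_accel, decel = w_decel,
         wellness = w_wellness)
  if (any(!is.finite(w))) stop("all load weights must be finite", call. = FALSE)
  structure(w, class = c("load_weights", "numeric"))
}

#' Weekly global load
#'
#' Scores each player-week as the weighted sum of its eight load inputs.
#' Match fields missing because the player had no match that week count as
#' zero; a missing training or wellness field makes the week's load missing.
#'
#' @param obs player-week tibble from [aggregate_week()] (or any tibble with
#'   the eight input columns).
#' @param weights a [load_weights()] vector.
#' @return numeric vector of loads, in arbitrary units, one per row.
#' @export
global_load <- function(obs, weights = load_weights()) {
  z <- function(x) ifelse(is.na(x), 0, x)  # absent match -> zero contribution
  fields <- list(obs$training_td, z(obs$match_td), obs$training_hvd,
                 z(obs$match_hvd), z(obs$match_work_rate),
                 z(obs$match_accels), z(obs$match_decels), obs$wellness_total)
  for (i in seq_along(fields)) {
    bad <- which(fields[[i]] < 0)
    if (length(bad))
      stop(sprintf("negative load input (%s) at row(s) %s",
                   names(weights)[i], paste(head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  Reduce(`+`, Map(`*`, fields, as.numeric(weights)))
}

#' Trailing rolling mean
#'
#' Mean of the current and previous `k - 1` weeks; undefined (NA) for the
#' first `k - 1` weeks and wherever the window contains a missing week.
#'
#' @param x numeric series on a contiguous weekly grid (NA = missing week).
#' @param k window length in weeks, >= 1.
#' @return numeric vector, same length as `x`.
#' @export
rolling_mean <- function(x, k) {
  if (length(k) != 1 || !is.finite(k) || k < 1 || k != round(k))
    stop("window k must be a positive integer", call. = FALSE)
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n >= k)
    for (w in k:n) out[w] <- mean(x[(w - k + 1):w])
  out
}

#' Exponential smoothing specification
#'
#' Decay factor lambda in (0, 1] with the time-constant convention
#' `1/lambda` weeks (not `(2 - lambda)/lambda`): the lambda set
#' {0.67, 0.5, 0.33, 0.25} gives time constants of 1.5, 2, 3 and 4 weeks.
#'
#' @param lambda decay factor in (0, 1].
#' @param init `"first_value"` seeds the recurrence with the first observed
#'   value; `"burn_in"` additionally discards the first `ceiling(1/lambda)`
#'   weeks of each run.
#' @return list of class `smoothing_spec` with `lambda`, `time_constant`
#'   (weeks, rounded to half-weeks) and `init`.
#' @export
smoothing_spec <- function(lambda, init = c("first_value", "burn_in")) {
  if (length(lambda) != 1 || !is.finite(lambda) || lambda <= 0 || lambda > 1)
    stop("lambda must be in (0, 1]", call. = FALSE)
  structure(list(lambda = lambda,
                 time_constant = round(2 / lambda) / 2,
                 init = match.arg(init)),
            class = "smoothing_spec")
}

#' Fraction of the exponential kernel inside the time constant
#'
#' The smoothed-load kernel puts weight `lambda * (1-lambda)^j` on the load
#' `j` weeks before the most recent one entering the recurrence. This returns
#' the cumulative weight of the first `n` kernel terms,
#' `1 - (1-lambda)^n`, with `n = ceiling(1/lambda)` by default — the share of
#' the total weighting contained within one time constant.
#'
#' @param lambda decay factor.
#' @param n number of leading kernel weights; default `ceiling(1/lambda)`.
#' @return numeric in (0, 1).
#' @export
ewma_weight_fraction <- function(lambda, n = ceiling(1 / lambda)) {
  1 - (1 - lambda)^n
}

# split an NA-gapped series into runs of consecutive observed weeks;
# the recurrence restarts after each gap.
observed_runs <- function(x) {
  obs <- !is.na(x)
  r <- rle(obs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

#' Exponentially weighted smoothed load
#'
#' Recurrence `S_w = lambda * L_{w-1} + (1 - lambda) * S_{w-1}` (with
#' `predictor_lag = 1`, the default: the smoothed value predicting week `w`
#' uses loads only through week `w - 1`). With `predictor_lag = 0` the
#' current week's load enters (`S_w = lambda * L_w + (1-lambda) * S_{w-1}`).
#' Under the `first_value` policy the recurrence is seeded with the first
#' observed load, so at lag 1 the first defined value is `S_2 = L_1`.
#' A missing week breaks the recurrence; it restarts after the gap.
#'
#' @param x weekly load series (NA = missing week).
#' @param spec a [smoothing_spec()] (or bare lambda).
#' @param predictor_lag 0 or 1 (default 1).
#' @return smoothed series, NA where undefined.
#' @export
smoothed_load <- function(x, spec, predictor_lag = 1) {
  if (is.numeric(spec)) spec <- smoothing_spec(spec)
  if (!predictor_lag %in% c(0, 1))
    stop("predictor_lag must be 0 or 1", call. = FALSE)
  lam <- spec$lambda
  out <- rep(NA_real_, length(x))
  for (run in observed_runs(x)) {
    if (length(run) < 2 - (predictor_lag == 0)) next
    v <- x[run]
    s <- v[1]
    if (predictor_lag == 0) {
      out[run[1]] <- s
      for (i in seq_along(v)[-1]) {
        s <- lam * v[i] + (1 - lam) * s
        out[run[i]] <- s
      }
    } else {
      for (i in seq_along(v)[-1]) {
        if (i > 2) s <- lam * v[i - 1] + (1 - lam) * s
        out[run[i]] <- s
      }
    }
    if (spec$init == "burn_in") {
      burn <- ceiling(1 / lam)
      out[run[seq_len(min(burn, length(run)))]] <- NA_real_
    }
  }
  out
}

#' Differential load (smoothed rate of change)
#'
#' The smoothing recurrence applied to week-to-week changes:
#' `D_w = lambda * dL_w + (1 - lambda) * D_{w-1}` with
#' `dL_w = L_w - L_{w-1}` (the change between the current and previous week;
#' `predictor_lag = 1` shifts to the previous change). Initialized at the
#' first defined change; restarts after gaps.
#'
#' @inheritParams smoothed_load
#' @param predictor_lag 0 (default) or 1.
#' @return differential-load series, NA where undefined.
#' @export
differential_load <- function(x, spec, predictor_lag = 0) {
  if (is.numeric(spec)) spec <- smoothing_spec(spec)
  if (!predictor_lag %in% c(0, 1))
    stop("predictor_lag must be 0 or 1", call. = FALSE)
  lam <- spec$lambda
  out <- rep(NA_real_, length(x))
  for (run in observed_runs(x)) {
    if (length(run) < 2 + predictor_lag) next
    d <- diff(x[run])                    # d[i] = change into week run[i + 1]
    s <- d[1]
    out[run[2 + predictor_lag]] <- s
    for (i in seq_along(d)[-1]) {
      s <- lam * d[i] + (1 - lam) * s
      j <- i + 1 + predictor_lag
      if (j <= length(run)) out[run[j]] <- s
    }
    if (spec$init == "burn_in") {
      burn <- ceiling(1 / lam)
      out[run[seq_len(min(burn + 1, length(run)))]] <- NA_real_
    }
  }
  out
}

#' Weekly training monotony and strain
#'
#' Over the trailing 3-week window: monotony is the rolling mean divided by
#' the sample SD (n−1) of the three weekly loads, and strain is monotony
#' times the rolling mean (= mean²/SD). A zero-SD window is flagged
#' undefined (NA), not infinite, so downstream models skip it.
#'
#' @param x weekly load series.
#' @return tibble with columns `monotony` and `strain`, one row per week.
#' @export
monotony_strain <- function(x) {
  m <- rolling_mean(x, 3)
  n <- length(x)
  s <- rep(NA_real_, n)
  if (n >= 3) for (w in 3:n) s[w] <- sd(x[(w - 2):w])
  mono <- ifelse(!is.na(s) & s > 0, m / s, NA_real_)
  tibble::tibble(monotony = mono, strain = mono * m)
}

#' Acute:chronic workload ratio
#'
#' The current week's load divided by the trailing 4-week rolling mean. The
#' chronic window is coupled: it includes the current week. A zero chronic
#' mean is flagged undefined (NA).
#'
#' @param x weekly load series.
#' @return numeric series of ratios.
#' @export
acute_chronic <- function(x) {
  chronic <- rolling_mean(x, 4)
  ifelse(!is.na(chronic) & chronic > 0, x / chronic, NA_real_)
}

#' Pooled within-player standard deviation
#'
#' The square root of the df-weighted mean of the players' squared SDs:
#' `sqrt(sum(df_i * s_i^2) / sum(df_i))`. This is the unit in which "1 SD"
#' training changes are expressed.
#'
#' @param sds per-player SDs.
#' @param dfs per-player degrees of freedom (n_i − 1).
#' @return pooled SD (scalar).
#' @export
within_player_sd <- function(sds, dfs) {
  keep <- !is.na(sds) & !is.na(dfs) & dfs >= 1
  if (!any(keep)) stop("within-player SD undefined: no player has df >= 1",
                       call. = FALSE)
  sqrt(sum(dfs[keep] * sds[keep]^2) / sum(dfs[keep]))
}

#' Measure names used throughout the package
#' @return character vector of the 15 training-measure names.
#' @export
measure_names <- function() {
  c("weekly", "roll1", "roll3", "roll4",
    "smooth1.5", "smooth2", "smooth3", "smooth4",
    "diff1.5", "diff2", "diff3", "diff4",
    "monotony", "strain", "acwr")
}

smooth_label <- function(prefix, lambda) {
  tc <- round(2 / lambda) / 2
  paste0(prefix, sub("\\.0$", "", format(tc, nsmall = 0)))
}

#' Derive the full training-measure table
#'
#' Computes, per player on a contiguous weekly grid, the weekly global load
#' and every derivative measure: 1/3/4-week rolling means, smoothed and
#' differential loads for each lambda, monotony, strain and the acute:chronic
#' ratio. Missing weeks (no sessions) propagate as gaps under each measure's
#' own policy.
#'
#' @param obs player-week tibble from [aggregate_week()].
#' @param weights a [load_weights()] vector.
#' @param lambdas decay factors; default `c(0.67, 0.5, 0.33, 0.25)` (time
#'   constants 1.5, 2, 3, 4 weeks).
#' @param predictor_lag lag convention passed to [smoothed_load()] /
#'   [differential_load()]: named list with elements `smooth` (default 1) and
#'   `diff` (default 0).
#' @param init initialization policy for the recurrences.
#' @return tidy tibble: `player_id, week_index, measure, value`.
#' @export
derive_measures <- function(obs, weights = load_weights(),
                            lambdas = c(0.67, 0.5, 0.33, 0.25),
                            predictor_lag = list(smooth = 1, diff = 0),
                            init = "first_value") {
  obs <- obs[!obs$no_sessions | is.na(obs$no_sessions), , drop = FALSE]
  obs$weekly <- global_load(obs, weights)
  out <- lapply(split(obs, obs$player_id), function(p) {
    weeks <- seq(min(p$week_index), max(p$week_index))
    x <- rep(NA_real_, length(weeks))
    x[match(p$week_index, weeks)] <- p$weekly
    ms <- monotony_strain(x)
    vals <- c(list(weekly = x,
                   roll1 = rolling_mean(x, 1),
                   roll3 = rolling_mean(x, 3),
                   roll4 = rolling_mean(x, 4)),
              setNames(lapply(lambdas, function(l)
                smoothed_load(x, smoothing_spec(l, init),
                              predictor_lag$smooth)),
                vapply(lambdas, smooth_label, "", prefix = "smooth")),
              setNames(lapply(lambdas, function(l)
                differential_load(x, smoothing_spec(l, init),
                                  predictor_lag$diff)),
                vapply(lambdas, smooth_label, "", prefix = "diff")),
              list(monotony = ms$monotony, strain = ms$strain,
                   acwr = acute_chronic(x)))
    tibble::tibble(player_id = p$player_id[1],
                   week_index = rep(weeks, length(vals)),
                   measure = rep(names(vals), each = length(weeks)),
                   value = unlist(vals, use.names = FALSE))
  })
  res <- dplyr::bind_rows(out)
  res$measure <- factor(res$measure, levels = measure_names())
  dplyr::arrange(res, .data$player_id, .data$measure, .data$week_index) |>
    dplyr::mutate(measure = as.character(.data$measure))
}
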