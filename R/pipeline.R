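#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML parses) with either an `input` block of ledger
#' file paths or a `simulate` block of [season_config()] overrides — not
#' both — plus optional `measures`, `lambdas`, `variant`, `inference`
#' overrides, `output_dir` and `seed`.
#'
#' @param path config file path.
#' @return the config as a named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$input) && !is.null(cfg$simulate))
    stop("config must have either 'input' or 'simulate', not both",
         call. = FALSE)
  cfg
}

#' Per-position descriptive table: mean and within-player SD
#'
#' One row per training measure (plus the performance score), one column per
#' position, each cell the player-week mean and the df-weighted pooled
#' within-player SD ([within_player_sd()]). Positions where a player
#' contributes fewer than 2 observations have that player dropped from the
#' SD pool. Monotony and the acute:chronic ratio are dimensionless;
#' performance, loads and strain are in arbitrary units.
#'
#' @param obs player-week tibble from [aggregate_week()].
#' @param derived tidy measure table from [derive_measures()].
#' @return tibble: `measure`, one `mean`/`within_sd` column pair per
#'   position, and a formatted `label` per cell in long attribute-free form:
#'   columns `measure, position, mean, within_sd, label`.
#' @export
summarize_descriptives <- function(obs, derived) {
  perf <- obs |>
    dplyr::filter(!is.na(.data$performance_score)) |>
    dplyr::transmute(.data$player_id, .data$week_index,
                     measure = "performance", value = .data$performance_score)
  long <- dplyr::bind_rows(perf, derived) |>
    dplyr::left_join(dplyr::distinct(obs[c("player_id", "position")]),
                     by = "player_id") |>
    dplyr::filter(!is.na(.data$value))
  long |>
    dplyr::group_by(.data$measure, .data$position) |>
    dplyr::group_modify(function(g, key) {
      per_player <- g |>
        dplyr::group_by(.data$player_id) |>
        dplyr::summarise(s = sd(.data$value), df = dplyr::n() - 1,
                         .groups = "drop") |>
        dplyr::filter(.data$df >= 1)
      wsd <- if (nrow(per_player)) within_player_sd(per_player$s,
                                                    per_player$df)
             else NA_real_
      tibble::tibble(mean = mean(g$value), within_sd = wsd,
                     n_obs = nrow(g))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = sprintf("%.0f ± %.0f", .data$mean,
                                  .data$within_sd),
                  dimensionless = .data$measure %in% c("monotony", "acwr"))
}

measure_sd_table <- function(derived, roster) {
  derived |>
    dplyr::left_join(roster, by = "player_id") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$measure, .data$position, .data$player_id) |>
    dplyr::summarise(s = sd(.data$value), df = dplyr::n() - 1,
                     .groups = "drop") |>
    dplyr::filter(.data$df >= 1) |>
    dplyr::group_by(.data$measure, .data$position) |>
    dplyr::summarise(within_sd = within_player_sd(.data$s, .data$df),
                     .groups = "drop")
}

#' Run the full load-to-performance pipeline
#'
#' Executes ledger aggregation, measure derivation, per-position quadratic
#' mixed fits for each requested measure, -1/+1 SD (and -2/+2 SD) effect
#' estimation, magnitude-based inference and training recommendations, and
#' (optionally) writes the report bundle — descriptives, effects table,
#' predicted curves, resolved config — to `output_dir`. With the same config
#' and seed the bundle is byte-identical across runs. Positions with very few
#' players (e.g. 3 rucks) produce wide, often unclear estimates; they are
#' reported, not suppressed, with a small-sample warning in the log.
#'
#' @param config list as from [read_pipeline_config()], or a
#'   [season_config()] to simulate directly.
#' @param seed RNG seed used for simulation (overridden by `config$seed`).
#' @return invisibly, a list: `obs`, `derived`, `descriptives`, `effects`
#'   (one row per measure x position x offset with MBI columns),
#'   `recommendations`, `curves`, `fits`, `log`.
#' @export
run_pipeline <- function(config = list(simulate = list()), seed = 1) {
  if (inherits(config, "season_config")) config <- list(simulate = config)
  if (!is.null(config$seed)) seed <- config$seed
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$input)) {
    led <- do.call(read_ledger, config$input)
    say("ledger read from files: %s", paste(unlist(config$input),
                                            collapse = ", "))
  } else {
    scfg <- config$simulate
    if (!inherits(scfg, "season_config"))
      scfg <- do.call(season_config, if (is.null(scfg)) list() else scfg)
    led <- simulate_squad(scfg, seed = seed)
    say("synthetic season simulated (seed %d, %d weeks)", seed, scfg$n_weeks)
  }
  obs <- aggregate_week(led$sessions, led$wellness, led$matches, led$roster,
                        led$problems)
  weights <- if (!is.null(config$weights)) do.call(load_weights,
                                                   config$weights)
             else load_weights()
  lambdas <- config$lambdas %||% c(0.67, 0.5, 0.33, 0.25)
  derived <- derive_measures(obs, weights, lambdas = lambdas)
  say("derived %d measure series for %d player-weeks",
      dplyr::n_distinct(derived$measure), nrow(obs))

  measures <- config$measures %||%
    c("weekly", "smooth1.5", "smooth4", "diff1.5", "diff4",
      "strain", "monotony", "acwr")
  variant <- config$variant %||% "simple"
  icfg <- if (!is.null(config$inference)) do.call(inference_config,
                                                  config$inference)
          else inference_config()
  descr <- summarize_descriptives(obs, derived)
  sds <- measure_sd_table(derived, led$roster)

  wide <- derived |>
    tidyr::pivot_wider(names_from = "measure", values_from = "value") |>
    dplyr::inner_join(
      obs[c("player_id", "week_index", "position", "performance_score",
            "match_time_pct", "subbed_on", "subbed_off", "match_id")],
      by = c("player_id", "week_index"))

  effects <- list(); curves <- list(); fits <- list(); recs <- list()
  for (ms in measures) {
    for (pos in sort(unique(wide$position))) {
      dp <- wide[wide$position == pos, ]
      n_pl <- dplyr::n_distinct(dp$player_id)
      if (n_pl < 5) say("small sample: %s has %d players; expect wide limits",
                        pos, n_pl)
      sd_row <- sds$within_sd[sds$measure == ms & sds$position == pos]
      if (!length(sd_row) || !is.finite(sd_row) || sd_row <= 0) next
      fit <- tryCatch(fit_quadratic_mixed(dp, ms, variant = variant),
                      error = function(e) NULL)
      if (is.null(fit)) {
        say("fit failed: %s / %s", ms, pos)
        next
      }
      if (!fit$converged) say("non-convergent fit flagged: %s / %s", ms, pos)
      eff <- effect_at_offsets(fit, sd_row)
      mbi <- mbi_probabilities(eff$delta, eff$cl90, eff$df, icfg)
      std <- standardize_and_classify(eff$delta, cfg = icfg)
      eff <- dplyr::bind_cols(
        tibble::tibble(measure = ms, position = pos, within_sd = sd_row,
                       converged = fit$converged),
        eff, mbi, std)
      effects[[paste(ms, pos)]] <- eff
      e_m1 <- eff[eff$offset == -1, ]
      e_p1 <- eff[eff$offset == 1, ]
      recs[[paste(ms, pos)]] <- tibble::tibble(
        measure = ms, position = pos,
        delta_minus1 = e_m1$delta, cl90_minus1 = e_m1$cl90,
        symbol_minus1 = e_m1$symbol,
        delta_plus1 = e_p1$delta, cl90_plus1 = e_p1$cl90,
        symbol_plus1 = e_p1$symbol,
        recommendation = recommend_training(e_m1, e_p1, icfg))
      curves[[paste(ms, pos)]] <- dplyr::bind_cols(
        tibble::tibble(measure = ms, position = pos),
        predict_performance_curve(fit, sd_row, grid = seq(-2, 2, by = 0.25)))
      fits[[paste(ms, pos)]] <- fit
    }
  }
  out <- list(obs = obs, derived = derived, descriptives = descr,
              effects = dplyr::bind_rows(effects),
              recommendations = dplyr::bind_rows(recs),
              curves = dplyr::bind_rows(curves), fits = fits,
              log = log, seed = seed)
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(out$descriptives, file.path(dir, "descriptives.csv"))
    readr::write_csv(out$effects, file.path(dir, "effects.csv"))
    readr::write_csv(out$recommendations,
                     file.path(dir, "recommendations.csv"))
    readr::write_csv(out$curves, file.path(dir, "curves.csv"))
    readr::write_csv(derived, file.path(dir, "derived_measures.csv"))
    resolved <- list(seed = seed, measures = measures, variant = variant,
                     lambdas = lambdas,
                     weights = as.list(as.numeric(weights)),
                     sic = icfg$sic, between_sd = icfg$between_sd)
    yaml::write_yaml(resolved, file.path(dir, "resolved_config.yml"))
    writeLines(log, file.path(dir, "run.log"))
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot the predicted dose-response curves
#'
#' Inverted-U style panel of predicted performance against SD offsets of a
#' measure, one facet per position, with the 90% confidence band.
#'
#' @param curves the `curves` tibble from [run_pipeline()].
#' @param measure which measure to plot.
#' @return a ggplot object.
#' @export
plot_dose_response <- function(curves, measure = "weekly") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- curves[curves$measure == measure, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$predicted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower90,
                                      ymax = .data$upper90), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~position, scales = "free_y") +
    ggplot2::labs(x = "training measure (within-player SD from the mean)",
                  y = "predicted performance score",
                  title = paste("Dose-response:", measure)) +
    ggplot2::theme_minimal()
}
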