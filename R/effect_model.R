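#' Fit a quadratic mixed dose-response model for one measure and position
#'
#' Match performance is regressed on a training measure, centered at its
#' position-group mean, with linear and quadratic fixed terms (estimating the
#' mean quadratic) plus %-match-time as a simple linear covariate. Random
#' effects are the player intercept and the player-by-linear and
#' player-by-quadratic interactions (individual differences in the players'
#' quadratics), fitted as independent variance components, plus the residual
#' (match-to-match variability). The `complex` variant adds subbed-on /
#' subbed-off dummies and a match-identity random intercept to adjust for
#' mean between-match differences.
#'
#' Estimation is by REML (`lme4::lmer`). If the fit does not converge the
#' player-by-quadratic term is dropped and the fit retried (then the
#' player-by-linear term); drops are recorded in the diagnostics. With a
#' single player (no between-player information) the model reduces to an
#' ordinary least-squares quadratic, flagged in the diagnostics.
#'
#' @param data player-week tibble containing `performance_score`,
#'   `match_time_pct`, `player_id` (and for the complex variant `subbed_on`,
#'   `subbed_off`, `match_id`) plus the measure column.
#' @param measure name of the measure column to use as the dose.
#' @param variant `"simple"` or `"complex"`.
#' @param center value at which to center the measure; default its mean over
#'   the rows used (the position-group mean).
#' @return an object of class `quad_fit`: list with `beta` (named fixed
#'   coefficients: `(Intercept)`, `xc`, `xc2`, covariates), `vcov_fixed`,
#'   `varcomp` (player intercept / linear / quadratic, match, residual
#'   variances), `center`, `df_resid`, `n_obs`, `n_players`, `measure`,
#'   `variant`, `converged`, `dropped`, `singular`, `covariate_offset`
#'   (mean fitted covariate contribution, for curves on the performance
#'   scale).
#' @export
fit_quadratic_mixed <- function(data, measure, variant = c("simple", "complex"),
                                center = NULL) {
  variant <- match.arg(variant)
  need <- c("performance_score", "match_time_pct", "player_id", measure)
  if (variant == "complex")
    need <- c(need, "subbed_on", "subbed_off", "match_id")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[stats::complete.cases(data[c("performance_score",
                                         "match_time_pct", measure)]), ]
  if (nrow(d) < 10)
    stop("need at least 10 complete observations", call. = FALSE)
  if (is.null(center)) center <- mean(d[[measure]])
  d$xc <- d[[measure]] - center
  d$xc2 <- d$xc^2
  if (var(d$xc) == 0)
    stop("singular design: measure '", measure, "' is constant", call. = FALSE)

  fixed <- "performance_score ~ xc + xc2 + match_time_pct"
  if (variant == "complex") fixed <- paste(fixed, "+ subbed_on + subbed_off")
  ran_player <- c("(1 | player_id)", "(0 + xc | player_id)",
                  "(0 + xc2 | player_id)")
  ran_match <- if (variant == "complex") "(1 | match_id)" else NULL

  n_players <- dplyr::n_distinct(d$player_id)
  dropped <- character()
  if (n_players < 2) {
    fit <- lm(stats::as.formula(fixed), data = d)
    beta <- coef(fit)
    V <- vcov(fit)
    vc <- c(player_intercept = 0, player_linear = 0, player_quadratic = 0,
            match = 0, residual = summary(fit)$sigma^2)
    conv <- TRUE; singular <- FALSE
    dropped <- "all_random_terms_single_player"
  } else {
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    try_fit <- function(ran) {
      f <- stats::as.formula(paste(c(fixed, ran, ran_match), collapse = " + "))
      ok <- TRUE
      fit <- withCallingHandlers(
        tryCatch(lme4::lmer(f, data = d, REML = TRUE, control = ctrl),
                 error = function(e) { ok <<- FALSE; NULL }),
        warning = function(w) {
          if (grepl("converge", conditionMessage(w))) ok <<- FALSE
          invokeRestart("muffleWarning")
        })
      list(fit = fit, ok = ok)
    }
    r <- try_fit(ran_player)
    if (!r$ok) {
      dropped <- "player_quadratic"
      r <- try_fit(ran_player[1:2])
    }
    if (!r$ok) {
      dropped <- c(dropped, "player_linear")
      r <- try_fit(ran_player[1])
    }
    fit <- r$fit
    conv <- r$ok && !is.null(fit)
    if (is.null(fit)) stop("mixed model failed to fit", call. = FALSE)
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    get_vc <- function(grp, v) {
      i <- which(vcdf$grp == grp & (is.na(v) | vcdf$var1 == v))
      if (length(i)) vcdf$vcov[i[1]] else 0
    }
    vc <- c(
      player_intercept = get_vc("player_id", "(Intercept)"),
      player_linear = max(get_vc("player_id.1", "xc"), get_vc("player_id", "xc")),
      player_quadratic = max(get_vc("player_id.2", "xc2"),
                             get_vc("player_id.1", "xc2"),
                             get_vc("player_id", "xc2")),
      match = if (!is.null(ran_match)) get_vc("match_id", "(Intercept)") else 0,
      residual = vcdf$vcov[vcdf$grp == "Residual"][1])
    singular <- lme4::isSingular(fit)
  }
  dimnames(V) <- list(names(beta), names(beta))
  cov_terms <- setdiff(names(beta), c("(Intercept)", "xc", "xc2"))
  cov_offset <- sum(vapply(cov_terms, function(tm) {
    col <- sub("TRUE$", "", tm)
    v <- d[[col]]
    if (is.logical(v)) v <- as.numeric(v)
    beta[[tm]] * mean(v)
  }, 0))
  structure(list(beta = beta, vcov_fixed = V, varcomp = vc, center = center,
                 df_resid = nrow(d) - length(beta), n_obs = nrow(d),
                 n_players = n_players, measure = measure, variant = variant,
                 converged = conv, singular = singular, dropped = dropped,
                 covariate_offset = cov_offset),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("Quadratic mixed dose-response fit (%s model)\n", x$variant))
  cat(sprintf("  measure: %s (centered at %.4g), %d obs, %d player(s)\n",
              x$measure, x$center, x$n_obs, x$n_players))
  cat(sprintf("  b0 = %.3f, b1 = %.4g, b2 = %.4g\n",
              x$beta[["(Intercept)"]], x$beta[["xc"]], x$beta[["xc2"]]))
  cat(sprintf("  residual SD = %.2f, player-intercept SD = %.2f\n",
              sqrt(x$varcomp[["residual"]]),
              sqrt(x$varcomp[["player_intercept"]])))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (length(x$dropped))
    cat("  dropped random terms:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Effect of a k-SD change in the measure on performance
#'
#' For the fitted mean quadratic `f(x) = b0 + b1 x + b2 x²` on the centered
#' measure scale, the effect of sitting `k` within-player SDs away from the
#' evaluation mean is `delta(k) = f(m + k s) − f(m) = b1 k s +
#' b2 (2 m k s + k² s²)` (covariates held fixed), with `m` the evaluation
#' point on the centered scale (0 = the position-group mean). The 90%
#' confidence limits come from the variance of the corresponding linear
#' combination of `(b1, b2)` under the fixed-effect covariance and a t
#' quantile with `df_resid` degrees of freedom.
#'
#' @param fit a `quad_fit`.
#' @param sd within-player SD of the measure (from [within_player_sd()]),
#'   > 0.
#' @param offsets SD multiples to evaluate; default `c(-2, -1, 1, 2)`.
#' @param at evaluation mean on the centered scale (default 0).
#' @param df degrees of freedom for the t quantile; default
#'   `fit$df_resid` (observations minus fixed effects).
#' @return tibble: `offset, delta, se, cl90, df`.
#' @export
effect_at_offsets <- function(fit, sd, offsets = c(-2, -1, 1, 2), at = 0,
                              df = fit$df_resid) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  b <- fit$beta
  V <- fit$vcov_fixed[c("xc", "xc2"), c("xc", "xc2")]
  rows <- lapply(offsets, function(k) {
    cvec <- c(k * sd, 2 * at * k * sd + (k * sd)^2)
    delta <- sum(cvec * b[c("xc", "xc2")])
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tibble::tibble(offset = k, delta = delta, se = se,
                   cl90 = qt(0.95, df) * se, df = df)
  })
  dplyr::bind_rows(rows)
}

#' Predicted performance curve over a grid of SD offsets
#'
#' Evaluates the fitted quadratic (plus the mean covariate contribution, so
#' predictions are on the performance-score scale) on a grid of within-player
#' SD offsets around the mean, with a 90% confidence band for the mean
#' prediction.
#'
#' @inheritParams effect_at_offsets
#' @param grid SD offsets; default `seq(-2, 2, by = 0.1)`.
#' @return tibble: `offset, x (centered measure units), predicted, lower90,
#'   upper90`.
#' @export
predict_performance_curve <- function(fit, sd, grid = seq(-2, 2, by = 0.1),
                                      at = 0, df = fit$df_resid) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  b <- fit$beta[c("(Intercept)", "xc", "xc2")]
  V <- fit$vcov_fixed[c("(Intercept)", "xc", "xc2"),
                      c("(Intercept)", "xc", "xc2")]
  x <- at + grid * sd
  X <- cbind(1, x, x^2)
  pred <- drop(X %*% b) + fit$covariate_offset
  se <- sqrt(rowSums((X %*% V) * X))
  hw <- qt(0.95, df) * se
  tibble::tibble(offset = grid, x = x, predicted = pred,
                 lower90 = pred - hw, upper90 = pred + hw)
}

#' Reliability analysis: true between-player SD of a training measure
#'
#' Mixed model of the measure with fixed effects for seasonal trend (linear
#' in week) and problem weeks (injury/illness-modified training), and random
#' intercepts for player, match and the match-by-problem interaction. The
#' true between-player SD is the square root of the player variance
#' component; substantial values would complicate interpreting within-player
#' effects.
#'
#' @param data player-week tibble with `player_id`, `week_index`,
#'   `problem_flag`, `match_id` and the measure column.
#' @param measure measure column name.
#' @return list of class `reliability_fit`: `between_sd`, `varcomp`,
#'   `trend` (per-week fixed slope), `problem_effect`, `converged`.
#' @export
reliability_between_sd <- function(data, measure) {
  d <- data[stats::complete.cases(data[c(measure, "week_index")]), ]
  if (dplyr::n_distinct(d$player_id) < 2 || dplyr::n_distinct(d$week_index) < 2)
    stop("need >= 2 players and >= 2 weeks", call. = FALSE)
  d$y <- d[[measure]]
  d$problem <- as.numeric(!is.na(d$problem_flag) & d$problem_flag)
  has_match <- "match_id" %in% names(d) && any(!is.na(d$match_id))
  ran <- "(1 | player_id)"
  if (has_match) {
    ran <- c(ran, "(1 | match_id)")
    if (any(d$problem > 0)) ran <- c(ran, "(1 | match_id:problem)")
  }
  f <- stats::as.formula(paste(c("y ~ week_index + problem", ran),
                               collapse = " + "))
  ok <- TRUE
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- withCallingHandlers(
    lme4::lmer(f, data = d, REML = TRUE, control = ctrl),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w))) ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  vcdf <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    i <- which(vcdf$grp == grp)
    if (length(i)) vcdf$vcov[i[1]] else 0
  }
  vc <- c(player = pick("player_id"), match = pick("match_id"),
          match_problem = pick("match_id:problem"),
          residual = vcdf$vcov[vcdf$grp == "Residual"][1])
  be <- lme4::fixef(fit)
  structure(list(between_sd = sqrt(vc[["player"]]), varcomp = vc,
                 trend = unname(be["week_index"]),
                 problem_effect = unname(be["problem"]),
                 measure = measure, converged = ok),
            class = "reliability_fit")
}
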