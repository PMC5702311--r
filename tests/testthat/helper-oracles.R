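# Independent brute-force oracle for the smoothing recurrence: expand the
# exponential kernel explicitly. With first-value seeding and lag 1, week w
# (w >= 2) weights load j by lam*(1-lam)^(w-1-j) for 2 <= j <= w-1 and the
# initial load by (1-lam)^(w-2).
oracle_smooth <- function(x, lam) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (w in 2:n) {
    s <- (1 - lam)^(w - 2) * x[1]
    if (w >= 3)
      for (j in 2:(w - 1)) s <- s + lam * (1 - lam)^(w - 1 - j) * x[j]
    out[w] <- s
  }
  out
}

# minimal player-week observation builder with all ledger columns
make_obs <- function(player_id, week_index, weekly_target = NULL, position = "defender",
                     training_td = 0, training_hvd = 0, match_td = NA_real_,
                     match_hvd = NA_real_, match_work_rate = NA_real_,
                     match_accels = NA_real_, match_decels = NA_real_,
                     wellness_total = 0, performance_score = NA_real_,
                     match_time_pct = NA_real_, subbed_on = FALSE,
                     subbed_off = FALSE, problem_flag = FALSE,
                     match_id = NA_character_) {
  n <- max(length(player_id), length(week_index))
  tibble::tibble(player_id = rep_len(player_id, n),
                 position = rep_len(position, n),
                 week_index = rep_len(week_index, n),
                 training_td = rep_len(training_td, n),
                 training_hvd = rep_len(training_hvd, n),
                 match_td = rep_len(match_td, n),
                 match_hvd = rep_len(match_hvd, n),
                 match_work_rate = rep_len(match_work_rate, n),
                 match_accels = rep_len(match_accels, n),
                 match_decels = rep_len(match_decels, n),
                 wellness_total = rep_len(wellness_total, n),
                 performance_score = rep_len(performance_score, n),
                 match_time_pct = rep_len(match_time_pct, n),
                 subbed_on = rep_len(subbed_on, n),
                 subbed_off = rep_len(subbed_off, n),
                 problem_flag = rep_len(problem_flag, n),
                 match_id = rep_len(match_id, n),
                 no_sessions = FALSE)
}

# fabricate a quad_fit with known coefficients for contrast-layer tests
fake_fit <- function(b0 = 0, b1 = 0, b2 = 0, V = diag(1e-6, 3),
                     df_resid = 1000) {
  beta <- c("(Intercept)" = b0, xc = b1, xc2 = b2)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(beta = beta, vcov_fixed = V,
                 varcomp = c(player_intercept = 0, player_linear = 0,
                             player_quadratic = 0, match = 0, residual = 1),
                 center = 0, df_resid = df_resid, n_obs = df_resid + 3,
                 n_players = 1, measure = "weekly", variant = "simple",
                 converged = TRUE, singular = FALSE, dropped = character(),
                 covariate_offset = 0),
            class = "quad_fit")
}
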