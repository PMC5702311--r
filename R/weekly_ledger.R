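#' @title Weekly athlete-monitoring ledger: record types, I/O and aggregation
#' @name weekly_ledger
#' @description
#' The ledger holds three record kinds, one CSV file each:
#' sessions (per GPS-monitored session), wellness (one 12-item diary total per
#' player-week) and matches (performance score, match-time and substitution
#' flags). Two small auxiliary files carry what the record kinds cannot: a
#' roster mapping each player to a static position for the season, and an
#' optional per player-week problem flag (injury/illness-modified training).
#' Everything downstream runs on the player-week grain produced by
#' [aggregate_week()].
NULL

POSITIONS <- c("defender", "forward", "midfielder", "ruck")
SESSION_KINDS <- c("training", "match", "recovery")

session_cols <- c("player_id", "week_index", "session_kind", "total_distance",
                  "high_velocity_distance", "avg_speed",
                  "high_accel_count", "high_decel_count")
wellness_cols <- c("player_id", "week_index", paste0("item_", 1:12), "total")
match_cols <- c("player_id", "week_index", "performance_score",
                "match_time_pct", "subbed_on", "subbed_off", "match_id")

stop_schema <- function(file, missing) {
  stop(sprintf("schema error in '%s': missing column(s) %s",
               file, paste(missing, collapse = ", ")), call. = FALSE)
}

check_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop_schema(file, miss)
  invisible(df)
}

#' Validate session records
#'
#' Checks field ranges and invariants: non-negative distances and counts,
#' high-velocity distance bounded by total distance, average speed present
#' exactly for match sessions.
#'
#' @param sessions tibble of session records.
#' @return the input, invisibly, or an error naming the offending rows.
#' @export
validate_sessions <- function(sessions) {
  bad_kind <- which(!sessions$session_kind %in% SESSION_KINDS)
  if (length(bad_kind))
    stop(sprintf("invalid session_kind at row(s) %s (allowed: %s)",
                 paste(head(bad_kind, 5), collapse = ", "),
                 paste(SESSION_KINDS, collapse = "/")), call. = FALSE)
  num <- c("total_distance", "high_velocity_distance",
           "high_accel_count", "high_decel_count")
  for (f in num) {
    bad <- which(!is.na(sessions[[f]]) & sessions[[f]] < 0)
    if (length(bad))
      stop(sprintf("negative %s at row(s) %s", f,
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.na(sessions$high_velocity_distance) &
               !is.na(sessions$total_distance) &
               sessions$high_velocity_distance > sessions$total_distance)
  if (length(bad))
    stop(sprintf("high_velocity_distance exceeds total_distance at row(s) %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  is_match <- sessions$session_kind == "match"
  bad <- which(is_match & is.na(sessions$avg_speed))
  if (length(bad))
    stop(sprintf("avg_speed missing for match session at row(s) %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  bad <- which(!is_match & !is.na(sessions$avg_speed))
  if (length(bad))
    stop(sprintf("avg_speed present for non-match session at row(s) %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  invisible(sessions)
}

#' Validate wellness records
#'
#' The diary has 12 items on a 1-10 Likert scale; the total must equal the
#' item sum and therefore lie in \[12, 120\].
#'
#' @param wellness tibble of wellness records.
#' @return the input, invisibly.
#' @export
validate_wellness <- function(wellness) {
  items <- as.matrix(wellness[paste0("item_", 1:12)])
  bad <- which(apply(items, 1, function(r) any(r < 1 | r > 10 | r != round(r))))
  if (length(bad))
    stop(sprintf(
      "wellness item outside range [1,10] at row(s) %s (10-point Likert scale)",
      paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  bad <- which(wellness$total != rowSums(items))
  if (length(bad))
    stop(sprintf("wellness total != sum of items at row(s) %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  invisible(wellness)
}

#' Validate match records
#'
#' @param matches tibble of match records.
#' @return the input, invisibly.
#' @export
validate_matches <- function(matches) {
  bad <- which(!is.finite(matches$performance_score))
  if (length(bad))
    stop(sprintf("non-finite performance_score at row(s) %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  bad <- which(matches$match_time_pct < 0 | matches$match_time_pct > 100)
  if (length(bad))
    stop(sprintf("match_time_pct outside [0,100] at row(s) %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  invisible(matches)
}

#' Read a monitoring ledger from CSV files
#'
#' Reads and validates the three record kinds plus the roster and optional
#' problem-flag file. Files are UTF-8 CSV with a header row; `week_index` is a
#' 1-based integer season week.
#'
#' @param sessions,wellness,matches,roster paths to the CSV files.
#' @param problems optional path to a player-week problem-flag CSV
#'   (`player_id, week_index, problem_flag`).
#' @return a list of validated tibbles: `sessions`, `wellness`, `matches`,
#'   `roster`, `problems` (the latter `NULL` when not supplied).
#' @export
read_ledger <- function(sessions, wellness, matches, roster, problems = NULL) {
  rd <- function(path) readr::read_csv(path, show_col_types = FALSE,
                                       progress = FALSE)
  ses <- check_cols(rd(sessions), session_cols, sessions)
  wel <- check_cols(rd(wellness), wellness_cols, wellness)
  mat <- check_cols(rd(matches), match_cols, matches)
  ros <- check_cols(rd(roster), c("player_id", "position"), roster)
  if (nrow(ses)) validate_sessions(ses)
  if (nrow(wel)) validate_wellness(wel)
  if (nrow(mat)) validate_matches(mat)
  bad <- which(!ros$position %in% POSITIONS)
  if (length(bad))
    stop(sprintf("unknown position at roster row(s) %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  prb <- NULL
  if (!is.null(problems))
    prb <- check_cols(rd(problems),
                      c("player_id", "week_index", "problem_flag"), problems)
  list(sessions = ses, wellness = wel, matches = mat, roster = ros,
       problems = prb)
}

#' Write a monitoring ledger to CSV files
#'
#' Inverse of [read_ledger()]; one file per record kind.
#'
#' @param ledger list as returned by [read_ledger()] or [simulate_squad()].
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_ledger <- function(ledger, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(ledger$sessions, file.path(dir, "sessions.csv"))
  readr::write_csv(ledger$wellness, file.path(dir, "wellness.csv"))
  readr::write_csv(ledger$matches, file.path(dir, "matches.csv"))
  readr::write_csv(ledger$roster, file.path(dir, "roster.csv"))
  if (!is.null(ledger$problems))
    readr::write_csv(ledger$problems, file.path(dir, "problems.csv"))
  invisible(dir)
}

#' Aggregate session, wellness and match records to player-weeks
#'
#' Training fields are sums over all non-match sessions of the week (recovery
#' sessions included: every monitored session contributes to load); match
#' fields are that week's single match session and match record. Weeks with no
#' match leave the match fields missing. A player-week with no sessions at all
#' is flagged missing (`no_sessions`) and yields no load.
#'
#' @param sessions,wellness,matches validated record tibbles.
#' @param roster tibble `player_id, position`.
#' @param problems optional tibble `player_id, week_index, problem_flag`.
#' @return a tibble with one row per player-week observed in any input,
#'   columns: `player_id, position, week_index, training_td, training_hvd,
#'   match_td, match_hvd, match_work_rate, match_accels, match_decels,
#'   wellness_total, performance_score, match_time_pct, subbed_on, subbed_off,
#'   problem_flag, match_id, no_sessions`.
#' @export
aggregate_week <- function(sessions, wellness, matches, roster,
                           problems = NULL) {
  dup <- matches |>
    dplyr::count(.data$player_id, .data$week_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup))
    stop(sprintf("ambiguous ledger: %d player-week(s) with two matches (first: player %s week %s)",
                 nrow(dup), dup$player_id[1], dup$week_index[1]), call. = FALSE)
  dup <- sessions |>
    dplyr::filter(.data$session_kind == "match") |>
    dplyr::count(.data$player_id, .data$week_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup))
    stop("ambiguous ledger: player-week with two match sessions", call. = FALSE)

  train <- sessions |>
    dplyr::filter(.data$session_kind != "match") |>
    dplyr::group_by(.data$player_id, .data$week_index) |>
    dplyr::summarise(training_td = sum(.data$total_distance),
                     training_hvd = sum(.data$high_velocity_distance),
                     .groups = "drop")
  match_ses <- sessions |>
    dplyr::filter(.data$session_kind == "match") |>
    dplyr::transmute(.data$player_id, .data$week_index,
                     match_td = .data$total_distance,
                     match_hvd = .data$high_velocity_distance,
                     match_work_rate = .data$avg_speed,
                     match_accels = .data$high_accel_count,
                     match_decels = .data$high_decel_count)
  wel <- wellness |>
    dplyr::select("player_id", "week_index", wellness_total = "total")
  mat <- matches |>
    dplyr::select("player_id", "week_index", "performance_score",
                  "match_time_pct", "subbed_on", "subbed_off", "match_id")

  keys <- dplyr::bind_rows(
    train[c("player_id", "week_index")],
    match_ses[c("player_id", "week_index")],
    wel[c("player_id", "week_index")],
    mat[c("player_id", "week_index")]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$player_id, .data$week_index)

  obs <- keys |>
    dplyr::left_join(train, by = c("player_id", "week_index")) |>
    dplyr::left_join(match_ses, by = c("player_id", "week_index")) |>
    dplyr::left_join(wel, by = c("player_id", "week_index")) |>
    dplyr::left_join(mat, by = c("player_id", "week_index")) |>
    dplyr::left_join(roster, by = "player_id") |>
    dplyr::mutate(
      no_sessions = is.na(.data$training_td) & is.na(.data$match_td),
      problem_flag = FALSE) |>
    dplyr::relocate("position", .after = "player_id")
  if (!is.null(problems)) {
    obs <- obs |>
      dplyr::select(-"problem_flag") |>
      dplyr::left_join(problems, by = c("player_id", "week_index")) |>
      dplyr::mutate(problem_flag = !is.na(.data$problem_flag) &
                      .data$problem_flag)
  }
  obs
}
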