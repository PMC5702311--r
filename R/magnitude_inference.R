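#' Magnitude-based inference configuration
#'
#' Holds the standardization thresholds, the probability qualifier scale and
#' the smallest important change (SIC). The SIC defaults to 0.2 times the
#' observed between-player SD of the performance score (about 25 across
#' position groups), i.e. 5 raw performance units.
#'
#' @param between_sd observed between-player SD of performance.
#' @param sic smallest important change, in performance units.
#' @param thresholds increasing |standardized| upper bounds of the trivial /
#'   small / moderate / large bins; effects beyond the last bound are
#'   "very large".
#' @param prob_breaks,prob_labels the probability qualifier scale: breaks
#'   partition \[0, 1\] into most unlikely ... most likely.
#' @return list of class `inference_config`.
#' @export
inference_config <- function(between_sd = 25, sic = 0.2 * between_sd,
                             thresholds = c(trivial = 0.2, small = 0.6,
                                            moderate = 1.2, large = 2.0),
                             prob_breaks = c(0, 0.005, 0.05, 0.25, 0.75,
                                             0.95, 0.995, 1),
                             prob_labels = c("most unlikely", "very unlikely",
                                             "unlikely", "possibly", "likely",
                                             "very likely", "most likely")) {
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (sic <= 0) stop("smallest important change must be > 0", call. = FALSE)
  if (length(prob_labels) != length(prob_breaks) - 1)
    stop("need one probability label per bin", call. = FALSE)
  structure(list(between_sd = between_sd, sic = sic, thresholds = thresholds,
                 prob_breaks = prob_breaks, prob_labels = prob_labels),
            class = "inference_config")
}

#' Standardize an effect and classify its magnitude
#'
#' Divides the raw change in performance by the between-player SD and bins
#' the absolute standardized value: <0.2 trivial, 0.2-<0.6 small, 0.6-<1.2
#' moderate, 1.2-<2.0 large, >=2.0 very large.
#'
#' @param delta raw effect(s), performance units.
#' @param between_sd between-player SD of performance, > 0.
#' @param cfg an [inference_config()].
#' @return tibble: `standardized`, `magnitude` (character).
#' @export
standardize_and_classify <- function(delta, between_sd = cfg$between_sd,
                                     cfg = inference_config()) {
  if (!is.finite(between_sd) || between_sd <= 0)
    stop("between_sd must be > 0", call. = FALSE)
  std <- delta / between_sd
  labs <- c(names(cfg$thresholds), "very large")
  idx <- findInterval(abs(std), c(cfg$thresholds, Inf)) + 1
  tibble::tibble(standardized = std, magnitude = labs[idx])
}

#' Magnitude-based inference probabilities and qualifier
#'
#' Converts an effect and its 90% confidence limits into the probabilities
#' that the true effect is substantially positive / negative (beyond +/- the
#' smallest important change) under a t sampling distribution, assigns the
#' qualitative probability qualifier, and declares the effect unclear when
#' both substantial probabilities exceed 5%. For df > 100 the normal
#' approximation is used to stabilize the tails.
#'
#' @param delta effect point estimate, performance units.
#' @param cl90 the +/- half-width of the 90% confidence interval, > 0.
#' @param df degrees of freedom (>= 1; `Inf` for the normal limit).
#' @param cfg an [inference_config()].
#' @return tibble: `p_substantial_pos`, `p_substantial_neg`, `p_trivial`,
#'   `qualifier` (label of the larger substantial probability, with
#'   direction), `symbol` (footnote code: `*`..`****` positive,
#'   `0`..`0000` negative, `""` otherwise), `clear` (logical).
#' @export
mbi_probabilities <- function(delta, cl90, df, cfg = inference_config()) {
  if (any(!is.finite(cl90) | cl90 <= 0)) stop("cl90 must be > 0", call. = FALSE)
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  df_use <- ifelse(df > 100, Inf, df)
  se <- cl90 / qt(0.95, df_use)
  sic <- cfg$sic
  p_pos <- pt((delta - sic) / se, df_use)
  p_neg <- pt((-sic - delta) / se, df_use)
  p_larger <- pmax(p_pos, p_neg)
  lab <- cfg$prob_labels[findInterval(p_larger, cfg$prob_breaks,
                                      rightmost.closed = TRUE)]
  dir_pos <- p_pos >= p_neg
  clear <- !(p_pos > 0.05 & p_neg > 0.05)
  level <- match(lab, c("possibly", "likely", "very likely", "most likely"))
  symbol <- ifelse(clear & !is.na(level),
                   ifelse(dir_pos,
                          strrep("*", ifelse(is.na(level), 0, level)),
                          strrep("0", ifelse(is.na(level), 0, level))),
                   "")
  qualifier <- ifelse(!clear, "unclear",
                      paste(lab, ifelse(dir_pos, "positive", "negative")))
  tibble::tibble(p_substantial_pos = p_pos, p_substantial_neg = p_neg,
                 p_trivial = 1 - p_pos - p_neg, qualifier = qualifier,
                 symbol = symbol, clear = clear)
}

#' Training recommendation from the -1 SD and +1 SD effects
#'
#' Deterministic mapping from the pair of estimated effects to a
#' prescription, reconstructed from the pattern a practitioner would read
#' off the paired effects (it is a heuristic, not a fitted rule):
#' a clear substantial decrement at +1 SD together with a clear substantial
#' benefit at -1 SD prescribes "Reduce by >1 SD"; a clear decrement at +1 SD
#' alone prescribes "Reduce by 0 to ~1 SD" when the -1 SD point estimate is
#' positive and "Reduce by ~1 SD" otherwise; a clear substantial benefit at
#' +1 SD prescribes "Increase"; anything else (trivial/unclear both sides)
#' "No change". "Substantial" means the point estimate is beyond the
#' smallest important change.
#'
#' @param effect_minus1,effect_plus1 one-row data frames with `delta` and
#'   `clear` (e.g. a joined row of [effect_at_offsets()] and
#'   [mbi_probabilities()] output).
#' @param cfg an [inference_config()].
#' @return a recommendation string, or `NA_character_` if either effect is
#'   missing.
#' @export
recommend_training <- function(effect_minus1, effect_plus1,
                               cfg = inference_config()) {
  if (is.null(effect_minus1) || is.null(effect_plus1) ||
      any(is.na(c(effect_minus1$delta, effect_plus1$delta))))
    return(NA_character_)
  sic <- cfg$sic
  dec_plus <- isTRUE(effect_plus1$clear) && effect_plus1$delta <= -sic
  ben_plus <- isTRUE(effect_plus1$clear) && effect_plus1$delta >= sic
  ben_minus <- isTRUE(effect_minus1$clear) && effect_minus1$delta >= sic
  if (dec_plus && ben_minus) return("Reduce by >1 SD")
  if (dec_plus) {
    if (effect_minus1$delta > 0) return("Reduce by 0 to ~1 SD")
    return("Reduce by ~1 SD")
  }
  if (ben_plus) return("Increase")
  "No change"
}
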