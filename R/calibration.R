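#' Baseline survival function
#'
#' Container for the baseline survival curve \eqn{S_0(t)} used to convert
#' scores into absolute distant-recurrence probabilities via
#' \eqn{S_0(t)^{\exp(score/100)}}. Either estimated internally from the
#' cohort (Breslow, see [breslow_baseline()]) or supplied as an external
#' table (e.g. from a previously published model).
#'
#' @param table data frame with columns `time_months` (ascending, >= 0)
#'   and `s0` in (0, 1], non-increasing. `S0(0) = 1` is implied.
#' @param mode `"external_table"` or `"internal_breslow"` (label only).
#' @return object of class `baseline_survival`.
#' @export
baseline_survival <- function(table, mode = "external_table") {
  stopifnot(is.data.frame(table),
            all(c("time_months", "s0") %in% names(table)))
  tb <- table[order(table$time_months), c("time_months", "s0")]
  if (any(tb$time_months < 0) || anyNA(tb$time_months))
    stop("baseline_survival: times must be >= 0", call. = FALSE)
  if (any(tb$s0 <= 0) || any(tb$s0 > 1) || anyNA(tb$s0))
    stop("baseline_survival: s0 must lie in (0, 1]", call. = FALSE)
  if (is.unsorted(rev(tb$s0)))
    stop("baseline_survival: s0 must be non-increasing in time",
         call. = FALSE)
  structure(list(table = tb, mode = mode), class = "baseline_survival")
}

#' Breslow baseline survival with a score offset
#'
#' Estimates \eqn{S_0(t) = \exp(-\Lambda_0(t))} by the Breslow estimator
#' treating the supplied linear predictor as a fixed offset (no
#' coefficient is refit):
#' \deqn{\Lambda_0(t) = \sum_{t_i \le t} d_i / \sum_{j \in R(t_i)}
#'   e^{lp_j}}
#' This is the self-calibrated ("internal") baseline: with it, the average
#' predicted event probability matches the cohort's observed experience by
#' construction when the proportional-hazards model holds.
#'
#' @param time_months,event outcome vectors.
#' @param lp linear predictor per subject (for the score models,
#'   score/100).
#' @return a [baseline_survival()] object with mode `"internal_breslow"`.
#' @export
breslow_baseline <- function(time_months, event, lp) {
  stopifnot(length(time_months) == length(event),
            length(lp) == length(event))
  if (any(!is.finite(lp)))
    stop("breslow_baseline: non-finite linear predictor", call. = FALSE)
  ord <- order(time_months)
  t <- time_months[ord]; e <- event[ord]; w <- exp(lp[ord])
  ut <- unique(t[e == 1])
  # risk-set sums via reverse cumulative sum over the sorted times
  rev_cum <- rev(cumsum(rev(w)))
  H <- vapply(ut, function(tt) {
    d <- sum(e == 1 & t == tt)
    at_risk <- rev_cum[match(TRUE, t >= tt)]
    d / at_risk
  }, numeric(1))
  s0 <- exp(-cumsum(H))
  tb <- data.frame(time_months = ut, s0 = s0)
  # the cumulative hazard is flat after the last event; the estimator is
  # supported up to the last observed (event or censoring) time
  if (!nrow(tb)) tb <- data.frame(time_months = max(t), s0 = 1)
  else if (max(t) > max(ut))
    tb <- rbind(tb, data.frame(time_months = max(t), s0 = s0[length(s0)]))
  baseline_survival(tb, mode = "internal_breslow")
}

s0_at <- function(baseline, horizon_months) {
  tb <- baseline$table
  if (horizon_months > max(tb$time_months))
    stop("predict_dr_probability: horizon beyond the baseline table's ",
         "support", call. = FALSE)
  idx <- which(tb$time_months <= horizon_months)
  if (!length(idx)) return(1)
  tb$s0[max(idx)]
}

#' Predicted distant-recurrence probability
#'
#' Converts a prognostic score into an absolute event probability at a
#' horizon under proportional hazards:
#' \deqn{P(DR \le t) = 1 - S_0(t)^{\exp(score/100)}}
#' The division by 100 undoes the presentation scaling of the scores
#' (which are printed as 100 x the Cox linear predictor).
#'
#' @param score numeric score(s) on the x100 presentation scale.
#' @param horizon_months prediction horizon (default 120 = 10 years).
#' @param baseline a [baseline_survival()] object.
#' @return predicted probabilities in `[0, 1]`.
#' @examples
#' b <- baseline_survival(data.frame(time_months = 120, s0 = 0.9))
#' predict_dr_probability(c(0, 100), 120, b)
#' @export
predict_dr_probability <- function(score, horizon_months = 120, baseline) {
  stopifnot(inherits(baseline, "baseline_survival"))
  s0 <- s0_at(baseline, horizon_months)
  1 - s0^exp(score / 100)
}

#' Decile calibration of predicted vs observed probabilities
#'
#' Splits the cohort into ten groups at the 10th percentiles of the score,
#' and within each group compares the mean predicted event probability at
#' the horizon to the observed Kaplan-Meier event probability
#' (1 - S_KM(horizon)) with its Greenwood log-log 95% CI. Perfectly
#' calibrated predictions lie on the 45-degree line of the resulting
#' predicted-vs-observed plot.
#'
#' @param scores score per subject (x100 presentation scale).
#' @param time_months,event outcome vectors aligned with `scores`.
#' @param horizon_months horizon (default 120).
#' @param baseline a [baseline_survival()] object; default is the internal
#'   Breslow baseline estimated from the same data with offset scores/100.
#' @return data frame of class `calibration_table` with one row per decile:
#'   `decile`, `n`, `score_min`, `score_max`, `predicted`, `observed`,
#'   `ci_low`, `ci_high`. Observed values are NA (flagged, not fabricated)
#'   when the group's follow-up does not reach the horizon.
#' @export
calibration_deciles <- function(scores, time_months, event,
                                horizon_months = 120, baseline = NULL) {
  stopifnot(length(scores) == length(time_months),
            length(event) == length(time_months))
  if (length(scores) < 10)
    stop("calibration_deciles: need at least 10 subjects", call. = FALSE)
  if (is.null(baseline))
    baseline <- breslow_baseline(time_months, event, scores / 100)
  cuts <- unique(quantile(scores, seq(0.1, 0.9, by = 0.1), type = 7,
                          names = FALSE))
  if (length(cuts) < 9)
    stop("calibration_deciles: degenerate deciles (tied score quantiles)",
         call. = FALSE)
  bin <- cut(scores, breaks = c(-Inf, cuts, Inf), labels = FALSE,
             right = FALSE)
  pred <- predict_dr_probability(scores, horizon_months, baseline)
  rows <- lapply(1:10, function(b) {
    sel <- bin == b
    obs <- lo <- hi <- NA_real_
    if (any(sel)) {
      km <- km_estimate(time_months[sel], event[sel])
      at <- km_at(km, min(horizon_months, max(km$time)))
      if (max(km$time) >= horizon_months ||
          sum(event[sel] == 1) == sum(sel)) {
        obs <- 1 - at$surv
        lo <- 1 - at$upper
        hi <- 1 - at$lower
      }
    }
    data.frame(decile = b, n = sum(sel),
               score_min = if (any(sel)) min(scores[sel]) else NA_real_,
               score_max = if (any(sel)) max(scores[sel]) else NA_real_,
               predicted = mean(pred[sel]),
               observed = obs, ci_low = lo, ci_high = hi)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Summary of predicted risks
#'
#' Reports the median, the 75th percentile and a full quantile grid of a
#' vector of predicted event probabilities.
#'
#' @param predictions predicted probabilities in `[0, 1]`.
#' @return list with `median`, `q75` and `quantiles` (0, 5, ..., 100%).
#' @export
predicted_risk_summary <- function(predictions) {
  if (!length(predictions))
    stop("predicted_risk_summary: empty input", call. = FALSE)
  qs <- quantile(predictions, probs = seq(0, 1, by = 0.05), type = 7)
  list(median = unname(quantile(predictions, 0.5, type = 7)),
       q75 = unname(quantile(predictions, 0.75, type = 7)),
       quantiles = qs)
}
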