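#' Derive the time-to-distant-recurrence outcome
#'
#' TTDR counts distant recurrence and deaths from breast cancer or unknown
#' cause (without prior distant recurrence) as events; every other recorded
#' outcome (none, local/regional recurrence, contralateral disease, death
#' from other causes) censors follow-up at the recorded time.
#'
#' @param time_months follow-up time from randomisation, months, >= 0.
#' @param event_type character/factor vector over
#'   `c("none","distant_recurrence","local_or_regional_recurrence",
#'   "contralateral","death_breast_cancer","death_unknown_cause",
#'   "death_other_cause")`.
#' @return data frame with `time_months` and binary `event`.
#' @examples
#' derive_ttdr(c(30, 40), c("distant_recurrence", "death_other_cause"))
#' @export
derive_ttdr <- function(time_months, event_type) {
  if (anyNA(time_months) || any(time_months < 0) ||
      any(!is.finite(time_months)))
    stop("derive_ttdr: time_months must be finite and >= 0", call. = FALSE)
  ev <- check_levels(event_type, ttdr_event_types(), "event_type")
  if (anyNA(ev))
    stop("derive_ttdr: missing event_type", call. = FALSE)
  data.frame(
    time_months = time_months,
    event = as.integer(ev %in% c("distant_recurrence", "death_breast_cancer",
                                 "death_unknown_cause"))
  )
}

ttdr_event_types <- function() {
  c("none", "distant_recurrence", "local_or_regional_recurrence",
    "contralateral", "death_breast_cancer", "death_unknown_cause",
    "death_other_cause")
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function with Greenwood
#' standard errors and log-log 95% confidence limits. Subjects censored at
#' an event time are counted at risk for that time.
#'
#' @param time_months,event aligned outcome vectors (`event` 0/1).
#' @return data frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `lower`, `upper`, one row per distinct observed time; survival
#'   is 1 at time 0 by convention.
#' @export
km_estimate <- function(time_months, event) {
  if (length(time_months) == 0)
    stop("km_estimate: empty input", call. = FALSE)
  fit <- survfit(Surv(time_months, event) ~ 1, conf.type = "log-log")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv,
             lower = fit$lower, upper = fit$upper)
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a Kaplan-Meier curve (right-continuous).
#'
#' @param km data frame from [km_estimate()].
#' @param at time at which to read off survival.
#' @return list with `surv`, `lower`, `upper` at `at`; `surv` is 1 before
#'   the first observed time. Values are NA if `at` exceeds follow-up.
#' @export
km_at <- function(km, at) {
  if (at > max(km$time))  # beyond last observed time: undefined
    return(list(surv = NA_real_, lower = NA_real_, upper = NA_real_))
  idx <- which(km$time <= at)
  if (!length(idx)) return(list(surv = 1, lower = NA_real_, upper = NA_real_))
  i <- max(idx)
  list(surv = km$surv[i], lower = km$lower[i], upper = km$upper[i])
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank comparison of survival across groups.
#'
#' @param time_months,event outcome vectors.
#' @param group grouping factor with >= 2 non-empty levels.
#' @return list with `statistic` (chi-square), `df` and `p.value`.
#' @export
logrank_test <- function(time_months, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2)
    stop("logrank_test: need at least two non-empty groups", call. = FALSE)
  if (any(table(group) == 0))
    stop("logrank_test: empty group", call. = FALSE)
  sdf <- survdiff(Surv(time_months, event) ~ group)
  df <- length(sdf$n) - 1
  list(statistic = unname(sdf$chisq), df = df,
       p.value = pchisq(sdf$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Maximises the Cox partial likelihood (Efron tie handling) for a set of
#' covariates and reports, per term, the coefficient, standard error,
#' hazard ratio with 95% Wald confidence interval and Wald p-value.
#' Degenerate designs (a constant covariate) and non-converged or
#' separated fits raise diagnostic errors rather than returning silent
#' output.
#'
#' @param time_months,event outcome vectors.
#' @param covariates data frame of covariates; factors are expanded to
#'   treatment contrasts.
#' @param forced character vector of covariate names protected from
#'   removal by [stepwise_backward()] (stored, not used in fitting).
#' @return object of class `pathies_cox`: list with `table` (term, coef,
#'   se, hr, ci_low, ci_high, p), `loglik`, `n`, `n_event`, `fit` (the
#'   underlying [survival::coxph] object) and `forced`.
#' @export
cox_fit <- function(time_months, event, covariates, forced = character()) {
  stopifnot(is.data.frame(covariates), ncol(covariates) >= 1)
  if (nrow(covariates) != length(time_months))
    stop("cox_fit: covariates and outcomes misaligned", call. = FALSE)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("cox_fit: covariate '", nm, "' is constant", call. = FALSE)
  }
  dat <- cbind(data.frame(.time = time_months, .event = event), covariates)
  fml <- as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- coxph(fml, data = dat, ties = "efron")
  check_cox_health(fit)
  structure(list(table = cox_table(fit),
                 loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_event = fit$nevent, fit = fit,
                 forced = forced),
            class = "pathies_cox")
}

check_cox_health <- function(fit) {
  if (!is.null(fit$info) && isTRUE(fit$info$flag > 0))
    stop("cox_fit: fit did not converge", call. = FALSE)
  co <- fit$coefficients
  se <- sqrt(diag(fit$var))
  if (anyNA(co) || any(!is.finite(co)))
    stop("cox_fit: undetermined coefficient (collinear design)",
         call. = FALSE)
  if (any(abs(co) > 15) || any(se > 100))
    stop("cox_fit: monotone likelihood / complete separation suspected ",
         "(coefficient or SE diverged)", call. = FALSE)
  invisible(fit)
}

cox_table <- function(fit) {
  co <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- co / se
  data.frame(term = names(co), coef = unname(co), se = unname(se),
             hr = exp(unname(co)),
             ci_low = exp(unname(co - 1.96 * se)),
             ci_high = exp(unname(co + 1.96 * se)),
             p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pathies_cox <- function(x, digits = 2, ...) {
  cat(sprintf("Cox model: n = %d, events = %d\n", x$n, x$n_event))
  tab <- x$table
  out <- data.frame(term = tab$term,
                    HR = round(tab$hr, digits),
                    `95% CI` = sprintf("%.*f-%.*f", digits, tab$ci_low,
                                       digits, tab$ci_high),
                    P = signif(tab$p, 2), check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Backward stepwise Cox selection with forced terms
#'
#' Iteratively refits the Cox model, removing at each step the non-forced
#' block with the largest p-value exceeding `alpha`, until every remaining
#' non-forced block is significant at `alpha`. Forced blocks (typically
#' treatment) are never removed. Blocks group the columns of a categorical
#' covariate so its indicators enter and leave together; a single-column
#' block is judged by its Wald p, a multi-column block by the
#' likelihood-ratio p for dropping the whole block.
#'
#' @param time_months,event outcome vectors.
#' @param covariates data frame of candidate covariates (one column per
#'   block; factors form natural blocks).
#' @param forced names of covariates kept regardless of significance.
#' @param alpha retention threshold, default 0.10.
#' @return list with `fit` (final `pathies_cox`), `removed` (character, in
#'   removal order) and `retained`.
#' @export
stepwise_backward <- function(time_months, event, covariates,
                              forced = character(), alpha = 0.10) {
  stopifnot(alpha > 0, alpha <= 1)
  if (!all(forced %in% names(covariates)))
    stop("stepwise_backward: forced terms must be candidate covariates",
         call. = FALSE)
  current <- names(covariates)
  removed <- character()
  repeat {
    fit <- cox_fit(time_months, event, covariates[current], forced)
    candidates <- setdiff(current, forced)
    if (!length(candidates)) break
    pvals <- vapply(candidates, function(nm) {
      block_p(fit, time_months, event, covariates, current, nm)
    }, numeric(1))
    worst <- candidates[which.max(pvals)]
    if (pvals[which.max(pvals)] <= alpha) break
    removed <- c(removed, worst)
    current <- setdiff(current, worst)
    if (!length(current))
      stop("stepwise_backward: all terms removed; no model left",
           call. = FALSE)
  }
  list(fit = fit, removed = removed, retained = current)
}

block_p <- function(fit, time_months, event, covariates, current, nm) {
  v <- covariates[[nm]]
  k <- if (is.factor(v) || is.character(v))
    length(unique(v[!is.na(v)])) - 1 else 1L
  if (k == 1) {
    tab <- fit$table
    idx <- which(startsWith(tab$term, nm) | startsWith(tab$term,
                                                       paste0("`", nm)))
    return(min(tab$p[idx]))
  }
  reduced <- setdiff(current, nm)
  if (!length(reduced)) {
    null_ll <- fit$fit$loglik[1]
    lr <- 2 * (fit$loglik - null_ll)
  } else {
    rfit <- cox_fit(time_months, event, covariates[reduced])
    lr <- 2 * (fit$loglik - rfit$loglik)
  }
  pchisq(lr, df = k, lower.tail = FALSE)
}

#' Treatment-by-risk-group interaction test
#'
#' Compares the Cox model with main effects of risk group and treatment
#' against the model adding their interaction, by likelihood-ratio test
#' (default) or Wald test on the interaction coefficients.
#'
#' @param time_months,event outcome vectors.
#' @param risk_group factor of risk groups (e.g. Q1/Q2Q3/Q4).
#' @param treatment factor with two arms.
#' @param method `"lr"` (default) or `"wald"`.
#' @return list with `p.value`, `statistic`, `df`, and `fit` (the
#'   interaction-model `pathies_cox`).
#' @export
interaction_test <- function(time_months, event, risk_group, treatment,
                             method = c("lr", "wald")) {
  method <- match.arg(method)
  risk_group <- droplevels(as.factor(risk_group))
  treatment <- droplevels(as.factor(treatment))
  if (nlevels(treatment) < 2)
    stop("interaction_test: only one treatment arm present", call. = FALSE)
  if (nlevels(risk_group) < 2)
    stop("interaction_test: risk group does not vary", call. = FALSE)
  if (any(table(risk_group, treatment) == 0))
    stop("interaction_test: empty risk-group x treatment cell",
         call. = FALSE)
  dat <- data.frame(.time = time_months, .event = event,
                    g = risk_group, trt = treatment)
  main <- coxph(Surv(.time, .event) ~ g + trt, data = dat, ties = "efron")
  full <- coxph(Surv(.time, .event) ~ g * trt, data = dat, ties = "efron")
  check_cox_health(full)
  df <- (nlevels(risk_group) - 1) * (nlevels(treatment) - 1)
  if (method == "lr") {
    stat <- 2 * (full$loglik[2] - main$loglik[2])
    p <- pchisq(stat, df, lower.tail = FALSE)
  } else {
    idx <- grep(":", names(full$coefficients))
    b <- full$coefficients[idx]
    V <- full$var[idx, idx, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    p <- pchisq(stat, df, lower.tail = FALSE)
  }
  fitobj <- structure(list(table = cox_table(full),
                           loglik = full$loglik[2], n = full$n,
                           n_event = full$nevent, fit = full,
                           forced = character()),
                      class = "pathies_cox")
  list(p.value = p, statistic = unname(stat), df = df, fit = fitobj)
}
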