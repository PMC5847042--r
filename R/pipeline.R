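#' Analysis configuration
#'
#' Options for [run_pipeline()].
#'
#' @param score_variants which score variants to analyse; any of
#'   `"ihc4"`, `"ihc4c"`, `"pathies"`.
#' @param risk_groups stratify each variant into quartile risk groups.
#' @param horizon_months calibration/prediction horizon (default 120).
#' @param baseline `"internal"` for the self-calibrated Breslow baseline,
#'   or a [baseline_survival()] object / path to a 2-column CSV
#'   (`time_months`, `s0`) for an external baseline.
#' @param alpha backward-selection retention threshold (default 0.10).
#' @param interaction_method `"lr"` or `"wald"`.
#' @param seed seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @param out_dir optional directory; when set, [run_pipeline()] writes
#'   all report tables as CSV.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(score_variants = c("ihc4", "ihc4c", "pathies"),
                            risk_groups = TRUE,
                            horizon_months = 120,
                            baseline = "internal",
                            alpha = 0.10,
                            interaction_method = "lr",
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, horizon_months > 0)
  score_variants <- match.arg(score_variants,
                              c("ihc4", "ihc4c", "pathies"),
                              several.ok = TRUE)
  if (is.character(baseline) && baseline != "internal")
    baseline <- baseline_survival(read.csv(baseline))
  structure(list(score_variants = score_variants, risk_groups = risk_groups,
                 horizon_months = horizon_months, baseline = baseline,
                 alpha = alpha, interaction_method = interaction_method,
                 seed = seed, out_dir = out_dir),
            class = "analysis_config")
}

#' Run the full prognostic-validation pipeline
#'
#' Orchestrates: eligibility filtering -> score computation -> quartile
#' risk groups -> TTDR derivation -> Kaplan-Meier curves and log-rank
#' tests per risk group -> Cox hazard ratios by quartile group (one table
#' per score variant) -> univariable Cox models for each clinical factor
#' -> multivariable backward selection with treatment forced -> treatment
#' x risk-group interaction test -> decile calibration of predicted
#' 10-year distant-recurrence probabilities. IHC4-only analyses use every
#' eligible patient; analyses involving the clinical score use the
#' complete-case subset.
#'
#' @param cohort data frame (schema per the shipped data dictionary) or
#'   path to a cohort CSV.
#' @param config an [analysis_config()].
#' @return object of class `pathies_report`: list with elements
#'   `counts` (row-count ledger), `exclusions`, `scored` (scored cohort),
#'   `cutpoints`, `characteristics`, `hr_by_quartile`, `km_curves`,
#'   `logrank`, `univariable`, `multivariable`, `interaction`,
#'   `calibration`, `risk_summary`, `nodal_risk_curves`, `log`.
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  check_cohort_schema(cohort)
  n_input <- nrow(cohort)

  flt <- eligibility_filter(cohort)
  dat <- score_cohort(flt$kept, risk_groups = config$risk_groups)
  out <- derive_ttdr(dat$time_months, dat$event_type)
  dat$ttdr_time <- out$time_months
  dat$ttdr_event <- out$event
  cc <- dat$complete_clinical

  counts <- c(input = n_input, excluded = nrow(flt$exclusions),
              eligible = nrow(dat), complete_clinical = sum(cc),
              ttdr_events = sum(dat$ttdr_event),
              ttdr_events_complete = sum(dat$ttdr_event[cc]))

  analysis_rows <- function(v) if (v == "ihc4") rep(TRUE, nrow(dat)) else cc

  hr_by_quartile <- list(); km_curves <- list(); logrank <- list()
  if (config$risk_groups) {
    for (v in config$score_variants) {
      sel <- analysis_rows(v) & !is.na(dat[[paste0(v, "_group")]])
      g <- droplevels(dat[[paste0(v, "_group")]][sel])
      fit <- cox_fit(dat$ttdr_time[sel], dat$ttdr_event[sel],
                     data.frame(group = g))
      tab <- fit$table
      tab$term <- sub("^`?group`?", "", tab$term)
      tab <- cbind(variant = v, n = fit$n, tab)
      hr_by_quartile[[v]] <- tab
      logrank[[v]] <- logrank_test(dat$ttdr_time[sel],
                                   dat$ttdr_event[sel], g)
      km_curves[[v]] <- do.call(rbind, lapply(levels(g), function(lev) {
        km <- km_estimate(dat$ttdr_time[sel][g == lev],
                          dat$ttdr_event[sel][g == lev])
        cbind(variant = v, group = lev, km)
      }))
    }
  }

  uni <- univariable_table(dat)
  multi <- multivariable_selection(dat, alpha = config$alpha)

  interaction <- NULL
  if (config$risk_groups && nlevels(droplevels(factor(dat$treatment))) == 2) {
    v <- config$score_variants[1]
    sel <- analysis_rows(v) & !is.na(dat[[paste0(v, "_group")]])
    interaction <- tryCatch(
      interaction_test(dat$ttdr_time[sel], dat$ttdr_event[sel],
                       dat[[paste0(v, "_group")]][sel],
                       dat$treatment[sel],
                       method = config$interaction_method),
      error = function(e) list(p.value = NA_real_, error = conditionMessage(e)))
  }

  calib <- NULL; risk_summary <- NULL; nodal_curves <- NULL
  if ("ihc4c" %in% config$score_variants ||
      "pathies" %in% config$score_variants) {
    v <- if ("ihc4c" %in% config$score_variants) "ihc4c" else "pathies"
    sel <- cc & !is.na(dat[[v]])
    bl <- if (identical(config$baseline, "internal"))
      breslow_baseline(dat$ttdr_time[sel], dat$ttdr_event[sel],
                       dat[[v]][sel] / 100)
    else config$baseline
    calib <- calibration_deciles(dat[[v]][sel], dat$ttdr_time[sel],
                                 dat$ttdr_event[sel],
                                 config$horizon_months, bl)
    preds <- predict_dr_probability(dat[[v]][sel], config$horizon_months,
                                    bl)
    risk_summary <- predicted_risk_summary(preds)
    if ("pathies" %in% config$score_variants)
      nodal_curves <- nodal_risk_curves(dat[cc & !is.na(dat$pathies), ],
                                        horizon = 108)
  }

  report <- structure(list(
    counts = counts, exclusions = flt$exclusions, scored = dat,
    cutpoints = attr(dat, "cutpoints"),
    characteristics = characteristics_table(dat),
    hr_by_quartile = if (length(hr_by_quartile))
      do.call(rbind, c(hr_by_quartile, make.row.names = FALSE)) else NULL,
    km_curves = if (length(km_curves))
      do.call(rbind, c(km_curves, make.row.names = FALSE)) else NULL,
    logrank = logrank, univariable = uni, multivariable = multi,
    interaction = interaction, calibration = calib,
    risk_summary = risk_summary, nodal_risk_curves = nodal_curves,
    log = run_log(counts, config)), class = "pathies_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

check_cohort_schema <- function(cohort) {
  need <- c("er_hscore", "pgr_percent", "her2_ihc", "ki67_percent",
            "age_years", "nodal_category", "tumour_size_cm", "grade",
            "treatment", "time_months", "event_type")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  invisible(cohort)
}

characteristics_table <- function(dat) {
  cat_freq <- function(x, label) {
    tab <- table(factor(x), useNA = "ifany")
    data.frame(variable = label,
               category = ifelse(is.na(names(tab)), "unavailable",
                                 names(tab)),
               n = as.integer(tab),
               percent = round(100 * as.integer(tab) / length(x), 1))
  }
  rbind(cat_freq(dat$treatment, "treatment"),
        cat_freq(cut(dat$age_years, c(0, 60, 70, Inf),
                     labels = c("<60", "60-69", "70+"), right = FALSE),
                 "age_years"),
        cat_freq(dat$grade, "grade"),
        cat_freq(dat$nodal_category, "nodes"),
        cat_freq(size_category(dat$tumour_size_cm), "tumour_size"))
}

univariable_table <- function(dat) {
  specs <- list(
    age_ge_65 = function(d) data.frame(age_ge_65 = d$age_years >= 65),
    nodes = function(d) data.frame(nodes = factor(d$nodal_category,
                                                  c("N0", "N1to3", "Ngt3"))),
    tumour_size = function(d) data.frame(tumour_size =
                                           size_category(d$tumour_size_cm)),
    grade = function(d) data.frame(grade = factor(d$grade,
                                                  c("G1", "G2", "G3"))),
    ihc4 = function(d) data.frame(ihc4 = d$ihc4),
    treatment = function(d) data.frame(treatment =
                                         factor(d$treatment,
                                                c("tamoxifen_only",
                                                  "switch_to_exemestane"))))
  rows <- lapply(names(specs), function(nm) {
    cov <- specs[[nm]](dat)
    keep <- complete.cases(cov)
    cov <- droplevels(cov[keep, , drop = FALSE])
    fit <- tryCatch(cox_fit(dat$ttdr_time[keep], dat$ttdr_event[keep], cov),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cbind(covariate = nm, n = fit$n, fit$table)
  })
  do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                   make.row.names = FALSE))
}

multivariable_selection <- function(dat, alpha = 0.10) {
  cc <- dat$complete_clinical
  cov <- data.frame(
    age_ge_65 = dat$age_years[cc] >= 65,
    nodes = factor(dat$nodal_category[cc], c("N0", "N1to3", "Ngt3")),
    tumour_size = size_category(dat$tumour_size_cm[cc]),
    grade = factor(dat$grade[cc], c("G1", "G2", "G3")),
    ihc4 = dat$ihc4[cc],
    treatment = factor(dat$treatment[cc],
                       c("tamoxifen_only", "switch_to_exemestane")))
  cov <- droplevels(cov)
  stepwise_backward(dat$ttdr_time[cc], dat$ttdr_event[cc], cov,
                    forced = "treatment", alpha = alpha)
}

nodal_risk_curves <- function(dat, horizon = 108) {
  bl <- breslow_baseline(dat$ttdr_time, dat$ttdr_event, dat$pathies / 100)
  if (horizon > max(bl$table$time_months)) horizon <- max(bl$table$time_months)
  do.call(rbind, lapply(split(dat, dat$nodal_category), function(d) {
    if (!nrow(d)) return(NULL)
    s <- seq(min(d$pathies), max(d$pathies), length.out = 50)
    data.frame(nodal_category = d$nodal_category[1], score = s,
               predicted = predict_dr_probability(s, horizon, bl))
  }))
}

run_log <- function(counts, config) {
  c(sprintf("pathies %s; R %s; survival %s",
            as.character(utils::packageVersion("pathies")),
            paste(R.version$major, R.version$minor, sep = "."),
            as.character(utils::packageVersion("survival"))),
    sprintf("seed: %d", config$seed),
    sprintf("alpha: %g; horizon: %g months", config$alpha,
            config$horizon_months),
    sprintf("rows: input %d = eligible %d + excluded %d",
            counts[["input"]], counts[["eligible"]], counts[["excluded"]]),
    sprintf("complete clinical cases: %d", counts[["complete_clinical"]]),
    sprintf("TTDR events: %d (complete cases: %d)",
            counts[["ttdr_events"]], counts[["ttdr_events_complete"]]))
}

#' Write a report bundle to CSV
#'
#' Serialises every table of a [run_pipeline()] report to a directory,
#' mirroring the published table layouts (HR-by-quartile, univariable and
#' multivariable Cox tables, calibration plot data, KM plot data).
#'
#' @param report a `pathies_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pathies_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x))
    write.csv(x, file.path(dir, f), row.names = FALSE, na = "")
  wr(report$scored, "scored_cohort.csv")
  wr(report$exclusions, "exclusion_log.csv")
  wr(report$characteristics, "characteristics.csv")
  wr(report$hr_by_quartile, "hr_by_quartile.csv")
  wr(report$km_curves, "km_curves.csv")
  wr(report$univariable, "cox_univariable.csv")
  if (!is.null(report$multivariable))
    wr(cbind(report$multivariable$fit$table,
             n = report$multivariable$fit$n), "cox_multivariable.csv")
  wr(as.data.frame(report$calibration), "calibration.csv")
  wr(report$nodal_risk_curves, "nodal_risk_curves.csv")
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pathies_report <- function(x, ...) {
  cat("PathIES prognostic analysis report\n")
  cat(paste0("  ", x$log), sep = "\n")
  if (!is.null(x$hr_by_quartile)) {
    cat("\nHazard ratios by quartile risk group (vs Q1):\n")
    tab <- x$hr_by_quartile
    print(data.frame(variant = tab$variant, term = tab$term, n = tab$n,
                     HR = round(tab$hr, 2),
                     `95% CI` = sprintf("%.2f-%.2f", tab$ci_low,
                                        tab$ci_high),
                     P = signif(tab$p, 2), check.names = FALSE),
          row.names = FALSE)
  }
  if (!is.null(x$interaction))
    cat(sprintf("\nTreatment x risk-group interaction: P = %.2g\n",
                x$interaction$p.value))
  invisible(x)
}

#' Generate and write a synthetic fixture cohort
#'
#' Thin wrapper over [generate_cohort()] + [write_cohort()] that also
#' prints a planted-truth summary.
#'
#' @param config a [generator_config()] or path to a YAML config.
#' @param out_dir output directory.
#' @return invisibly, the `synthetic_cohort`.
#' @export
make_fixture <- function(config = generator_config(), out_dir) {
  if (is.character(config)) config <- read_generator_config(config)
  x <- generate_cohort(config)
  paths <- write_cohort(x, out_dir)
  ttdr <- derive_ttdr(x$cohort$time_months, x$cohort$event_type)
  message(sprintf(
    "wrote %s: n = %d, mode = %s, score = %s, TTDR events = %d",
    paths[["cohort"]], nrow(x$cohort), config$mode, config$score,
    sum(ttdr$event)))
  invisible(x)
}
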