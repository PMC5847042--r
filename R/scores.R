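#' IHC4 prognostic score
#'
#' Combines the four immunohistochemical markers (ER H-score, PgR percent
#' positivity, HER2 IHC category, Ki67 percent positivity) into the IHC4
#' score:
#' \deqn{IHC4 = 94.7 \times (-0.100\, ER_{10} - 0.079\, PgR_{10} +
#'   0.586\, HER2 + 0.240 \ln(1 + 4\, Ki67))}
#' where \eqn{ER_{10}} is the H-score divided by 30, \eqn{PgR_{10}} the
#' percent positivity divided by 10, HER2 the indicator of 3+ staining
#' (0/1+/2+ all count as negative, with no ISH reflex), and Ki67 enters on
#' the percent scale (0-100).
#'
#' @param er_hscore integer ER H-score, 0-300.
#' @param pgr_percent PgR percent positive tumour nuclei, 0-100.
#' @param her2_ihc HER2 IHC category: one of `"0"`, `"1+"`, `"2+"`, `"3+"`.
#' @param ki67_percent Ki67 percent positive, 0-100.
#' @param ki67_scale `"percent"` (default) or `"fraction"`; with
#'   `"fraction"` Ki67 is interpreted on 0-1 and rescaled internally. The
#'   percent convention reproduces published cohort score distributions.
#' @return numeric vector of IHC4 scores (dimensionless, log-hazard x 94.7
#'   scale).
#' @examples
#' ihc4_score(180, 50, "2+", 13)
#' @export
ihc4_score <- function(er_hscore, pgr_percent, her2_ihc, ki67_percent,
                       ki67_scale = c("percent", "fraction")) {
  ki67_scale <- match.arg(ki67_scale)
  check_range(er_hscore, 0, 300, "er_hscore")
  check_range(pgr_percent, 0, 100, "pgr_percent")
  her2 <- her2_positive(her2_ihc)
  if (ki67_scale == "fraction") {
    check_range(ki67_percent, 0, 1, "ki67_percent")
    ki67_percent <- 100 * ki67_percent
  } else {
    check_range(ki67_percent, 0, 100, "ki67_percent")
  }
  94.7 * (-0.100 * er_hscore / 30 -
            0.079 * pgr_percent / 10 +
            0.586 * her2 +
            0.240 * log(1 + 4 * ki67_percent))
}

#' Clinical prognostic score
#'
#' Clinical component of the IHC4+C model, built from nodal status, tumour
#' size, grade and age (treatment term omitted):
#' \deqn{C = 100 \times (0.417 N_{1-3} + 1.566 N_{>3} + 0.93 (0.497 T_{1-2} +
#'  0.882 T_{2-3} + 1.838 T_{>3} + 0.559 G_2 + 0.970 G_3 +
#'  0.130\, [age \ge 65]))}
#' Size categories: T0 < 1 cm, T1-2 = 1-2 cm, T2-3 = 2-3 cm, T>3 > 3 cm.
#' Records with grade `not_assessable`/`unknown`/`NA` or missing nodes/size
#' cannot be scored and raise an error; exclude them upstream (see
#' [eligibility_filter()]).
#'
#' @param age_years age at randomisation in years; the indicator is 1 for
#'   age >= 65.
#' @param nodal_category one of `"N0"`, `"N1to3"`, `"Ngt3"`.
#' @param tumour_size_cm pathological tumour size in cm (> 0).
#' @param grade one of `"G1"`, `"G2"`, `"G3"`.
#' @return numeric vector of clinical scores.
#' @examples
#' clinical_score(70, "Ngt3", 4.0, "G3")
#' @export
clinical_score <- function(age_years, nodal_category, tumour_size_cm, grade) {
  n <- check_recycle(age_years = age_years, nodal_category = nodal_category,
                     tumour_size_cm = tumour_size_cm, grade = grade)
  if (anyNA(grade) || !all(grade %in% c("G1", "G2", "G3")))
    stop("clinical_score: grade must be G1/G2/G3; missing or not-assessable ",
         "grade records must be excluded upstream", call. = FALSE)
  if (anyNA(nodal_category) || anyNA(tumour_size_cm) || anyNA(age_years))
    stop("clinical_score: missing age/nodes/size; exclude record upstream",
         call. = FALSE)
  nodes <- check_levels(nodal_category, c("N0", "N1to3", "Ngt3"),
                        "nodal_category")
  if (any(tumour_size_cm <= 0))
    stop("clinical_score: tumour_size_cm must be > 0", call. = FALSE)
  if (any(age_years <= 0))
    stop("clinical_score: age_years must be > 0", call. = FALSE)
  size <- size_category(tumour_size_cm)
  100 * (0.417 * (nodes == "N1to3") +
           1.566 * (nodes == "Ngt3") +
           0.93 * (0.497 * (size == "T1_2") +
                     0.882 * (size == "T2_3") +
                     1.838 * (size == "Tgt3") +
                     0.559 * (grade == "G2") +
                     0.970 * (grade == "G3") +
                     0.130 * (age_years >= 65)))
}

#' IHC4 + Clinical PathIES score
#'
#' The refitted combined score for cohorts that switched from tamoxifen to
#' exemestane, re-estimated by Cox regression with the IHC4 score as a
#' continuous covariate and a treatment adjustment:
#' \deqn{100 \times (-0.13\, exe + 0.46 N_{1-3} + 1.45 N_{>3} + 1.37 T_{1-2}
#'   + 1.65 T_{2-3} + 2.21 T_{>3} + 0.0048\, IHC4)}
#' Grade and age do not appear: they were removed by backward selection.
#'
#' @param ihc4 IHC4 score from [ihc4_score()].
#' @param nodal_category,tumour_size_cm as in [clinical_score()].
#' @param treatment `"tamoxifen_only"` or `"switch_to_exemestane"`.
#' @return numeric vector of PathIES scores (x100 presentation scale; the
#'   Cox linear predictor is score/100).
#' @examples
#' pathies_score(100, "Ngt3", 4.0, "switch_to_exemestane")
#' @export
pathies_score <- function(ihc4, nodal_category, tumour_size_cm, treatment) {
  check_recycle(ihc4 = ihc4, nodal_category = nodal_category,
                tumour_size_cm = tumour_size_cm, treatment = treatment)
  if (anyNA(ihc4) || any(!is.finite(ihc4)))
    stop("pathies_score: ihc4 must be finite", call. = FALSE)
  if (anyNA(nodal_category) || anyNA(tumour_size_cm))
    stop("pathies_score: missing nodes/size; exclude record upstream",
         call. = FALSE)
  nodes <- check_levels(nodal_category, c("N0", "N1to3", "Ngt3"),
                        "nodal_category")
  trt <- check_levels(treatment, c("tamoxifen_only", "switch_to_exemestane"),
                      "treatment")
  size <- size_category(tumour_size_cm)
  100 * (-0.13 * (trt == "switch_to_exemestane") +
           0.46 * (nodes == "N1to3") +
           1.45 * (nodes == "Ngt3") +
           1.37 * (size == "T1_2") +
           1.65 * (size == "T2_3") +
           2.21 * (size == "Tgt3") +
           0.0048 * ihc4)
}

#' Tumour size category
#'
#' Maps size in cm to the categories used by the clinical and PathIES
#' scores: `T0` (< 1 cm), `T1_2` (1-2 cm inclusive), `T2_3` (>2-3 cm),
#' `Tgt3` (> 3 cm). The 2 cm boundary belongs to T1_2, matching the
#' conventional <=2 / >2 split.
#'
#' @param tumour_size_cm numeric vector of sizes in cm.
#' @return factor with levels T0, T1_2, T2_3, Tgt3 (NA preserved).
#' @export
size_category <- function(tumour_size_cm) {
  out <- rep(NA_character_, length(tumour_size_cm))
  x <- tumour_size_cm
  out[!is.na(x) & x < 1] <- "T0"
  out[!is.na(x) & x >= 1 & x <= 2] <- "T1_2"
  out[!is.na(x) & x > 2 & x <= 3] <- "T2_3"
  out[!is.na(x) & x > 3] <- "Tgt3"
  factor(out, levels = c("T0", "T1_2", "T2_3", "Tgt3"))
}

#' Quartile risk groups
#'
#' Splits scores at the cohort's empirical 25th and 75th percentiles
#' (type-7 quantiles): Q1 below the 25th percentile, Q4 at or above the
#' 75th, Q2Q3 in between. Scores exactly at a cutpoint go to the upper
#' group.
#'
#' @param scores numeric vector, at least 4 non-missing values.
#' @return list with `group` (factor Q1/Q2Q3/Q4, NA for missing scores) and
#'   `cutpoints` (named numeric, the 25th/75th percentiles).
#' @examples
#' assign_risk_groups(1:100)$cutpoints
#' @export
assign_risk_groups <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 4)
    stop("assign_risk_groups: need at least 4 non-missing scores",
         call. = FALSE)
  q <- quantile(scores[ok], c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] >= q[2])
    stop("assign_risk_groups: degenerate quartiles (25th and 75th ",
         "percentiles coincide)", call. = FALSE)
  grp <- rep(NA_character_, length(scores))
  grp[ok & scores < q[1]] <- "Q1"
  grp[ok & scores >= q[1] & scores < q[2]] <- "Q2Q3"
  grp[ok & scores >= q[2]] <- "Q4"
  grp <- factor(grp, levels = c("Q1", "Q2Q3", "Q4"))
  tab <- table(grp)
  if (tab["Q1"] == 0)
    stop("assign_risk_groups: degenerate lower quartile (no score below ",
         "the 25th percentile)", call. = FALSE)
  list(group = grp, cutpoints = c(q25 = q[1], q75 = q[2]))
}

#' Eligibility and completeness filter
#'
#' Applies the analysis-set rules: a patient is ER-positive if any of
#' (a) ER percent positive >= 1, (b) ER H-score >= 1, (c) Allred score >= 3
#' holds on a non-missing measure; rows with no ER measure at all are
#' unassessable. Kept rows additionally require all four IHC4 markers
#' (ER H-score, PgR, HER2, Ki67). Kept rows are flagged
#' `complete_clinical` when age, nodal category, tumour size and an
#' assessable grade are all present, defining the complete-case set used by
#' clinical-score analyses.
#'
#' @param cohort data frame with marker columns (`er_hscore`, `pgr_percent`,
#'   `her2_ihc`, `ki67_percent`, optionally `er_percent`, `er_allred`) and
#'   clinical columns (`age_years`, `nodal_category`, `tumour_size_cm`,
#'   `grade`).
#' @return list with `kept` (eligible rows plus a `complete_clinical`
#'   column) and `exclusions` (data frame `row`, `reason`; one reason per
#'   dropped row).
#' @export
eligibility_filter <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("er_hscore", "pgr_percent", "her2_ihc", "ki67_percent")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("eligibility_filter: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n <- nrow(cohort)
  er_pct <- if ("er_percent" %in% names(cohort)) cohort$er_percent else
    rep(NA_real_, n)
  er_all <- if ("er_allred" %in% names(cohort)) cohort$er_allred else
    rep(NA_real_, n)
  er_h <- cohort$er_hscore

  has_er <- !(is.na(er_pct) & is.na(er_all) & is.na(er_h))
  er_pos <- (!is.na(er_pct) & er_pct >= 1) |
    (!is.na(er_h) & er_h >= 1) |
    (!is.na(er_all) & er_all >= 3)

  reason <- rep(NA_character_, n)
  reason[!has_er] <- "ER unassessable"
  reason[has_er & !er_pos] <- "ER negative"
  for (m in need) {
    miss <- is.na(cohort[[m]]) & is.na(reason)
    reason[miss] <- paste0("missing marker: ", m)
  }

  kept <- cohort[is.na(reason), , drop = FALSE]
  grade_ok <- !is.na(kept$grade) & kept$grade %in% c("G1", "G2", "G3")
  kept$complete_clinical <- grade_ok &
    !is.na(kept$age_years) &
    !is.na(kept$nodal_category) &
    !is.na(kept$tumour_size_cm)
  exclusions <- data.frame(row = which(!is.na(reason)),
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
  list(kept = kept, exclusions = exclusions)
}

#' Score a cohort table
#'
#' Appends the four scores and (optionally) quartile risk groups to an
#' eligible cohort table. IHC4 is computed for every row; the clinical,
#' IHC4+C and PathIES scores only for rows where their inputs are complete
#' (others are NA). Risk groups for each variant are derived from the
#' cohort's own quartiles over non-missing scores.
#'
#' @param cohort data frame as accepted by [eligibility_filter()] (already
#'   filtered; must contain `treatment` for the PathIES score).
#' @param risk_groups logical; append `<variant>_group` columns.
#' @return the cohort with columns `ihc4`, `clinical`, `ihc4c`, `pathies`
#'   appended, plus group columns and a `cutpoints` attribute when
#'   `risk_groups = TRUE`.
#' @export
score_cohort <- function(cohort, risk_groups = TRUE) {
  stopifnot(is.data.frame(cohort))
  cohort$ihc4 <- ihc4_score(cohort$er_hscore, cohort$pgr_percent,
                            cohort$her2_ihc, cohort$ki67_percent)
  cc <- !is.na(cohort$age_years) & !is.na(cohort$nodal_category) &
    !is.na(cohort$tumour_size_cm) &
    !is.na(cohort$grade) & cohort$grade %in% c("G1", "G2", "G3")
  cohort$clinical <- NA_real_
  cohort$clinical[cc] <- clinical_score(cohort$age_years[cc],
                                        as.character(cohort$nodal_category[cc]),
                                        cohort$tumour_size_cm[cc],
                                        as.character(cohort$grade[cc]))
  cohort$ihc4c <- cohort$ihc4 + cohort$clinical
  cohort$pathies <- NA_real_
  cp <- !is.na(cohort$nodal_category) & !is.na(cohort$tumour_size_cm) &
    !is.na(cohort$treatment)
  cohort$pathies[cp] <- pathies_score(cohort$ihc4[cp],
                                      as.character(cohort$nodal_category[cp]),
                                      cohort$tumour_size_cm[cp],
                                      as.character(cohort$treatment[cp]))
  if (risk_groups) {
    cuts <- list()
    for (v in c("ihc4", "ihc4c", "pathies")) {
      rg <- assign_risk_groups(cohort[[v]])
      cohort[[paste0(v, "_group")]] <- rg$group
      cuts[[v]] <- rg$cutpoints
    }
    attr(cohort, "cutpoints") <- cuts
  }
  cohort
}

her2_positive <- function(her2_ihc) {
  check_levels(as.character(her2_ihc), c("0", "1+", "2+", "3+"),
               "her2_ihc") == "3+"
}

check_range <- function(x, lo, hi, name) {
  if (anyNA(x) || !is.numeric(x))
    stop(sprintf("%s: missing or non-numeric value", name), call. = FALSE)
  if (any(x < lo | x > hi))
    stop(sprintf("%s: value out of range [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

check_levels <- function(x, levels, name) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    stop(sprintf("%s: invalid value '%s' (expected one of %s)", name,
                 x[bad][1], paste(levels, collapse = ", ")), call. = FALSE)
  x
}

check_recycle <- function(...) {
  lens <- lengths(list(...))
  n <- max(lens)
  if (!all(lens %in% c(1L, n)))
    stop("arguments have incompatible lengths", call. = FALSE)
  n
}
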