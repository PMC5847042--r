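test_that("IHC4 score reproduces hand-computed reference values", {
  # every term vanishes
  expect_equal(ihc4_score(0, 0, "1+", 0), 0)
  # 94.7 * (-1.0 - 0.79)
  expect_equal(ihc4_score(300, 100, "0", 0), -169.513)
  # 94.7 * 0.586
  expect_equal(ihc4_score(0, 0, "3+", 0), 55.4942)
  # 2+ counts as HER2-negative
  expect_equal(ihc4_score(180, 50, "2+", 13),
               94.7 * (-0.6 - 0.395 + 0.240 * log(53)),
               tolerance = 1e-12)
  expect_equal(round(ihc4_score(180, 50, "2+", 13), 2), -3.99)
})

test_that("IHC4 rejects out-of-range markers, naming the field", {
  expect_error(ihc4_score(301, 0, "0", 0), "er_hscore")
  expect_error(ihc4_score(0, 120, "0", 0), "pgr_percent")
  expect_error(ihc4_score(0, 0, "4+", 0), "her2_ihc")
  expect_error(ihc4_score(0, 0, "0", -1), "ki67_percent")
})

test_that("Ki67 may be supplied as a fraction via ki67_scale", {
  expect_equal(ihc4_score(100, 50, "0", 0.13, ki67_scale = "fraction"),
               ihc4_score(100, 50, "0", 13))
  expect_error(ihc4_score(0, 0, "0", 13, ki67_scale = "fraction"),
               "ki67_percent")
})

test_that("clinical score reproduces hand-computed reference values", {
  # reference category everywhere
  expect_equal(clinical_score(50, "N0", 0.8, "G1"), 0)
  # 100 * (1.566 + 0.93 * (1.838 + 0.970 + 0.130))
  expect_equal(clinical_score(70, "Ngt3", 4.0, "G3"), 429.834)
  # 100 * (0.417 + 0.93 * (0.497 + 0.559))
  expect_equal(clinical_score(50, "N1to3", 1.5, "G2"), 139.908)
  # age boundary: 65 scores the indicator
  expect_equal(clinical_score(65, "N0", 0.5, "G1") -
                 clinical_score(64.9, "N0", 0.5, "G1"), 100 * 0.93 * 0.130)
})

test_that("clinical score refuses missing or unassessable inputs", {
  expect_error(clinical_score(50, "N0", 1.0, "unknown"), "grade")
  expect_error(clinical_score(50, "N0", 1.0, NA), "grade")
  expect_error(clinical_score(50, NA, 1.0, "G1"), "missing")
  expect_error(clinical_score(50, "N0", -1, "G1"), "tumour_size_cm")
})

test_that("PathIES score reproduces hand-computed reference values", {
  expect_equal(pathies_score(0, "N0", 0.8, "tamoxifen_only"), 0)
  expect_equal(pathies_score(0, "N0", 0.8, "switch_to_exemestane"), -13)
  # 100 * (-0.13 + 1.45 + 2.21 + 0.48)
  expect_equal(pathies_score(100, "Ngt3", 4.0, "switch_to_exemestane"), 401)
  expect_error(pathies_score(Inf, "N0", 1, "tamoxifen_only"), "finite")
  expect_error(pathies_score(0, NA, 1, "tamoxifen_only"), "missing")
})

test_that("all three scores agree with brute-force evaluation on random inputs", {
  set.seed(101)
  for (i in 1:1000) {
    p <- random_panel()
    q <- random_profile()
    ih <- ihc4_score(p$er, p$pgr, p$her2, p$ki67)
    expect_equal(ih, naive_ihc4(p$er, p$pgr, p$her2, p$ki67),
                 tolerance = 1e-12)
    expect_equal(clinical_score(q$age, q$nodes, q$size, q$grade),
                 naive_clinical(q$age, q$nodes, q$size, q$grade),
                 tolerance = 1e-12)
    expect_equal(pathies_score(ih, q$nodes, q$size, q$treatment),
                 naive_pathies(ih, q$nodes, q$size, q$treatment),
                 tolerance = 1e-12)
  }
})

test_that("IHC4 monotonicity and the HER2 jump", {
  base <- ihc4_score(150, 50, "0", 20)
  expect_lt(ihc4_score(200, 50, "0", 20), base)
  expect_lt(ihc4_score(150, 80, "0", 20), base)
  expect_gt(ihc4_score(150, 50, "0", 40), base)
  expect_equal(ihc4_score(150, 50, "3+", 20) - base, 94.7 * 0.586,
               tolerance = 1e-12)
})

test_that("size categories split at 1, 2 (inclusive) and 3 cm", {
  expect_equal(as.character(size_category(c(0.9, 1, 2, 2.1, 3, 3.5))),
               c("T0", "T1_2", "T1_2", "T2_3", "T2_3", "Tgt3"))
  expect_true(is.na(size_category(NA)))
})

test_that("risk groups: labels, cutpoints, boundaries, degeneracy", {
  rg <- assign_risk_groups(1:100)
  expect_equal(as.character(rg$group[c(10, 50, 90)]), c("Q1", "Q2Q3", "Q4"))
  # boundary scores at a cutpoint go to the upper group
  expect_equal(as.character(rg$group)[1:100 >= rg$cutpoints["q75"]],
               rep("Q4", sum(1:100 >= rg$cutpoints["q75"])))
  expect_false(anyNA(rg$group))
  # re-application of cutpoints reproduces labels
  relabel <- ifelse(1:100 < rg$cutpoints["q25"], "Q1",
                    ifelse(1:100 < rg$cutpoints["q75"], "Q2Q3", "Q4"))
  expect_equal(as.character(rg$group), relabel)
  expect_error(assign_risk_groups(c(1, 2, 3)), "at least 4")
  expect_error(assign_risk_groups(rep(5, 10)), "degenerate")
  expect_error(assign_risk_groups(c(0, 0, 0, 10)), "degenerate lower")
})

test_that("risk-group proportions approach 25/50/25 on continuous scores", {
  set.seed(7)
  rg <- assign_risk_groups(rnorm(1000))
  pr <- as.numeric(table(rg$group)) / 1000
  expect_equal(pr, c(0.25, 0.50, 0.25), tolerance = 0.02)
})

test_that("combined IHC4+C equals the sum of its components", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_panel(); q <- random_profile()
    ih <- ihc4_score(p$er, p$pgr, p$her2, p$ki67)
    cl <- clinical_score(q$age, q$nodes, q$size, q$grade)
    df <- data.frame(er_hscore = p$er, pgr_percent = p$pgr,
                     her2_ihc = p$her2, ki67_percent = p$ki67,
                     age_years = q$age, nodal_category = q$nodes,
                     tumour_size_cm = q$size, grade = q$grade,
                     treatment = q$treatment)
    sc <- score_cohort(df, risk_groups = FALSE)
    expect_equal(sc$ihc4c, ih + cl, tolerance = 1e-9)
  }
})

test_that("eligibility filter applies the three ER criteria and marker completeness", {
  cohort <- data.frame(
    er_hscore = c(0, NA, 250, 120, 0, 200),
    er_percent = c(0.5, NA, 90, NA, NA, 80),
    er_allred = c(NA, NA, 8, NA, 3, NA),
    pgr_percent = c(50, 50, 60, 70, 80, NA),
    her2_ihc = c("0", "1+", "2+", "3+", "0", "1+"),
    ki67_percent = c(10, 10, 15, 20, 12, 14),
    age_years = c(60, 61, 62, 63, 64, 65),
    nodal_category = c("N0", "N0", "N1to3", NA, "N0", "N0"),
    tumour_size_cm = c(1, 1, 2, 2, 1.5, 1),
    grade = c("G1", "G2", "G3", "G1", NA, "G2"),
    treatment = "tamoxifen_only",
    stringsAsFactors = FALSE)
  fl <- eligibility_filter(cohort)
  # row 1 fails all three ER criteria; row 2 has no ER measure at all;
  # row 6 lacks PgR
  expect_equal(fl$exclusions$row, c(1L, 2L, 6L))
  expect_equal(fl$exclusions$reason,
               c("ER negative", "ER unassessable",
                 "missing marker: pgr_percent"))
  expect_equal(nrow(fl$kept), 3)
  # Allred 3 with all markers kept, but incomplete for the clinical set
  expect_equal(fl$kept$complete_clinical, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(fl$kept) + nrow(fl$exclusions), nrow(cohort))
})

test_that("complete-case count on a generated fixture matches the planted missingness", {
  cfg <- generator_config(seed = 12)
  x <- generate_cohort(cfg)
  fl <- eligibility_filter(x$cohort)
  expected <- 430 * (1 - cfg$miss_grade) * (1 - cfg$miss_nodes) *
    (1 - cfg$miss_size)
  expect_lt(abs(sum(fl$kept$complete_clinical) - expected), 15)
})
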