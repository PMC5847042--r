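test_that("TTDR endpoint: distant recurrence and BC/unknown deaths are events, the rest censor", {
  expect_equal(derive_ttdr(30, "distant_recurrence"),
               data.frame(time_months = 30, event = 1L))
  expect_equal(derive_ttdr(40, "death_other_cause")$event, 0L)
  expect_equal(derive_ttdr(120, "none")$event, 0L)
  ev <- derive_ttdr(rep(10, 7), c("none", "distant_recurrence",
                                  "local_or_regional_recurrence",
                                  "contralateral", "death_breast_cancer",
                                  "death_unknown_cause",
                                  "death_other_cause"))$event
  expect_equal(ev, c(0L, 1L, 0L, 0L, 1L, 1L, 0L))
  expect_error(derive_ttdr(-1, "none"), "time_months")
  expect_error(derive_ttdr(10, "exploded"), "event_type")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 2], 1 / 3, tolerance = 1e-12)
  expect_equal(km_estimate(c(5, 8), c(0, 0))$surv, c(1, 1))
  expect_equal(km_estimate(5, 1)$surv, 0)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("without censoring the KM estimator is the empirical survival function", {
  set.seed(21)
  t <- rexp(200, 0.05)
  km <- km_estimate(t, rep(1, 200))
  for (at in c(5, 10, 30, 60))
    expect_equal(km_at(km, at)$surv, mean(t > at), tolerance = 1e-12)
})

test_that("km_at reads the step function and refuses extrapolation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km_at(km, 0.5)$surv, 1)
  expect_equal(km_at(km, 2.7)$surv, 1 / 3, tolerance = 1e-12)
  expect_true(is.na(km_at(km, 10)$surv))
})

test_that("log-rank: symmetry, df, and invariances", {
  set.seed(31)
  t <- rexp(60, 0.02); e <- rbinom(60, 1, 0.7)
  # identical outcome lists in both groups
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 60))
  expect_lt(lr$statistic, 1e-8)
  expect_gt(lr$p.value, 0.999)
  # df = groups - 1
  g3 <- sample(c("a", "b", "c"), 120, TRUE)
  expect_equal(logrank_test(c(t, t), c(e, e), g3)$df, 2)
  # invariance to label permutation and to uniform time rescaling
  g <- rep(c("a", "b"), 30)
  s1 <- logrank_test(t, e, g)$statistic
  expect_equal(logrank_test(t, e, ifelse(g == "a", "b", "a"))$statistic, s1)
  expect_equal(logrank_test(t * 7, e, g)$statistic, s1, tolerance = 1e-12)
  expect_error(logrank_test(t, e, rep("a", 60)), "two")
})

test_that("log-rank detects a planted rate ratio", {
  set.seed(33)
  detected <- replicate(10, {
    d1 <- sim_surv(500, 0.01)
    d2 <- sim_surv(500, 0.03)
    logrank_test(c(d1$time, d2$time), c(d1$event, d2$event),
                 rep(1:2, each = 500))$p.value < 0.001
  })
  expect_true(all(detected))
})

test_that("Cox fit agrees with brute-force partial-likelihood maximisation", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    t <- round(rexp(n, 0.02 * exp(0.8 * x)), 6)  # continuous, no ties
    e <- rbinom(n, 1, 0.8)
    if (sum(e) < 3) e[1:3] <- 1
    fit <- cox_fit(t, e, data.frame(x = x))
    expect_equal(fit$table$coef, brute_cox_binary(t, e, x),
                 tolerance = 5e-4)
  }
})

test_that("Cox fit recovers a planted hazard ratio of 2", {
  set.seed(43)
  hrs <- replicate(5, {
    lp <- rep(c(0, log(2)), each = 2000)
    d <- sim_surv(4000, 0.008, lp)
    cox_fit(d$time, d$event, data.frame(x = lp > 0))$table$hr
  })
  expect_gte(mean(hrs > 1.8 & hrs < 2.2), 0.8)
  expect_equal(mean(hrs), 2, tolerance = 0.05)
})

test_that("Cox fit rejects degenerate designs and reports layout fields", {
  d <- sim_surv(50, 0.02)
  expect_error(cox_fit(d$time, d$event, data.frame(x = rep(1, 50))),
               "constant")
  set.seed(44)
  fit <- cox_fit(d$time, d$event, data.frame(x = rnorm(50)))
  expect_named(fit$table,
               c("term", "coef", "se", "hr", "ci_low", "ci_high", "p"))
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_equal(fit$table$ci_low, exp(fit$table$coef - 1.96 * fit$table$se))
  expect_output(print(fit), "Cox model")
})

test_that("Cox fit flags complete separation instead of returning estimates", {
  # covariate perfectly orders events before censorings: monotone likelihood
  t <- c(1:10, 101:110)
  e <- c(rep(1, 10), rep(0, 10))
  x <- c(rep(1, 10), rep(0, 10))
  expect_error(suppressWarnings(cox_fit(t, e, data.frame(x = x))),
               "separation|converge")
})

test_that("backward selection keeps forced treatment and drops null terms", {
  set.seed(51)
  n <- 3000
  nodes <- factor(sample(c("N0", "N1to3", "Ngt3"), n, TRUE,
                         c(0.5, 0.35, 0.15)), c("N0", "N1to3", "Ngt3"))
  size <- runif(n, 0.5, 5)
  grade <- factor(sample(c("G1", "G2", "G3"), n, TRUE))
  age65 <- runif(n) < 0.4
  trt <- factor(sample(c("tam", "exe"), n, TRUE))
  lp <- 0.6 * (nodes == "N1to3") + 1.4 * (nodes == "Ngt3") + 0.3 * size
  d <- sim_surv(n, 0.002, lp)
  cov <- data.frame(nodes = nodes, size = size, grade = grade,
                    age_ge_65 = age65, treatment = trt)
  sel <- stepwise_backward(d$time, d$event, cov, forced = "treatment",
                           alpha = 0.10)
  expect_true(all(c("nodes", "size", "treatment") %in% sel$retained))
  expect_true(all(c("grade", "age_ge_65") %in% sel$removed))
  # alpha = 1 is the identity on the full model
  sel1 <- stepwise_backward(d$time, d$event, cov, forced = "treatment",
                            alpha = 1)
  expect_equal(sort(sel1$retained), sort(names(cov)))
  expect_length(sel1$removed, 0)
  # only forced terms: returned unchanged
  self <- stepwise_backward(d$time, d$event, cov["treatment"],
                            forced = "treatment", alpha = 0.1)
  expect_equal(self$retained, "treatment")
  # a stricter alpha never retains a superset
  sel05 <- stepwise_backward(d$time, d$event, cov, forced = "treatment",
                             alpha = 0.05)
  expect_true(all(sel05$retained %in% sel$retained))
})

test_that("interaction test: guards and power against a planted interaction", {
  set.seed(61)
  n <- 2000
  g <- factor(sample(c("Q1", "Q4"), n, TRUE))
  trt <- factor(sample(c("tam", "exe"), n, TRUE), c("tam", "exe"))
  expect_error(interaction_test(rexp(n), rbinom(n, 1, 0.5), g,
                                factor(rep("tam", n))), "one treatment arm")
  # qualitative interaction: exemestane halves the hazard in Q1,
  # doubles it in Q4
  lp <- ifelse(g == "Q1", ifelse(trt == "exe", log(0.5), 0),
               ifelse(trt == "exe", log(2), 0))
  d <- sim_surv(n, 0.004, lp)
  ps <- replicate(5, {
    d <- sim_surv(n, 0.004, lp)
    interaction_test(d$time, d$event, g, trt)$p.value
  })
  expect_true(mean(ps < 0.01) >= 0.8)
  # empty cell
  g2 <- g; g2[trt == "exe"] <- "Q1"
  expect_error(interaction_test(d$time, d$event, droplevels(g2), trt),
               "empty")
  # Wald variant agrees in order of magnitude with the LR test
  pw <- interaction_test(d$time, d$event, g, trt, method = "wald")$p.value
  pl <- interaction_test(d$time, d$event, g, trt)$p.value
  expect_lt(abs(log10(pw + 1e-300) - log10(pl + 1e-300)), 2)
})
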