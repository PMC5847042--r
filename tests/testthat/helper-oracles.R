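# Independent brute-force oracles, coded directly from the printed score
# equations and the partial-likelihood definition; deliberately naive and
# separate from the package implementation.

naive_ihc4 <- function(er, pgr, her2, ki67) {
  er10 <- er / 30
  pgr10 <- pgr / 10
  h <- if (her2 == "3+") 1 else 0
  94.7 * (-0.1 * er10 - 0.079 * pgr10 + 0.586 * h + 0.240 * log(1 + 4 * ki67))
}

naive_clinical <- function(age, nodes, size_cm, grade) {
  n13 <- if (nodes == "N1to3") 1 else 0
  n3 <- if (nodes == "Ngt3") 1 else 0
  t12 <- if (size_cm >= 1 && size_cm <= 2) 1 else 0
  t23 <- if (size_cm > 2 && size_cm <= 3) 1 else 0
  t3 <- if (size_cm > 3) 1 else 0
  g2 <- if (grade == "G2") 1 else 0
  g3 <- if (grade == "G3") 1 else 0
  a65 <- if (age >= 65) 1 else 0
  100 * (0.417 * n13 + 1.566 * n3 +
           0.93 * (0.497 * t12 + 0.882 * t23 + 1.838 * t3 +
                     0.559 * g2 + 0.970 * g3 + 0.130 * a65))
}

naive_pathies <- function(ihc4, nodes, size_cm, treatment) {
  exe <- if (treatment == "switch_to_exemestane") 1 else 0
  n13 <- if (nodes == "N1to3") 1 else 0
  n3 <- if (nodes == "Ngt3") 1 else 0
  t12 <- if (size_cm >= 1 && size_cm <= 2) 1 else 0
  t23 <- if (size_cm > 2 && size_cm <= 3) 1 else 0
  t3 <- if (size_cm > 3) 1 else 0
  100 * (-0.13 * exe + 0.46 * n13 + 1.45 * n3 +
           1.37 * t12 + 1.65 * t23 + 2.21 * t3 + 0.0048 * ihc4)
}

random_panel <- function() {
  list(er = sample(0:300, 1),
       pgr = runif(1, 0, 100),
       her2 = sample(c("0", "1+", "2+", "3+"), 1),
       ki67 = runif(1, 0, 100))
}

random_profile <- function() {
  list(age = runif(1, 45, 85),
       nodes = sample(c("N0", "N1to3", "Ngt3"), 1),
       size = runif(1, 0.2, 6),
       grade = sample(c("G1", "G2", "G3"), 1),
       treatment = sample(c("tamoxifen_only", "switch_to_exemestane"), 1))
}

# Brute-force Cox partial likelihood for one binary covariate, no ties:
# direct evaluation of the log partial likelihood maximised over a grid.
brute_cox_binary <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  logpl <- function(beta) {
    ord <- order(time)
    t <- time[ord]; e <- event[ord]; xx <- x[ord]
    sum(vapply(which(e == 1), function(i) {
      risk <- t >= t[i]
      beta * xx[i] - log(sum(exp(beta * xx[risk])))
    }, numeric(1)))
  }
  stats::optimize(logpl, c(-8, 8), maximum = TRUE)$maximum
}

# Simple two-group exponential survival sampler used across tests.
sim_surv <- function(n, rate, lp = rep(0, n), cens_range = c(40, 120)) {
  t <- stats::rexp(n, rate * exp(lp))
  c0 <- stats::runif(n, cens_range[1], cens_range[2])
  data.frame(time = pmin(t, c0), event = as.integer(t <= c0))
}
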