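test_that("km_estimate matches the product-limit definition", {
  km <- km_estimate(survival_records(time = 1:4, event = rep(1, 4)))
  expect_equal(km$surv, c(0.75, 0.50, 0.25, 0))
  expect_equal(km$median, 2)  # smallest t with S(t) <= 0.5

  # all censored: flat curve, median unreached
  km2 <- km_estimate(survival_records(time = c(10, 20, 30), event = 0))
  expect_true(all(km2$surv == 1))
  expect_false(km2$median_reached)

  expect_error(km_estimate(data.frame(time = c(1, -2), event = c(1, 1))),
               "positive")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(31)
  times <- round(rexp(200, 1 / 300)) + 1
  km <- km_estimate(survival_records(time = times, event = 1))
  emp <- vapply(km$time, function(t) mean(times > t), 0)
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("KM median recovers the true exponential median at large n", {
  set.seed(17)
  times <- rexp(2000, log(2) / 300)
  km <- km_estimate(survival_records(time = times, event = 1))
  expect_lt(abs(km$median - 300), 15)
  expect_true(km$median_lcl <= km$median && km$median <= km$median_ucl)
})

test_that("reverse KM estimates median potential follow-up", {
  rec <- survival_records(time = c(100, 200, 300, 400),
                          event = c(1, 0, 0, 0))
  rkm <- reverse_km_followup(rec)
  expect_equal(rkm$median, 300)

  # nobody died: reverse KM is the plain distribution of observation times
  rec2 <- survival_records(time = c(100, 200, 300), event = 0)
  expect_equal(reverse_km_followup(rec2)$median, 200)
})

test_that("logrank_test matches the hand-computed hypergeometric sums", {
  # toy cohort: group A events at 1, 2, 3; group B events at 10, 20, 30
  time <- c(1, 2, 3, 10, 20, 30)
  event <- rep(1L, 6)
  group <- rep(c("A", "B"), each = 3)
  # hand oracle: at each event time, O - E and hypergeometric variance
  o_minus_e <- 0; v <- 0
  for (t in sort(time)) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == "A")
    d <- sum(time == t)
    o_minus_e <- o_minus_e + sum(time == t & group == "A") - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2_hand <- o_minus_e^2 / v
  lr <- logrank_test(data.frame(time = time, event = event), group)
  expect_equal(lr$chi2, chi2_hand, tolerance = 1e-9)

  # identical groups: no signal
  rec <- data.frame(time = rep(c(5, 10, 15), 2), event = rep(1, 6))
  lr0 <- logrank_test(rec, rep(c("x", "y"), each = 3))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
})

test_that("logrank agrees with the Cox score test on tie-free two-group data", {
  set.seed(5)
  n <- 80
  g <- rep(0:1, each = n / 2)
  time <- rexp(n, 1 / 100 * exp(0.6 * g)) + runif(n, 0, 1e-4)  # break ties
  rec <- data.frame(time = time, event = 1L, g = g)
  lr <- logrank_test(rec, g)
  cx <- cox_fit(rec, "g")
  expect_equal(lr$chi2, cx$score_chi2, tolerance = 1e-6)
})

test_that("cox_fit recovers planted hazard ratios", {
  set.seed(91)
  n <- 2000
  x <- rbinom(n, 1, 0.4)
  h <- (log(2) / 300) * exp(log(0.314) * x)
  time <- rexp(n, h)
  cens <- rexp(n, log(2) / 900)
  rec <- data.frame(time = pmin(time, cens), event = as.integer(time <= cens),
                    x = x)
  fit <- cox_fit(rec, "x")
  expect_true(fit$converged)
  expect_gt(fit$table$hr, 0.25)
  expect_lt(fit$table$hr, 0.39)
  expect_true(fit$table$ci_lower < 0.314 && 0.314 < fit$table$ci_upper)

  # a covariate independent of hazard gives HR near 1
  rec$noise <- rnorm(n)
  fit0 <- cox_fit(rec, "noise")
  expect_lt(abs(fit0$table$log_hr), 3 * fit0$table$se)

  # two independent planted effects recovered jointly within 2 SE
  z1 <- rbinom(n, 1, 0.5); z2 <- rnorm(n)
  t2 <- rexp(n, (log(2) / 300) * exp(log(2) * z1 - 0.5 * z2))
  rec2 <- data.frame(time = t2, event = 1L, z1 = z1, z2 = z2)
  fit2 <- cox_fit(rec2, c("z1", "z2"))
  expect_lt(abs(fit2$table$log_hr[1] - log(2)), 2 * fit2$table$se[1])
  expect_lt(abs(fit2$table$log_hr[2] - (-0.5)), 2 * fit2$table$se[2])
})

test_that("cox_fit flags degenerate inputs instead of failing silently", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                    x = c(1, 1, 1, 1))
  expect_error(cox_fit(rec, "x"), "constant")
  expect_error(cox_fit(data.frame(time = 1:3, event = 0, x = c(1, 2, 3)),
                       "x"), "no events")
  # complete separation: short times all x = 1
  sep <- data.frame(time = c(1, 2, 3, 100, 200, 300),
                    event = c(1, 1, 1, 1, 1, 1),
                    x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(sep, "x")
  expect_false(fit$converged)
})

test_that("survival_roc matches the pairwise-concordance oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    score <- round(rnorm(n), 1)  # ties likely
    death <- rbinom(n, 1, plogis(score))
    time <- ifelse(death == 1, runif(n, 1, 180), runif(n, 190, 900))
    rec <- data.frame(time = time, event = death, cin_score = score)
    if (sum(death) == 0 || sum(death) == n) next
    roc <- survival_roc(rec, "cin_score", 183, n_boot = 0)
    want <- oracle_auc(score[death == 1], score[death == 0])
    expect_equal(roc$auc, want, tolerance = 1e-12)
  }
})

test_that("survival_roc handles exclusions, errors and perfect separation", {
  rec <- data.frame(time = c(50, 100, 400, 500, 90),
                    event = c(1, 1, 0, 0, 0),
                    cin_score = c(15, 14, 3, 2, 8))
  roc <- survival_roc(rec, "cin_score", 183, n_boot = 50)
  expect_equal(roc$auc, 1.0)  # cases 15, 14 vs controls 3, 2
  expect_equal(roc$n_excluded_censored, 1L)  # censored at 90
  expect_equal(roc$n_used, 4L)

  expect_error(survival_roc(data.frame(time = c(400, 500), event = c(0, 0),
                                       cin_score = c(1, 2)),
                            "cin_score", 183), "183")
})

test_that("survival ROC AUC is invariant under monotone score transforms", {
  set.seed(13)
  n <- 120
  score <- rnorm(n)
  death <- rbinom(n, 1, plogis(score))
  time <- ifelse(death == 1, runif(n, 1, 180), runif(n, 190, 900))
  rec <- data.frame(time = time, event = death, cin_score = score)
  a1 <- survival_roc(rec, "cin_score", 183, n_boot = 0)$auc
  rec$cin_score <- exp(3 * score) - 5
  a2 <- survival_roc(rec, "cin_score", 183, n_boot = 0)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("choose_cutoff maximizes Youden J with a smallest-threshold tie rule", {
  # single sharp risk step at a known score
  rec <- data.frame(time = c(rep(30, 10), rep(400, 10)),
                    event = c(rep(1, 10), rep(0, 10)),
                    cin_score = c(12:21, 2:11))
  roc <- survival_roc(rec, "cin_score", 183, n_boot = 0)
  expect_equal(choose_cutoff(roc), 12)

  # plateau of equal J: smallest threshold wins
  rec2 <- data.frame(time = c(30, 30, 400, 400),
                     event = c(1, 1, 0, 0),
                     cin_score = c(10, 20, 1, 2))
  roc2 <- survival_roc(rec2, "cin_score", 183, n_boot = 0)
  expect_equal(choose_cutoff(roc2), 10)  # J = 1 at both 10 and 20
})

test_that("fisher_exact reproduces published table p-values and the oracle", {
  # discovery vs validation gender split
  expect_equal(round(fisher_exact(matrix(c(17, 50, 89, 124), 2,
                                         byrow = TRUE))$p, 2), 0.02)
  # unidentified primary site
  expect_lt(fisher_exact(matrix(c(22, 45, 28, 185), 2, byrow = TRUE))$p,
            0.001)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1)

  # enumeration oracle on small random tables
  set.seed(19)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(fisher_exact(m)$p, oracle_fisher_p(m), tolerance = 1e-12)
  }

  # symmetry under row and column swaps
  m <- matrix(c(3, 9, 14, 4), 2)
  p <- fisher_exact(m)$p
  expect_equal(fisher_exact(m[2:1, ])$p, p)
  expect_equal(fisher_exact(m[, 2:1])$p, p)
  expect_equal(fisher_exact(t(m))$p, p)

  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})
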