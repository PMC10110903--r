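# From-scratch survival statistics against hand computations, brute-force
# enumeration, and the survival package as an independent implementation.

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kmCurve(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$time, c(1, 2))
  expect_equal(km$surv, c(2 / 3, 1 / 3))
  expect_equal(kmSurvAt(km, c(0.5, 1, 2.5, 10)), c(1, 2 / 3, 1 / 3, 1 / 3))

  # all censored -> S identically 1
  expect_equal(nrow(kmCurve(c(1, 2, 3), c(0, 0, 0))), 0)
  expect_equal(kmSurvAt(kmCurve(c(1, 2), c(0, 0)), 1.5), 1)

  # no censoring -> complement of the ECDF
  tt <- c(1, 2, 2, 4, 7)
  km2 <- kmCurve(tt, rep(1, 5))
  expect_equal(kmSurvAt(km2, tt), 1 - ecdf(tt)(tt))
})

test_that("Kaplan-Meier is non-increasing within [0, 1] and matches survfit", {
  skip_if_not_installed("survival")
  for (s in 1:5) {
    r <- toy_records(seed = s)
    km <- kmCurve(r$time, r$event)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    sf <- summary(survival::survfit(survival::Surv(r$time, r$event) ~ 1))
    expect_equal(km$surv, sf$surv, tolerance = 1e-12)
    expect_equal(km$time, sf$time)
  }
})

test_that("log-rank statistic matches the hand O/E/V table and survdiff", {
  # two-group toy: A = (1 censored, 2 event, 3 event), B = (2, 4 events, 5 cens)
  tA <- c(1, 2, 3); eA <- c(0, 1, 1)
  tB <- c(2, 4, 5); eB <- c(1, 1, 0)
  # event times 2 (n=5, nA=2, d=2, dA=1), 3 (n=3, nA=1, d=1, dA=1),
  # 4 (n=2, nA=0, d=1, dA=0)
  E <- 2 * 2 / 5 + 1 * 1 / 3 + 0
  V <- 2 * (2 / 5) * (3 / 5) * (5 - 2) / (5 - 1) +
    1 * (1 / 3) * (2 / 3) * (3 - 1) / (3 - 1) + 0
  O <- 2
  lr <- logrankTest(tA, eA, tB, eB)
  expect_equal(lr$chi_square, (O - E)^2 / V, tolerance = 1e-9)
  expect_equal(lr$p, pchisq((O - E)^2 / V, 1, lower.tail = FALSE))

  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(c(tA, tB), c(eA, eB)) ~
                             rep(1:2, c(3, 3)))
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-9)
})

test_that("log-rank is symmetric in group labels and degenerates sanely", {
  r <- toy_records(seed = 3, n = 16)
  a <- 1:8; b <- 9:16
  l1 <- logrankTest(r$time[a], r$event[a], r$time[b], r$event[b])
  l2 <- logrankTest(r$time[b], r$event[b], r$time[a], r$event[a])
  expect_equal(l1$chi_square, l2$chi_square)
  expect_true(l1$chi_square >= 0)
  # identical groups record-for-record -> statistic 0 is not guaranteed in
  # finite samples, but zero events overall must give exactly (0, 1)
  l0 <- logrankTest(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_equal(l0$chi_square, 0)
  expect_equal(l0$p, 1)
})

test_that("binary Cox HR maximizes the explicit partial likelihood", {
  # tie-free 6-record toy; oracle = grid maximization of Breslow loglik
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 1, 0)
  group <- c(1, 0, 1, 0, 1, 0)
  fit <- coxHRBinary(time, event, group)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, function(b)
    desep:::.cox_breslow(b, time, event, group)$loglik, 0)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-3)
  # score at the reported estimate is (numerically) zero
  expect_lt(abs(desep:::.cox_breslow(fit$beta, time, event, group)$score), 1e-8)

  skip_if_not_installed("survival")
  cx <- survival::coxph(survival::Surv(time, event) ~ group,
                        ties = "breslow")
  expect_equal(fit$beta, unname(coef(cx)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(vcov(cx)[1, 1])), tolerance = 1e-6)
})

test_that("Cox HR inverts under relabeling and handles ties via Breslow", {
  skip_if_not_installed("survival")
  set.seed(7)
  time <- round(rexp(40, 0.5), 1) + 0.1  # rounding induces ties
  event <- rbinom(40, 1, 0.8)
  group <- rep(0:1, 20)
  f1 <- coxHRBinary(time, event, group)
  f2 <- coxHRBinary(time, event, 1 - group)
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-6)
  cx <- survival::coxph(survival::Surv(time, event) ~ group,
                        ties = "breslow")
  expect_equal(f1$beta, unname(coef(cx)), tolerance = 1e-6)
})

test_that("Cox recovers a planted HR of 2 on exponential simulations", {
  set.seed(21)
  n <- 1000
  group <- rep(0:1, n / 2)
  time <- rexp(n, 0.3 * exp(log(2) * group))
  cens <- rexp(n, 0.1)
  fit <- coxHRBinary(pmin(time, cens), as.integer(time <= cens), group)
  expect_gt(fit$hr, 2 * exp(-2.5 * fit$se))
  expect_lt(fit$hr, 2 * exp(2.5 * fit$se))
})

test_that("monotone Cox likelihood is flagged with unbounded CI", {
  # all events in group 1, all early; group 0 censored late
  time <- c(1, 2, 3, 10, 11, 12)
  event <- c(1, 1, 1, 0, 0, 0)
  group <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit <- coxHRBinary(time, event, group), "monotone")
  expect_true(fit$flagged)
  expect_equal(fit$ci_high, Inf)
})

test_that("Harrell's c equals brute-force pair enumeration exactly", {
  for (s in c(1, 2, 9)) {
    r <- toy_records(seed = s, n = 12)
    expect_equal(harrellsC(r$time, r$event, r$score),
                 bf_harrells_c(r$time, r$event, r$score))
  }
})

test_that("Harrell's c boundary conventions hold", {
  # scores perfectly anti-ranked with times, no censoring -> 1
  tt <- c(1, 2, 3, 4, 5)
  expect_equal(harrellsC(tt, rep(1, 5), -tt), 1)
  # all scores tied -> 0.5
  expect_equal(harrellsC(tt, rep(1, 5), rep(0, 5)), 0.5)
  # complement identity without score ties
  r <- toy_records(seed = 4, n = 10)
  expect_equal(harrellsC(r$time, r$event, r$score) +
                 harrellsC(r$time, r$event, -r$score), 1)
  # no usable pairs
  expect_error(harrellsC(c(1, 2), c(0, 0), c(0, 1)), "no usable pairs")
})

test_that("Cramer's phi closed form, boundaries and chi-square relation", {
  expect_equal(cramersPhi(matrix(c(10, 0, 0, 10), 2))$phi, 1)
  expect_equal(cramersPhi(matrix(c(5, 5, 5, 5), 2))$phi, 0)
  ph <- cramersPhi(matrix(c(8, 3, 2, 7), 2, byrow = FALSE))
  expect_equal(ph$phi, 50 / sqrt(9900), tolerance = 1e-12)
  # cross-check via sqrt(chi^2 / n) against chisq.test without correction
  ct <- suppressWarnings(chisq.test(matrix(c(8, 3, 2, 7), 2), correct = FALSE))
  expect_equal(abs(ph$phi), sqrt(unname(ct$statistic) / 20), tolerance = 1e-12)
  expect_equal(ph$p, unname(ct$p.value), tolerance = 1e-12)
  # sign flips when one variable's labels swap
  expect_equal(cramersPhi(matrix(c(3, 8, 7, 2), 2))$phi, -ph$phi)
  expect_error(cramersPhi(matrix(c(0, 0, 3, 7), 2)), "zero margin")
})

test_that("log-rank p-values are approximately uniform under the null", {
  # beta = 0 phantom survival null over seeded replicates
  cfg <- PhantomConfig(n_patients = 60, log_hr_morphology = 0, seed = 1)
  set.seed(101)
  pvals <- replicate(200, {
    s <- simulateSurvival(rnorm(60), cfg)
    g <- rep(c(TRUE, FALSE), 30)
    logrankTest(s$os_time[g], s$os_event[g],
                s$os_time[!g], s$os_event[!g])$p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bootstrap c standard error is seeded and plausible", {
  r <- toy_records(seed = 6, n = 30)
  b1 <- harrellsCBoot(r$time, r$event, r$score, B = 50, seed = 2)
  b2 <- harrellsCBoot(r$time, r$event, r$score, B = 50, seed = 2)
  expect_identical(b1, b2)
  expect_true(b1$se > 0 && b1$se < 0.5)
})
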