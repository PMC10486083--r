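test_that("Kaplan-Meier estimates match hand lifetable computation", {
  # times {1, 2+, 3}: S(1) = 2/3, S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)
  # no events: S = 1 everywhere (only the t = 0 row remains)
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # four distinct event times: steps 3/4, 1/2, 1/4, 0
  km4 <- km_estimate(1:4, rep(1, 4))
  expect_equal(km4$surv[-1], c(3 / 4, 1 / 2, 1 / 4, 0))
})

test_that("Kaplan-Meier equals exhaustive lifetable products on tiny cohorts", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- sample(0:1, n, replace = TRUE)
    km <- km_estimate(time, event)
    # independent lifetable: walk distinct event times
    s <- 1
    for (t in sort(unique(time[event == 1]))) {
      at_risk <- sum(time >= t)
      d <- sum(time == t & event == 1)
      s <- s * (1 - d / at_risk)
      expect_equal(km$surv[km$time == t], s, info = i)
    }
  }
})

test_that("log-rank behaves on degenerate and hand-computed instances", {
  same <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(numeric(0), numeric(0), c(1), c(1)), "empty")
  # complete separation: A all die before any B death
  # hand computation: event times 1,2,3 (A), 10,20,30 (B)
  # t=1: O_A=1 E_A=3/6;  t=2: O_A=1 E_A=2/5;  t=3: O_A=1 E_A=1/4
  # t=10: O_A=0 E_A=0 (A exhausted) etc.
  # O-E = 3 - (0.5+0.4+0.25) = 1.85; V = sum of hypergeometric variances
  v <- (3 * 3 / 36) * 1 + (2 * 3 / 25) * 1 + (1 * 3 / 16) * 1
  chi2_hand <- (3 - (3 / 6 + 2 / 5 + 1 / 4))^2 / v
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(10, 20, 30), c(1, 1, 1))
  expect_equal(lr$chi2, chi2_hand, tolerance = 1e-10)
})

test_that("log-rank statistic is invariant under common time rescaling", {
  set.seed(72)
  tA <- rexp(30); tB <- rexp(30) * 1.5
  eA <- rbinom(30, 1, 0.8); eB <- rbinom(30, 1, 0.8)
  a <- logrank_test(tA, eA, tB, eB)
  b <- logrank_test(tA * 365, eA, tB * 365, eB)
  expect_equal(a$chi2, b$chi2)
})

test_that("ridge Cox agrees with the survival package penalized fit", {
  set.seed(73)
  n <- 150
  x <- matrix(rnorm(n * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  haz <- 0.01 * exp(0.6 * x[, 1] - 0.4 * x[, 2])
  time <- rexp(n, haz); event <- rbinom(n, 1, 0.85)
  lambda <- 0.1
  mine <- fit_cox_ridge(time, event, x, lambda = lambda)
  ref <- survival::coxph(survival::Surv(time, event) ~
                           survival::ridge(a, b, c, theta = 2 * lambda,
                                           scale = FALSE),
                         data = data.frame(x), ties = "breslow")
  expect_equal(as.numeric(mine), unname(coef(ref)), tolerance = 1e-4)
})

test_that("ridge Cox recovers a planted log-2 hazard ratio", {
  set.seed(74)
  n <- 500
  x <- matrix(rbinom(n, 1, 0.5), ncol = 1, dimnames = list(NULL, "f"))
  time <- rexp(n, 0.01 * exp(log(2) * x[, 1]))
  event <- rep(1L, n)
  beta <- fit_cox_ridge(time, event, x, lambda = 1e-3)
  expect_lt(abs(unname(beta) - log(2)), 0.15)
})

test_that("duplicating every patient leaves the coefficients unchanged", {
  set.seed(75)
  n <- 80
  x <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  time <- rexp(n, 0.01 * exp(0.5 * x[, 1]))
  event <- rbinom(n, 1, 0.9)
  b1 <- fit_cox_ridge(time, event, x, lambda = 0)
  b2 <- fit_cox_ridge(rep(time, 2), rep(event, 2), rbind(x, x), lambda = 0)
  expect_equal(as.numeric(b1), as.numeric(b2), tolerance = 1e-5)
})

test_that("degenerate survival inputs are rejected", {
  x <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "a"))
  expect_error(fit_cox_ridge(1:10, rep(0, 10), x), "events")
  xz <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(fit_cox_ridge(1:10, rep(1, 10), xz), "zero-variance")
})

test_that("bootstrap signatures are deterministic under a fixed seed", {
  sim <- small_sim()
  feats <- setdiff(names(sim$survival$records),
                   c("patient_id", "time", "event"))[1:6]
  m1 <- bootstrap_signature(sim$survival$records, feats, n_boot = 30, seed = 5)
  m2 <- bootstrap_signature(sim$survival$records, feats, n_boot = 30, seed = 5)
  expect_identical(m1$features, m2$features)
  expect_equal(m1$coefficients, m2$coefficients)
  expect_equal(m1$boot_coefs, m2$boot_coefs)
})

test_that("the planted prognostic features drive the selected signature", {
  sim <- small_sim()
  # candidate set: the retro-miR matures, as in the pipeline stage
  matures <- unlist(lapply(sim$retro_mirnas, function(m) m$matures$id))
  feats <- intersect(names(sim$survival$records), matures)
  m <- bootstrap_signature(sim$survival$records, feats, n_boot = 50, seed = 3)
  truth <- sim$survival$ledger
  planted <- truth$feature[truth$true_beta != 0]
  expect_true(all(planted %in% m$features))
  ev <- evaluate_signature(m, sim$survival$records)
  expect_lt(ev$p, 0.01)
  # higher score = higher hazard = worse survival
  expect_true(is.na(ev$median_surv["high"]) || is.na(ev$median_surv["low"]) ||
                ev$median_surv["high"] < ev$median_surv["low"])
})

test_that("the median split sends ties to the low group", {
  model <- structure(list(features = "f", coefficients = c(f = 1),
                          center = c(f = 0), scale = c(f = 1),
                          consistency = c(f = 1)),
                     class = "signature_model")
  rec <- data.frame(time = c(5, 4, 3, 2), event = c(1, 1, 1, 1),
                    f = exp(c(1, 2, 3, 4)) - 1)  # log1p-scores 1..4
  ev <- evaluate_signature(model, rec)
  expect_identical(ev$group, c("low", "low", "high", "high"))
})
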