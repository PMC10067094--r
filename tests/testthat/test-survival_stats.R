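test_that("KM estimate matches closed-form product-limit arithmetic", {
  # all events
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  # censoring between events: S(1) = 2/3, then the last subject dies
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2/3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # all censored -> flat at 1
  km3 <- km_estimate(c(5, 6), c(0, 0))
  expect_true(all(km3$surv == 1))
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM curve is monotone in [0,1] and equals the empirical survival without censoring", {
  set.seed(41)
  for (i in 1:10) {
    t <- round(rexp(40, 0.1) + 0.1, 1)
    ev <- rbinom(40, 1, 0.7)
    km <- km_estimate(t, ev)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_equal(km$surv[1], 1 - km$n_event[1] / km$n_risk[1])
  }
  t <- round(rexp(60, 0.1) + 0.1, 1)
  km <- km_estimate(t, rep(1, 60))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp)
  # and agrees with the hand product-limit oracle under censoring
  ev <- rbinom(60, 1, 0.6)
  km_c <- km_estimate(t, ev)
  hand <- km_hand(t, ev)
  expect_equal(km_c$surv[km_c$n_event > 0], hand$surv)
})

test_that("log-rank equals the hypergeometric oracle and respects symmetry", {
  # identical groups -> statistic 0, p = 1
  t <- c(2, 4, 6, 8); ev <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  set.seed(53)
  for (i in 1:15) {
    n <- sample(8:30, 1)
    time <- round(rexp(n, 0.1) + 0.1, 1)
    event <- rbinom(n, 1, 0.7)
    grp <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    lr <- logrank_test(time, event, grp)
    expect_equal(lr$statistic, logrank_enum_chisq(time, event, grp),
                 tolerance = 1e-8)
    # label swap leaves the statistic unchanged
    swapped <- ifelse(grp == "x", "y", "x")
    expect_equal(logrank_test(time, event, swapped)$statistic,
                 lr$statistic)
  }
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), ">= 2")
})

test_that("Cox estimates match a partial-likelihood grid oracle", {
  set.seed(61)
  for (i in 1:5) {
    n <- 8
    d <- data.frame(os_months = round(rexp(n, 0.2) + 0.1, 1),
                    os_event = rbinom(n, 1, 0.8),
                    x = rep(0:1, each = 4))
    if (sum(d$os_event) < 2) next
    fit <- cox_fit(d, "x")
    beta_oracle <- cox_grid_beta(d$os_months, d$os_event, d$x)
    expect_equal(fit$terms$coef, beta_oracle, tolerance = 1e-3)
  }
})

test_that("Cox fits obey reparameterization and translation laws", {
  set.seed(71)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(0.8 * x))
  d <- data.frame(os_months = t, os_event = 1L, x = x, x10 = 10 * x,
                  xshift = x + 3)
  f1 <- cox_fit(d, "x")
  f2 <- cox_fit(d, "x10")
  expect_equal(f2$terms$coef, f1$terms$coef / 10, tolerance = 1e-8)
  expect_equal(f2$terms$hr^10, f1$terms$hr, tolerance = 1e-6)
  f3 <- cox_fit(d, "xshift")
  expect_equal(f3$terms$coef, f1$terms$coef, tolerance = 1e-8)
  expect_true(f1$terms$ci_lower <= f1$terms$hr &
                f1$terms$hr <= f1$terms$ci_upper)
})

test_that("Cox validation rejects constant covariates and too few events", {
  d <- data.frame(os_months = c(1, 2, 3, 4), os_event = c(1, 1, 1, 1),
                  x = c(1, 1, 1, 1), y = c(0, 1, 0, 1))
  expect_error(cox_fit(d, "x"), "constant")
  d2 <- data.frame(os_months = c(1, 2, 3), os_event = c(0, 0, 0),
                   y = c(0, 1, 0))
  expect_error(cox_fit(d2, "y"), "fewer events")
})

test_that("Cox recovers a known log hazard ratio from simulated data", {
  set.seed(83)
  ests <- replicate(10, {
    x <- rbinom(400, 1, 0.5)
    s <- simulate_survival(1.0 * x, shape = 1.2, scale = 30, horizon = 60,
                           censor_rate = 0.01)
    d <- data.frame(os_months = s$time, os_event = s$event, x = x)
    cox_fit(d, "x")$terms$coef
  })
  expect_lt(abs(mean(ests) - 1.0), 0.15)
})

test_that("the full survival design reports per-scheme comparisons", {
  sim <- simulate_cohort(simulation_config(n_patients = 400L, seed = 19))
  cl <- read_clinical_table(sim$clinical)
  res <- annotate_variant_file(read_variant_table(sim$variants), refset)
  st <- aggregate_patient_tp53(cl, res$annotations)
  filt <- apply_cohort_filters(cl, TRUE, TRUE, TRUE)
  rep <- run_survival_analysis(filt$clinical, st)
  expect_s3_class(rep, "tp53_survival_report")
  expect_setequal(names(rep$schemes),
                  c("missense_vs_others", "nondisruptive_vs_others",
                    "exon8_vs_others", "eap53_vs_others"))
  for (r in rep$schemes) {
    expect_true(r$cox_univariate$converged)
    expect_equal(r$logrank$df, 1L)
    expect_true(all(c("others") %in% names(r$km) |
                      length(r$km) == 2L))
    # KM curves valid per group
    for (km in r$km) expect_true(all(km$surv >= 0 & km$surv <= 1))
  }
  # the generative signal sits on the EAp53 exposure
  ea <- rep$schemes$eap53_vs_others
  expect_lt(ea$logrank$p_value, 0.05)
  mt <- ea$cox_multivariate$terms
  expect_gt(mt$hr[mt$term == "exposure"], 1)
})

test_that("a single-group scheme is skipped with a warning", {
  cl <- make_clinical(sprintf("P%02d", 1:20), os_months = 10,
                      os_event = 1L)
  cl$os_months <- seq(1, 20)
  cl$sex <- rep(c("male", "female"), 10)
  cl$smoking <- rep(c("smoker", "nonsmoker"), 10)
  cl$egfr_status <- rep(c("mutant", "wild_type"), 10)
  st <- aggregate_patient_tp53(cl,
                               annotate_simple("R282W",
                                               patient_id = "P01")[0, ])
  expect_warning(run_survival_analysis(cl, st,
                                       schemes = "missense_vs_others"),
                 "single group")
})
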