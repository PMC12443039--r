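test_that("concordance index matches hand-enumerated cases", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0))
  expect_equal(concordance_index(c(3, 2, 1), d), 1)       # all 3 pairs concordant
  expect_equal(concordance_index(c(1, 2, 3), d), 0)
  expect_equal(concordance_index(c(5, 5, 5), d), 0.5)     # ties -> 0.5
  # no comparable pairs
  d0 <- data.frame(time = c(1, 2), event = c(0, 0))
  expect_warning(ci <- concordance_index(c(1, 2), d0), "comparable")
  expect_true(is.nan(ci))
})

test_that("concordance index equals the brute-force pair oracle on random instances", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(3:50, 1)
    time <- round(rexp(n, 0.1), 1) + 0.1     # rounding induces time ties
    event <- rbinom(n, 1, 0.7)
    risk <- sample(round(rnorm(n), 1), n, replace = TRUE)  # induces risk ties
    if (sum(event) == 0) event[1] <- 1
    d <- data.frame(time = time, event = event)
    expect_identical(concordance_index(risk, d),
                     cindex_bruteforce(risk, time, event))
  }
})

test_that("Cox wrapper reproduces coxph and is invariant to dataset duplication", {
  set.seed(10)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(0.7 * x))
  cens <- rexp(n, 0.02)
  d <- data.frame(time = pmin(time, cens), event = as.integer(time <= cens))
  fit <- fit_cox(d, data.frame(x = x))
  ref <- survival::coxph(survival::Surv(time, event) ~ x, data = cbind(d, x = x),
                         ties = "efron")
  expect_equal(fit$coefficients$coef, unname(coef(ref)), tolerance = 1e-8)
  expect_true(fit$converged)
  # duplicating every observation leaves the estimate unchanged under the
  # Breslow tie correction (the duplicated likelihood is proportional to
  # the square of the original; Efron reweights within tied sets)
  d2 <- rbind(d, d)
  fitb <- fit_cox(d, data.frame(x = x), ties = "breslow")
  fit2 <- fit_cox(d2, data.frame(x = c(x, x)), ties = "breslow")
  expect_equal(fit2$coefficients$coef, fitb$coefficients$coef, tolerance = 1e-6)
})

test_that("likelihood-ratio test compares nested models", {
  set.seed(11)
  n <- 150
  x <- rnorm(n)
  z <- rnorm(n)
  time <- rexp(n, 0.05 * exp(0.8 * x))
  d <- data.frame(time = time, event = rep(1L, n))
  full <- fit_cox(d, data.frame(x = x, z = z))
  nested <- fit_cox(d, data.frame(z = z))
  lrt <- cox_lrt(full, nested)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p, 1e-6)        # x truly prognostic
  null_test <- cox_lrt(nested)  # z alone vs null
  expect_gt(null_test$p, 0.001) # z is noise
})

test_that("monotone likelihood triggers the flagged ridge fallback", {
  # perfectly separating covariate
  d <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = rep(1L, 6))
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_cox(d, data.frame(x = x))
  expect_false(fit$converged)
  expect_true(fit$ridged)
  expect_true(all(is.finite(fit$coefficients$coef)))
})

test_that("Kaplan-Meier curves match product-limit hand calculations", {
  d <- data.frame(time = c(1, 2), event = c(1, 1))
  km <- kaplan_meier(d, groups = c("a", "a"))
  expect_equal(km$surv[km$time == 0], 1)
  expect_equal(km$surv[km$time == 1], 0.5)
  expect_equal(km$surv[km$time == 2], 0)
  # no events: constant at 1
  d2 <- data.frame(time = c(3, 5), event = c(0, 0))
  km2 <- kaplan_meier(d2, groups = c("a", "a"))
  expect_true(all(km2$surv == 1))
  # all events at distinct times equal the empirical survival function
  set.seed(5)
  t3 <- sample(1:100, 8)
  km3 <- kaplan_meier(data.frame(time = t3, event = rep(1L, 8)), rep("g", 8))
  for (tt in t3)
    expect_equal(km3$surv[km3$time == tt], mean(t3 > tt))
  # curves are non-increasing within groups
  ds <- generate_dataset(small_config(seed = 3))
  km4 <- kaplan_meier(ds$survival, ds$true_labels)
  for (g in unique(km4$group))
    expect_true(all(diff(km4$surv[km4$group == g]) <= 1e-12))
})

test_that("follow-up truncation censors at the horizon and is a no-op beyond it", {
  d <- data.frame(time = c(5, 50, 130), event = c(1, 0, 1))
  tr <- truncate_followup(d, 120)
  expect_equal(tr$time, c(5, 50, 120))
  expect_equal(tr$event, c(1, 0, 0))
  expect_identical(truncate_followup(d, 1e6), d)
})

test_that("the model registry equalizes c-indexes when test equals train", {
  ds <- generate_dataset(small_config(seed = 22))
  sel <- select_genes(normalize_counts(ds$counts), n_top = 150)
  sig <- build_signature(sel, ds$true_labels, n_per_class = 5)
  cohort <- list(expr = sel, survival = ds$survival)
  reg <- run_model_registry(cohort, cohort, sig)
  expect_setequal(reg$model_id, LETTERS[1:9])
  done <- !is.na(reg$cindex_test)
  expect_equal(reg$cindex_test[done], reg$cindex_train[done], tolerance = 1e-10)
  # LRT p-values reported for the single-modality comparisons
  expect_true(all(is.finite(reg$lrt_p[reg$model_id %in% c("A", "B", "C", "D")])))
})

test_that("models needing grade are evaluated train-only when the test cohort lacks it", {
  ds <- generate_dataset(small_config(seed = 23))
  ds2 <- generate_dataset(small_config(seed = 24))
  sel <- select_genes(normalize_counts(ds$counts), n_top = 150)
  sel2 <- normalize_counts(ds2$counts)   # full matrix: signature genes present
  sig <- build_signature(sel, ds$true_labels, n_per_class = 5)
  surv2 <- ds2$survival
  surv2$grade <- NULL
  reg <- run_model_registry(list(expr = sel, survival = ds$survival),
                            list(expr = sel2, survival = surv2), sig)
  for (id in c("D", "H")) {
    row <- reg[reg$model_id == id, ]
    expect_true(is.na(row$cindex_test))
    expect_true(is.finite(row$cindex_train))
    expect_match(row$note, "train-only")
  }
  expect_true(is.finite(reg$cindex_test[reg$model_id == "C"]))
})
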