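test_that("Box-Cox selection finds the log and identity transforms", {
  set.seed(101)
  y_log <- exp(rnorm(2000))
  expect_true(abs(select_boxcox(y_log)) <= 0.15)
  y_id <- rnorm(2000, 10, 1)
  lam <- select_boxcox(y_id)
  expect_true(lam >= 0.6 && lam <= 1.4)
  expect_error(select_boxcox(c(-1, 1, 2)), "non-positive")
})

test_that("lambda = 1 is an affine map and the transform inverts", {
  y <- c(0.5, 1, 2, 7)
  expect_equal(boxcox_transform(y, 1), y - 1)
  for (lam in c(-1.5, -0.5, 0, 0.33, 1, 2)) {
    expect_equal(inv_boxcox(boxcox_transform(y, lam), lam), y,
                 tolerance = 1e-10)
  }
})

test_that("zero-variance data reduce the mixed fit to the OLS oracle", {
  cfg <- calcium_sim_config(
    cells_per_coverslip = 10L, cells_jitter = 2L,
    variance_components = c(day = 0, coverslip = 0, cell = 0.05,
                            noise = 0.02),
    seed = 31)
  sim <- simulate_calcium(cfg)
  f <- extract_features(sim$traces, default_protocol(cfg$phase_times))
  fit <- fit_condition_model(f, "resting", lambda = 1)
  ols <- lm(resting ~ line * treatment,
            data = transform(f,
                             line = factor(line, c("NCM460", "HT29")),
                             treatment = factor(treatment,
                                                c("control", "DFMO"))))
  grid <- expand.grid(line = factor(c("NCM460", "HT29"),
                                    c("NCM460", "HT29")),
                      treatment = factor(c("control", "DFMO"),
                                         c("control", "DFMO")))
  ols_means <- predict(ols, grid)
  names(ols_means) <- paste(grid$line, grid$treatment, sep = ".")
  expect_equal(fit$emmeans$emmean + 1,
               unname(ols_means[fit$emmeans$condition]),
               tolerance = 1e-6)
})

test_that("noiseless balanced data return the configured condition means", {
  cfg <- calcium_sim_config(
    cells_per_coverslip = 4L, cells_jitter = 0L,
    variance_components = c(day = 0, coverslip = 0, cell = 0, noise = 0),
    seed = 1)
  sim <- simulate_calcium(cfg)
  f <- extract_features(sim$traces, default_protocol(cfg$phase_times))
  # degenerate residuals: fixed-effects path with identity transform
  fit <- fit_condition_model(f, "resting", random = character(0), lambda = 1)
  cm <- cfg$condition_means
  means <- fit$emmeans$response_mean
  names(means) <- fit$emmeans$condition
  for (i in seq_len(nrow(cm)))
    expect_equal(unname(means[paste(cm$line[i], cm$treatment[i],
                                    sep = ".")]),
                 cm$resting[i], tolerance = 1e-10)
})

test_that("random-structure selection tracks the generating process", {
  n_hit <- 0
  for (r in 1:20) {
    cfg <- calcium_sim_config(
      n_days = 4L, cells_per_coverslip = 12L, cells_jitter = 0L,
      phase_times = c(35, 60, 90),
      variance_components = c(day = 0.02, coverslip = 0.08, cell = 0.03,
                              noise = 0.01),
      seed = 300 + r)
    sim <- simulate_calcium(cfg)
    f <- extract_features(sim$traces, default_protocol(cfg$phase_times))
    sel <- select_random_structure(f, "resting", lambda = 1)
    if (sel$best == "day_coverslip") n_hit <- n_hit + 1
  }
  expect_gte(n_hit, 18)
  # single candidate is returned unchanged
  f1 <- make_features(20, means = c(1, 2, 3, 4), sd = 0.5)
  names(f1)[names(f1) == "y"] <- "resting"
  one <- select_random_structure(f1, "resting", lambda = 1,
                                 candidates = list(day = "day"))
  expect_equal(one$best, "day")
  expect_equal(one$random, "day")
})

test_that("diagnostics behave under Gaussian and heavy-tailed errors", {
  set.seed(7)
  f <- make_features(120, means = c(1, 1.5, 2, 2.5), sd = 0.3)
  names(f)[names(f) == "y"] <- "resting"
  fit <- fit_condition_model(f, "resting", random = character(0), lambda = 1)
  d <- check_assumptions(fit)
  expect_gt(d$shapiro$p.value, 0.001)
  expect_gt(d$bartlett_p, 0.001)
  expect_true(all(c(d$bartlett_p, d$breusch_pagan_p,
                    d$jarque_bera$p.value) <= 1))

  # heavy tails are detected most of the time
  hits <- 0
  for (r in 1:10) {
    set.seed(800 + r)
    fh <- make_features(125, means = c(1, 1, 1, 1), sd = 1)
    fh$y <- 5 + rt(nrow(fh), df = 2)
    names(fh)[names(fh) == "y"] <- "resting"
    fit_h <- fit_condition_model(fh, "resting", random = character(0),
                                 lambda = 1)
    dh <- check_assumptions(fit_h)
    if (dh$shapiro$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)

  # constant residuals hit the degenerate error path
  fc <- make_features(5, means = c(1, 2, 3, 4), sd = 0)
  names(fc)[names(fc) == "y"] <- "resting"
  fit_c <- fit_condition_model(fc, "resting", random = character(0),
                               lambda = 1)
  expect_error(check_assumptions(fit_c), "constant")
})

test_that("parametric bootstrap is reproducible and agrees with the fit", {
  set.seed(9)
  f <- make_features(60, means = c(1, 1.4, 2, 1.2), sd = 0.4)
  names(f)[names(f) == "y"] <- "resting"
  fit <- fit_condition_model(f, "resting", lambda = 1)
  b1 <- parametric_bootstrap(fit, B = 60, seed = 4)
  b2 <- parametric_bootstrap(fit, B = 60, seed = 4)
  expect_identical(b1$summary, b2$summary)
  expect_error(parametric_bootstrap(fit, B = 0), "at least 1")

  # percentile intervals bracket the point estimate at moderate B
  expect_true(all(b1$summary$lower <= b1$summary$estimate &
                    b1$summary$estimate <= b1$summary$upper))

  # OLS path: bootstrap mean matches the estimate and the CI midpoint
  # agrees with the Wald interval within a fraction of the half-width
  fit_lm <- fit_condition_model(f, "resting", random = character(0),
                                lambda = 1)
  bl <- parametric_bootstrap(fit_lm, B = 1000, seed = 11)
  mc_se <- apply(bl$samples, 2, sd) / sqrt(bl$B)
  expect_true(all(abs(bl$summary$boot_mean - bl$summary$estimate) <
                    3 * mc_se + 1e-8))
  wald_half <- qt(0.975, fit_lm$emmeans$df) * fit_lm$emmeans$SE
  mid <- (bl$summary$lower + bl$summary$upper) / 2
  expect_true(all(abs(mid - bl$summary$estimate) < 0.15 * wald_half))
})

test_that("bootstrap intervals shrink like one over root n", {
  widths <- sapply(c(100, 400, 1600), function(n) {
    set.seed(1000 + n)
    f <- make_features(n, means = c(1, 1, 1, 1), sd = 0.5)
    names(f)[names(f) == "y"] <- "resting"
    fit <- fit_condition_model(f, "resting", random = character(0),
                               lambda = 1)
    b <- parametric_bootstrap(fit, B = 400, seed = 2)
    mean(b$summary$upper - b$summary$lower)
  })
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.2)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.2)
})

test_that("two-group Box-Cox comparison holds its size and finds real shifts", {
  # null: identical lognormal groups
  rejections <- 0
  for (r in 1:200) {
    set.seed(2000 + r)
    y <- exp(rnorm(9, 0, 0.5))
    g <- rep(c("a", "b"), c(6, 3))
    res <- boxcox_group_compare(y, g)
    if (res$p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / 200, 0.10)

  # 2-fold lognormal shift at n = 6:3
  power_hits <- 0
  lambdas <- numeric(50)
  for (r in 1:50) {
    set.seed(3000 + r)
    y <- c(exp(rnorm(6, 0, 0.25)), exp(rnorm(3, log(2), 0.25)))
    g <- rep(c("ctrl", "dfmo"), c(6, 3))
    res <- boxcox_group_compare(y, g)
    lambdas[r] <- res$lambda
    if (res$p < 0.05) power_hits <- power_hits + 1
  }
  expect_gte(power_hits / 50, 0.8)
  expect_lt(abs(median(lambdas)), 0.8)

  # degenerate: zero-variance groups with distinct means separate exactly
  sep <- boxcox_group_compare(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_true(sep$separated)
  expect_equal(sep$p, 0)
  expect_error(boxcox_group_compare(c(1, 2, 3), c("a", "a", "b")),
               "at least 2")
})

test_that("back-transformed marginal means preserve ordering", {
  set.seed(55)
  f <- make_features(40, means = c(1, 2, 3, 4), sd = 0.2)
  names(f)[names(f) == "y"] <- "resting"
  for (lam in c(-0.5, 0, 0.5, 1)) {
    fit <- fit_condition_model(f, "resting", random = character(0),
                               lambda = lam)
    expect_equal(order(fit$emmeans$emmean), order(fit$emmeans$response_mean))
  }
})
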