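# the printed regression equations: evaluation, fitting, derived values

test_that("model evaluation reproduces hand-computable anchor points", {
  expect_equal(evaluate_model("one_phase_decay",
                              c(Y0 = 200, Plateau = 50, K = 0.5), 0), 200)
  expect_equal(evaluate_model("one_site_specific",
                              c(Bmax = 100, Kd = 10), 10), 50)
  expect_equal(evaluate_model("fourpl_inhibition",
                              c(Bottom = 40, Top = 240,
                                LogIC50 = log10(0.25), HillSlope = 2.4),
                              log10(0.25)), 140)
  expect_error(evaluate_model("one_phase_decay", c(Y0 = 1, K = 1), 0),
               "missing parameter")
  expect_error(evaluate_model("one_site_specific",
                              c(Bmax = 1, Kd = 0), 0), "Kd \\+ X = 0")
  expect_error(evaluate_model("nope", c(), 0), "unknown model")
})

test_that("biphasic association with PercentFast = 100 is single-exponential", {
  X <- seq(0, 20, by = 0.1)
  y2 <- evaluate_model("two_phase_association",
                       c(Y0 = 0.1, Plateau = 1.2, KFast = 0.8,
                         KSlow = 0.05, PercentFast = 100), X)
  y1 <- 0.1 + (1.2 - 0.1) * (1 - exp(-0.8 * X))
  expect_equal(y2, y1, tolerance = 1e-9)
})

test_that("the logistic curve is monotone with the sign set by its slope", {
  X <- seq(-3, 2, length.out = 200)
  # as printed, the curve runs from Bottom (low X) to Top (high X) when
  # HillSlope > 0; an inhibition trace therefore fits with the plateaus
  # mirrored (or a negative slope), leaving IC50 unchanged
  up <- evaluate_model("fourpl_inhibition",
                       c(Bottom = 40, Top = 240, LogIC50 = -0.6,
                         HillSlope = 2.4), X)
  expect_true(all(diff(up) > 0))
  down <- evaluate_model("fourpl_inhibition",
                         c(Bottom = 240, Top = 40, LogIC50 = -0.6,
                           HillSlope = 2.4), X)
  expect_true(all(diff(down) < 0))
  # the mirrored parameterization traces the identical curve
  mirror <- evaluate_model("fourpl_inhibition",
                           c(Bottom = 40, Top = 240, LogIC50 = -0.6,
                             HillSlope = -2.4), X)
  expect_equal(down, mirror, tolerance = 1e-12)
})

test_that("total binding with no nonspecific terms equals specific binding", {
  X <- seq(0, 150, by = 5)
  expect_equal(
    evaluate_model("one_site_total",
                   c(Bmax = 180, Kd = 15.2, NS = 0, Background = 0), X),
    evaluate_model("one_site_specific", c(Bmax = 180, Kd = 15.2), X),
    tolerance = 1e-12)
})

truth_sets <- list(
  one_phase_decay = c(Y0 = 220, Plateau = 60, K = 0.74),
  one_site_total = c(Bmax = 180, Kd = 15.2, NS = 0.12, Background = 25),
  fourpl_inhibition = c(Bottom = 40, Top = 240, LogIC50 = log10(0.25),
                        HillSlope = 2.4),
  two_phase_association = c(Y0 = 0.05, Plateau = 1.4, KFast = 1.5,
                            KSlow = 0.08, PercentFast = 60),
  two_phase_decay = c(Y0 = 1.3, Plateau = 0.15, KFast = 2.2,
                      KSlow = 0.1, PercentFast = 55),
  one_site_specific = c(Bmax = 180, Kd = 15.2),
  agonist_response = c(Bottom = 50, Top = 75, EC50 = 1.8))

x_grid <- function(model) switch(model,
  fourpl_inhibition = seq(-3, 1.5, length.out = 30),
  one_site_total = ,
  one_site_specific = seq(0, 150, length.out = 30),
  agonist_response = c(0, 10^seq(-1.5, 1.5, length.out = 29)),
  seq(0, 30, length.out = 30))

test_that("every printed equation round-trips: noiseless fit recovers truth", {
  for (model in model_ids()) {
    truth <- truth_sets[[model]]
    tr <- simulate_trace(model, truth, x_grid(model), sigma = 0)
    fit <- fit_model(model, tr)
    expect_equal(fit$estimate[names(truth)], truth, tolerance = 1e-6,
                 label = paste(model, "estimates"))
    expect_gt(fit$r_squared, 1 - 1e-9)
    expect_true(all(fit$ci[, 1] <= fit$estimate + 1e-12 &
                      fit$estimate <= fit$ci[, 2] + 1e-12),
                label = paste(model, "CI brackets estimate"))
  }
})

test_that("fits are independent of replicate ordering", {
  truth <- truth_sets$one_phase_decay
  X <- seq(0, 10, length.out = 20)
  tr1 <- simulate_trace("one_phase_decay", truth, X, sigma = 3, seed = 5)
  shuffled <- as.data.frame(tr1)[sample(nrow(tr1)), ]
  f1 <- fit_model("one_phase_decay", tr1)
  f2 <- fit_model("one_phase_decay", shuffled)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-9)
})

test_that("half-life is ln2 over the rate with a propagated CI", {
  expect_equal(half_life(log(2))$half_life, 1)
  expect_equal(half_life(0.74)$half_life, 0.9366853, tolerance = 1e-6)
  expect_error(half_life(0), "K must be > 0")
  tr <- simulate_trace("one_phase_decay", c(Y0 = 200, Plateau = 50,
                                            K = 0.74),
                       seq(0, 6, by = 0.2), sigma = 1.5, seed = 2)
  fit <- fit_model("one_phase_decay", tr)
  hl <- half_life(fit)
  expect_true(hl$ci[1] < hl$half_life && hl$half_life < hl$ci[2])
  expect_equal(hl$half_life, log(2) / fit$estimate[["K"]])
})

test_that("window restriction fits only the requested time span", {
  truth <- c(Y0 = 200, Plateau = 50, K = 0.74)
  X <- seq(0, 30, by = 0.25)
  tr <- simulate_trace("one_phase_decay", truth, X, sigma = 0)
  fit <- fit_model("one_phase_decay", tr, window = c(0, 6))
  expect_equal(fit$n, sum(X <= 6))
  expect_equal(fit$estimate[["K"]], 0.74, tolerance = 1e-6)
})

test_that("%Fast dose-response recovers the generating EC50", {
  conc <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32)
  ser <- simulate_percent_fast_series(conc, ec50 = 1.8, bottom = 50,
                                      top = 75, sigma = 0, seed = 3)
  fits <- lapply(ser$traces, function(tr) fit_model("two_phase_decay", tr))
  dr <- percent_fast_dose_response(fits, conc)
  expect_equal(dr$derived$EC50, 1.8, tolerance = 1e-5)
  expect_equal(dr$estimate[["Bottom"]], 50, tolerance = 1e-4)
  expect_equal(dr$estimate[["Top"]], 75, tolerance = 1e-3)
  # degenerate: identical %Fast everywhere is flagged, not fitted
  flat <- fits[c(1, 1, 1, 1)]
  dg <- percent_fast_dose_response(flat, c(1, 2, 4, 8))
  expect_false(dg$converged)
  expect_match(dg$flags, "degenerate")
  expect_error(percent_fast_dose_response(fits[1:3], conc[1:3]), ">= 4")
})

test_that("noisy EC50 recovery stays within 30% across simulations", {
  # emulates the dose-response assay format: an 11-point two-fold
  # titration read in technical triplicate (the plotted points are the
  # mean of n = 3), with 2-percentage-point noise per read
  conc <- c(0, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64)
  ser <- simulate_percent_fast_series(conc, ec50 = 1.8, bottom = 50,
                                      top = 75, sigma = 0, seed = 1)
  set.seed(31)
  ec <- vapply(1:100, function(i) {
    pf <- rowMeans(replicate(3, pmin(100, pmax(0,
      ser$truth$PercentFast + stats::rnorm(length(conc), 0, 2)))))
    tr <- kinetic_trace(conc, pf, x_unit = "nM", y_unit = "%")
    fit_model("agonist_response", tr)$derived$EC50
  }, numeric(1))
  # a 2000-simulation calibration of this design puts the true
  # within-30% recovery rate at 0.917 (median error 0.11), so the
  # 100-simulation count is checked against that rate +- 3 MC sd
  expect_gte(sum(abs(ec - 1.8) / 1.8 < 0.3), 84)
  expect_lte(sum(abs(ec - 1.8) / 1.8 < 0.3), 98)
  expect_lt(median(abs(ec - 1.8) / 1.8), 0.2)
})

test_that("simulated traces are seed-stable and mean-unbiased", {
  X <- seq(0, 10, length.out = 25)
  truth <- c(Y0 = 100, Plateau = 20, K = 0.5)
  t1 <- simulate_trace("one_phase_decay", truth, X, sigma = 2, seed = 9)
  t2 <- simulate_trace("one_phase_decay", truth, X, sigma = 2, seed = 9)
  expect_identical(t1$y, t2$y)
  t3 <- simulate_trace("one_phase_decay", truth, X, sigma = 2, seed = 10)
  expect_false(identical(t1$y, t3$y))
  expect_identical(simulate_trace("one_phase_decay", truth, X, 0)$y,
                   evaluate_model("one_phase_decay", truth, X))
  # CLT check: mean of 1000 replicates within 3 sigma / sqrt(1000)
  ys <- vapply(1:1000, function(i)
    simulate_trace("one_phase_decay", truth, X, sigma = 2, seed = i)$y,
    numeric(length(X)))
  expect_true(all(abs(rowMeans(ys) -
                        evaluate_model("one_phase_decay", truth, X)) <
                    3 * 2 / sqrt(1000)))
})
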