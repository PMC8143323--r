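test_that("curve constructor enforces the data contract", {
  expect_error(concentration_curve(1:3, c(1, 2, 1)), "at least 4")
  expect_error(concentration_curve(c(0, 1, 1, 2), rep(1, 4)), "strictly increasing")
  expect_error(concentration_curve(0:3, c(1, -1, 1, 1)), "non-negative")
  expect_s3_class(concentration_curve(0:3, c(0, 2, 1, 0.5)), "concentration_curve")
})

test_that("terminal-phase selection takes all strictly post-peak positive points", {
  cv <- concentration_curve(0:5, c(5, 4, 3, 2, 1, 0.5))
  expect_identical(select_terminal_phase(cv), 2:6)
  # monotone increasing curve has no post-absorption phase
  up <- concentration_curve(0:4, 1:5)
  expect_error(select_terminal_phase(up), "0 post-peak")
  # Bateman sampled on the documented grid: peak falls between samples, the
  # observed-peak sample (t = 2) is excluded by the strictly-after rule
  tt <- c(0, 0.5, 1, 2, 4, 8, 12, 24, 36, 48)
  cc <- bateman_concentration(tt, 100, 1, 10, ka = 2, ke = 0.1)
  cv2 <- concentration_curve(tt, cc)
  expect_identical(which.max(cc), 4L)  # observed peak is the t = 2 sample
  expect_identical(select_terminal_phase(cv2), 5:10)
  # insufficient points reports the count found
  short <- concentration_curve(0:4, c(0, 5, 4, 3, 2))
  expect_error(select_terminal_phase(short, min_points = 4), "3 post-peak")
})

test_that("terminal slope recovers ke from log-linear data", {
  tt <- c(4, 6, 8, 10, 12)
  cv <- concentration_curve(c(0, 1, tt), c(0, 11, 10 * exp(-0.2 * tt)))
  fit <- fit_terminal_slope(cv, 3:7)
  expect_equal(fit$ke, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$log_intercept, 1, tolerance = 1e-10)  # log10(10)
  # Bateman late samples: absorption term negligible at ka = 2, t >= 12
  tt2 <- c(0, 1, 2, 12, 18, 24, 36, 48)
  cc2 <- bateman_concentration(tt2, 100, 1, 10, 2, 0.1)
  fit2 <- fit_terminal_slope(concentration_curve(tt2, cc2), 4:8)
  expect_equal(fit2$ke, 0.1, tolerance = 0.01)
  expect_error(fit_terminal_slope(cv, 1:3), "positive concentrations")
})

test_that("mean recovered ke is unbiased under multiplicative noise", {
  tt <- c(12, 18, 24, 36, 48)
  base <- bateman_concentration(tt, 100, 1, 10, 2, 0.1)
  kes <- vapply(1:500, function(s) {
    set.seed(s)
    cc <- base * exp(0.05 * rnorm(5))
    cv <- concentration_curve(c(0, 1, 2, tt), c(0, 1, 2, cc))
    fit_terminal_slope(cv, 4:8)$ke
  }, numeric(1))
  expect_lt(abs(mean(kes) - 0.1) / 0.1, 0.02)
})

test_that("full extraction recovers the generating parameters on a dense grid", {
  sc <- noise_free_scenario(ka = 1, ke = 0.1, dose = 100, f = 1, vd = 10,
                            schedule = seq(0, 72, by = 0.01))
  p <- extract_pk(simulate_curve(sc, "control"))
  expect_equal(p$ka, 1, tolerance = 0.01)
  expect_equal(p$ke, 0.1, tolerance = 0.01)
  expect_equal(p$auc, 100, tolerance = 0.01)  # f*dose/(vd*ke)
  expect_identical(p$branch, "absorption_limited")
})

test_that("a provided tabulated Tmax takes precedence over the observed peak", {
  tt <- c(0, 0.5, 1, 2, 4, 8, 12, 24, 36, 48)
  cc <- bateman_concentration(tt, 100, 1, 10, 1, 0.1)
  cv <- concentration_curve(tt, cc)
  p <- extract_pk(cv, tmax_source = "provided", provided_tmax = log(10) / 0.9)
  expect_equal(p$ka, 1, tolerance = 0.02)  # ke carries small grid error
  expect_error(extract_pk(cv, tmax_source = "provided"), "provided_tmax")
})

test_that("extraction fails cleanly when the peak is the last positive sample", {
  cv <- concentration_curve(0:4, c(0, 1, 2, 3, 4))
  expect_error(extract_pk(cv), "post-peak")
})

test_that("parameter recovery holds across 200 noisy synthetic scenarios", {
  set.seed(7)
  ratios <- exp(stats::runif(200, log(2), log(50)))
  ka_err <- numeric(200); ke_err <- numeric(200)
  for (i in 1:200) {
    ke <- stats::runif(1, 0.05, 0.3)
    ka <- ke * ratios[i]
    tmax <- tmax_forward(ka, ke)
    t_half <- log(2) / ke
    n_early <- 6
    schedule <- unique(round(c(0, seq(tmax / 3, 2 * tmax, length.out = n_early),
                               seq(3 * tmax, tmax + 5 * t_half, length.out = 6)), 3))
    sc <- simulation_scenario(true_ka = ka, true_ke = ke, dose = 100, f = 0.9,
                              vd = 50, schedule = schedule,
                              noise_model = "proportional_lognormal",
                              sigma = 0.05, seed = i)
    p <- extract_pk(simulate_curve(sc, "control", subject = 1))
    ka_err[i] <- abs(p$ka - ka) / ka
    ke_err[i] <- abs(p$ke - ke) / ke
  }
  expect_lt(stats::median(ka_err), 0.10)
  expect_lt(stats::median(ke_err), 0.03)
})

test_that("trapezoid-plus-tail exposure converges as sampling densifies", {
  errs <- vapply(c(0.8, 0.4, 0.2, 0.1), function(dt) {
    sc <- noise_free_scenario(schedule = seq(0, 72, by = dt))
    abs(extract_pk(simulate_curve(sc, "control"))$auc - 100)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # asymptotically second order: error ratio approaches 4 when dt halves
  expect_gt(errs[3] / errs[4], 3)
})

test_that("extraction is scale invariant where it should be", {
  tt <- dense_schedule()
  cc <- bateman_concentration(tt, 100, 1, 10, 1.5, 0.12)
  p1 <- extract_pk(concentration_curve(tt, cc))
  p2 <- extract_pk(concentration_curve(tt, 7.3 * cc))
  expect_equal(p2$ka, p1$ka, tolerance = 1e-9)
  expect_equal(p2$ke, p1$ke, tolerance = 1e-9)
  expect_equal(p2$tmax, p1$tmax)
  expect_equal(p2$cmax, 7.3 * p1$cmax, tolerance = 1e-12)
  expect_equal(p2$auc, 7.3 * p1$auc, tolerance = 1e-9)
})

test_that("curve CSV reading handles per-arm and long formats", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  cv <- concentration_curve(0:5, c(0, 3, 2, 1, 0.5, 0.2), fq = "drug")
  write_curve(cv, f1)
  back <- read_curves(f1, fq = "drug")
  expect_equal(back$times, cv$times)
  expect_equal(back$concentrations, cv$concentrations)
  f2 <- withr::local_tempfile(fileext = ".csv")
  long <- rbind(data.frame(arm = "control", time_h = 0:5, conc_ug_ml = c(0, 3, 2, 1, 0.5, 0.2)),
                data.frame(arm = "treatment", time_h = 0:5, conc_ug_ml = c(0, 1, 0.7, 0.3, 0.2, 0.1)))
  utils::write.csv(long, f2, row.names = FALSE)
  curves <- read_curves(f2)
  expect_named(curves, c("control", "treatment"))
  expect_error(read_curves(withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")),
               "time_h")
})
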