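test_that("kink law reproduces hand values, symmetry and its asymptote", {
  expect_equal(kink_mass(0, B = 0.2, a = 1, A_scale = 1, t0 = 0), 0.2)
  expect_equal(kink_mass(1, B = 0, a = 1, A_scale = 1, t0 = 0), tanh(1))
  # antisymmetry about (t0, B)
  d <- seq(0.5, 400, length.out = 40)
  expect_equal(kink_mass(30 + d, 0.16, 0.74, 106.8, 30) +
                 kink_mass(30 - d, 0.16, 0.74, 106.8, 30),
               rep(2 * 0.16, 40))
  # asymptote B + a once the argument saturates
  expect_equal(kink_mass(1e6, 0.16, 0.74, 106.8, 30), 0.9, tolerance = 1e-6)
  expect_error(kink_mass(1, B = 0, a = -1, A_scale = 1),
               class = "ocurel_domain_error")
})

test_that("classical baselines evaluate to their closed forms", {
  expect_equal(classical_release("higuchi", 4, list(kH = 0.1)), 0.2)
  t <- seq(0, 300, by = 10)
  expect_equal(classical_release("korsmeyer-peppas", t,
                                 list(k = 0.1, n = 0.5)),
               classical_release("higuchi", t, list(kH = 0.1)))
  expect_equal(classical_release("weibull", 120,
                                 list(Minf = 0.9, lambda = 120, b = 1)),
               0.9 * (1 - exp(-1)))
  # Hixson-Crowell clips at complete dissolution
  hc <- classical_release("hixson-crowell", c(100, 500, 800),
                          list(M0 = 0.9, kHC = 1 / 500))
  expect_equal(hc[2], 0.9)
  expect_equal(hc[3], 0.9)
  expect_lt(hc[1], 0.9)
  expect_error(classical_release("zeroth-order", 1, list()))
})

test_that("kink fit recovers exact parameters from a noiseless curve", {
  truth <- default_kink_params()
  curve <- synth_release_curve(times_min = default_release_grid(),
                               noise_sd = 0, seed = 1)
  fit <- suppressMessages(fit_kink(curve))
  expect_true(fit$converged)
  for (nm in names(truth)) {
    expect_rel(fit$params[[nm]], truth[[nm]], 1e-6)
  }
  expect_lt(fit$rss, 1e-12)
  expect_error(fit_kink(curve[1:4, ]), class = "ocurel_domain_error")
  flat <- release_curve(1:10, rep(0.5, 10))
  expect_error(suppressMessages(fit_kink(flat)),
               class = "ocurel_domain_error")
})

test_that("kink fit on a noisy curve recovers the plateau and tracks the truth", {
  truth <- default_kink_params()
  curve <- synth_release_curve(times_min = default_release_grid(),
                               noise_sd = 0.018, seed = 404)
  fit <- fit_kink(curve)
  expect_true(fit$converged)
  plateau_true <- truth$B + truth$a
  expect_rel(fit$params$B + fit$params$a, plateau_true, 0.02)
  # fitted curve stays within the noise floor of the truth
  tg <- seq(0, 4320, by = 10)
  rmse <- sqrt(mean((kink_mass(tg, fit$params$B, fit$params$a,
                               fit$params$A_scale, fit$params$t0) -
                       kink_mass(tg, truth$B, truth$a, truth$A_scale,
                                 truth$t0))^2))
  expect_lt(rmse, 0.018)
})

test_that("tidy and glance expose release-fit parameters and statistics", {
  curve <- synth_release_curve(times_min = default_release_grid(),
                               noise_sd = 0, seed = 2)
  fit <- suppressMessages(fit_kink(curve))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("B", "a", "A_scale", "t0"))
  gl <- glance(fit)
  expect_equal(gl$model, "kink")
  expect_true(gl$converged)
  expect_lte(gl$r_squared, 1)
})

test_that("model comparison ranks the generating model first at low noise", {
  grid <- default_release_grid()
  specs <- study_model_params()
  for (m in names(specs)) {
    truth_curve <- classical_release(m, grid, specs[[m]])
    cv <- synth_release_curve(model = m, params = specs[[m]],
                              times_min = grid,
                              noise_sd = 0.005 * max(truth_curve),
                              seed = 301)
    set <- fit_release_models(cv)
    expect_equal(set$comparison$model[[1]], m)
    expect_equal(nrow(set$comparison), 5)
    expect_true(all(diff(set$comparison$aicc) >= 0))
  }
})

test_that("model ranking is invariant to a minutes-to-hours rescale", {
  grid <- default_release_grid()
  cv <- synth_release_curve(times_min = grid, noise_sd = 0.01, seed = 77)
  rank_min <- fit_release_models(cv)$comparison$model
  cv_h <- release_curve(cv$time_min / 60, cv$mean_release,
                        sd_release = cv$sd_release, drug = "kink-hours")
  rank_h <- fit_release_models(cv_h)$comparison$model
  expect_equal(rank_h, rank_min)
})

test_that("glance on a model set returns the ranked comparison", {
  cv <- synth_release_curve(times_min = default_release_grid(),
                            noise_sd = 0.01, seed = 5)
  set <- fit_release_models(cv, models = c("kink", "higuchi"))
  expect_equal(nrow(glance(set)), 2)
  expect_equal(nrow(tidy(set)), 5) # 4 kink + 1 higuchi parameters
})

test_that("absorbance preprocessing applies calibration and sampling correction", {
  cal <- list(slope = 0.05, intercept = 0)
  abs_tab <- tibble::tibble(time_min = c(30, 60, 120),
                            absorbance = c(0.5, 0.5, 0.5))
  # concentration 10 ug/mL throughout, 50 mL bath, no sampling loss
  out <- release_from_absorbance(abs_tab, cal, bath_volume_mL = 50)
  expect_equal(out$mean_release, rep(500, 3))
  # 2 mL withdrawn and replaced: running correction accumulates
  out2 <- release_from_absorbance(abs_tab, cal, bath_volume_mL = 50,
                                  sample_volume_mL = 2)
  expect_equal(out2$mean_release, c(500, 520, 540))
  # all-zero absorbances give an all-zero curve
  zero <- release_from_absorbance(
    tibble::tibble(time_min = 1:3, absorbance = 0), cal, 50)
  expect_equal(zero$mean_release, rep(0, 3))
  # below-intercept absorbance clips with a warning
  expect_warning(
    release_from_absorbance(
      tibble::tibble(time_min = 1:2, absorbance = c(-0.1, 0.5)), cal, 50),
    "clipped")
  expect_error(release_from_absorbance(abs_tab, list(slope = -1), 50),
               class = "ocurel_domain_error")
})

test_that("cumulative output is nondecreasing for nondecreasing concentrations", {
  withr::with_seed(31, {
    a <- cumsum(runif(20, 0, 0.05))
    out <- release_from_absorbance(
      tibble::tibble(time_min = seq(10, 200, by = 10), absorbance = a),
      list(slope = 0.05, intercept = 0), bath_volume_mL = 50,
      sample_volume_mL = 3)
    expect_true(all(diff(out$mean_release) >= 0))
  })
})

test_that("plateau time matches the analytic inversion of the kink law", {
  p <- default_kink_params()
  grid <- default_release_grid()
  curve <- synth_release_curve(times_min = grid, noise_sd = 0, seed = 1)
  t95 <- plateau_time(curve, frac = 0.95)
  # closed-form inversion: plateau estimate equals B + a on this grid
  plateau <- p$B + p$a
  t_exact <- p$t0 + (p$A_scale / p$a) * atanh((0.95 * plateau - p$B) / p$a)
  expect_lt(abs(t95 - t_exact), 1.5) # linear-interpolation error only
  # monotone step curve: the step time
  step <- release_curve(c(0, 10, 20, 30, 40, 50),
                        c(0, 0, 1, 1, 1, 1))
  expect_equal(plateau_time(step, frac = 0.95), 19.5)
  # unbounded ramp has no plateau
  ramp <- release_curve(1:20, seq(0.05, 1, length.out = 20))
  expect_error(plateau_time(ramp), class = "ocurel_no_plateau_error")
})
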