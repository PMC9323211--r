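test_that("coefficient reduction yields the oscillatory normal form or refuses", {
  p <- riccati_from_coefficients(1, 0, -1)
  expect_equal(p$A, 1)
  expect_equal(p$B, 0)
  expect_equal(p$omega, 1)
  expect_error(riccati_from_coefficients(0, 1, 1),
               class = "ocurel_domain_error")
  expect_error(riccati_from_coefficients(1, 0, 1),
               class = "ocurel_nonoscillatory_error")
  expect_error(riccati_params(omega = 1, r = 1),
               class = "ocurel_domain_error")
})

test_that("closed-form solution matches hand evaluation and degenerate cases", {
  # r = 0: constant B + i*A*Omega
  p0 <- riccati_params(omega = 2, r = 0, A = 1.5, B = 0.3)
  z <- riccati_z(c(0, 0.7, 3.1), p0)
  expect_equal(z, rep(0.3 + 3i, 3))
  # phi = pi at t - t0 = pi/2 with Omega = 1: denominator (1-r)^2
  p <- riccati_params(omega = 1, r = 0.5)
  expect_equal(riccati_z(pi / 2, p), 0 + 3i, tolerance = 1e-12)
})

test_that("solution is periodic with period pi/Omega", {
  for (pars in list(c(1.1, 0.1), c(1.5, 0.5), c(14, 0.1), c(28, 0.1))) {
    p <- riccati_params(omega = pars[1], r = pars[2], A = 1.2, B = -0.4,
                        t0 = 0.3)
    t <- seq(0, 3, length.out = 101)
    amp <- p$A * p$omega
    expect_lt(max(Mod(riccati_z(t + pi / p$omega, p) - riccati_z(t, p))),
              1e-9 * amp)
  }
})

test_that("period means, extrema and imaginary bounds match their closed forms", {
  # <Re z> = B and <Im z> = A*Omega over one period (Poisson-kernel
  # integral); extrema B +/- 2*A*Omega*r/(1 - r^2) against refined grid
  # search; Im z within [A*Omega*(1-r)/(1+r), A*Omega*(1+r)/(1-r)]
  grid_pts <- expand.grid(omega = c(1.1, 1.5, 5, 14, 28),
                          r = c(0.1, 0.3, 0.5, 0.9))
  for (i in seq_len(nrow(grid_pts))) {
    om <- grid_pts$omega[i]
    r <- grid_pts$r[i]
    p <- riccati_params(omega = om, r = r, A = 1.3, B = 0.4, t0 = 0.2)
    per <- pi / om
    tg <- seq(0, per, length.out = 4001)[-4001]
    z <- riccati_z(tg, p)
    expect_rel(mean(Re(z)), p$B, 1e-6)
    expect_rel(mean(Im(z)), p$A * om, 1e-6)
    closed_max <- p$B + 2 * p$A * om * r / (1 - r^2)
    f <- function(t) Re(riccati_z(t, p))
    i_max <- which.max(Re(z))
    refined <- optimize(f, c(tg[max(i_max - 1, 1)],
                             tg[min(i_max + 1, length(tg))]),
                        maximum = TRUE, tol = 1e-14)$objective
    expect_rel(refined, closed_max, 1e-8)
    im <- Im(z)
    lo <- p$A * om * (1 - r) / (1 + r)
    hi <- p$A * om * (1 + r) / (1 - r)
    expect_true(all(im > 0))
    expect_true(all(im >= lo - 1e-12 & im <= hi + 1e-12))
  }
})

test_that("Mobius-transform ODE residual is small and second-order convergent", {
  p <- riccati_params(omega = 1.5, r = 0.5, A = 1, B = 0)
  per <- pi / p$omega
  r1000 <- riccati_ode_residual(p, seq(0, 5 * per, length.out = 5001))
  expect_lt(r1000, 1e-3 * p$omega)
  r500 <- riccati_ode_residual(p, seq(0, 5 * per, length.out = 2501))
  expect_gt(r500 / r1000, 3.5)
  expect_lt(r500 / r1000, 4.5)
  # r = 0 transform is identically zero
  expect_equal(riccati_ode_residual(riccati_params(1, 0), seq(0, 10, 0.01)),
               0)
  expect_error(
    riccati_ode_residual(p, seq(0, 10 * per, length.out = 41)),
    class = "ocurel_resolution_error")
})

test_that("regime sweep produces one bounded series per parameter pair", {
  times <- seq(0, 20, by = 0.01)
  sweep <- riccati_sweep(omega = c(1.1, 14), r = c(0.1, 0.5), times = times)
  expect_equal(nrow(sweep), 4 * length(times))
  expect_equal(nrow(dplyr::distinct(sweep, omega, r)), 4)
  # |Re z - B| <= 2*A*Omega*r/(1 - r^2)
  bounds <- dplyr::summarise(
    dplyr::group_by(sweep, omega, r),
    ok = all(abs(re_z) <= 2 * omega * r / (1 - r^2) + 1e-12))
  expect_true(all(bounds$ok))
  single <- riccati_sweep(1, 0.2, times = 0.5)
  expect_equal(nrow(single), 1)
  expect_error(riccati_sweep(1, 1.2, times), class = "ocurel_domain_error")
})

test_that("regime classification separates small-r harmonics from large-r spikes", {
  times <- seq(0, 8 * pi, by = 0.005)
  near <- riccati_sweep(1, 0.05, times)
  spike <- riccati_sweep(1, 0.9, times)
  out_near <- classify_regime(near)
  out_spike <- classify_regime(spike)
  expect_equal(out_near$label, "near-harmonic")
  # sinusoid duty cycle is 2/3
  expect_rel(out_near$duty_cycle, 2 / 3, 0.05)
  expect_equal(out_spike$label, "spike-train")
  expect_lt(out_spike$duty_cycle, 0.25)
  # deterministic
  expect_identical(classify_regime(near), out_near)
  expect_error(classify_regime(riccati_sweep(1, 0.1, seq(0, 2, 0.01))),
               class = "ocurel_domain_error")
})
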