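test_that("Stokes-Einstein diameter and diffusivity match hand-evaluated values", {
  m298 <- medium_properties(temperature_K = 298)
  # kB*298 / (3*pi*8.9e-4*2.429e-12), evaluated by hand
  expect_rel(hydrodynamic_diameter(2.429e-12, m298), 2.019347e-07, 1e-6)
  expect_rel(diffusion_from_size(100e-9, medium_properties()), 4.907462e-12,
             1e-6)
  # inverse of the first example recovers the input diffusivity
  expect_rel(diffusion_from_size(2.019347e-07, m298), 2.429e-12, 1e-6)
  expect_error(hydrodynamic_diameter(-1e-12, m298),
               class = "ocurel_domain_error")
  expect_error(medium_properties(viscosity_Pa_s = 0),
               class = "ocurel_domain_error")
})

test_that("Stokes-Einstein round trip and homogeneity hold over random inputs", {
  withr::with_seed(11, {
    d <- 10^runif(1000, -9, -6)
    temps <- runif(1000, 277, 320)
    viscs <- 10^runif(1000, -3.2, -2.5)
    for (i in c(1, 250, 500, 1000)) {
      m <- medium_properties(temperature_K = temps[i],
                             viscosity_Pa_s = viscs[i])
      expect_rel(hydrodynamic_diameter(diffusion_from_size(d[i], m), m),
                 d[i], 1e-12)
    }
    m <- medium_properties()
    expect_equal(hydrodynamic_diameter(diffusion_from_size(d, m), m), d,
                 tolerance = 1e-12)
  })
  # degree -1 in D and eta, +1 in T
  m <- medium_properties()
  m2eta <- medium_properties(viscosity_Pa_s = 2 * m$viscosity_Pa_s)
  m2T <- medium_properties(temperature_K = 2 * m$temperature_K)
  expect_equal(hydrodynamic_diameter(2e-12, m2eta),
               hydrodynamic_diameter(2e-12, m) / 2)
  expect_equal(hydrodynamic_diameter(4e-12, m),
               hydrodynamic_diameter(2e-12, m) / 2)
  expect_equal(hydrodynamic_diameter(2e-12, m2T),
               hydrodynamic_diameter(2e-12, m) * 2)
  # smaller diameter => larger diffusivity
  dd <- sort(10^runif(50, -9, -6))
  expect_true(all(diff(diffusion_from_size(dd, m)) < 0))
})

test_that("Smoluchowski zeta conversion is linear and odd in mobility", {
  m <- medium_properties()
  expect_rel(zeta_from_mobility(2e-8, m), 2.561151e-2, 1e-6)
  expect_equal(zeta_from_mobility(0, m), 0)
  expect_equal(zeta_from_mobility(-2e-8, m), -zeta_from_mobility(2e-8, m))
})

test_that("stability screen applies size, PDI and RI rules", {
  rec <- function(size, pdi, ri = NA_real_) {
    tibble::tibble(label = "x", size_nm = size, pdi = pdi,
                   refractive_index = ri)
  }
  expect_true(stability_screen(rec(181, 0.072, 1.35))$passed)
  s <- stability_screen(rec(600, 0.2))
  expect_false(s$passed)
  expect_equal(s$violations[[1]]$rule, "size_nm")
  s <- stability_screen(rec(300, 0.35))
  expect_equal(s$violations[[1]]$rule, "pdi")
  # RI rule: inclusive bound, skipped when absent
  expect_true(stability_screen(rec(300, 0.2, 1.476))$passed)
  expect_false(stability_screen(rec(300, 0.2, 1.477))$passed)
  expect_true(stability_screen(rec(499.9, 0.299))$passed)
  expect_false(stability_screen(rec(500, 0.2))$passed)
})

test_that("stability screen is monotone: worsening a field never rescues a failure", {
  base <- tibble::tibble(label = "x", size_nm = 400, pdi = 0.25,
                         refractive_index = 1.4)
  worse <- list(
    dplyr::mutate(base, size_nm = 550),
    dplyr::mutate(base, pdi = 0.31),
    dplyr::mutate(base, refractive_index = 1.5)
  )
  for (w in worse) {
    expect_false(stability_screen(w)$passed)
    # worsening a second field keeps it failing
    expect_false(stability_screen(dplyr::mutate(w, size_nm = 700))$passed)
  }
})

test_that("formulation selection picks the smallest-size PDI-eligible record", {
  tab <- fixture_formulations()
  expect_equal(nrow(tab), 4)
  expect_equal(select_formulation(tab), "PE2")
  expect_equal(tab$size_nm[tab$label == "PE2"], 136)
  # permutation invariance
  expect_equal(select_formulation(tab[c(3, 1, 4, 2), ]), "PE2")
  # singleton
  expect_equal(select_formulation(tab[1, ]), "PE0")
  # equal size: lower PDI wins
  tie <- tibble::tibble(label = c("a", "b"), ctab_pct = c(1, 2),
                        size_nm = c(150, 150), pdi = c(0.2, 0.1))
  expect_equal(select_formulation(tie), "b")
  # no eligible record
  bad <- tibble::tibble(label = "a", size_nm = 100, pdi = 0.4)
  expect_error(select_formulation(bad), class = "ocurel_selection_error")
  expect_error(select_formulation(tab[0, ]), class = "ocurel_format_error")
})
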