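#' Default Kink parameters and time grid for synthetic release studies
#'
#' The default synthetic release study mirrors the design of the dialysis
#' release experiments the package analyses: fractional release with a
#' plateau at 0.9 of the dose, a small (~1%) initial burst, an inflection
#' lag of 30 min and a rise scaled so that 95% of the plateau is reached
#' near 280 min -- inside the 200-360 min window in which these
#' layer-by-layer formulations release their payload. The default grid
#' covers 72 h with dense sampling before 600 min.
#'
#' @return `default_kink_params()`: a named list `B, a, A_scale, t0`;
#'   `default_release_grid()`: a numeric vector of times in minutes.
#' @export
default_kink_params <- function() {
  list(B = 0.1612, a = 0.7388, A_scale = 106.8, t0 = 30)
}

#' @rdname default_kink_params
#' @export
default_release_grid <- function() {
  c(seq(0, 600, by = 15), seq(660, 4320, by = 180))
}

synth_models <- c("kink", "korsmeyer-peppas", "higuchi", "hixson-crowell",
                  "weibull")

#' Generate a seeded synthetic release curve
#'
#' Draws `n_replicates` noisy realisations of a chosen release model
#' (i.i.d. Gaussian noise per time point per replicate) and returns the
#' replicate-averaged curve with per-time SDs. With `noise_sd = 0` the mean
#' equals the model exactly and all SDs are zero. Identical seeds give
#' identical curves.
#'
#' @param model One of `"kink"`, `"korsmeyer-peppas"`, `"higuchi"`,
#'   `"hixson-crowell"`, `"weibull"`.
#' @param params Named list of model parameters (see
#'   [classical_release()]); defaults to [default_kink_params()] for the
#'   kink model.
#' @param times_min Sampling grid; default [default_release_grid()].
#' @param noise_sd Replicate noise SD in release units. The default, 0.018,
#'   is 2% of the default 0.9 plateau.
#' @param n_replicates Number of replicates (default 3, the usual release
#'   study design).
#' @param seed Integer seed; required.
#' @param drug Identifier for the curve.
#' @return A [release_curve()] (`units = "fraction"` for the default
#'   parameter scale).
#' @examples
#' synth_release_curve(seed = 1)
#' @export
synth_release_curve <- function(model = "kink", params = NULL,
                                times_min = default_release_grid(),
                                noise_sd = 0.018, n_replicates = 3L,
                                seed, drug = model) {
  model <- match.arg(model, synth_models)
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is required for synthetic generation.",
          class = "ocurel_domain_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be nonnegative.", class = "ocurel_domain_error")
  }
  if (is.null(params)) {
    if (model != "kink") {
      abort("`params` must be supplied for non-kink models.",
            class = "ocurel_domain_error")
    }
    params <- default_kink_params()
  }
  truth <- classical_release(model, times_min, params)
  reps <- withr::with_seed(as.integer(seed), {
    matrix(rnorm(length(times_min) * n_replicates, mean = truth,
                 sd = noise_sd),
           nrow = length(times_min), ncol = n_replicates)
  })
  m <- rowMeans(reps)
  s <- if (n_replicates > 1) apply(reps, 1, sd) else rep(0, length(times_min))
  units <- if (max(truth) <= 1.05) "fraction" else "ug"
  release_curve(times_min, pmax(m, 0),
                sd_release = s, drug = drug, units = units,
                n_replicates = n_replicates)
}

#' Generate the three-drug synthetic release panel
#'
#' Produces pilocarpine-like, dexamethasone-like and bevacizumab-like
#' release curves sharing the default Kink backbone and time grid but with
#' strictly increasing high-frequency roughness amplitude in ratio 1:2:4
#' (base 1% of the plateau). The roughness is added to the mean curve
#' itself -- it emulates the drug-specific irregularity of measured release
#' curves, not replicate noise -- so the fractality degree of the panel is
#' decidable and ordered bevacizumab > dexamethasone > pilocarpine.
#'
#' @param seed Integer seed.
#' @param base_roughness_sd Roughness SD for the smoothest
#'   (pilocarpine-like) curve, in release units. Default `0.009` (1% of the
#'   0.9 plateau).
#' @param times_min Uniform grid; default 256 points spanning 0-765 min
#'   (3-min spacing), uniform so both fractality estimators apply.
#' @return A named list of three [release_curve()]s
#'   (`pilocarpine`, `dexamethasone`, `bevacizumab`).
#' @export
synth_drug_panel <- function(seed, base_roughness_sd = 0.009,
                             times_min = seq(0, 765, by = 3)) {
  if (missing(seed)) {
    abort("`seed` is required.", class = "ocurel_domain_error")
  }
  p <- default_kink_params()
  backbone <- kink_mass(times_min, p$B, p$a, p$A_scale, p$t0)
  mult <- c(pilocarpine = 1, dexamethasone = 2, bevacizumab = 4)
  curves <- withr::with_seed(as.integer(seed), {
    purrr::imap(mult, function(m, drug) {
      rough <- rnorm(length(times_min), sd = base_roughness_sd * m)
      release_curve(times_min, pmax(backbone + rough, 0),
                    sd_release = rep(base_roughness_sd * m,
                                     length(times_min)),
                    drug = drug, units = "fraction")
    })
  })
  curves
}

#' Generate a seeded DLS size sample with target mean and PDI
#'
#' Draws a lognormal particle-size sample whose theoretical mean equals
#' `mean_nm` and whose polydispersity index -- in the DLS cumulant
#' convention `PDI = variance / mean^2` -- equals `pdi`
#' (`sigma^2 = log(1 + pdi)`). The summary statistics are recomputed from
#' the sample.
#'
#' @param mean_nm Target mean diameter in nm, positive.
#' @param pdi Target PDI in `[0, 0.5)`.
#' @param n Sample size, at least 100.
#' @param seed Integer seed.
#' @return A list with `sizes_nm` (length-`n` sample), `mean_nm` and `pdi`
#'   (sample statistics).
#' @examples
#' s <- synth_dls_sizes(209, 0.281, n = 1e4, seed = 7)
#' s$mean_nm; s$pdi
#' @export
synth_dls_sizes <- function(mean_nm, pdi, n = 1000L, seed) {
  if (mean_nm <= 0) {
    abort("`mean_nm` must be positive.", class = "ocurel_domain_error")
  }
  if (pdi < 0 || pdi >= 0.5) {
    abort("`pdi` must lie in [0, 0.5).", class = "ocurel_domain_error")
  }
  if (n < 100) {
    abort("`n` must be at least 100.", class = "ocurel_domain_error")
  }
  sigma2 <- log(1 + pdi)
  mu <- log(mean_nm) - sigma2 / 2
  sizes <- withr::with_seed(as.integer(seed),
                            exp(rnorm(n, mean = mu, sd = sqrt(sigma2))))
  list(sizes_nm = sizes, mean_nm = mean(sizes),
       pdi = var(sizes) / mean(sizes)^2)
}

#' Generate a layer-by-layer coating sequence
#'
#' Emulates the size growth and zeta-potential charge inversion of
#' layer-by-layer polyelectrolyte deposition: starting from the core, each
#' polyanion layer (hyaluronate/heparin) flips the surface negative and
#' each chitosan layer flips it positive; sizes never decrease step to
#' step. Zeta magnitudes are drawn uniformly within 5-50 mV.
#'
#' @param core_zeta_mV Zeta potential of the uncoated core (its sign sets
#'   step 0).
#' @param n_layers Number of deposited layers, `>= 1`; layers alternate
#'   polyanion, chitosan, polyanion, ...
#' @param seed Integer seed.
#' @param core_size_nm Core diameter in nm (default 136).
#' @return A tibble with one row per step (`step` 0 = core):
#'   `step, layer, size_nm, zeta_mV`.
#' @export
synth_lbl_series <- function(core_zeta_mV, n_layers, seed,
                             core_size_nm = 136) {
  if (n_layers < 1) {
    abort("`n_layers` must be >= 1.", class = "ocurel_domain_error")
  }
  layers <- rep(c("polyanion", "chitosan"), length.out = n_layers)
  withr::with_seed(as.integer(seed), {
    growth <- runif(n_layers, min = 5, max = 60)
    mags <- runif(n_layers, min = 5, max = 50)
    sign_seq <- ifelse(layers == "polyanion", -1, 1)
    tibble(
      step = 0:n_layers,
      layer = c("core", layers),
      size_nm = cumsum(c(core_size_nm, growth)),
      zeta_mV = c(core_zeta_mV, sign_seq * mags)
    )
  })
}

#' Generate a HET-CAM observation of a requested irritation level
#'
#' Draws onset times from per-category windows chosen so the continuous
#' irritation score lands in the requested category's range; the draw is
#' checked against [classify_irritation()] at generation time.
#'
#' @param level One of `"non-irritant"`, `"less irritant"`,
#'   `"moderate irritant"`, `"severe irritant"`.
#' @param seed Integer seed.
#' @return A one-row tibble `h_s, l_s, c_s, score, category`.
#' @export
synth_hetcam <- function(level = hetcam_categories, seed) {
  level <- match.arg(level)
  window <- switch(level,
    "non-irritant" = c(290, 301),
    "less irritant" = c(240, 283),
    "moderate irritant" = c(180, 225),
    "severe irritant" = c(1, 150)
  )
  obs <- withr::with_seed(as.integer(seed), {
    tibble(h_s = runif(1, window[1], window[2]),
           l_s = runif(1, window[1], window[2]),
           c_s = runif(1, window[1], window[2]))
  })
  out <- score_hetcam(obs)
  stopifnot(as.character(out$category) == level) # closed-loop check
  out
}
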