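#' Dispersion-medium properties for DLS post-processing
#'
#' Bundles the physical properties of the dispersion medium needed by the
#' Stokes-Einstein and Smoluchowski relations. Defaults correspond to water
#' at 25 degrees C, the usual Zetasizer measurement condition.
#'
#' @param temperature_K Absolute temperature in kelvin. Must be positive.
#' @param viscosity_Pa_s Dynamic viscosity of the medium in Pa s. Must be
#'   positive.
#' @param dielectric_F_per_m Absolute dielectric constant (permittivity) of
#'   the medium in F/m. Note this is the absolute permittivity
#'   `epsilon_0 * epsilon_r`, not the relative one; water at 25 degrees C has
#'   about `6.95e-10` F/m.
#'
#' @return A list of class `medium_properties`.
#' @examples
#' medium_properties()
#' medium_properties(temperature_K = 310.15)
#' @export
medium_properties <- function(temperature_K = 298.15,
                              viscosity_Pa_s = 8.9e-4,
                              dielectric_F_per_m = 6.95e-10) {
  for (nm in c("temperature_K", "viscosity_Pa_s", "dielectric_F_per_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm),
            class = "ocurel_domain_error")
    }
  }
  structure(
    list(temperature_K = temperature_K,
         viscosity_Pa_s = viscosity_Pa_s,
         dielectric_F_per_m = dielectric_F_per_m),
    class = "medium_properties"
  )
}

check_medium <- function(medium) {
  if (!inherits(medium, "medium_properties")) {
    if (is.list(medium) &&
        all(c("temperature_K", "viscosity_Pa_s", "dielectric_F_per_m") %in%
            names(medium))) {
      medium <- medium_properties(medium$temperature_K, medium$viscosity_Pa_s,
                                  medium$dielectric_F_per_m)
    } else {
      abort("`medium` must be created with `medium_properties()`.",
            class = "ocurel_domain_error")
    }
  }
  medium
}

#' Stokes-Einstein hydrodynamic diameter
#'
#' Converts a translational diffusion coefficient measured by dynamic light
#' scattering into a hydrodynamic diameter via the Stokes-Einstein relation
#' `DH = kB * T / (3 * pi * eta * D)`.
#'
#' @param diffusion_m2_s Translational diffusion coefficient in m^2/s.
#'   Vectorised; all values must be positive.
#' @param medium A [medium_properties()] object.
#'
#' @return Hydrodynamic diameter(s) in metres.
#' @seealso [diffusion_from_size()] for the algebraic inverse.
#' @examples
#' m <- medium_properties(temperature_K = 298)
#' hydrodynamic_diameter(2.429e-12, m) * 1e9 # ~202 nm
#' @export
hydrodynamic_diameter <- function(diffusion_m2_s, medium = medium_properties()) {
  medium <- check_medium(medium)
  if (!is.numeric(diffusion_m2_s) || any(!is.finite(diffusion_m2_s)) ||
      any(diffusion_m2_s <= 0)) {
    abort("`diffusion_m2_s` must be positive and finite.",
          class = "ocurel_domain_error")
  }
  BOLTZMANN_J_PER_K * medium$temperature_K /
    (3 * pi * medium$viscosity_Pa_s * diffusion_m2_s)
}

#' Diffusion coefficient from hydrodynamic diameter
#'
#' Inverse of [hydrodynamic_diameter()]: `D = kB * T / (3 * pi * eta * DH)`.
#' Smaller particles diffuse faster, strictly monotonically.
#'
#' @param diameter_m Hydrodynamic diameter(s) in metres; positive.
#' @inheritParams hydrodynamic_diameter
#' @return Diffusion coefficient(s) in m^2/s.
#' @export
diffusion_from_size <- function(diameter_m, medium = medium_properties()) {
  medium <- check_medium(medium)
  if (!is.numeric(diameter_m) || any(!is.finite(diameter_m)) ||
      any(diameter_m <= 0)) {
    abort("`diameter_m` must be positive and finite.",
          class = "ocurel_domain_error")
  }
  BOLTZMANN_J_PER_K * medium$temperature_K /
    (3 * pi * medium$viscosity_Pa_s * diameter_m)
}

#' Zeta potential from electrophoretic mobility (Smoluchowski)
#'
#' Computes `zeta = eta * mu / eps` from electrophoretic mobility. The medium
#' carries the *absolute* dielectric constant; some texts write the same
#' relation as `mu * eta / (eps0 * eps_r)` with a relative permittivity --
#' callers here supply the product directly.
#'
#' @param mobility_m2_Vs Electrophoretic mobility in m^2/(V s). Vectorised;
#'   the sign of the result equals the sign of the mobility.
#' @inheritParams hydrodynamic_diameter
#' @return Zeta potential(s) in volts.
#' @examples
#' zeta_from_mobility(2e-8, medium_properties()) * 1e3 # ~25.6 mV
#' @export
zeta_from_mobility <- function(mobility_m2_Vs, medium = medium_properties()) {
  medium <- check_medium(medium)
  if (!is.numeric(mobility_m2_Vs) || any(!is.finite(mobility_m2_Vs))) {
    abort("`mobility_m2_Vs` must be finite.", class = "ocurel_domain_error")
  }
  medium$viscosity_Pa_s * mobility_m2_Vs / medium$dielectric_F_per_m
}

validate_formulations <- function(records) {
  records <- as_tibble(records)
  required <- c("label", "size_nm", "pdi")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("Formulation table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ocurel_format_error")
  }
  if (nrow(records) == 0) {
    abort("Formulation table has no rows.", class = "ocurel_format_error")
  }
  if (any(!is.finite(records$size_nm)) || any(records$size_nm <= 0)) {
    abort("`size_nm` must be positive.", class = "ocurel_domain_error")
  }
  if (any(!is.finite(records$pdi)) || any(records$pdi < 0)) {
    abort("`pdi` must be nonnegative.", class = "ocurel_domain_error")
  }
  if ("refractive_index" %in% names(records)) {
    ri <- records$refractive_index
    if (any(!is.na(ri) & ri < 1)) {
      abort("`refractive_index` must be >= 1 when present.",
            class = "ocurel_domain_error")
    }
  }
  records
}

#' Read a formulation characterization table
#'
#' Reads a CSV of per-formulation DLS summaries with columns
#' `label, ctab_pct, size_nm, size_sd_nm, pdi, pdi_sd, zeta_mv, zeta_sd_mv`
#' and an optional `refractive_index`. The CTAB pre-emulsion series
#' characterized in the source study ships with the package:
#' `system.file("extdata", "ctab_preemulsions.csv", package = "ocurel")`.
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per formulation.
#' @examples
#' tab <- read_formulation_table(
#'   system.file("extdata", "ctab_preemulsions.csv", package = "ocurel"))
#' tab
#' @export
read_formulation_table <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_formulations(records)
}

#' Screen formulations against colloidal stability limits
#'
#' Applies the rule set used to screen ophthalmic nanoparticle formulations:
#' mean size strictly below `max_size_nm`, polydispersity index strictly
#' below `max_pdi`, and (when a refractive index is reported) refractive
#' index at most `max_ri`. The refractive-index rule is skipped for records
#' without one.
#'
#' @param records A data frame with at least `label`, `size_nm` and `pdi`
#'   columns; `refractive_index` is optional.
#' @param max_size_nm Size limit in nm (strict `<`). Default 500.
#' @param max_pdi PDI limit (strict `<`). Default 0.3.
#' @param max_ri Refractive-index limit (inclusive `<=`). Default 1.476.
#'
#' @return A tibble with columns `label`, `passed`, and a `violations`
#'   list-column; each element is a tibble `rule, value, threshold` with one
#'   row per violated rule. `passed` is `TRUE` iff `violations` is empty.
#' @examples
#' tab <- read_formulation_table(
#'   system.file("extdata", "ctab_preemulsions.csv", package = "ocurel"))
#' stability_screen(tab)
#' @export
stability_screen <- function(records, max_size_nm = 500, max_pdi = 0.3,
                             max_ri = 1.476) {
  records <- validate_formulations(records)
  ri <- if ("refractive_index" %in% names(records)) {
    records$refractive_index
  } else {
    rep(NA_real_, nrow(records))
  }
  violations <- purrr::pmap(
    list(records$size_nm, records$pdi, ri),
    function(size, pdi, ri) {
      v <- tibble(rule = character(), value = double(), threshold = double())
      if (!(size < max_size_nm)) {
        v <- dplyr::add_row(v, rule = "size_nm", value = size,
                            threshold = max_size_nm)
      }
      if (!(pdi < max_pdi)) {
        v <- dplyr::add_row(v, rule = "pdi", value = pdi, threshold = max_pdi)
      }
      if (!is.na(ri) && !(ri <= max_ri)) {
        v <- dplyr::add_row(v, rule = "refractive_index", value = ri,
                            threshold = max_ri)
      }
      v
    }
  )
  tibble(
    label = as.character(records$label),
    passed = purrr::map_lgl(violations, ~ nrow(.x) == 0),
    violations = violations
  )
}

#' Select the lead formulation from a characterization table
#'
#' Among formulations with PDI strictly below `max_pdi`, selects the one
#' with the smallest mean size; ties are broken by lower PDI, then lower
#' CTAB percentage. This is the rule under which the 2% CTAB pre-emulsion
#' (136 nm) is chosen from the packaged CTAB series.
#'
#' @inheritParams stability_screen
#' @return The `label` of the selected formulation (length-1 character).
#' @examples
#' tab <- read_formulation_table(
#'   system.file("extdata", "ctab_preemulsions.csv", package = "ocurel"))
#' select_formulation(tab) # "PE2"
#' @export
select_formulation <- function(records, max_pdi = 0.3) {
  records <- validate_formulations(records)
  eligible <- dplyr::filter(records, .data$pdi < max_pdi)
  if (nrow(eligible) == 0) {
    abort("No formulation satisfies the PDI rule; nothing to select.",
          class = "ocurel_selection_error")
  }
  if (!"ctab_pct" %in% names(eligible)) eligible$ctab_pct <- NA_real_
  chosen <- dplyr::arrange(eligible, .data$size_nm, .data$pdi, .data$ctab_pct)
  as.character(chosen$label[[1]])
}
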