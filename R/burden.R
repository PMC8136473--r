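# Conversion of accepted counts to number densities and to asbestos
# bodies per gram of dry lung, with replicate statistics.

#' Stereological conversion factors
#'
#' Factors linking a count per embedded-tissue volume to a burden per
#' gram of dry lung: `V_s`, the volumetric shrinkage from formalin-fixed
#' to paraffin-embedded tissue (dimensionless, 2.3); `R_wv`, wet tissue
#' weight per unit fixed-tissue volume (0.916 g/cm^3); `D_dw`, the
#' wet-to-dry mass ratio (close to 10 for lung); and `O_c`, the
#' orientation correction for thin-section counting, exactly 1 for true
#' 3D volumes (see [orientation_correction()]).
#'
#' @param V_s shrinkage correction, dimensionless, > 0.
#' @param R_wv wet weight to volume ratio in g/cm^3, > 0.
#' @param D_dw wet-to-dry weight conversion factor, > 0.
#' @param O_c orientation correction factor, >= 1.
#' @return An object of class `ab_conversion_factors`.
#' @export
conversion_factors <- function(V_s = 2.3, R_wv = 0.916, D_dw = 10,
                               O_c = 1) {
  vals <- c(V_s = V_s, R_wv = R_wv, D_dw = D_dw, O_c = O_c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all conversion factors must be strictly positive and finite")
  if (O_c < 1) stop("O_c must be >= 1")
  structure(as.list(vals), class = "ab_conversion_factors")
}

#' Number density over replicate volumes
#'
#' Per-replicate densities `count_i / V_c_i` with their mean and sample
#' standard deviation (n - 1 convention; `NA` for a single replicate).
#'
#' @param counts accepted AB counts, one per replicate volume.
#' @param volumes_cm3 probed physical volumes `V_c` in cm^3, same length.
#' @return An object of class `ab_burden` with fields `densities_cm3`,
#'   `mean_cm3`, `sd_cm3`, `n_replicates`.
#' @export
count_density <- function(counts, volumes_cm3) {
  if (length(counts) == 0L || length(counts) != length(volumes_cm3))
    stop("counts and volumes_cm3 must be non-empty and of equal length")
  if (any(volumes_cm3 <= 0)) stop("all volumes must be strictly positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  dens <- counts / volumes_cm3
  structure(list(densities_cm3 = dens, mean_cm3 = mean(dens),
                 sd_cm3 = if (length(dens) > 1L) sd(dens) else NA_real_,
                 n_replicates = length(dens)),
            class = "ab_burden")
}

#' Orientation correction factor for thin-section counting
#'
#' When bodies are counted in thin 2D sections, a body whose projection
#' normal to the section exceeds the section thickness is seen (and
#' counted) in more than one consecutive section. Under orientations
#' uniform on the sphere, the expected count per section is proportional
#' to `T + L * E|cos(theta)|` with `E|cos(theta)| = 1/2`, giving
#' `O_c = 1 + L / (2 T)`. For a true 3D volume (`section_thickness =
#' Inf`) the factor is exactly 1, independent of length: the 3D count is
#' exact.
#'
#' @param mean_length_um average body length in micrometres, >= 0.
#' @param section_thickness_um section thickness in micrometres, > 0 or
#'   `Inf` for a 3D volume.
#' @return The dimensionless factor `O_c >= 1`.
#' @export
orientation_correction <- function(mean_length_um,
                                   section_thickness_um = Inf) {
  if (mean_length_um < 0) stop("mean_length_um must be >= 0")
  if (section_thickness_um <= 0)
    stop("section_thickness_um must be positive (or Inf for 3D)")
  if (is.infinite(section_thickness_um)) return(1)
  1 + mean_length_um / (2 * section_thickness_um)
}

#' Convert a number density to bodies per gram of dry lung
#'
#' `N_gdw = density * D_dw / (V_s * O_c * R_wv)`, linear in density.
#'
#' @param density_cm3 number density in cm^-3, >= 0.
#' @param factors an [conversion_factors()] object.
#' @return Burden in counts per gram of dry tissue.
#' @examples
#' convert_to_gdw(2.35e6, conversion_factors())  # ~1.12e7 per g_dw
#' @export
convert_to_gdw <- function(density_cm3, factors = conversion_factors()) {
  stopifnot(inherits(factors, "ab_conversion_factors"))
  if (any(density_cm3 < 0)) stop("density must be >= 0")
  density_cm3 * factors$D_dw / (factors$V_s * factors$O_c * factors$R_wv)
}

#' Wet-to-dry weight conversion factor
#'
#' `D_dw = wet_mass / dry_mass`, from weighing a tissue aliquot before
#' and after dehydration.
#'
#' @param wet_mass_g wet tissue mass in grams.
#' @param dry_mass_g dry tissue mass in grams, `0 < dry <= wet`.
#' @return The dimensionless factor `D_dw >= 1`.
#' @export
compute_ddw <- function(wet_mass_g, dry_mass_g) {
  if (dry_mass_g <= 0) stop("dry_mass_g must be strictly positive")
  if (dry_mass_g > wet_mass_g)
    stop("dry mass cannot exceed wet mass")
  wet_mass_g / dry_mass_g
}

#' Compare a burden with the occupational-exposure threshold
#'
#' The European Respiratory Society guideline value indicating a high
#' level of occupational asbestos exposure is 10^3 bodies per gram of
#' dry lung tissue.
#'
#' @param n_gdw burden in counts per gram dry tissue, >= 0.
#' @return `TRUE` iff `n_gdw` strictly exceeds 10^3 per g_dw.
#' @export
classify_exposure <- function(n_gdw) {
  if (any(n_gdw < 0)) stop("n_gdw must be >= 0")
  n_gdw > 1e3
}

#' Full burden result from replicate counts
#'
#' Composes [count_density()] and [convert_to_gdw()] and flags the
#' exposure threshold.
#'
#' @param counts accepted counts per replicate.
#' @param volumes_cm3 probed volumes per replicate, cm^3.
#' @param factors an [conversion_factors()] object.
#' @return An `ab_burden` object extended with `n_gdw` and `exceeds_ers`.
#' @export
burden_result <- function(counts, volumes_cm3,
                          factors = conversion_factors()) {
  b <- count_density(counts, volumes_cm3)
  b$factors <- unclass(factors)
  b$n_gdw <- convert_to_gdw(b$mean_cm3, factors)
  b$exceeds_ers <- classify_exposure(b$n_gdw)
  b
}

#' @export
print.ab_burden <- function(x, ...) {
  cat(sprintf("<ab_burden> %d replicate(s): mean %.3g cm^-3 (SD %.3g)\n",
              x$n_replicates, x$mean_cm3,
              if (is.na(x$sd_cm3)) NA else x$sd_cm3))
  if (!is.null(x$n_gdw))
    cat(sprintf("  N_gdw = %.3g per g dry lung (exceeds ERS 1e3/g_dw: %s)\n",
                x$n_gdw, x$exceeds_ers))
  invisible(x)
}
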