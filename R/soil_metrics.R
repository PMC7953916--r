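#' Soil organic matter by loss on ignition
#'
#' Percent of dry soil mass lost when a dried sample is ignited in a muffle
#' furnace; the combusted fraction approximates soil organic matter.
#'
#' @param dry_mass_g positive numeric: oven-dry sample mass.
#' @param ignited_mass_g nonnegative numeric: mass after ignition (at most the
#'   dry mass).
#' @return percent of dry mass, in \[0, 100\].
#' @export
#' @examples
#' loi_som_percent(30, 28.5)  # 5
loi_som_percent <- function(dry_mass_g, ignited_mass_g) {
  if (anyNA(dry_mass_g) || anyNA(ignited_mass_g)) abort_validation("Missing mass")
  if (any(dry_mass_g <= 0)) abort_validation("Dry mass must be positive")
  if (any(ignited_mass_g < 0)) abort_validation("Ignited mass must be nonnegative")
  if (any(ignited_mass_g > dry_mass_g)) {
    abort_measurement("Ignited mass exceeds dry mass")
  }
  100 * (dry_mass_g - ignited_mass_g) / dry_mass_g
}

#' Fine particulate organic matter as percent of initial soil mass
#'
#' The 53-500 micron fraction is isolated by wet sieving, dried, weighed, and
#' ashed; its organic portion (dry minus ash mass) is expressed as a percent
#' of the initial soil mass.
#'
#' @param initial_soil_mass_g positive numeric: soil mass put through the
#'   sieves (about 30 g in practice).
#' @param fraction_dry_mass_g nonnegative numeric: dried mass of the isolated
#'   fraction.
#' @param fraction_ash_mass_g nonnegative numeric: mass remaining after
#'   ashing the fraction (at most its dry mass).
#' @return percent of initial soil mass.
#' @export
#' @examples
#' fpom_percent(30, 1.2, 0.9)  # 1
fpom_percent <- function(initial_soil_mass_g, fraction_dry_mass_g,
                         fraction_ash_mass_g) {
  if (anyNA(initial_soil_mass_g) || anyNA(fraction_dry_mass_g) ||
      anyNA(fraction_ash_mass_g)) {
    abort_validation("Missing mass")
  }
  if (any(initial_soil_mass_g <= 0)) abort_validation("Initial soil mass must be positive")
  if (any(fraction_ash_mass_g < 0) || any(fraction_dry_mass_g < 0)) {
    abort_validation("Fraction masses must be nonnegative")
  }
  if (any(fraction_ash_mass_g > fraction_dry_mass_g)) {
    abort_measurement("Ash mass exceeds the fraction's dry mass")
  }
  if (any(fraction_dry_mass_g > initial_soil_mass_g)) {
    abort_measurement("Fraction dry mass exceeds initial soil mass")
  }
  100 * (fraction_dry_mass_g - fraction_ash_mass_g) / initial_soil_mass_g
}

#' Bulk density of a cylindrical soil core
#'
#' Dry mass divided by core volume. The field kit uses 8.5 cm deep, 5 cm
#' diameter cores.
#'
#' @param dry_mass_g positive numeric: oven-dry core mass.
#' @param depth_cm positive numeric core depth (default 8.5).
#' @param diameter_cm positive numeric core diameter (default 5).
#' @return bulk density in g/cm^3.
#' @export
#' @examples
#' bulk_density(250)  # 250 / (pi * 2.5^2 * 8.5) = 1.498
bulk_density <- function(dry_mass_g, depth_cm = 8.5, diameter_cm = 5) {
  if (anyNA(dry_mass_g)) abort_validation("Missing dry mass")
  if (any(dry_mass_g <= 0)) abort_validation("Dry mass must be positive")
  if (any(depth_cm <= 0) || any(diameter_cm <= 0)) {
    abort_validation("Core dimensions must be positive")
  }
  dry_mass_g / (pi * (diameter_cm / 2)^2 * depth_cm)
}

#' Single-ring infiltration rate
#'
#' The field kit pours 444 mL into a 15 cm ring (a ~1 inch, 2.51 cm head of
#' water) and times its disappearance; the rate is that depth per elapsed
#' time. Both pours of the protocol can be computed; the second (wet-soil)
#' pour is the conventional headline rate.
#'
#' @param time_to_saturation_s positive numeric: seconds for the water to
#'   infiltrate.
#' @param water_volume_ml poured volume (default 444).
#' @param ring_diameter_cm ring inner diameter (default 15).
#' @return tibble with `water_depth_cm` and `rate_cm_per_hr`.
#' @export
#' @examples
#' infiltration_rate(300)  # 2.513 cm head, 30.2 cm/hr
infiltration_rate <- function(time_to_saturation_s, water_volume_ml = 444,
                              ring_diameter_cm = 15) {
  if (anyNA(time_to_saturation_s)) abort_validation("Missing time")
  if (any(time_to_saturation_s <= 0)) abort_validation("Time must be positive")
  if (any(water_volume_ml <= 0) || any(ring_diameter_cm <= 0)) {
    abort_validation("Volume and diameter must be positive")
  }
  depth <- water_volume_ml / (pi * (ring_diameter_cm / 2)^2)
  tibble(
    water_depth_cm = depth + 0 * time_to_saturation_s,
    rate_cm_per_hr = depth / time_to_saturation_s * 3600
  )
}

#' Haney soil health score
#'
#' Combines the one-day CO2 burst with water-extractable organic carbon and
#' nitrogen: `co2_c/10 + weoc/50 + weon/10`.
#'
#' @param co2_c_ppm nonnegative numeric: 1-day incubation CO2-C (ppm).
#' @param weoc_ppm nonnegative numeric: water-extractable organic C (ppm).
#' @param weon_ppm nonnegative numeric: water-extractable organic N (ppm).
#' @return nonnegative score, linear in each argument.
#' @export
#' @examples
#' haney_score(100, 150, 20)  # 10 + 3 + 2 = 15
haney_score <- function(co2_c_ppm, weoc_ppm, weon_ppm) {
  if (anyNA(co2_c_ppm) || anyNA(weoc_ppm) || anyNA(weon_ppm)) {
    abort_validation("Missing assay value")
  }
  if (any(co2_c_ppm < 0) || any(weoc_ppm < 0) || any(weon_ppm < 0)) {
    abort_validation("Assay values must be nonnegative")
  }
  co2_c_ppm / 10 + weoc_ppm / 50 + weon_ppm / 10
}

# layer-profile validation shared by esm_stock
validate_layers <- function(layers) {
  layers <- as_tibble(layers)
  need <- c("top_cm", "bottom_cm", "bulk_density_g_cm3", "carbon_pct")
  miss <- setdiff(need, names(layers))
  if (length(miss)) abort_schema(paste0("Missing layer column(s): ", paste(miss, collapse = ", ")))
  if (nrow(layers) < 1) abort_validation("At least one layer required")
  layers <- layers[order(layers$top_cm), , drop = FALSE]
  if (layers$top_cm[1] != 0) abort_validation("Profile must start at 0 cm")
  if (any(layers$bottom_cm <= layers$top_cm)) abort_validation("Layers must have bottom_cm > top_cm")
  if (nrow(layers) > 1 &&
      any(abs(layers$top_cm[-1] - layers$bottom_cm[-nrow(layers)]) > 1e-8)) {
    abort_validation("Layers must be contiguous (each top at the previous bottom)")
  }
  if (any(layers$bulk_density_g_cm3 <= 0)) abort_validation("Bulk density must be positive")
  layers
}

#' Equivalent-soil-mass carbon or nitrogen stock
#'
#' Converts a layered profile of bulk densities and element concentrations to
#' a stock at a fixed cumulative soil mass rather than a fixed depth, removing
#' compaction bias. Layer boundaries give knots of cumulative soil mass
#' (100 * BD * thickness, Mg/ha per layer) against cumulative element mass;
#' a cubic spline through the knots (including the origin) is evaluated at the
#' reference mass. The default interpolant is the monotone (Hyman-filtered)
#' cubic, which cannot overshoot the bracketing knots; `method = "natural"`
#' gives an unconstrained natural cubic for sensitivity checks. A profile
#' whose total mass falls short of the reference mass is an error - the curve
#' is never extrapolated.
#'
#' @param layers data frame with `top_cm`, `bottom_cm`, `bulk_density_g_cm3`,
#'   `carbon_pct` and (for `element = "N"`) `nitrogen_pct`; contiguous from
#'   0 cm downward.
#' @param element `"C"` or `"N"`.
#' @param reference_mass_Mg_ha cumulative soil mass at which to read the stock
#'   (default 6000 Mg/ha, roughly the 0-60 cm layer).
#' @param method `"monotone"` (default) or `"natural"` spline.
#' @return stock in Mg/ha, with attribute `depth_cm`: the interpolated depth
#'   at which the profile reaches the reference mass (a diagnostic, not a
#'   target).
#' @export
#' @examples
#' one <- tibble::tibble(top_cm = 0, bottom_cm = 60,
#'                       bulk_density_g_cm3 = 1, carbon_pct = 1)
#' esm_stock(one)  # 60 Mg C / ha at 6000 Mg soil
esm_stock <- function(layers, element = c("C", "N"),
                      reference_mass_Mg_ha = 6000,
                      method = c("monotone", "natural")) {
  element <- match.arg(element)
  method <- match.arg(method)
  layers <- validate_layers(layers)
  pct_col <- if (element == "C") "carbon_pct" else "nitrogen_pct"
  if (!pct_col %in% names(layers)) {
    abort_schema(paste0("Missing layer column: ", pct_col))
  }
  pct <- layers[[pct_col]]
  if (anyNA(pct) || any(pct < 0)) abort_validation("Element percent must be nonnegative")
  if (any(reference_mass_Mg_ha <= 0)) abort_validation("Reference mass must be positive")

  thick <- layers$bottom_cm - layers$top_cm
  layer_soil <- 100 * layers$bulk_density_g_cm3 * thick     # Mg/ha per layer
  cum_soil <- c(0, cumsum(layer_soil))
  cum_elem <- c(0, cumsum(layer_soil * pct / 100))
  if (any(reference_mass_Mg_ha > cum_soil[length(cum_soil)] + 1e-8)) {
    abort_insufficient(paste0(
      "Profile holds ", round(cum_soil[length(cum_soil)], 1),
      " Mg/ha of soil, less than the reference mass ",
      max(reference_mass_Mg_ha), "; never extrapolated"
    ))
  }
  # Fritsch-Carlson monotone cubic: interpolates the knots, cannot overshoot
  # the bracketing cumulative totals, and hugs the chord more closely than
  # Hyman filtering on these concave cumulative curves.
  fun <- splinefun(cum_soil, cum_elem,
                   method = if (method == "monotone") "monoH.FC" else "natural")
  out <- fun(reference_mass_Mg_ha)
  attr(out, "depth_cm") <- approx(cum_soil, c(0, layers$bottom_cm),
                                  xout = reference_mass_Mg_ha)$y
  out
}
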