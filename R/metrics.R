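#' Structural riverscape indices
#'
#' Scalar morphometric indices computed per physical discontinuity zone
#' (PDZ): mean depth from volume and area, confluence density of inflowing
#' tributaries, the tributary hydrological index (THI), running cumulated
#' watershed area, and the wetland proportion of the water area.
#'
#' @name riverscape_metrics
NULL

#' Mean depth from volume and area
#'
#' `Z_m = volume / area`, with volume in km^3 and area in km^2, returned in
#' metres (x1000 unit conversion).
#'
#' @param volume_km3 Water volume, km^3, > 0.
#' @param area_km2 Water area, km^2, > 0.
#' @return Mean depth, m.
#' @export
#' @examples
#' mean_depth(1.12, 225.4) # 4.97 m
mean_depth <- function(volume_km3, area_km2) {
  if (any(area_km2 <= 0)) rl_abort("area must be > 0", "domain_error")
  if (any(volume_km3 <= 0)) rl_abort("volume must be > 0", "domain_error")
  1000 * volume_km3 / area_km2
}

#' Confluence density of inflowing tributaries
#'
#' Number of confluents per km of channel length.
#'
#' @param n_tributaries Count of inflowing tributaries, >= 0.
#' @param channel_length_km Channel length, km, > 0 (may differ from the
#'   zone's nominal length).
#' @return Tributaries per km.
#' @export
#' @examples
#' confluence_density(5, 35) # 0.1428571
confluence_density <- function(n_tributaries, channel_length_km) {
  if (any(channel_length_km <= 0))
    rl_abort("channel length must be > 0", "domain_error")
  if (any(n_tributaries < 0))
    rl_abort("tributary count must be >= 0", "domain_error")
  n_tributaries / channel_length_km
}

#' Tributary hydrological index (THI)
#'
#' Tributary discharge rate divided by the mean depth of the receiving zone;
#' indexes the capacity of an inflow to structure water masses.
#'
#' @param discharge Tributary discharge, m^3 s^-1.
#' @param mean_depth_m Mean depth of the receiving zone, m, > 0.
#' @return THI (m^2 s^-1).
#' @export
thi <- function(discharge, mean_depth_m) {
  if (any(mean_depth_m <= 0)) rl_abort("mean depth must be > 0", "domain_error")
  discharge / mean_depth_m
}

#' Cumulated watershed area in downstream order
#'
#' @param watershed_area_km2 Watershed areas of the zones, ordered
#'   downstream.
#' @return Running sum, km^2 (empty input gives empty output).
#' @export
#' @examples
#' cumulated_watershed(c(772000, 148843)) # 772000 920843
cumulated_watershed <- function(watershed_area_km2) {
  cumsum(watershed_area_km2)
}

#' Wetland proportion of the water area
#'
#' @param wetland_area_km2 Wetland area, km^2, >= 0.
#' @param water_area_km2 Water area, km^2, > 0.
#' @return Percentage.
#' @export
#' @examples
#' wetland_proportion(160.98, 241.02) # 66.79 %
wetland_proportion <- function(wetland_area_km2, water_area_km2) {
  if (any(water_area_km2 <= 0)) rl_abort("water area must be > 0", "domain_error")
  if (any(wetland_area_km2 < 0)) rl_abort("wetland area must be >= 0", "domain_error")
  100 * wetland_area_km2 / water_area_km2
}

#' Bundled PDZ morphometry table
#'
#' Loads the morphometry fixture shipped with the package: one row per
#' physical discontinuity zone with printed lengths, areas, volumes, counts
#' and the reported summary columns. `density_reproducible` flags rows whose
#' printed confluence density follows from the printed tributary count and
#' length (some zones were reported with alternate channel lengths that are
#' not listed).
#'
#' @return Tibble of PDZ records.
#' @export
pdz_table <- function() {
  readr::read_csv(system.file("extdata", "pdz_morphometry.csv",
                              package = "riverlight"),
                  show_col_types = FALSE)
}

#' Recompute the riverscape summary table from raw morphometry
#'
#' Applies [mean_depth()], [confluence_density()], [cumulated_watershed()]
#' and [wetland_proportion()] to a PDZ record table (downstream order) and
#' returns both raw and report-rounded values (half-up at the conventional
#' printed precision).
#'
#' @param pdz Tibble like [pdz_table()] with columns `pdz`,
#'   `volume_km3`, `water_area_km2`, `n_tributaries`, `channel_length_km`,
#'   `watershed_area_km2`, `wetland_area_km2`.
#' @return Tibble with computed `mean_depth_m`, `confluence_density`,
#'   `cumulated_watershed_km2`, `wetland_pct` plus `*_report` rounded columns.
#' @export
pdz_metrics <- function(pdz) {
  pdz <- as_tibble(pdz)
  pdz %>%
    mutate(
      mean_depth_m = mean_depth(.data$volume_km3, .data$water_area_km2),
      confluence_density = confluence_density(.data$n_tributaries,
                                              .data$channel_length_km),
      cumulated_watershed_km2 = cumulated_watershed(.data$watershed_area_km2),
      wetland_pct = wetland_proportion(.data$wetland_area_km2,
                                       .data$water_area_km2),
      mean_depth_report = round_half_up(.data$mean_depth_m, 2),
      confluence_density_report = round_half_up(.data$confluence_density, 3),
      wetland_pct_report = round_half_up(.data$wetland_pct, 2)
    )
}

# round half away from zero, matching printed report tables
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
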