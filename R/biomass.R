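## Above-ground biomass from stem tables -----------------------------------
##
## Moist-forest allometry: AGB (kg) = 0.0509 * rho * dbh^2 * H with dbh in
## cm, H in m and wood density rho in g cm^-3. Heights are estimated from
## dbh through the simplified allometry H = c * dbh^(2/3), with c
## calibrated per station from the measured tallest tree in each plot.
## Subcanopy (10 m radius) and canopy (20 m radius) nested plots are merged
## on a per-area basis.

#' Wood density lookup table
#'
#' Builds a lookup with species-level and genus-level densities and a site
#' default used when neither matches.
#'
#' @param df data.frame with columns `level` (`"species"` or `"genus"`),
#'   `name`, `density_g_cm3`.
#' @param site_default fallback density (g cm^-3).
#' @return object of class `wood_density_table`.
#' @export
wood_density_table <- function(df, site_default = 0.56) {
  stopifnot(all(c("level", "name", "density_g_cm3") %in% names(df)))
  if (!all(df$level %in% c("species", "genus")))
    stop_elevgrad("level must be 'species' or 'genus'", "invalid_argument")
  dens <- c(df$density_g_cm3, site_default)
  if (any(dens <= 0.1 | dens >= 1.5))
    stop_elevgrad("densities must lie in (0.1, 1.5) g cm^-3",
                  "invalid_argument")
  sp <- df[df$level == "species", ]
  gn <- df[df$level == "genus", ]
  structure(list(
    species_level = setNames(sp$density_g_cm3, sp$name),
    genus_level = setNames(gn$density_g_cm3, gn$name),
    site_default = site_default), class = "wood_density_table")
}

## genus = first token of the binomial (whitespace or underscore separated)
species_genus <- function(species) {
  vapply(strsplit(species, "[ _]"), `[[`, character(1), 1L)
}

#' Resolve wood density for species
#'
#' Lookup order: species-level match, then genus-level (genus taken as the
#' first token of the binomial), then the site default. Always resolves.
#'
#' @param species character vector of binomials.
#' @param table a [wood_density_table()].
#' @return data.frame with columns `species`, `density` (g cm^-3) and
#'   `provenance` (`"species"`, `"genus"` or `"default"`).
#' @export
resolve_wood_density <- function(species, table) {
  stopifnot(inherits(table, "wood_density_table"))
  genus <- species_genus(species)
  density <- unname(table$species_level[species])
  provenance <- ifelse(is.na(density), NA_character_, "species")
  gd <- unname(table$genus_level[genus])
  use_genus <- is.na(density) & !is.na(gd)
  density[use_genus] <- gd[use_genus]
  provenance[use_genus] <- "genus"
  use_def <- is.na(density)
  density[use_def] <- table$site_default
  provenance[use_def] <- "default"
  data.frame(species = species, density = density,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Calibrate the height-allometry coefficient per station
#'
#' From each plot's tallest tree, `c = H / dbh^(2/3)`; the station
#' coefficient is the arithmetic mean of its plot values.
#'
#' @param tallest_pairs data.frame with columns `station`, `height` (m) and
#'   `dbh` (cm), one row per plot.
#' @return data.frame with columns `station`, `c` and `n_plots`; the
#'   per-plot values are attached as attribute `plot_c`.
#' @export
calibrate_height_coefficient <- function(tallest_pairs) {
  stopifnot(all(c("station", "height", "dbh") %in% names(tallest_pairs)))
  if (nrow(tallest_pairs) == 0)
    stop_elevgrad("no tallest-tree pairs supplied", "missing_calibration")
  if (any(tallest_pairs$height <= 0) || any(tallest_pairs$dbh <= 0))
    stop_elevgrad("heights and dbh must be positive", "invalid_argument")
  c_plot <- tallest_pairs$height / tallest_pairs$dbh^(2 / 3)
  agg <- aggregate(c_plot, by = list(station = tallest_pairs$station),
                   FUN = mean)
  n <- aggregate(c_plot, by = list(station = tallest_pairs$station),
                 FUN = length)
  out <- data.frame(station = agg$station, c = agg$x, n_plots = n$x)
  attr(out, "plot_c") <- data.frame(station = tallest_pairs$station,
                                    c = c_plot)
  out
}

#' Estimate tree height from dbh
#'
#' `H = c * dbh^(2/3)` with dbh in cm and H in m.
#'
#' @param dbh diameter at breast height (cm), non-negative.
#' @param c height coefficient (m cm^-2/3), positive.
#' @return heights (m).
#' @export
estimate_height <- function(dbh, c) {
  if (any(dbh < 0))
    stop_elevgrad("dbh must be non-negative", "invalid_argument")
  if (any(c <= 0))
    stop_elevgrad("height coefficient must be positive",
                  "invalid_argument")
  c * dbh^(2 / 3)
}

#' Above-ground biomass of a single stem
#'
#' Moist-forest allometry `AGB = 0.0509 * rho * dbh^2 * H`, giving kg for
#' dbh in cm, H in m and wood density rho in g cm^-3.
#'
#' @param dbh diameter at breast height (cm).
#' @param height total height (m).
#' @param rho wood density (g cm^-3).
#' @return biomass (kg).
#' @export
#' @examples
#' stem_agb(10, 10, 0.5) # 25.45 kg
stem_agb <- function(dbh, height, rho) {
  if (any(dbh < 0) || any(height < 0) || any(rho < 0))
    stop_elevgrad("dbh, height and rho must be non-negative",
                  "invalid_argument")
  0.0509 * rho * dbh^2 * height
}

#' Per-plot above-ground biomass density
#'
#' Computes stem-level AGB for subcanopy (`[10, 30)` cm dbh) and canopy
#' (`>= 30` cm) stems, with heights from the station's calibrated height
#' coefficient and densities from the wood-density lookup, then merges the
#' nested 10 m and 20 m radius plots on a per-area basis:
#' `density = sum(AGB subcanopy)/(pi 10^2) + sum(AGB canopy)/(pi 20^2)`.
#' This equals extrapolating subcanopy totals by the 4x area ratio over the
#' 20 m plot. Understorey stems (dbh < 10 cm) are filtered with a warning;
#' they are censused on a smaller nested plot and excluded from biomass.
#'
#' @param stems data.frame with columns `species` and `dbh` for one plot.
#' @param c_station calibrated height coefficient for the plot's station.
#' @param densities a [wood_density_table()].
#' @param radii radii (m) of the subcanopy and canopy nested plots.
#' @param dbh_bounds dbh thresholds (cm) separating subcanopy and canopy.
#' @return object of class `plot_biomass`: list with `agb_subcanopy` (kg),
#'   `agb_canopy` (kg), `agb_density` (kg m^-2), `areas` (m^2) and
#'   `n_stems`.
#' @export
plot_agb_density <- function(stems, c_station, densities,
                             radii = c(10, 20), dbh_bounds = c(10, 30)) {
  stopifnot(all(c("species", "dbh") %in% names(stems)))
  small <- stems$dbh < dbh_bounds[1]
  if (any(small)) {
    warning(sprintf("filtered %d stem(s) below %g cm dbh from biomass",
                    sum(small), dbh_bounds[1]))
    stems <- stems[!small, , drop = FALSE]
  }
  areas <- pi * radii^2
  if (nrow(stems) == 0) {
    return(structure(list(agb_subcanopy = 0, agb_canopy = 0,
                          agb_density = 0,
                          areas = setNames(areas,
                                           c("subcanopy", "canopy")),
                          n_stems = 0L), class = "plot_biomass"))
  }
  rho <- resolve_wood_density(stems$species, densities)$density
  h <- estimate_height(stems$dbh, c_station)
  agb <- stem_agb(stems$dbh, h, rho)
  canopy <- stems$dbh >= dbh_bounds[2]
  agb_sub <- sum(agb[!canopy])
  agb_can <- sum(agb[canopy])
  structure(list(
    agb_subcanopy = agb_sub,
    agb_canopy = agb_can,
    agb_density = agb_sub / areas[1] + agb_can / areas[2],
    areas = setNames(areas, c("subcanopy", "canopy")),
    n_stems = nrow(stems)), class = "plot_biomass")
}

#' @export
print.plot_biomass <- function(x, ...) {
  cat(sprintf(
    "Plot AGB: %.1f kg subcanopy + %.1f kg canopy -> %.3f kg m^-2\n",
    x$agb_subcanopy, x$agb_canopy, x$agb_density))
  invisible(x)
}
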