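## Synthetic community generator -------------------------------------------
##
## Emulates a stationed nested-plot vegetation survey: stations at fixed
## elevations, each with several nested circular plots; a regional species
## pool with log-series abundance structure; Gaussian occupancy response
## curves along elevation whose optima may carry phylogenetic signal
## (Brownian motion on a simulated tree); stratum-specific dbh
## distributions; and plot covariates with prescribed elevational trends.

#' Configuration for the synthetic gradient generator
#'
#' Bundles every parameter of the synthetic sampling design. The defaults
#' emulate a seven-station survey at 200 m vertical intervals from 1000 to
#' 2200 m asl with three plots per station and nested plot radii of
#' 1/5/10/20 m, a woody species pool of 92 species and a ground-cover pool
#' of 67 species (the richness recorded by the field survey this design
#' mirrors), and covariate trends of a hump-shaped leaf area index and a
#' linearly declining canopy height.
#'
#' @param n_stations number of elevational stations.
#' @param station_elevations strictly increasing elevations (m asl).
#' @param plots_per_station plots per station.
#' @param pool_size woody species pool size (>= 2).
#' @param ground_pool_size ground-cover species pool size.
#' @param logseries_alpha regional log-series diversity parameter.
#' @param optimum_range range (m) to which species optima are clipped.
#' @param tolerance_distribution `c(meanlog, sdlog)` of the log-normal
#'   distribution of species niche breadths (m).
#' @param phylo_signal Brownian-motion variance of elevational optima
#'   accumulated from root to tip (tree rescaled to unit height);
#'   0 disables phylogenetic signal.
#' @param root_optimum ancestral elevational optimum (m).
#' @param max_occupancy occupancy probability at a species' optimum, in
#'   (0, 1].
#' @param strata_dbh_bounds dbh thresholds (cm) separating understorey,
#'   subcanopy and canopy strata; strictly increasing.
#' @param plot_radii nested plot radii (m); strictly increasing.
#' @param stems_per_plot expected sizes (Poisson means) of the plot-level
#'   log-series draws for the three woody strata, before occupancy
#'   thinning; realized per-plot stem counts are roughly the draw size
#'   times the mean occupancy probability (about one fifth under the
#'   defaults, giving survey-like densities of a few tens of stems per
#'   plot).
#' @param dbh_max maximum canopy dbh (cm).
#' @param covariate_params list of covariate-trend coefficients; see
#'   [generate_environment()].
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @return an object of class `gradient_config` (a validated list).
#' @export
gradient_config <- function(n_stations = 7,
                            station_elevations = seq(1000, 2200, by = 200),
                            plots_per_station = 3,
                            pool_size = 92,
                            ground_pool_size = 67,
                            logseries_alpha = 20,
                            optimum_range = c(600, 2400),
                            tolerance_distribution = c(meanlog = log(250),
                                                       sdlog = 0.3),
                            phylo_signal = 1.6e5,
                            root_optimum = 900,
                            max_occupancy = 0.8,
                            strata_dbh_bounds = c(2, 10, 30),
                            plot_radii = c(1, 5, 10, 20),
                            stems_per_plot = c(understorey = 120,
                                               subcanopy = 60,
                                               canopy = 15),
                            dbh_max = 120,
                            covariate_params = list(),
                            seed = 1L) {
  defaults <- list(
    lai_peak = 1500, lai_max = 4.5, lai_curv = 2.5, lai_sd = 0.5,
    height_base = 32, height_slope = -0.012, height_sd = 3,
    slope_mean = 20, slope_sd = 8,
    open_min = 10, open_peak = 1500, open_curv = 25, open_sd = 5,
    height_coef = 2.0, height_coef_sd = 0.15,
    ground_optimum_mean = 1500, ground_optimum_sd = 300
  )
  covariate_params <- utils::modifyList(defaults, covariate_params)
  cfg <- list(n_stations = as.integer(n_stations),
              station_elevations = as.numeric(station_elevations),
              plots_per_station = as.integer(plots_per_station),
              pool_size = as.integer(pool_size),
              ground_pool_size = as.integer(ground_pool_size),
              logseries_alpha = logseries_alpha,
              optimum_range = as.numeric(optimum_range),
              tolerance_distribution = tolerance_distribution,
              phylo_signal = phylo_signal,
              root_optimum = root_optimum,
              max_occupancy = max_occupancy,
              strata_dbh_bounds = as.numeric(strata_dbh_bounds),
              plot_radii = as.numeric(plot_radii),
              stems_per_plot = stems_per_plot,
              dbh_max = dbh_max,
              covariate_params = covariate_params,
              seed = as.integer(seed))
  if (length(cfg$station_elevations) != cfg$n_stations)
    stop_elevgrad("station_elevations must have length n_stations",
                  "invalid_argument")
  if (any(diff(cfg$station_elevations) <= 0))
    stop_elevgrad("station elevations must be strictly increasing",
                  "invalid_argument")
  if (any(diff(cfg$plot_radii) <= 0))
    stop_elevgrad("plot radii must be strictly increasing",
                  "invalid_argument")
  if (any(diff(cfg$strata_dbh_bounds) <= 0))
    stop_elevgrad("dbh bounds must be strictly increasing",
                  "invalid_argument")
  if (cfg$pool_size < 2)
    stop_elevgrad("pool_size must be >= 2", "invalid_argument")
  if (cfg$max_occupancy <= 0 || cfg$max_occupancy > 1)
    stop_elevgrad("max_occupancy must lie in (0, 1]", "invalid_argument")
  if (cfg$logseries_alpha <= 0)
    stop_elevgrad("logseries_alpha must be positive", "invalid_argument")
  class(cfg) <- "gradient_config"
  cfg
}

#' Simulate a regional species-pool phylogeny
#'
#' Pure-birth (Yule) tree conditioned on the number of tips, hence rooted,
#' ultrametric, with strictly positive branch lengths. Tips are labelled
#' with synthetic binomials (`GenusXX_spYYY`) sharing genera so that
#' genus-level wood-density lookups are exercised.
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth_rate speciation rate of the Yule process.
#' @param seed integer seed; same seed gives an identical tree.
#' @return an [ape::phylo] object.
#' @export
generate_phylogeny <- function(n_taxa, birth_rate = 1, seed = 1L) {
  if (!is_count(n_taxa) || n_taxa < 2)
    stop_elevgrad("n_taxa must be an integer >= 2", "invalid_argument")
  if (birth_rate <= 0)
    stop_elevgrad("birth_rate must be positive", "invalid_argument")
  set.seed(seed)
  tree <- ape::rphylo(n = n_taxa, birth = birth_rate, death = 0)
  n_genera <- max(2L, ceiling(n_taxa / 2.5))
  genus <- sort(sample.int(n_genera, n_taxa, replace = TRUE))
  tree$tip.label <- sprintf("Genus%02d_sp%03d", genus, seq_len(n_taxa))
  tree
}

tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Evolve species elevational optima on a phylogeny
#'
#' Brownian motion on the tree (rescaled to unit height so `bm_rate` is the
#' root-to-tip variance in m^2), started at `root_value`, then clipped to
#' `range_clip`. With `bm_rate = 0` every tip inherits the root value.
#'
#' @param tree an [ape::phylo] object.
#' @param root_value ancestral optimum (m).
#' @param bm_rate non-negative Brownian variance accumulated root-to-tip.
#' @param range_clip length-2 numeric range the optima are clipped to.
#' @param seed integer seed.
#' @return named numeric vector of optima, one per tip.
#' @export
evolve_optima <- function(tree, root_value, bm_rate, range_clip, seed = 1L) {
  if (bm_rate < 0)
    stop_elevgrad("bm_rate must be non-negative", "invalid_argument")
  set.seed(seed)
  if (bm_rate == 0) {
    opt <- setNames(rep(root_value, length(tree$tip.label)), tree$tip.label)
    return(opt)
  }
  scaled <- tree
  scaled$edge.length <- scaled$edge.length / tree_height(tree)
  opt <- ape::rTraitCont(scaled, model = "BM", sigma = sqrt(bm_rate),
                         root.value = root_value)
  pmin(pmax(opt, range_clip[1]), range_clip[2])
}

#' Sample a log-series community of fixed size
#'
#' Sequential urn construction (Ewens sampling): the i-th individual founds
#' a new species with probability `alpha / (alpha + i - 1)`, otherwise it
#' joins the species of a uniformly chosen earlier individual. Expected
#' richness is `alpha * (digamma(alpha + n) - digamma(alpha))`, which
#' matches the log-series relation `alpha * log(1 + n/alpha)` closely for
#' the community sizes used here, so the diversity parameter of the
#' generated communities is known by construction. Abundances sum exactly
#' to `n_individuals`.
#'
#' @param alpha positive log-series diversity parameter.
#' @param n_individuals community size (>= 1).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return integer vector of species abundances (order of discovery).
#' @export
sample_logseries_abundances <- function(alpha, n_individuals, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop_elevgrad("alpha must be a positive number", "invalid_argument")
  if (!is_count(n_individuals) || n_individuals < 1)
    stop_elevgrad("n_individuals must be an integer >= 1",
                  "invalid_argument")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_individuals)
  assign <- integer(n)
  assign[1L] <- 1L
  s <- 1L
  if (n > 1L) {
    u <- runif(n - 1L)
    for (i in 2:n) {
      if (u[i - 1L] < alpha / (alpha + i - 1)) {
        s <- s + 1L
        assign[i] <- s
      } else {
        assign[i] <- assign[sample.int(i - 1L, 1L)]
      }
    }
  }
  tabulate(assign, nbins = s)
}

#' Gaussian occupancy response curve
#'
#' Probability that a species occupies a plot at a given elevation:
#' `max_occupancy * exp(-(elevation - optimum)^2 / (2 * tolerance^2))`.
#' Vectorized over all arguments.
#'
#' @param elevation plot elevation (m).
#' @param optimum species optimum (m).
#' @param tolerance positive niche breadth (m).
#' @param max_occupancy occupancy probability at the optimum.
#' @return occupancy probabilities in `[0, max_occupancy]`.
#' @export
occupancy_probability <- function(elevation, optimum, tolerance,
                                  max_occupancy = 1) {
  if (any(tolerance <= 0))
    stop_elevgrad("tolerance must be positive", "invalid_argument")
  max_occupancy * exp(-(elevation - optimum)^2 / (2 * tolerance^2))
}

plot_ids <- function(config) {
  data.frame(
    station = rep(as.integer(config$station_elevations),
                  each = config$plots_per_station),
    plot = rep(letters[seq_len(config$plots_per_station)],
               config$n_stations),
    stringsAsFactors = FALSE
  )
}

#' Sample woody communities for every plot and stratum
#'
#' For each plot, presence of each pool species is Bernoulli with the
#' Gaussian occupancy probability at the plot's elevation; abundances given
#' presence come from thinning a plot-level log-series draw (the draw's
#' species slots are assigned to random pool species and only those passing
#' the occupancy filter are kept), so the plot-level abundance structure
#' stays tied to the regional log-series parameter.
#'
#' @param config a [gradient_config()].
#' @param phylogeny species-pool tree (tips define the pool).
#' @param optima named optima per species (m).
#' @param seed integer seed.
#' @param tolerances optional named per-species tolerances (m); drawn from
#'   `config$tolerance_distribution` when `NULL`.
#' @return named list of plots x species integer abundance matrices, one
#'   per stratum, with the tolerances used attached as an attribute.
#' @export
sample_station_communities <- function(config, phylogeny, optima, seed = 1L,
                                       tolerances = NULL) {
  species <- phylogeny$tip.label
  if (!all(species %in% names(optima)))
    stop_elevgrad("optima must be defined for every pool species",
                  "invalid_argument")
  set.seed(seed)
  optima <- optima[species]
  if (is.null(tolerances)) {
    td <- config$tolerance_distribution
    tolerances <- setNames(
      exp(rnorm(length(species), td[[1]], td[[2]])), species)
  }
  plots <- plot_ids(config)
  sites <- paste0(plots$station, plots$plot)
  strata <- names(config$stems_per_plot)
  out <- lapply(strata, function(st) {
    m <- matrix(0L, nrow = nrow(plots), ncol = length(species),
                dimnames = list(sites, species))
    for (p in seq_len(nrow(plots))) {
      z <- plots$station[p]
      pres <- runif(length(species)) <
        occupancy_probability(z, optima, tolerances, config$max_occupancy)
      n_ind <- rpois(1, config$stems_per_plot[[st]])
      if (n_ind == 0) next
      ab <- sample_logseries_abundances(config$logseries_alpha, n_ind)
      slots <- sample.int(length(species),
                          size = min(length(ab), length(species)))
      ab <- ab[seq_along(slots)]
      keep <- pres[slots]
      if (any(keep)) m[p, slots[keep]] <- as.integer(ab[keep])
    }
    m
  })
  names(out) <- strata
  attr(out, "tolerances") <- tolerances
  out
}

#' Sample stem diameters per stratum
#'
#' Draws dbh values from truncated exponential distributions inside each
#' stratum's half-open dbh interval: understorey `[b1, b2)`, subcanopy
#' `[b2, b3)` and canopy `[b3, dbh_max]`.
#'
#' @param counts named integer vector of stem counts for strata
#'   `understorey`, `subcanopy`, `canopy`.
#' @param strata_dbh_bounds the three dbh thresholds (cm).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param dbh_max maximum canopy dbh (cm).
#' @param scales exponential scale (cm) within each stratum.
#' @return named list of dbh vectors.
#' @export
sample_stem_sizes <- function(counts, strata_dbh_bounds = c(2, 10, 30),
                              seed = NULL, dbh_max = 120,
                              scales = c(3, 8, 25)) {
  if (any(diff(strata_dbh_bounds) <= 0))
    stop_elevgrad("dbh bounds must be strictly increasing",
                  "invalid_argument")
  if (!is.null(seed)) set.seed(seed)
  b <- strata_dbh_bounds
  lims <- list(understorey = c(b[1], b[2]), subcanopy = c(b[2], b[3]),
               canopy = c(b[3], dbh_max))
  out <- lapply(names(lims), function(st) {
    k <- if (st %in% names(counts)) counts[[st]] else 0L
    if (k == 0) return(numeric(0))
    lim <- lims[[st]]
    sc <- scales[match(st, names(lims))]
    u <- runif(k)
    ## inverse-CDF of an exponential truncated to [lim1, lim2)
    lim[1] - sc * log(1 - u * (1 - exp(-(lim[2] - lim[1]) / sc)))
  })
  names(out) <- names(lims)
  out
}

#' Generate plot covariates with prescribed elevational trends
#'
#' Leaf area index follows a quadratic (hump-shaped) trend with its peak at
#' `lai_peak`; canopy height declines linearly; slope is independent noise
#' uncorrelated with elevation; canopy openness follows a U-shaped trend
#' clipped to `[0, 100]`. Each plot also carries a tallest-tree
#' `(height, dbh)` pair for height-allometry calibration: height is the
#' true generating height coefficient plus noise applied to `dbh^(2/3)`.
#' When `tallest_dbh` is not supplied (e.g. before stems are generated) a
#' canopy-sized dbh is drawn.
#'
#' @param config a [gradient_config()].
#' @param seed integer seed.
#' @param tallest_dbh optional per-plot vector of tallest-tree dbh (cm).
#' @return data.frame with one row per plot (station, plot, elevation,
#'   slope, lai, canopy_openness, canopy_height, tallest_height,
#'   tallest_dbh).
#' @export
generate_environment <- function(config, seed = 1L, tallest_dbh = NULL) {
  set.seed(seed)
  cp <- config$covariate_params
  plots <- plot_ids(config)
  n <- nrow(plots)
  z <- plots$station
  lai <- cp$lai_max - cp$lai_curv * ((z - cp$lai_peak) / 1000)^2 +
    rnorm(n, 0, cp$lai_sd)
  lai <- pmax(lai, 0)
  canopy_height <- cp$height_base +
    cp$height_slope * (z - config$station_elevations[1]) +
    rnorm(n, 0, cp$height_sd)
  canopy_height <- pmax(canopy_height, 2)
  slope <- pmin(pmax(rnorm(n, cp$slope_mean, cp$slope_sd), 0), 60)
  openness <- cp$open_min + cp$open_curv * ((z - cp$open_peak) / 1000)^2 +
    rnorm(n, 0, cp$open_sd)
  openness <- pmin(pmax(openness, 0), 100)
  if (is.null(tallest_dbh))
    tallest_dbh <- config$strata_dbh_bounds[3] +
      rexp(n, rate = 1 / 25)
  c_plot <- cp$height_coef + rnorm(n, 0, cp$height_coef_sd)
  tallest_height <- pmax(c_plot, 0.2) * tallest_dbh^(2 / 3)
  data.frame(plots,
             elevation = z,
             slope = slope,
             lai = lai,
             canopy_openness = openness,
             canopy_height = canopy_height,
             tallest_height = tallest_height,
             tallest_dbh = tallest_dbh,
             stringsAsFactors = FALSE)
}

## latent ground-cover percentage -> ordinal class on the 7-point scale
## 0: absent; 1: <1%; 2: 1-4%; 3: 5-24%; 4: 25-49%; 5: 50-74%; 6: 75-100%
cover_class_from_percent <- function(pct) {
  stopifnot(all(pct >= 0 & pct <= 100))
  as.integer(ifelse(pct == 0, 0L,
                    findInterval(pct, c(1, 5, 25, 50, 75)) + 1L))
}

#' Generate a complete synthetic gradient dataset
#'
#' Orchestrates the full generator: species-pool phylogeny, Brownian
#' optima, per-plot woody communities and stem diameters, ground-cover
#' records on the ordinal cover scale, plot covariates and a wood-density
#' lookup table. The `truth` element records every generating parameter
#' (optima, tolerances, covariate coefficients, the height coefficient) for
#' recovery tests. All stages are seeded deterministically from
#' `config$seed`.
#'
#' @param config a [gradient_config()].
#' @return an object of class `synthetic_dataset`: list with elements
#'   `stems`, `ground_cover`, `environment`, `phylogeny`, `wood_density`,
#'   `truth`, `config`.
#' @export
generate_dataset <- function(config = gradient_config()) {
  seed <- config$seed
  cp <- config$covariate_params
  tree <- generate_phylogeny(config$pool_size,
                             seed = derive_seed(seed, "tree"))
  optima <- evolve_optima(tree, config$root_optimum, config$phylo_signal,
                          config$optimum_range,
                          seed = derive_seed(seed, "optima"))
  comm <- sample_station_communities(config, tree, optima,
                                     seed = derive_seed(seed,
                                                        "communities"))
  tolerances <- attr(comm, "tolerances")
  plots <- plot_ids(config)
  sites <- paste0(plots$station, plots$plot)

  ## expand abundance matrices into stem records with stratum-level dbh
  set.seed(derive_seed(seed, "sizes"))
  stems <- vector("list", nrow(plots))
  tallest_dbh <- numeric(nrow(plots))
  for (p in seq_len(nrow(plots))) {
    rows <- list()
    for (st in names(comm)) {
      ab <- comm[[st]][p, ]
      ab <- ab[ab > 0]
      if (!length(ab)) next
      counts <- setNames(list(sum(ab)), st)
      d <- sample_stem_sizes(counts, config$strata_dbh_bounds,
                             dbh_max = config$dbh_max)[[st]]
      rows[[st]] <- data.frame(
        station = plots$station[p], plot = plots$plot[p],
        species = rep(names(ab), ab), dbh = round(d, 1),
        stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(station = integer(0), plot = character(0),
                 species = character(0), dbh = numeric(0))
    stems[[p]] <- df
    canopy_d <- df$dbh[df$dbh >= config$strata_dbh_bounds[3]]
    tallest_dbh[p] <- if (length(canopy_d)) max(canopy_d) else
      if (nrow(df)) max(df$dbh) else stats::runif(1, 3, 8)
  }
  stems <- do.call(rbind, stems)
  rownames(stems) <- NULL

  environment <- generate_environment(config,
                                      seed = derive_seed(seed,
                                                         "environment"),
                                      tallest_dbh = tallest_dbh)

  ## ground cover: iid Gaussian response curves (no phylogeny), latent
  ## percentage cover binned through the ordinal scale
  set.seed(derive_seed(seed, "ground"))
  gspecies <- sprintf("herb_sp%03d", seq_len(config$ground_pool_size))
  g_opt <- setNames(rnorm(config$ground_pool_size, cp$ground_optimum_mean,
                          cp$ground_optimum_sd), gspecies)
  g_tol <- setNames(exp(rnorm(config$ground_pool_size,
                              config$tolerance_distribution[[1]],
                              config$tolerance_distribution[[2]])),
                    gspecies)
  ground <- list()
  for (p in seq_len(nrow(plots))) {
    z <- plots$station[p]
    pres <- runif(length(gspecies)) <
      occupancy_probability(z, g_opt, g_tol, config$max_occupancy)
    if (!any(pres)) next
    pct <- rbeta(sum(pres), 1.2, 6) * 100
    ground[[length(ground) + 1L]] <- data.frame(
      station = plots$station[p], plot = plots$plot[p],
      species = gspecies[pres],
      cover_class = cover_class_from_percent(pct),
      stringsAsFactors = FALSE)
  }
  ground <- if (length(ground)) do.call(rbind, ground) else
    data.frame(station = integer(0), plot = character(0),
               species = character(0), cover_class = integer(0))
  ground <- ground[ground$cover_class > 0, , drop = FALSE]
  rownames(ground) <- NULL

  ## wood densities: species-level for some species, genus-level for some
  ## genera, site default for the rest
  set.seed(derive_seed(seed, "density"))
  species <- tree$tip.label
  genera <- unique(species_genus(species))
  sp_known <- sample(species, size = round(0.35 * length(species)))
  gen_known <- sample(genera, size = round(0.45 * length(genera)))
  wd <- rbind(
    data.frame(level = "species", name = sp_known,
               density_g_cm3 = round(pmin(pmax(
                 rnorm(length(sp_known), 0.56, 0.10), 0.15), 1.2), 3),
               stringsAsFactors = FALSE),
    data.frame(level = "genus", name = gen_known,
               density_g_cm3 = round(pmin(pmax(
                 rnorm(length(gen_known), 0.56, 0.08), 0.15), 1.2), 3),
               stringsAsFactors = FALSE))

  out <- list(
    stems = stems,
    ground_cover = ground,
    environment = environment,
    phylogeny = tree,
    wood_density = wood_density_table(wd, site_default = 0.56),
    truth = list(optima = optima, tolerances = tolerances,
                 ground_optima = g_opt, ground_tolerances = g_tol,
                 covariate_params = cp,
                 height_coef = cp$height_coef,
                 logseries_alpha = config$logseries_alpha,
                 seed = seed),
    config = config)
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic elevational-gradient dataset\n")
  cat(sprintf("  stations: %d (%d-%d m), plots: %d\n",
              x$config$n_stations, min(x$config$station_elevations),
              max(x$config$station_elevations), nrow(x$environment)))
  cat(sprintf("  stems: %d (%d species), ground-cover records: %d\n",
              nrow(x$stems), length(unique(x$stems$species)),
              nrow(x$ground_cover)))
  invisible(x)
}
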