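## End-to-end orchestration -------------------------------------------------

#' Analysis configuration
#'
#' Settings for [run_full_analysis()]. Defaults keep a full pipeline run
#' on a 21-plot dataset in the order of a minute; the resampling and
#' null-model sizes can be raised for publication-grade p-values.
#'
#' @param n_resamples bootstrap resamples for the multivariate analysis
#'   of deviance.
#' @param n_null null samples for the independent-swap MPD null.
#' @param burn_in,thin swap-chain schedule for [ses_mpd()].
#' @param retain_rule model-averaging retention fraction.
#' @param mos_level significance level for the extremum test.
#' @param forest_max_elevation stations above this elevation are dropped
#'   in the forest-only analysis (the default mirrors a gradient whose
#'   top station is fire-maintained grassland).
#' @param min_occurrence minimum number of occupied plots for a species
#'   to enter the composition analysis.
#' @param run_both run both the all-stations and forest-only analyses.
#' @param seed master seed for the analysis stages.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(n_resamples = 199, n_null = 199,
                            burn_in = 10000, thin = 500,
                            retain_rule = 0.10, mos_level = 0.05,
                            forest_max_elevation = 2000,
                            min_occurrence = 3,
                            run_both = TRUE, seed = 1L) {
  structure(list(n_resamples = n_resamples, n_null = n_null,
                 burn_in = burn_in, thin = thin,
                 retain_rule = retain_rule, mos_level = mos_level,
                 forest_max_elevation = forest_max_elevation,
                 min_occurrence = min_occurrence,
                 run_both = run_both, seed = as.integer(seed)),
            class = "analysis_config")
}

station_of <- function(site) as.integer(substr(site, 1, 4))

plot_environment_design <- function(env) {
  data.frame(site = paste0(env$station, env$plot),
             elevation = env$elevation, slope = env$slope,
             lai = env$lai, canopy_height = env$canopy_height,
             stringsAsFactors = FALSE)
}

## basal area (m^2) of subcanopy + canopy stems per plot
plot_basal_area <- function(stems, sites, dbh_bounds = c(2, 10, 30)) {
  big <- stems[stems$dbh >= dbh_bounds[2], , drop = FALSE]
  key <- paste0(big$station, big$plot)
  ba <- tapply(pi * (big$dbh / 200)^2, key, sum, default = 0)
  out <- setNames(rep(0, length(sites)), sites)
  out[names(ba)] <- ba
  out
}

analyse_subset <- function(bundle, config) {
  strata <- c(ground = "ground", understorey = "understorey",
              subcanopy = "subcanopy", canopy = "canopy")
  env <- bundle$environment
  env <- env[order(paste0(env$station, env$plot)), , drop = FALSE]
  sites <- paste0(env$station, env$plot)
  design <- plot_environment_design(env)
  design$basal_area <- plot_basal_area(bundle$stems, sites)

  ## --- diversity: per-plot alpha and per-station partition per stratum
  diversity <- list()
  trends <- list()
  log <- character(0)
  for (nm in names(strata)) {
    mats <- try(build_community_matrices(
      bundle, level = "plot", form = "abundance",
      strata = if (nm == "ground") "ground" else strata[[nm]]),
      silent = TRUE)
    if (inherits(mats, "try-error")) {
      log <- c(log, sprintf("stratum %s: no records, skipped", nm))
      next
    }
    alpha_tab <- suppressWarnings(plot_alpha_table(mats))
    alpha_tab$station <- station_of(alpha_tab$site)
    parts <- lapply(split(seq_len(nrow(mats)),
                          station_of(rownames(mats))), function(idx) {
      p <- try(suppressWarnings(
        additive_beta_partition(mats[idx, , drop = FALSE])),
        silent = TRUE)
      if (inherits(p, "try-error")) NULL else p
    })
    part_tab <- do.call(rbind, lapply(names(parts), function(stn) {
      p <- parts[[stn]]
      if (is.null(p)) return(data.frame(
        station = as.integer(stn), station_alpha = NA_real_,
        mean_plot_alpha = NA_real_, beta = NA_real_, n_plots = NA_integer_))
      data.frame(station = as.integer(stn),
                 station_alpha = p$station_alpha,
                 mean_plot_alpha = p$mean_plot_alpha, beta = p$beta,
                 n_plots = p$n_plots)
    }))
    diversity[[nm]] <- list(alpha = alpha_tab, partition = part_tab)

    ## --- trend modelling: alpha vs elevation/slope/lai at plot level
    merged <- merge(alpha_tab, design, by = "site")
    merged <- merged[!is.na(merged$alpha), , drop = FALSE]
    tr <- list()
    if (nrow(merged) >= 8) {
      avg <- trend_model_averaging(
        merged$alpha, merged[, c("elevation", "slope", "lai")],
        retain_rule = config$retain_rule)
      tr$alpha <- avg
      if (identical(avg$elevation_form, "quadratic"))
        tr$alpha_mos <- mos_extremum_test(merged$elevation, merged$alpha,
                                          level = config$mos_level)
    }
    ## beta vs station-level covariates (few observations: models that
    ## cannot be estimated are skipped inside trend_model_averaging)
    beta_ok <- part_tab[!is.na(part_tab$beta), , drop = FALSE]
    if (nrow(beta_ok) >= 5) {
      env_stn <- aggregate(design[, c("elevation", "slope", "lai")],
                           by = list(station = station_of(design$site)),
                           FUN = mean)
      bm <- merge(beta_ok, env_stn, by = "station")
      tr$beta <- try(trend_model_averaging(
        bm$beta, bm[, c("elevation", "slope", "lai")],
        max_interaction_order = 1,
        retain_rule = config$retain_rule), silent = TRUE)
      if (inherits(tr$beta, "try-error")) {
        log <- c(log, sprintf("stratum %s: beta trend not estimable", nm))
        tr$beta <- NULL
      }
    }
    trends[[nm]] <- tr
  }

  ## --- biomass
  calib <- calibrate_height_coefficient(
    data.frame(station = env$station, height = env$tallest_height,
               dbh = env$tallest_dbh))
  biomass <- do.call(rbind, lapply(seq_along(sites), function(i) {
    stn <- env$station[i]
    pl <- bundle$stems[paste0(bundle$stems$station,
                              bundle$stems$plot) == sites[i], ,
                       drop = FALSE]
    pl <- pl[pl$dbh >= 10, , drop = FALSE]
    pb <- plot_agb_density(pl, calib$c[match(stn, calib$station)],
                           bundle$wood_density)
    data.frame(site = sites[i], station = stn,
               agb_kg_subcanopy = pb$agb_subcanopy,
               agb_kg_canopy = pb$agb_canopy,
               agb_density_kg_m2 = pb$agb_density)
  }))
  biomass_trend <- try(trend_model_averaging(
    biomass$agb_density_kg_m2,
    design[match(biomass$site, design$site), c("elevation", "slope")],
    main_effects = c("elevation", "slope"),
    retain_rule = config$retain_rule), silent = TRUE)
  if (inherits(biomass_trend, "try-error")) biomass_trend <- NULL

  ## --- composition: multivariate GLM analysis of deviance per stratum
  composition <- list()
  for (nm in names(strata)) {
    mats <- try(build_community_matrices(
      bundle, level = "plot", form = "abundance",
      strata = if (nm == "ground") "ground" else strata[[nm]]),
      silent = TRUE)
    if (inherits(mats, "try-error")) next
    ## drop very rare species: with ~20 sites, species seen in fewer
    ## than 3 plots carry almost no information and destabilize the
    ## per-species dispersion estimates
    mats <- mats[, colSums(mats > 0) >= config$min_occurrence,
                 drop = FALSE]
    if (ncol(mats) < 2) next
    d <- design[match(rownames(mats), design$site), , drop = FALSE]
    sdes <- standardize_predictors(
      d[, c("elevation", "slope", "lai", "canopy_height",
            "basal_area")])
    term_blocks <- if (nm == "ground")
      list(structure = c("basal_area", "canopy_height", "lai"),
           slope = "slope", elevation = "elevation")
    else list(slope = "slope", elevation = "elevation")
    comp <- try({
      fit <- suppressWarnings(multivariate_fit(mats, sdes,
                                               terms = term_blocks))
      percent_deviance(anova_deviance_resampled(
        fit, n_resamples = config$n_resamples))
    }, silent = TRUE)
    if (inherits(comp, "try-error")) {
      log <- c(log, sprintf("stratum %s: composition analysis failed",
                            nm))
      next
    }
    composition[[nm]] <- comp
  }

  ## --- phylogenetic structure: station-level pooled woody presence
  phylo <- try({
    pres <- build_community_matrices(bundle, level = "station",
                                     form = "presence")
    keep <- intersect(colnames(pres), bundle$phylogeny$tip.label)
    if (length(keep) < ncol(pres))
      log <- c(log, sprintf("phylo: %d species not in tree dropped",
                            ncol(pres) - length(keep)))
    suppressWarnings(ses_mpd(pres[, keep, drop = FALSE],
                             bundle$phylogeny, n_null = config$n_null,
                             burn_in = config$burn_in,
                             thin = config$thin))
  }, silent = TRUE)
  if (inherits(phylo, "try-error")) {
    log <- c(log, "phylo structure analysis failed")
    phylo <- NULL
  }

  list(diversity = diversity, trends = trends,
       height_calibration = calib, biomass = biomass,
       biomass_trend = biomass_trend, composition = composition,
       phylo = phylo, log = log)
}

#' Run the full gradient analysis
#'
#' Orchestrates every stage on a dataset bundle: per-stratum diversity
#' partitioning, trend model averaging, biomass estimation, multivariate
#' composition analysis and phylogenetic community structure. The whole
#' set of result tables is produced twice - for all stations and for
#' stations at or below `forest_max_elevation` - mirroring the dual
#' analyses appropriate when a gradient's top station belongs to a
#' different habitat. The run is reproducible for a fixed
#' `config$seed`.
#'
#' @param bundle a `gradient_bundle` or `synthetic_dataset`.
#' @param config an [analysis_config()].
#' @param out optional directory; when given, result tables are written
#'   as CSV plus a JSON run summary.
#' @return list of class `gradient_results` with elements `all` and
#'   `forest` (each as returned by the per-subset analysis) and `config`.
#' @export
run_full_analysis <- function(bundle, config = analysis_config(),
                              out = NULL) {
  subset_bundle <- function(b, max_elev) {
    keep_env <- b$environment$elevation <= max_elev
    stations <- b$environment$station[keep_env]
    b$environment <- b$environment[keep_env, , drop = FALSE]
    b$stems <- b$stems[b$stems$station %in% stations, , drop = FALSE]
    b$ground_cover <- b$ground_cover[b$ground_cover$station %in%
                                       stations, , drop = FALSE]
    b
  }
  set.seed(derive_seed(config$seed, "analysis"))
  res_all <- analyse_subset(bundle, config)
  res_forest <- NULL
  if (config$run_both) {
    set.seed(derive_seed(config$seed, "analysis"))
    res_forest <- analyse_subset(
      subset_bundle(bundle, config$forest_max_elevation), config)
  }
  results <- structure(list(all = res_all, forest = res_forest,
                            config = config),
                       class = "gradient_results")
  if (!is.null(out)) write_results(results, out)
  results
}

#' Write result tables and a JSON run summary
#'
#' @param results a `gradient_results` object.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump_subset <- function(res, tag) {
    if (is.null(res)) return(NULL)
    for (nm in names(res$diversity)) {
      write.csv(res$diversity[[nm]]$alpha,
                file.path(dir, sprintf("%s_alpha_%s.csv", tag, nm)),
                row.names = FALSE)
      write.csv(res$diversity[[nm]]$partition,
                file.path(dir, sprintf("%s_beta_%s.csv", tag, nm)),
                row.names = FALSE)
    }
    write.csv(res$biomass, file.path(dir, sprintf("%s_biomass.csv", tag)),
              row.names = FALSE)
    for (nm in names(res$composition))
      write.csv(as.data.frame(res$composition[[nm]]),
                file.path(dir, sprintf("%s_composition_%s.csv", tag, nm)),
                row.names = FALSE)
    if (!is.null(res$phylo))
      write.csv(as.data.frame(res$phylo),
                file.path(dir, sprintf("%s_phylo.csv", tag)),
                row.names = FALSE)
    for (nm in names(res$trends)) {
      tr <- res$trends[[nm]]
      if (!is.null(tr$alpha))
        write.csv(tr$alpha$table,
                  file.path(dir, sprintf("%s_models_alpha_%s.csv",
                                         tag, nm)), row.names = FALSE)
    }
  }
  dump_subset(results$all, "all")
  dump_subset(results$forest, "forest")
  summary <- results_summary(results)
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Headline statistics of a full analysis
#'
#' @param results a `gradient_results` object.
#' @return nested list of the run's headline numbers.
#' @export
results_summary <- function(results) {
  one <- function(res) {
    if (is.null(res)) return(NULL)
    imp <- lapply(res$trends, function(tr)
      if (!is.null(tr$alpha)) as.list(tr$alpha$importance) else NULL)
    comp <- lapply(res$composition, function(tab)
      list(pct_model_total = tab$pct_model_total[1],
           p_values = setNames(as.list(tab$p_value), tab$term)))
    phylo <- if (!is.null(res$phylo))
      setNames(as.list(res$phylo$nri), res$phylo$community) else NULL
    list(alpha_importance = imp,
         composition = comp,
         nri = phylo,
         biomass_range_kg_m2 = range(res$biomass$agb_density_kg_m2),
         log = res$log)
  }
  list(all = one(results$all), forest = one(results$forest))
}

#' @export
print.gradient_results <- function(x, ...) {
  cat("Elevational-gradient analysis results\n")
  for (tag in c("all", "forest")) {
    res <- x[[tag]]
    if (is.null(res)) next
    cat(sprintf("  [%s] strata analysed: %s\n", tag,
                paste(names(res$diversity), collapse = ", ")))
    if (!is.null(res$phylo)) {
      sig <- res$phylo$community[!is.na(res$phylo$nri) &
                                   res$phylo$p_low < 0.05]
      cat(sprintf("  [%s] phylogenetically clustered stations: %s\n",
                  tag, if (length(sig)) paste(sig, collapse = ", ")
                  else "none"))
    }
  }
  invisible(x)
}
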