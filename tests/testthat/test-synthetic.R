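test_that("configuration invariants are enforced", {
  expect_s3_class(gradient_config(), "gradient_config")
  expect_error(gradient_config(station_elevations = c(1000, 1000),
                               n_stations = 2),
               class = "invalid_argument")
  expect_error(gradient_config(plot_radii = c(5, 1, 10, 20)),
               class = "invalid_argument")
  expect_error(gradient_config(strata_dbh_bounds = c(10, 2, 30)),
               class = "invalid_argument")
  expect_error(gradient_config(pool_size = 1),
               class = "invalid_argument")
})

test_that("simulated phylogenies are ultrametric, labelled and seeded", {
  cherry <- generate_phylogeny(2, seed = 5)
  depths <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(depths[1], depths[2])
  big <- generate_phylogeny(50, seed = 5)
  expect_length(big$tip.label, 50)
  expect_false(anyDuplicated(big$tip.label) > 0)
  expect_true(all(big$edge.length > 0))
  expect_true(ape::is.ultrametric(big, tol = 1e-8))
  again <- generate_phylogeny(50, seed = 5)
  expect_identical(ape::write.tree(big), ape::write.tree(again))
  expect_error(generate_phylogeny(1), class = "invalid_argument")
})

test_that("optima respect the Brownian degenerate case and clipping", {
  tree <- generate_phylogeny(20, seed = 3)
  flat <- evolve_optima(tree, 1500, 0, c(800, 2400), seed = 1)
  expect_true(all(flat == 1500))
  opt <- evolve_optima(tree, 1500, 4e5, c(800, 2400), seed = 1)
  expect_true(all(opt >= 800 & opt <= 2400))
  expect_error(evolve_optima(tree, 1500, -1, c(800, 2400)),
               class = "invalid_argument")
})

test_that("Brownian optima diverge with phylogenetic distance", {
  ## squared tip differences should increase with cophenetic distance
  sq_diff <- dist_cop <- numeric(0)
  for (rep in 1:100) {
    tree <- generate_phylogeny(8, seed = 1000 + rep)
    opt <- evolve_optima(tree, 0, 1e4, c(-1e6, 1e6), seed = 2000 + rep)
    D <- stats::cophenetic(tree)
    ut <- upper.tri(D)
    dd <- outer(opt, opt, `-`)[ut]^2
    sq_diff <- c(sq_diff, dd)
    dist_cop <- c(dist_cop, (D / max(D))[ut])
  }
  expect_gt(cor(sq_diff, dist_cop, method = "spearman"), 0.1)
})

test_that("log-series sampler conserves individuals and matches theory", {
  expect_identical(sample_logseries_abundances(5, 1, seed = 1), 1L)
  for (i in 1:25) {
    n <- sample(1:400, 1)
    ab <- sample_logseries_abundances(runif(1, 0.5, 40), n)
    expect_identical(sum(ab), n)
    expect_true(all(ab >= 1))
  }
  expect_error(sample_logseries_abundances(0, 10),
               class = "invalid_argument")
  expect_error(sample_logseries_abundances(-2, 10),
               class = "invalid_argument")
  ## E[S] close to alpha*log(1 + n/alpha)
  set.seed(42)
  alpha <- 5
  n <- 1000
  s_obs <- replicate(500, length(sample_logseries_abundances(alpha, n)))
  expect_lt(abs(mean(s_obs) / (alpha * log(1 + n / alpha)) - 1), 0.05)
})

test_that("occupancy response curve is a clipped Gaussian", {
  expect_equal(occupancy_probability(1500, 1500, 200, 0.8), 0.8)
  expect_equal(occupancy_probability(1700, 1500, 200, 0.8),
               occupancy_probability(1300, 1500, 200, 0.8))
  expect_lt(occupancy_probability(1500 + 10 * 200, 1500, 200, 1), 1e-20)
  expect_error(occupancy_probability(1500, 1500, 0, 1),
               class = "invalid_argument")
})

test_that("stem sizes respect the stratum dbh intervals", {
  sz <- sample_stem_sizes(c(understorey = 300, subcanopy = 300,
                            canopy = 300), seed = 9)
  expect_true(all(sz$understorey >= 2 & sz$understorey < 10))
  expect_true(all(sz$subcanopy >= 10 & sz$subcanopy < 30))
  expect_true(all(sz$canopy >= 30 & sz$canopy <= 120))
  empty <- sample_stem_sizes(c(understorey = 0), seed = 9)
  expect_length(empty$understorey, 0)
  expect_length(empty$canopy, 0)
})

test_that("community sampling is seeded and responds to the filter", {
  cfg <- gradient_config(pool_size = 30, seed = 11)
  tree <- generate_phylogeny(30, seed = 11)
  opt <- evolve_optima(tree, 1500, 1e5, cfg$optimum_range, seed = 12)
  a <- sample_station_communities(cfg, tree, opt, seed = 13)
  b <- sample_station_communities(cfg, tree, opt, seed = 13)
  expect_identical(a, b)
  expect_true(all(a$understorey >= 0))
  expect_true(all(a$understorey == round(a$understorey)))
  ## degenerate filter: certain occupancy keeps every drawn individual
  cfg_open <- gradient_config(pool_size = 30, max_occupancy = 1, seed = 11)
  tol <- setNames(rep(1e9, 30), tree$tip.label)
  open <- sample_station_communities(cfg_open, tree, opt, seed = 13,
                                     tolerances = tol)
  narrow <- sample_station_communities(cfg, tree, opt, seed = 13,
                                       tolerances = setNames(
                                         rep(50, 30), tree$tip.label))
  expect_gt(sum(open$understorey), sum(narrow$understorey))
  expect_true(all(rowSums(open$understorey) > 0))
})

test_that("environment trends follow the configured shapes", {
  cfg <- gradient_config(covariate_params = list(
    lai_sd = 0, height_sd = 0, slope_sd = 0, open_sd = 0,
    height_coef_sd = 0), seed = 2)
  env <- generate_environment(cfg, seed = 2)
  cp <- cfg$covariate_params
  expect_equal(env$lai,
               cp$lai_max - cp$lai_curv * ((env$elevation - cp$lai_peak) /
                                             1000)^2,
               tolerance = 1e-12)
  expect_equal(env$canopy_height,
               cp$height_base + cp$height_slope * (env$elevation - 1000),
               tolerance = 1e-12)
  env2 <- generate_environment(gradient_config(seed = 3), seed = 3)
  expect_true(all(env2$canopy_openness >= 0 &
                    env2$canopy_openness <= 100))
})

test_that("slope is uncorrelated with elevation across replicates", {
  cors <- vapply(1:60, function(i) {
    env <- generate_environment(gradient_config(seed = i), seed = i)
    cor(env$slope, env$elevation)
  }, numeric(1))
  se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors)), 2 * se + 0.02)
})

test_that("the full dataset satisfies its invariants", {
  ds <- default_test_dataset()
  expect_equal(nrow(ds$environment), 7 * 3)
  expect_true(all(ds$stems$dbh >= 2))
  expect_true(all(ds$stems$species %in% ds$phylogeny$tip.label))
  expect_true(all(paste0(ds$stems$station, ds$stems$plot) %in%
                    paste0(ds$environment$station, ds$environment$plot)))
  expect_true(all(ds$ground_cover$cover_class %in% 1:6))
  expect_setequal(names(ds$truth$optima), ds$phylogeny$tip.label)
  ## determinism and non-degeneracy
  ds2 <- generate_dataset(gradient_config(seed = 20260924))
  expect_identical(ds$stems, ds2$stems)
  expect_identical(ape::write.tree(ds$phylogeny),
                   ape::write.tree(ds2$phylogeny))
  ds3 <- generate_dataset(gradient_config(seed = 1))
  expect_false(identical(ds$stems, ds3$stems))
})
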