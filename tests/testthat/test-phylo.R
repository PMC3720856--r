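test_that("cophenetic distances are path sums", {
  tree <- ape::read.tree(text = "((A:2,B:2):3,C:5);")
  D <- cophenetic_matrix(tree)
  expect_equal(D["A", "B"], 4)
  expect_equal(D["A", "C"], 10)
  expect_equal(D["B", "C"], 10)
  expect_true(all(diag(D) == 0))
  ## two leaves at depth 5
  two <- ape::read.tree(text = "(A:5,B:5);")
  expect_equal(cophenetic_matrix(two)["A", "B"], 10)
  ## random tree vs the naive path-walking oracle
  rt <- generate_phylogeny(12, seed = 77)
  Dr <- cophenetic_matrix(rt)
  Do <- oracle_cophenetic(rt)
  expect_equal(Dr[rownames(Do), colnames(Do)], Do, tolerance = 1e-10)
  dup <- tree
  dup$tip.label <- c("A", "A", "C")
  expect_error(cophenetic_matrix(dup), class = "invalid_tree")
})

test_that("MPD averages pairwise distances of the present species", {
  tree <- ape::read.tree(text = "((A:2,B:2):3,C:5);")
  D <- cophenetic_matrix(tree)
  expect_equal(mpd_observed(c("A", "B"), D), 4)
  expect_equal(mpd_observed(c("A", "B", "C"), D), mean(c(4, 10, 10)))
  ## star tree: every pair at twice the tip depth
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  Ds <- cophenetic_matrix(star)
  expect_equal(mpd_observed(c("A", "C", "D"), Ds), 6)
  expect_error(mpd_observed("A", D), class = "undefined_mpd")
  expect_error(mpd_observed(c("A", "Z"), D), class = "invalid_argument")
})

test_that("checkerboard swaps preserve margins exactly", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  out <- independent_swap(m, n_attempts = 1, seed = 1)
  expect_equal(attr(out, "n_swapped"), 1)
  expect_equal(unclass(out)[, ], matrix(c(0L, 1L, 1L, 0L), 2, 2))
  set.seed(123)
  big <- matrix(rbinom(20 * 15, 1, 0.3), 20, 15)
  storage.mode(big) <- "integer"
  ran <- independent_swap(big, n_attempts = 1e5, seed = 2)
  expect_identical(rowSums(ran), rowSums(big))
  expect_identical(colSums(ran), colSums(big))
  expect_gt(attr(ran, "n_swapped"), 0)
  ## a matrix with no checkerboard is returned unchanged with a warning
  full <- matrix(1L, 3, 3)
  expect_warning(sw <- independent_swap(full, 100, seed = 3),
                 "no checkerboard")
  expect_true(attr(sw, "unswappable"))
  expect_error(independent_swap(matrix(2, 2, 2), 10),
               class = "invalid_argument")
})

test_that("the swap chain explores the fixed-margin space", {
  m <- rbind(c(1L, 1L, 0L), c(1L, 0L, 0L), c(0L, 0L, 1L))
  seen <- character(0)
  set.seed(5)
  cur <- m
  for (i in 1:200) {
    cur <- independent_swap(cur, 20)
    seen <- c(seen, matrix_key(cur))
  }
  expect_gt(length(unique(seen)), 1)
})

test_that("SES/NRI obeys its identities and degenerate flags", {
  set.seed(6)
  tree <- generate_phylogeny(15, seed = 6)
  sp <- tree$tip.label
  pres <- rbind(
    full = rep(1L, 15),
    a = as.integer(runif(15) < 0.5),
    b = as.integer(runif(15) < 0.4),
    c = as.integer(runif(15) < 0.6))
  colnames(pres) <- sp
  res <- ses_mpd(pres, tree, n_null = 99, burn_in = 2000, thin = 50,
                 seed = 7)
  expect_s3_class(res, "phylo_structure")
  ok <- !is.na(res$ses)
  expect_equal(res$nri[ok], -res$ses[ok])
  expect_true(all(res$p_low[!is.na(res$p_low)] > 0 &
                    res$p_low[!is.na(res$p_low)] <= 1))
  ## the full community cannot change under an occupancy-preserving null
  expect_true(res$degenerate[res$community == "full"])
  expect_true(is.na(res$nri[res$community == "full"]))
  ## observed MPD matches a direct computation
  expect_equal(res$mpd_obs[res$community == "a"],
               mpd_observed(sp[pres["a", ] == 1],
                            cophenetic_matrix(tree)))
})

test_that("random communities have NRI centred on zero", {
  set.seed(8)
  tree <- generate_phylogeny(25, seed = 8)
  sp <- tree$tip.label
  nris <- c()
  for (r in 1:30) {
    pres <- t(sapply(1:5, function(i)
      as.integer(seq_along(sp) %in% sample(25, 10))))
    colnames(pres) <- sp
    rownames(pres) <- paste0("c", 1:5)
    res <- ses_mpd(pres, tree, n_null = 99, burn_in = 1000, thin = 30)
    nris <- c(nris, res$nri[!is.na(res$nri)])
  }
  se <- sd(nris) / sqrt(length(nris))
  expect_lt(abs(mean(nris)), 3 * se + 0.05)
})

test_that("without phylogenetic signal the generated gradients show no structure", {
  nris <- c()
  for (r in 1:30) {
    ds <- generate_dataset(gradient_config(
      pool_size = 40, ground_pool_size = 5, phylo_signal = 0,
      root_optimum = 1600,
      tolerance_distribution = c(meanlog = log(400), sdlog = 0.2),
      seed = 7000 + r))
    pres <- build_community_matrices(ds, "station", "presence")
    sm <- suppressWarnings(ses_mpd(pres, ds$phylogeny, n_null = 99,
                                   burn_in = 3000, thin = 100))
    nris <- c(nris, sm$nri[!is.na(sm$nri) & !sm$degenerate])
  }
  se <- sd(nris) / sqrt(length(nris))
  expect_lt(abs(mean(nris)), 2 * se + 0.05)
})

test_that("NRI from printed components reproduces a published summary", {
  ref <- read.csv(system.file("extdata", "phylo_structure_reference.csv",
                              package = "elevgrad"))
  nri <- nri_components(ref$mpd_observed, ref$null_mean, ref$null_sd)
  expect_equal(nri, ref$nri_printed, tolerance = 0.01)
})
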