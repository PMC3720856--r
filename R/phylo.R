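## Community phylogenetic structure ----------------------------------------
##
## Mean phylogenetic (cophenetic) distance per community and its
## standardized effect size / net relatedness index under the
## independent-swap null model, which randomizes a binary site x species
## matrix by 2x2 checkerboard flips, preserving community richness (row
## sums) and species occupancy (column sums) exactly.

#' Cophenetic distance matrix of a phylogeny
#'
#' Pairwise leaf-to-leaf path-length distances (sums of branch lengths).
#'
#' @param tree an [ape::phylo] object with unique tip labels.
#' @return square symmetric numeric matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop_elevgrad("tree must be a 'phylo' object", "invalid_argument")
  if (length(tree$tip.label) < 2)
    stop_elevgrad("tree must have >= 2 leaves", "invalid_argument")
  if (anyDuplicated(tree$tip.label))
    stop_elevgrad("duplicate leaf labels", "invalid_tree")
  stats::cophenetic(tree)
}

#' Mean phylogenetic distance of a community
#'
#' Mean cophenetic distance over all unordered pairs of distinct species
#' present (presence-weighted; abundances ignored).
#'
#' @param present_species character vector of >= 2 species labels.
#' @param dist cophenetic distance matrix indexed by species labels.
#' @return mean pairwise distance.
#' @export
mpd_observed <- function(present_species, dist) {
  present_species <- unique(present_species)
  if (length(present_species) < 2)
    stop_elevgrad("MPD undefined for fewer than 2 species",
                  "undefined_mpd")
  if (!all(present_species %in% rownames(dist)))
    stop_elevgrad("species missing from the distance matrix",
                  "invalid_argument")
  sub <- dist[present_species, present_species]
  mean(sub[upper.tri(sub)])
}

#' Independent-swap randomization of a presence/absence matrix
#'
#' Repeatedly draws random 2x2 submatrices and flips those in
#' checkerboard form (`[[1,0],[0,1]]` or `[[0,1],[1,0]]`). Row and column
#' sums are conserved exactly. If the matrix admits no checkerboard the
#' input is returned with a warning and attribute `unswappable = TRUE`.
#'
#' @param presence binary sites x species matrix.
#' @param n_attempts number of swap attempts.
#' @param seed optional integer seed.
#' @return randomized binary matrix with attribute `n_swapped`.
#' @export
independent_swap <- function(presence, n_attempts = 30000, seed = NULL) {
  if (!all(presence %in% c(0, 1)))
    stop_elevgrad("matrix must be binary", "invalid_argument")
  if (!is.null(seed)) set.seed(seed)
  storage.mode(presence) <- "integer"
  res <- cpp_swap_run(presence, n_attempts)
  out <- res$matrix
  dimnames(out) <- dimnames(presence)
  attr(out, "n_swapped") <- res$n_swapped
  if (res$n_swapped == 0 && !has_checkerboard(presence)) {
    warning("matrix admits no checkerboard; returned unchanged")
    attr(out, "unswappable") <- TRUE
  }
  out
}

#' Net relatedness index from its components
#'
#' The NRI identity `nri = -(mpd_obs - null_mean) / null_sd`: positive
#' values indicate phylogenetic clustering (observed communities more
#' closely related than the null), negative values overdispersion. Useful
#' for recomputing NRI from published (observed, expected +/- sd)
#' summaries; a packaged example of such a summary table ships as
#' `system.file("extdata", "phylo_structure_reference.csv",
#' package = "elevgrad")`.
#'
#' @param mpd_obs observed mean phylogenetic distance.
#' @param null_mean,null_sd null-distribution moments.
#' @return NRI values.
#' @export
nri_components <- function(mpd_obs, null_mean, null_sd) {
  (null_mean - mpd_obs) / null_sd
}

has_checkerboard <- function(m) {
  if (nrow(m) < 2 || ncol(m) < 2) return(FALSE)
  for (i in seq_len(nrow(m) - 1))
    for (j in (i + 1):nrow(m)) {
      d <- m[i, ] - m[j, ]
      if (any(d == 1) && any(d == -1)) return(TRUE)
    }
  FALSE
}

#' Standardized effect size of MPD and the net relatedness index
#'
#' Builds a null distribution of each community's MPD from a sequential
#' independent-swap chain on the whole presence matrix (`burn_in`
#' attempts, then one sample every `thin` attempts), and reports the
#' standardized effect size `ses = (obs - null mean) / null sd`, the net
#' relatedness index `nri = -ses` (positive NRI = phylogenetic
#' clustering, negative = overdispersion), and the one-tailed proportion
#' `p_low = (1 + #(null <= obs)) / (1 + n_null)`, small when the
#' community is more closely related than the null expects. Null moments
#' use the null samples only (the observed value is not pooled in).
#' Communities with fewer than 2 species get `NA` with a warning;
#' communities whose null distribution is degenerate (e.g. the full pool)
#' are flagged and get `NA` NRI.
#'
#' @param presence binary sites x species matrix (rows = communities).
#' @param tree phylogeny containing every species in the matrix, or a
#'   precomputed cophenetic matrix.
#' @param n_null number of null samples (>= 99).
#' @param burn_in swap attempts before the first sample.
#' @param thin swap attempts between samples.
#' @param seed optional integer seed.
#' @return data.frame of class `phylo_structure`: one row per community
#'   with `community`, `n_species`, `mpd_obs`, `null_mean`, `null_sd`,
#'   `ses`, `nri`, `p_low`, `n_null`, `degenerate`.
#' @export
ses_mpd <- function(presence, tree, n_null = 999, burn_in = 30000,
                    thin = 3000, seed = NULL) {
  if (n_null < 99)
    stop_elevgrad("need n_null >= 99", "invalid_argument")
  if (!all(presence %in% c(0, 1)))
    stop_elevgrad("matrix must be binary", "invalid_argument")
  if (!is.null(seed)) set.seed(seed)
  D <- if (inherits(tree, "phylo")) cophenetic_matrix(tree) else tree
  sp <- colnames(presence)
  if (is.null(sp) || !all(sp %in% rownames(D)))
    stop_elevgrad("matrix species must appear in the phylogeny",
                  "invalid_argument")
  D <- D[sp, sp]
  storage.mode(presence) <- "integer"
  rich <- rowSums(presence)
  if (any(rich < 2))
    warning(sprintf("%d communit(y/ies) with < 2 species: NA returned",
                    sum(rich < 2)))
  mpd_row <- function(m, i) {
    idx <- which(m[i, ] == 1)
    if (length(idx) < 2) return(NA_real_)
    sub <- D[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  obs <- vapply(seq_len(nrow(presence)), function(i)
    mpd_row(presence, i), numeric(1))
  samples <- cpp_swap_samples(presence, as.integer(n_null), burn_in, thin)
  null_mpd <- matrix(NA_real_, nrow = n_null, ncol = nrow(presence))
  for (s in seq_len(n_null)) {
    m <- samples[[s]]
    null_mpd[s, ] <- vapply(seq_len(nrow(presence)), function(i)
      mpd_row(m, i), numeric(1))
  }
  null_mean <- colMeans(null_mpd)
  null_sd <- apply(null_mpd, 2, sd)
  degenerate <- is.finite(null_sd) & null_sd == 0
  ses <- (obs - null_mean) / null_sd
  ses[degenerate] <- NA_real_
  p_low <- vapply(seq_along(obs), function(i) {
    if (is.na(obs[i])) return(NA_real_)
    (1 + sum(null_mpd[, i] <= obs[i])) / (1 + n_null)
  }, numeric(1))
  communities <- rownames(presence)
  if (is.null(communities))
    communities <- as.character(seq_len(nrow(presence)))
  out <- data.frame(community = communities,
                    n_species = rich,
                    mpd_obs = obs,
                    null_mean = null_mean,
                    null_sd = null_sd,
                    ses = ses,
                    nri = -ses,
                    p_low = p_low,
                    n_null = n_null,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("phylo_structure", "data.frame")
  out
}
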