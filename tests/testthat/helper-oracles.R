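# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain bisection for the log-series relation,
# naive path walking for tree distances, exhaustive subset filtering for
# model lattices and fixed-margin matrices.

# bisection solver for S = a * log(1 + N/a), independent of fisher_alpha()
oracle_fisher_alpha <- function(s, n, tol = 1e-12) {
  f <- function(a) a * log(1 + n / a) - s
  lo <- 1e-9
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol * (1 + hi)) break
  }
  (lo + hi) / 2
}

# naive cophenetic distances by walking tip-to-root paths
oracle_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(tip) {
    nodes <- integer(0)
    depth <- numeric(0)
    node <- tip
    d <- 0
    while (node != root) {
      nodes <- c(nodes, node)
      depth <- c(depth, d)
      d <- d + elen[node]
      node <- parent[node]
    }
    nodes <- c(nodes, root)
    depth <- c(depth, d)
    list(nodes = nodes, depth = depth)
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  D <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1))
    for (j in (i + 1):ntip) {
      pi_ <- paths[[i]]
      pj <- paths[[j]]
      common <- intersect(pi_$nodes, pj$nodes)
      anc <- common[which.min(match(common, pi_$nodes))]
      di <- pi_$depth[match(anc, pi_$nodes)]
      dj <- pj$depth[match(anc, pj$nodes)]
      D[i, j] <- D[j, i] <- di + dj
    }
  D
}

# every marginality-closed subset of the term lattice, constructed by a
# different route than the package (grow models by adding one admissible
# term at a time until closure of the reachable set)
oracle_hierarchical_models <- function(mains, max_order = length(mains)) {
  terms <- character(0)
  for (k in seq_len(min(max_order, length(mains))))
    terms <- c(terms, apply(combn(sort(mains), k), 2, paste,
                            collapse = ":"))
  admissible <- function(model, term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1) return(TRUE)
    margins <- apply(combn(parts, length(parts) - 1), 2,
                     function(p) paste(sort(p), collapse = ":"))
    all(margins %in% model)
  }
  seen <- new.env()
  key <- function(m) paste0("m:", paste(sort(m), collapse = "|"))
  frontier <- list(character(0))
  assign(key(character(0)), TRUE, envir = seen)
  models <- list(character(0))
  while (length(frontier)) {
    nxt <- list()
    for (m in frontier) {
      for (t in setdiff(terms, m)) {
        if (admissible(m, t)) {
          m2 <- c(m, t)
          k <- key(m2)
          if (!exists(k, envir = seen)) {
            assign(k, TRUE, envir = seen)
            models[[length(models) + 1]] <- m2
            nxt[[length(nxt) + 1]] <- m2
          }
        }
      }
    }
    frontier <- nxt
  }
  models
}

# all binary matrices with the given row/column sums, by exhaustion
oracle_fixed_margin_matrices <- function(rsum, csum) {
  nr <- length(rsum)
  nc <- length(csum)
  out <- list()
  for (mask in 0:(2^(nr * nc) - 1)) {
    m <- matrix(as.integer(intToBits(mask))[seq_len(nr * nc)], nr, nc)
    if (all(rowSums(m) == rsum) && all(colSums(m) == csum))
      out[[length(out) + 1]] <- m
  }
  out
}

matrix_key <- function(m) paste(as.integer(m), collapse = "")

default_test_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(gradient_config(seed = 20260924))
    cache
  }
})
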