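# Brute-force oracles and small fixtures shared across the suite. Every
# oracle recomputes its quantity by a route independent of the package
# implementation it checks.

# Shared-path covariance by explicit path enumeration.
oracle_vcv <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  edge_above <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2L])
  path_edges <- lapply(seq_len(ntip), function(tip) {
    out <- integer(0); node <- tip
    while (!is.na(edge_above[node])) {
      out <- c(out, edge_above[node])
      node <- tree$edge[edge_above[node], 1L]
    }
    out
  })
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    shared <- intersect(path_edges[[i]], path_edges[[j]])
    C[i, j] <- sum(tree$edge.length[shared])
  }
  C
}

# Dense-inverse multivariate normal log-density.
oracle_mvn <- function(x, m, V) {
  n <- length(x)
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
            t(x - m) %*% solve(V) %*% (x - m))[1]
}

# GLS coefficients by explicit normal equations.
oracle_gls <- function(x, V, D) {
  Vi <- solve(V)
  drop(solve(t(D) %*% Vi %*% D, t(D) %*% Vi %*% x))
}

# OU tip covariance by variance accumulation down the tree (law of total
# covariance along the shared/unshared path segments).
oracle_ou <- function(tree, alpha, s2) {
  C <- termevol::phylo_vcv(tree)
  Td <- diag(C)
  n <- nrow(C)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tm <- C[i, j]
    vm <- s2 / (2 * alpha) * (1 - exp(-2 * alpha * tm))
    V[i, j] <- exp(-alpha * (Td[i] + Td[j] - 2 * tm)) * vm
  }
  V
}

# Profiled BM/transform likelihood on a dense (sigma2, z0) grid; used to
# confirm the optimizer is never beaten by more than a hair.
oracle_grid_loglik <- function(tree, x, sigma2_grid, z0_grid) {
  C <- termevol::phylo_vcv(tree)
  best <- -Inf
  for (s2 in sigma2_grid) for (z0 in z0_grid) {
    ll <- oracle_mvn(x, rep(z0, length(x)), s2 * C)
    if (ll > best) best <- ll
  }
  best
}

# A reproducible non-ultrametric tree: coalescent with tip-depth jitter.
fossil_tree <- function(n, seed, jitter = 0.3) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  term <- tr$edge[, 2L] <= n
  tr$edge.length[term] <- pmax(tr$edge.length[term] +
                                 stats::runif(sum(term), -jitter, jitter) *
                                   tr$edge.length[term], 1e-3)
  tr
}

# Small species table for matching/subsampling tests.
toy_records <- function() {
  data.frame(
    species = c("Alpha_a", "Alpha_b", "Beta_a", "Gamma_a", "Fossilus_rex"),
    genus = c("Alpha", "Alpha", "Beta", "Gamma", "Fossilus"),
    family = "F",
    caste = "imago",
    head_width_mm = c(1.0, 2.0, 1.5, 3.0, 2.5),
    status = c("modern", "modern", "modern", "modern", "fossil"),
    stringsAsFactors = FALSE)
}
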