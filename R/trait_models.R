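# Mean vectors and covariance matrices of the candidate trait-evolution
# models, and the exact multivariate-normal machinery underneath them.
#
# All models are Gaussian: the tip vector x ~ N(m(theta), sigma2 * W(shape)),
# where W is the (possibly transformed) phylogenetic covariance. The mean
# parameters (root state z0 and, for trend models, the slope mu) and sigma2
# profile out analytically, so fitting reduces to a 1-D search over the shape
# parameter (lambda, kappa, delta, alpha) or none at all (BM, trend).

MODEL_NAMES <- c("BM", "trend", "OU", "lambda", "kappa", "delta", "trend_BM")

#' Specify a trait-evolution model
#'
#' Builds a validated parameter set for one of the seven candidate models of
#' continuous trait evolution on a (possibly non-ultrametric) phylogeny:
#' unbiased Brownian motion (`BM`), BM with a directional trend (`trend`),
#' single-optimum Ornstein-Uhlenbeck (`OU`), Pagel's `lambda`, `kappa` and
#' `delta` transforms, and the clade-mixed `trend_BM` model in which a
#' designated clade evolves by plain BM while the rest of the tree carries a
#' directional trend.
#'
#' @param name Model name, one of
#'   `"BM", "trend", "OU", "lambda", "kappa", "delta", "trend_BM"`.
#' @param sigma2 Brownian rate (trait^2 per unit time), > 0.
#' @param z0 Root state (ln mm for head-width analyses).
#' @param mu Trend slope (trait per unit time); `trend` and `trend_BM` only.
#' @param alpha OU restoring strength (1/time), > 0; `OU` only.
#' @param lambda Pagel's lambda in \[0, 1\]; `lambda` only.
#' @param kappa Branch-length exponent in \[0, 1\]; `kappa` only.
#' @param delta Node-depth exponent in (0, 3\]; `delta` only.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(name, sigma2 = 1, z0 = 0, mu = NULL, alpha = NULL,
                       lambda = NULL, kappa = NULL, delta = NULL) {
  name <- match.arg(name, MODEL_NAMES)
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  shape <- list(mu = mu, alpha = alpha, lambda = lambda, kappa = kappa,
                delta = delta)
  given <- names(shape)[!vapply(shape, is.null, logical(1))]
  expected <- switch(name,
    BM = character(0), trend = "mu", trend_BM = "mu", OU = "alpha",
    lambda = "lambda", kappa = "kappa", delta = "delta")
  if (!identical(sort(given), sort(expected)))
    stop("model '", name, "' takes exactly the shape parameter(s) {",
         paste(expected, collapse = ", "), "}; got {",
         paste(given, collapse = ", "), "}")
  if (name == "OU" && alpha <= 0) stop("alpha must be > 0")
  if (name == "lambda" && (lambda < 0 || lambda > 1)) stop("lambda must be in [0, 1]")
  if (name == "kappa" && (kappa < 0 || kappa > 1)) stop("kappa must be in [0, 1]")
  if (name == "delta" && (delta <= 0 || delta > 3)) stop("delta must be in (0, 3]")
  structure(list(name = name, sigma2 = sigma2, z0 = z0, mu = mu, alpha = alpha,
                 lambda = lambda, kappa = kappa, delta = delta),
            class = "model_spec")
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving tip
#' variances unchanged. `lambda = 1` is the identity; `lambda = 0` is a star
#' phylogeny.
#'
#' @param C Symmetric PSD phylogenetic covariance.
#' @param lambda Value in \[0, 1\].
#' @export
transform_lambda <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  Cp <- C * lambda
  diag(Cp) <- diag(C)
  Cp
}

#' Pagel's kappa transform of branch lengths
#'
#' Raises every branch length to the power `kappa` (with 0^kappa defined as
#' 0). `kappa = 0` makes every positive branch contribute one unit of
#' expected change: evolution proportional to cladogenetic events.
#'
#' @param tree A `"phylo"`.
#' @param kappa Value in \[0, 1\].
#' @return The transformed tree (topology unchanged).
#' @export
transform_kappa <- function(tree, kappa) {
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  el <- tree$edge.length
  tree$edge.length <- ifelse(el == 0, 0, el^kappa)
  tree
}

#' Pagel's delta transform of node depths
#'
#' Maps every node's age-from-root t to t^delta, recomputes branch lengths,
#' and rescales the tree so its maximum tip depth equals the original
#' (keeping the rate parameter comparable across delta values). delta < 1
#' concentrates change early; delta > 1 concentrates it late.
#'
#' @param tree A `"phylo"`.
#' @param delta Value in (0, 3\].
#' @return The transformed tree (topology unchanged).
#' @export
transform_delta <- function(tree, delta) {
  if (delta <= 0 || delta > 3) stop("delta must be in (0, 3]")
  depth <- ape::node.depth.edgelength(tree)
  Tmax <- max(depth[seq_len(ape::Ntip(tree))])
  new_depth <- depth^delta * Tmax^(1 - delta)
  tree$edge.length <- new_depth[tree$edge[, 2L]] - new_depth[tree$edge[, 1L]]
  tree
}

#' Ornstein-Uhlenbeck covariance on a (possibly non-ultrametric) tree
#'
#' For tips i, j with shared path length `C_ij` and patristic distance
#' `d_ij = T_i + T_j - 2 C_ij`,
#' `V_ij = sigma2 / (2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha C_ij))`,
#' the covariance of a single-optimum OU process started at the optimum.
#' `expm1` keeps the Brownian limit (alpha -> 0, V -> sigma2 C) accurate.
#'
#' @param tree A `"phylo"`.
#' @param alpha Restoring strength, > 0.
#' @param sigma2 Rate, > 0.
#' @export
ou_covariance <- function(tree, alpha, sigma2 = 1) {
  if (alpha <= 0) stop("alpha must be > 0")
  C <- phylo_vcv(tree)
  Tdep <- diag(C)
  d <- outer(Tdep, Tdep, `+`) - 2 * C
  V <- sigma2 / (2 * alpha) * exp(pmax(-alpha * d, -745)) * (-expm1(pmax(-2 * alpha * C, -745)))
  (V + t(V)) / 2
}

#' Paint a clade for the mixed trend+BM model
#'
#' Labels every branch of the tree with a regime: `"bm"` for the crown group
#' of the designated clade, `"trend"` elsewhere. By convention the clade's
#' stem branch belongs to the trend regime (the directional size change runs
#' up to the origin of the clade); set `stem_in_bm = TRUE` for the opposite
#' convention.
#'
#' @param tree A `"phylo"`.
#' @param clade_tips Character vector of tip labels whose MRCA defines the
#'   clade, or `NULL` for no clade (all branches `"trend"`).
#' @param stem_in_bm Include the clade's stem branch in the `"bm"` regime.
#' @return A list of class `"regime_painting"` with `edge_label` (one label
#'   per row of `tree$edge`) and `clade_node`.
#' @export
paint_clade <- function(tree, clade_tips = NULL, stem_in_bm = FALSE) {
  validate_phylo(tree)
  lab <- rep("trend", nrow(tree$edge))
  node <- NULL
  if (!is.null(clade_tips) && length(clade_tips)) {
    miss <- setdiff(clade_tips, tree$tip.label)
    if (length(miss)) stop("clade tips not in tree: ", paste(miss, collapse = ", "))
    node <- if (length(clade_tips) == 1L) match(clade_tips, tree$tip.label)
            else ape::getMRCA(tree, clade_tips)
    desc <- .descendant_nodes(tree, node)
    in_crown <- tree$edge[, 1L] %in% c(node, desc)
    lab[in_crown] <- "bm"
    if (stem_in_bm) lab[tree$edge[, 2L] == node] <- "bm"
  }
  structure(list(edge_label = lab, clade_node = node, tree_hash = ape::Ntip(tree)),
            class = "regime_painting")
}

#' Paint every branch with a single regime
#'
#' @param tree A `"phylo"`.
#' @param regime `"trend"` or `"bm"`.
#' @export
paint_all <- function(tree, regime = c("trend", "bm")) {
  regime <- match.arg(regime)
  structure(list(edge_label = rep(regime, nrow(tree$edge)), clade_node = NULL,
                 tree_hash = ape::Ntip(tree)),
            class = "regime_painting")
}

.descendant_nodes <- function(tree, node) {
  # all nodes below `node`, excluding `node`
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack)) {
    kids <- unlist(children[as.character(stack)], use.names = FALSE)
    out <- c(out, kids)
    stack <- kids[kids > ape::Ntip(tree)]
  }
  out
}

#' Per-tip trend exposure under a regime painting
#'
#' For each tip, the summed length of the branches on its root-to-tip path
#' that are labelled `"trend"`. Under an all-trend painting this is the tip
#' depth; tips wholly inside the BM clade are exposed only along the path
#' down to the clade.
#'
#' @param tree A `"phylo"`.
#' @param painting A `"regime_painting"` covering every branch.
#' @return Named numeric vector of exposures, one per tip.
#' @export
trend_path_lengths <- function(tree, painting) {
  stopifnot(inherits(painting, "regime_painting"))
  lab <- painting$edge_label
  if (length(lab) != nrow(tree$edge))
    stop("painting labels ", length(lab), " branches; tree has ", nrow(tree$edge))
  if (any(!lab %in% c("trend", "bm"))) stop("unlabelled branch in painting")
  ntip <- ape::Ntip(tree)
  parent_edge <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2L])
  tau <- numeric(ntip)
  for (i in seq_len(ntip)) {
    node <- i; s <- 0
    repeat {
      e <- parent_edge[node]
      if (is.na(e)) break
      if (lab[e] == "trend") s <- s + tree$edge.length[e]
      node <- tree$edge[e, 1L]
    }
    tau[i] <- s
  }
  stats::setNames(tau, tree$tip.label)
}

#' Mean vector and covariance matrix of a model
#'
#' Assembles the exact multivariate-normal distribution of tip values implied
#' by a model specification on a given tree: for `BM`/`lambda`/`kappa`/
#' `delta` the mean is flat at the root state and the covariance is the
#' (transformed) phylogenetic covariance scaled by the rate; `trend` adds
#' `mu * depth` to each tip's mean; `trend_BM` adds `mu * trend exposure`
#' (see [trend_path_lengths()]); `OU` has a flat mean at the optimum-root and
#' the covariance of [ou_covariance()].
#'
#' @param spec A `"model_spec"`.
#' @param tree A `"phylo"`.
#' @param painting A `"regime_painting"`; required iff `spec$name ==
#'   "trend_BM"`.
#' @return List with `mean` (named vector) and `V` (covariance matrix).
#' @export
model_mean_cov <- function(spec, tree, painting = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if ((spec$name == "trend_BM") != !is.null(painting))
    stop("a regime painting is required exactly when the model is trend_BM")
  C <- phylo_vcv(tree)
  Tdep <- diag(C)
  n <- length(Tdep)
  m <- rep(spec$z0, n)
  V <- switch(spec$name,
    BM = spec$sigma2 * C,
    lambda = spec$sigma2 * transform_lambda(C, spec$lambda),
    kappa = spec$sigma2 * phylo_vcv(transform_kappa(tree, spec$kappa)),
    delta = spec$sigma2 * (C^spec$delta * max(Tdep)^(1 - spec$delta)),
    OU = ou_covariance(tree, spec$alpha, spec$sigma2),
    trend = { m <- spec$z0 + spec$mu * Tdep; spec$sigma2 * C },
    trend_BM = {
      m <- spec$z0 + spec$mu * trend_path_lengths(tree, painting)
      spec$sigma2 * C
    })
  names(m) <- rownames(C)
  list(mean = m, V = V)
}

#' Exact multivariate-normal log-likelihood
#'
#' Computes `-0.5 * (n log 2 pi + log |V| + (x - m)' V^{-1} (x - m))` via a
#' Cholesky factorization (no explicit inverse). Fails with the smallest
#' eigenvalue reported when `V` is not positive definite.
#'
#' @param x Observed tip values.
#' @param m Mean vector.
#' @param V Covariance matrix (symmetric positive definite).
#' @export
mvn_loglik <- function(x, m, V) {
  n <- length(x)
  if (length(m) != n || nrow(V) != n || ncol(V) != n)
    stop("dimension mismatch between x, m and V")
  L <- .chol_or_die(V)
  z <- backsolve(L, x - m, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

.chol_or_die <- function(V) {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(out)) {
    ev <- min(eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    stop("covariance matrix is not positive definite (smallest eigenvalue ",
         format(ev), "); near-zero branch lengths may need jitter")
  }
  out
}

#' Generalized least squares estimate of the mean parameters
#'
#' Solves `(D' V^{-1} D)^{-1} D' V^{-1} x` for the design `D` (a column of
#' ones for the root state and, for trend models, a column of tip depths or
#' trend exposures). Signals rank deficiency explicitly — on an ultrametric
#' tree the depth column is constant and the trend slope is confounded with
#' the root state.
#'
#' @param x Observed tip values.
#' @param V Covariance (symmetric positive definite).
#' @param design Design matrix with full column rank.
#' @return List with `coef`, `resid`, and `qform` (the GLS residual quadratic
#'   form `r' V^{-1} r`).
#' @export
gls_root_estimate <- function(x, V, design) {
  design <- as.matrix(design)
  L <- .chol_or_die(V)
  Dw <- backsolve(L, design, transpose = TRUE)
  xw <- backsolve(L, x, transpose = TRUE)
  qr_D <- qr(Dw)
  if (qr_D$rank < ncol(design))
    stop("rank-deficient design: mean parameters are confounded ",
         "(a trend is unidentifiable on an ultrametric tree); drop mu")
  coef <- qr.coef(qr_D, xw)
  resid <- x - design %*% coef
  rw <- xw - Dw %*% coef
  list(coef = drop(coef), resid = drop(resid), qform = sum(rw^2),
       XtX_inv_chol = qr_D)
}

#' Serialize or read a regime painting as two-column text
#'
#' Writes one row per branch (`child_node  label`) so a painting can be
#' stored beside a tree and reloaded against the same topology.
#'
#' @param painting A `"regime_painting"`.
#' @param tree The `"phylo"` it belongs to.
#' @param path Output (or input) file path.
#' @return `write_painting` returns `path` invisibly; `read_painting`
#'   returns a `"regime_painting"`.
#' @export
write_painting <- function(painting, tree, path) {
  stopifnot(inherits(painting, "regime_painting"),
            length(painting$edge_label) == nrow(tree$edge))
  utils::write.table(
    data.frame(child = tree$edge[, 2L], label = painting$edge_label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_painting
#' @export
read_painting <- function(path, tree) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("child", "label") %in% names(tab)))
    stop("painting file needs 'child' and 'label' columns")
  lab <- tab$label[match(tree$edge[, 2L], tab$child)]
  if (anyNA(lab)) stop("painting does not cover every branch of the tree")
  if (any(!lab %in% c("trend", "bm"))) stop("labels must be 'trend' or 'bm'")
  structure(list(edge_label = lab, clade_node = NULL,
                 tree_hash = ape::Ntip(tree)),
            class = "regime_painting")
}
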