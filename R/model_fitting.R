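# Maximum-likelihood fitting, AICc comparison with Akaike weights, and the
# replicated one-species-per-genus subsampling pipeline.
#
# Every candidate model factors as x ~ N(D beta, sigma2 W(shape)) with a
# design D of at most two columns (intercept; trend exposure). beta and
# sigma2 then profile out of the likelihood analytically:
#   sigma2_hat = r' W^{-1} r / n,
#   lnL(shape) = -n/2 (log 2 pi + 1) - n/2 log sigma2_hat - 1/2 log |W|,
# so the ML search is one-dimensional over the bounded shape parameter
# (or a closed form for BM and trend). The search is a deterministic coarse
# grid followed by golden-section refinement around the best grid cell.

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param lnL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (tips); must exceed `k + 1`.
#' @export
aicc <- function(lnL, k, n) {
  if (k > 0 && n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  corr <- if (k > 0) 2 * k * (k + 1) / (n - k - 1) else 0
  -2 * lnL + 2 * k + corr
}

#' Akaike weights
#'
#' Normalized relative likelihoods `exp(-(AICc_i - min AICc)/2)`, summing to
#' one over the compared model set.
#'
#' @param values Numeric vector of AICc values (may contain `Inf` for failed
#'   fits).
#' @export
akaike_weights <- function(values) {
  if (!any(is.finite(values))) stop("no finite AICc value to compare")
  d <- values - min(values)
  w <- exp(-d / 2)
  w / sum(w)
}

.shape_bounds <- function(name, tree) {
  Tmax <- max(ape::node.depth.edgelength(tree))
  switch(name,
    lambda = c(0, 1),
    kappa  = c(0, 1),
    delta  = c(1e-5, 3),
    OU     = c(log(1e-8), log(500 / Tmax)),  # log-alpha scale
    NULL)
}

# Profiled log-likelihood pieces for one W; returns lnL, coefficients, sigma2.
.profile_fit <- function(x, W, design) {
  L <- .chol_or_die(W)
  g <- gls_root_estimate(x, W, design)
  n <- length(x)
  s2 <- g$qform / n
  if (s2 <= 0) s2 <- .Machine$double.eps
  lnL <- -0.5 * n * (log(2 * pi) + 1) - 0.5 * n * log(s2) - sum(log(diag(L)))
  list(lnL = lnL, coef = g$coef, sigma2 = s2, W_chol = L, gls = g)
}

.build_W <- function(name, shape, tree, C, painting) {
  switch(name,
    BM = , trend = , trend_BM = C,
    lambda = transform_lambda(C, shape),
    kappa = ape::vcv.phylo(transform_kappa(tree, shape)),
    delta = C^shape * max(diag(C))^(1 - shape),
    OU = ou_covariance(tree, exp(shape), sigma2 = 1))
}

.build_design <- function(name, tree, C, painting) {
  n <- nrow(C)
  switch(name,
    trend = cbind(z0 = rep(1, n), mu = diag(C)),
    trend_BM = cbind(z0 = rep(1, n), mu = trend_path_lengths(tree, painting)),
    cbind(z0 = rep(1, n)))
}

#' Fit one trait-evolution model by maximum likelihood
#'
#' Maximizes the exact Gaussian likelihood of the named model on `(tree, x)`.
#' The root state (and trend slope, where present) and the rate are profiled
#' out analytically; the remaining bounded shape parameter is searched by a
#' deterministic multi-start grid (resolution `5 * n_starts` points) refined
#' with [stats::optimize()]. The fit is deterministic; the `seed` argument is
#' accepted for interface symmetry with the stochastic pipeline steps.
#'
#' @param name Model name (see [model_spec()]).
#' @param tree A `"phylo"`.
#' @param x Named numeric vector of tip values (ln mm), aligned by name to
#'   the tips.
#' @param painting Regime painting; required iff `name == "trend_BM"`.
#' @param bounds Optional length-2 numeric overriding the default shape
#'   bounds (for `OU`, on the natural alpha scale).
#' @param n_starts Grid-resolution control for the shape search (default 5).
#' @param seed Unused (deterministic fit); kept for API uniformity.
#' @return A list of class `"model_fit"`: `model`, `theta` (named: `sigma2`,
#'   `z0`, shape/slope), `lnL`, `k`, `n`, `AICc`, `root_ln`, `root_mm`,
#'   `converged`.
#' @export
fit_model <- function(name, tree, x, painting = NULL, bounds = NULL,
                      n_starts = 5, seed = NULL) {
  name <- match.arg(name, MODEL_NAMES)
  validate_phylo(tree)
  if (!is.null(names(x))) {
    if (!setequal(names(x), tree$tip.label))
      stop("names of x do not match tree tip labels")
    x <- x[tree$tip.label]
  } else if (length(x) != ape::Ntip(tree))
    stop("x has ", length(x), " values for ", ape::Ntip(tree), " tips")
  if ((name == "trend_BM") && is.null(painting))
    stop("trend_BM requires a regime painting")
  C <- phylo_vcv(tree)
  design <- .build_design(name, tree, C, painting)
  n <- length(x)
  k <- if (name == "BM") 2L else 3L
  if (n <= ncol(design))
    stop("too few tips (", n, ") for ", ncol(design), " mean parameters")

  obj <- function(shape) {
    W <- .build_W(name, shape, tree, C, painting)
    tryCatch(.profile_fit(x, W, design)$lnL, error = function(e) -Inf)
  }

  shape_hat <- NULL
  converged <- TRUE
  if (name %in% c("BM", "trend", "trend_BM")) {
    fit <- .profile_fit(x, C, design)
  } else {
    b <- .shape_bounds(name, tree)
    if (!is.null(bounds)) {
      stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
      b <- if (name == "OU") log(bounds) else bounds
    }
    grid <- seq(b[1], b[2], length.out = max(5L * n_starts, 10L))
    vals <- vapply(grid, obj, numeric(1))
    if (!any(is.finite(vals))) {
      converged <- FALSE
      best <- grid[1]
    } else {
      i <- which.max(vals)
      lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
      opt <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                             tol = 1e-8)
      best <- if (opt$objective >= vals[i]) opt$maximum else grid[i]
    }
    shape_hat <- best
    fit <- .profile_fit(x, .build_W(name, shape_hat, tree, C, painting), design)
  }

  theta <- c(sigma2 = fit$sigma2, z0 = unname(fit$coef[1L]))
  if (name %in% c("trend", "trend_BM")) theta["mu"] <- unname(fit$coef[2L])
  if (name == "OU") { theta["alpha"] <- exp(shape_hat) }
  if (name == "lambda") theta["lambda"] <- shape_hat
  if (name == "kappa") theta["kappa"] <- shape_hat
  if (name == "delta") theta["delta"] <- shape_hat

  structure(list(model = name, theta = theta, lnL = fit$lnL, k = k, n = n,
                 AICc = if (n > k + 1) aicc(fit$lnL, k, n) else NA_real_,
                 root_ln = unname(fit$coef[1L]),
                 root_mm = exp(unname(fit$coef[1L])),
                 converged = converged, n_starts = n_starts),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, n = %d, AICc = %.4f\n",
              x$model, x$lnL, x$k, x$n, x$AICc))
  cat("  theta:", paste(sprintf("%s = %.6g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  cat(sprintf("  root: %.4f (ln scale) = %.4f mm\n", x$root_ln, x$root_mm))
  invisible(x)
}

.shape_of <- function(fit) {
  nm <- intersect(c("mu", "alpha", "lambda", "kappa", "delta"), names(fit$theta))
  if (length(nm)) unname(fit$theta[nm[1L]]) else NA_real_
}

#' Fit and compare a set of trait-evolution models
#'
#' Fits each requested model on the same dataset and computes Akaike weights
#' from AICc across the successful fits. On an ultrametric tree the plain
#' trend model is dropped by default (its slope is confounded with the root
#' state when all tips are contemporaneous); the clade-mixed `trend_BM`
#' remains identifiable because trend exposure varies among tips.
#'
#' @param tree A `"phylo"`.
#' @param x Named tip values (ln mm).
#' @param painting Regime painting for `trend_BM` (required iff requested).
#' @param models Character vector of model names to compare.
#' @param drop_trend_if_ultrametric Drop `trend` on ultrametric input
#'   (default `TRUE`); set `FALSE` to keep it flagged as confounded instead.
#' @param n_starts,seed Passed to [fit_model()].
#' @return A list of class `"model_comparison"`: `fits` (named list of
#'   `"model_fit"`), `weights`, `table` (tidy data.frame), `best` (name of
#'   the top-weight model; ties broken toward fewer parameters then
#'   lexicographic order), `errors` (named character of per-model failures).
#' @export
fit_all_models <- function(tree, x, painting = NULL, models = MODEL_NAMES,
                           drop_trend_if_ultrametric = TRUE,
                           n_starts = 5, seed = NULL) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  if (!length(models)) stop("empty model set")
  if ("trend_BM" %in% models && is.null(painting))
    stop("trend_BM requested without a regime painting")
  ultra <- ape::is.ultrametric(tree, tol = 1e-8)
  if (ultra && drop_trend_if_ultrametric && "trend" %in% models)
    models <- setdiff(models, "trend")
  fits <- list(); errors <- character(0)
  for (m in models) {
    f <- tryCatch(fit_model(m, tree, x, painting = painting,
                            n_starts = n_starts, seed = seed),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "model_fit")) fits[[m]] <- f else errors[m] <- f
  }
  if (!length(fits)) stop("every model fit failed; first error: ", errors[1L])
  av <- vapply(fits, `[[`, numeric(1), "AICc")
  w <- akaike_weights(av)
  tab <- data.frame(model = names(fits),
                    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    AICc = av, weight = w,
                    root_ln = vapply(fits, `[[`, numeric(1), "root_ln"),
                    root_mm = vapply(fits, `[[`, numeric(1), "root_mm"),
                    parameter = vapply(fits, .shape_of, numeric(1)),
                    row.names = NULL)
  # best model: max weight; ties toward fewer parameters, then name
  ord <- order(-tab$weight, tab$k, tab$model)
  structure(list(fits = fits, weights = w, table = tab,
                 best = tab$model[ord[1L]], ultrametric = ultra,
                 errors = errors),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (", nrow(x$table), " models; best: ", x$best, ")\n",
      sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Replicated genus-subsampling model comparison
#'
#' Runs the full subsample-match-fit pipeline `n_rep` times: each replicate
#' draws one species per modern genus at random (fossils always included),
#' matches the records against the tree, fits every requested model, and
#' computes Akaike weights. Returns per-model means and standard deviations
#' over replicates of AICc, weight, back-transformed root (mm) and the shape
#' parameter. Weights are computed per replicate and then averaged, never
#' from mean AICc. Fully reproducible from `seed`.
#'
#' @param records A trait table (one row per species, one caste).
#' @param tree A `"phylo"` whose modern tips are genus-labelled and fossil
#'   tips species-labelled.
#' @param n_rep Number of subsampling replicates (study design: 100).
#' @param seed Integer seed.
#' @param models Model names to compare.
#' @param clade_tips Tip labels defining the BM-regime clade for `trend_BM`
#'   (`NULL` to skip `trend_BM` painting; then `trend_BM` must not be in
#'   `models`).
#' @param drop_trend_if_ultrametric Passed to [fit_all_models()].
#' @return A list of class `"fit_summary"`: `summary` (per-model data.frame
#'   of means and sds), `replicates` (tidy per-replicate table), `n_rep`,
#'   `seed`, `failed` (count of failed replicates).
#' @export
replicate_fit <- function(records, tree, n_rep = 100, seed = 1,
                          models = MODEL_NAMES, clade_tips = NULL,
                          drop_trend_if_ultrametric = TRUE) {
  stopifnot(n_rep >= 1)
  rows <- list(); failed <- 0L
  for (r in seq_len(n_rep)) {
    rep_seed <- (as.integer(seed) + 7919L * r) %% .Machine$integer.max
    res <- tryCatch({
      sub <- subsample_one_per_genus(records, seed = rep_seed)
      ds <- match_tree_and_traits(tree, sub, level = "species")
      painting <- if (!is.null(clade_tips))
        paint_clade(ds$tree, intersect(clade_tips, ds$tree$tip.label)) else NULL
      cmp <- fit_all_models(ds$tree, ds$x, painting = painting, models = models,
                            drop_trend_if_ultrametric = drop_trend_if_ultrametric)
      cbind(replicate = r, cmp$table)
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- failed + 1L else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("every replicate failed")
  reps <- do.call(rbind, rows)
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  agg <- lapply(split(reps, reps$model), function(d) data.frame(
    model = d$model[1L],
    mean_AICc = mean(d$AICc), sd_AICc = sd0(d$AICc),
    mean_weight = mean(d$weight), sd_weight = sd0(d$weight),
    mean_root_mm = mean(d$root_mm), sd_root_mm = sd0(d$root_mm),
    mean_parameter = mean(d$parameter), sd_parameter = sd0(d$parameter),
    n_replicates = nrow(d)))
  summary <- do.call(rbind, agg)
  summary <- summary[order(-summary$mean_weight), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, replicates = reps, n_rep = n_rep,
                 seed = seed, failed = failed,
                 sd_defined = n_rep > 1L),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat("Replicated model comparison over", x$n_rep, "genus subsamples",
      if (x$failed) paste0("(", x$failed, " failed)"), "\n")
  if (!x$sd_defined) cat("  [single replicate: sd reported as 0]\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Serialize a fit summary
#'
#' Writes the tidy per-replicate table as TSV and the per-model summary as
#' JSON mirroring the usual model-comparison table layout.
#'
#' @param fs A `"fit_summary"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_fit_summary <- function(fs, dir, prefix = "model_comparison") {
  stopifnot(inherits(fs, "fit_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, paste0(prefix, "_replicates.tsv"))
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  utils::write.table(fs$replicates, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(n_rep = fs$n_rep, seed = fs$seed,
                            failed = fs$failed, summary = fs$summary),
                       js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(tsv, js))
}
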