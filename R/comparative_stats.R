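# PGLS under ML branch-length transforms, Bartlett variance tests, and
# caste-disparity indices.

#' Proportional head-width disparity between two castes
#'
#' `(a - b) / b`: positive when the first caste (e.g. the imago) is larger.
#'
#' @param a_mm,b_mm Head widths in mm, > 0. Vectorized.
#' @export
disparity <- function(a_mm, b_mm) {
  if (any(a_mm <= 0) || any(b_mm <= 0)) stop("head widths must be positive")
  (a_mm - b_mm) / b_mm
}

#' Bartlett's test of homogeneity of variance
#'
#' Thin wrapper around [stats::bartlett.test()] returning the statistic,
#' degrees of freedom and p-value, plus the per-group variances and sizes.
#' Bartlett's test does not account for phylogenetic non-independence among
#' taxa; a warning saying so is always emitted, and results on comparative
#' data should be treated with caution.
#'
#' @param values Numeric observations (or a list of group samples, with
#'   `groups` omitted).
#' @param groups Group labels aligned with `values`.
#' @return A list with `K` (the chi-squared statistic), `df`, `p.value`,
#'   `group_variances`, `group_sizes`.
#' @export
bartlett_test <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    samples <- values
  } else {
    samples <- split(values, groups)
  }
  if (length(samples) < 2L) stop("at least two groups are required")
  ns <- lengths(samples)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  vars <- vapply(samples, stats::var, numeric(1))
  if (any(vars == 0))
    warning("a group has zero variance; the statistic is infinite")
  bt <- stats::bartlett.test(samples)
  warning("Bartlett's test ignores phylogenetic non-independence among taxa; ",
          "interpret with caution", call. = FALSE)
  list(K = unname(bt$statistic), df = unname(bt$parameter),
       p.value = bt$p.value, group_variances = vars, group_sizes = ns)
}

.pgls_W <- function(transform, param, tree, C) {
  switch(transform,
    BM = C,
    lambda = transform_lambda(C, param),
    kappa = ape::vcv.phylo(transform_kappa(tree, param)),
    delta = C^param * max(diag(C))^(1 - param))
}

#' Phylogenetic generalized least squares under a branch-length transform
#'
#' GLS regression whose error covariance is the phylogenetic covariance of
#' `tree` under one of the `BM`, `lambda`, `kappa` or `delta` transforms.
#' The transform parameter is profiled by maximum likelihood within the
#' regression (not imported from trait-model fits) unless `param` is fixed.
#' Coefficient standard errors use the unbiased residual variance
#' `RSS_gls / (n - p)`; the F statistic tests all non-intercept terms jointly
#' against the intercept-only model under the same covariance. `AIC = -2 lnL
#' + 2k` with `k` = coefficients + 1 (residual variance) + 1 for a non-BM
#' transform parameter.
#'
#' @param formula Model formula, e.g. `y ~ group`.
#' @param data Data frame with row names equal to tip labels (or a `tip`
#'   column).
#' @param tree A `"phylo"`; pruned internally to the rows of `data`.
#' @param transform `"BM"`, `"lambda"`, `"kappa"` or `"delta"`.
#' @param param Optional fixed transform parameter (skips ML profiling).
#' @return A list of class `"pgls_fit"` with `coefficients` (estimate, se,
#'   t, p), `F`, `F_df`, `F_p`, `lnL`, `AIC`, `transform`, `param`, `n`,
#'   `sigma2`, `fitted`, `residuals`.
#' @export
pgls_fit <- function(formula, data, tree, transform = c("BM", "lambda",
                     "kappa", "delta"), param = NULL) {
  transform <- match.arg(transform)
  tips <- if (!is.null(data$tip)) as.character(data$tip) else rownames(data)
  if (is.null(tips) || !all(tips %in% tree$tip.label))
    stop("data rows must be named by (or carry a 'tip' column of) tree tip labels")
  if (anyDuplicated(tips)) stop("duplicate tips in data")
  drop <- setdiff(tree$tip.label, tips)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  data <- data[match(tree$tip.label, tips), , drop = FALSE]

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("too few tips (", n, ") for ", p, " coefficients")
  C <- phylo_vcv(tree)

  lnL_at <- function(par) {
    W <- .pgls_W(transform, par, tree, C)
    tryCatch(.profile_fit(y, W, X)$lnL, error = function(e) -Inf)
  }
  if (transform == "BM") {
    param_hat <- NA_real_
  } else if (!is.null(param)) {
    param_hat <- param
  } else {
    b <- switch(transform, lambda = c(0, 1), kappa = c(0, 1),
                delta = c(1e-5, 3))
    grid <- seq(b[1], b[2], length.out = 25L)
    vals <- vapply(grid, lnL_at, numeric(1))
    i <- which.max(vals)
    opt <- stats::optimize(lnL_at, lower = grid[max(1L, i - 1L)],
                           upper = grid[min(length(grid), i + 1L)],
                           maximum = TRUE, tol = 1e-8)
    param_hat <- if (opt$objective >= vals[i]) opt$maximum else grid[i]
  }
  W <- .pgls_W(transform, if (is.na(param_hat)) 1 else param_hat, tree, C)
  pf <- .profile_fit(y, W, X)
  g <- pf$gls
  s2_unb <- g$qform / (n - p)
  XtXi <- chol2inv(qr.R(g$XtX_inv_chol))
  # undo the QR pivoting, if any
  piv <- g$XtX_inv_chol$pivot
  XtXi <- XtXi[order(piv), order(piv), drop = FALSE]
  se <- sqrt(diag(XtXi) * s2_unb)
  est <- pf$coef
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coef_tab <- data.frame(term = colnames(X), estimate = est, se = se,
                         t = tval, p = pval, row.names = NULL)

  # F for the non-intercept block vs intercept-only under the same W
  has_int <- "(Intercept)" %in% colnames(X)
  q <- p - as.integer(has_int)
  if (q > 0) {
    g0 <- gls_root_estimate(y, W, matrix(1, n, 1))
    Fstat <- ((g0$qform - g$qform) / q) / (g$qform / (n - p))
    Fp <- stats::pf(Fstat, q, n - p, lower.tail = FALSE)
  } else {
    Fstat <- NA_real_; Fp <- NA_real_
  }
  k <- p + 1 + as.integer(transform != "BM")
  structure(list(formula = formula, transform = transform, param = param_hat,
                 coefficients = coef_tab, F = Fstat, F_df = c(q, n - p),
                 F_p = Fp, lnL = pf$lnL, AIC = -2 * pf$lnL + 2 * k, k = k,
                 n = n, sigma2 = pf$sigma2,
                 fitted = drop(X %*% est),
                 residuals = drop(y - X %*% est)),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s transform%s): n = %d, lnL = %.3f, AIC = %.3f\n",
              x$transform,
              if (!is.na(x$param)) sprintf(", parameter = %.4f", x$param) else "",
              x$n, x$lnL, x$AIC))
  print(x$coefficients, digits = 4)
  if (!is.na(x$F))
    cat(sprintf("F_%d = %.4f on (%d, %d) df, p = %.4g\n",
                x$F_df[1], x$F, x$F_df[1], x$F_df[2], x$F_p))
  invisible(x)
}

#' PGLS with AIC selection over branch-length transforms
#'
#' Fits the regression under the Brownian, lambda, kappa and delta transforms
#' and returns the minimum-AIC fit with the full comparison table attached.
#' Exact ties are broken toward BM (fewest parameters).
#'
#' @inheritParams pgls_fit
#' @return The winning `"pgls_fit"` with an extra element
#'   `transform_comparison` (data.frame of transform, parameter, lnL, AIC).
#' @export
pgls_best <- function(formula, data, tree) {
  transforms <- c("BM", "lambda", "kappa", "delta")
  fits <- lapply(transforms, function(tr)
    tryCatch(pgls_fit(formula, data, tree, transform = tr),
             error = function(e) NULL))
  names(fits) <- transforms
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("every transform fit failed")
  aics <- vapply(fits[ok], `[[`, numeric(1), "AIC")
  ks <- vapply(fits[ok], `[[`, numeric(1), "k")
  ord <- order(round(aics, 10), ks)  # tie -> fewer parameters (BM)
  best <- fits[ok][[ord[1L]]]
  best$transform_comparison <- data.frame(
    transform = names(fits)[ok],
    parameter = vapply(fits[ok], `[[`, numeric(1), "param"),
    lnL = vapply(fits[ok], `[[`, numeric(1), "lnL"),
    AIC = aics, row.names = NULL)
  best
}

#' Per-level intercept tests for a disparity response
#'
#' Refits the PGLS of a disparity response on a binary factor twice, once
#' with each level as the baseline, and reports the intercept t test of each
#' level's mean against zero. The fitted values are invariant to the choice
#' of baseline; only the parameterization changes.
#'
#' @param y Disparity values named by tip.
#' @param group Factor (two levels) named by tip.
#' @param tree A `"phylo"`.
#' @param transform Passed to [pgls_fit()]; default profiles over all four
#'   via [pgls_best()].
#' @return Data frame with one row per level: `level`, `intercept`, `se`,
#'   `t`, `p`.
#' @export
intercept_tests <- function(y, group, tree, transform = NULL) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("group factor must have at least two levels")
  if (is.null(names(y))) stop("y must be named by tip label")
  stopifnot(length(y) == length(group))
  rows <- lapply(levels(group), function(lv) {
    d <- data.frame(y = y, g = stats::relevel(group, ref = lv))
    rownames(d) <- names(y)
    f <- if (is.null(transform)) pgls_best(y ~ g, d, tree)
         else pgls_fit(y ~ g, d, tree, transform = transform)
    ic <- f$coefficients[f$coefficients$term == "(Intercept)", ]
    data.frame(level = lv, intercept = ic$estimate, se = ic$se, t = ic$t,
               p = ic$p)
  })
  do.call(rbind, rows)
}

#' Pairwise PGLS correlation of head width between castes
#'
#' Regresses one caste's ln head width on another's across genera under the
#' AIC-best branch-length transform.
#'
#' @param table Data frame with one row per genus, columns named by caste
#'   holding head widths in mm, and row names (or `tip`) matching the tree.
#' @param pair Character vector of two caste column names,
#'   `c(response, predictor)`.
#' @param tree A `"phylo"`.
#' @return A `"pgls_fit"`.
#' @export
caste_correlation <- function(table, pair, tree) {
  stopifnot(length(pair) == 2L, all(pair %in% names(table)))
  keep <- stats::complete.cases(table[, pair])
  d <- table[keep, , drop = FALSE]
  if (nrow(d) < 3L) stop("fewer than 3 genera have both castes measured")
  d2 <- data.frame(y = log(d[[pair[1L]]]), x = log(d[[pair[2L]]]))
  rownames(d2) <- rownames(d)
  if (!is.null(d$tip)) d2$tip <- d$tip
  pgls_best(y ~ x, d2, tree)
}
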