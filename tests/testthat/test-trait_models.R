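test_that("branch-length transforms behave at their boundary and hand-checked values", {
  C <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(transform_lambda(C, 1), C)
  expect_equal(transform_lambda(C, 0), diag(c(2, 2)))
  expect_equal(transform_lambda(C, 0.5), matrix(c(2, 0.5, 0.5, 2), 2, 2))
  expect_error(transform_lambda(C, 1.2), "lambda")

  tr <- ape::read.tree(text = "(A:1,B:4);")
  expect_equal(transform_kappa(tr, 0.5)$edge.length, c(1, 2))
  expect_equal(transform_kappa(tr, 1)$edge.length, tr$edge.length)
  k0 <- transform_kappa(tr, 0)
  expect_equal(k0$edge.length, c(1, 1))  # speciational change
  trz <- tr; trz$edge.length[1] <- 0
  expect_equal(transform_kappa(trz, 0)$edge.length[1], 0)  # 0^kappa := 0

  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  expect_equal(transform_delta(tr2, 1)$edge.length, tr2$edge.length)
  d2 <- transform_delta(tr2, 2)
  # hand computation: depths {1,2,2,1} -> t^2/Tmax; internal node 1 -> 0.5
  dep <- ape::node.depth.edgelength(d2)
  expect_equal(sort(dep[1:3]), c(0.5, 2, 2))
  expect_error(transform_delta(tr2, 0), "delta")
  # 2-tip star unchanged for any delta (single segments + rescale)
  star <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(transform_delta(star, 2.5)$edge.length, c(1, 1))
})

test_that("OU covariance matches closed forms, the BM limit, and the recursion oracle", {
  tr <- ape::read.tree(text = "(A:3,B:3);")
  V <- ou_covariance(tr, alpha = 0.7, sigma2 = 2)
  expect_equal(V[1, 1], 2 / (2 * 0.7) * (1 - exp(-2 * 0.7 * 3)))
  expect_equal(V[1, 2], 0)
  # BM limit
  tr2 <- fossil_tree(8, seed = 2)
  C <- phylo_vcv(tr2)
  V0 <- ou_covariance(tr2, alpha = 1e-8, sigma2 = 1.5)
  expect_equal(V0, 1.5 * C, tolerance = 1e-6)
  # brute-force recursion over branches
  for (s in 1:5) {
    tr3 <- fossil_tree(6, seed = 10 + s)
    a <- 0.2 + 0.3 * s
    expect_equal(ou_covariance(tr3, a, 1.3), oracle_ou(tr3, a, 1.3),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("trend exposure follows the painting", {
  tr <- ape::read.tree(text = "(((A:1,B:1):0.5,C:1.5):0.7,D:2.2);")
  tau_all <- trend_path_lengths(tr, paint_all(tr, "trend"))
  expect_equal(unname(tau_all[tr$tip.label]),
               ape::node.depth.edgelength(tr)[1:4])
  expect_equal(unname(trend_path_lengths(tr, paint_all(tr, "bm"))),
               rep(0, 4))
  p <- paint_clade(tr, c("A", "B"))
  tau <- trend_path_lengths(tr, p)
  # A, B exposed only outside the crown of (A,B): 0.7 + 0.5
  expect_equal(unname(tau[c("A", "B")]), c(1.2, 1.2))
  expect_equal(unname(tau[c("C", "D")]), c(2.2, 2.2))
  # stem-in-bm convention removes the 0.5 stem branch as well
  tau2 <- trend_path_lengths(tr, paint_clade(tr, c("A", "B"), stem_in_bm = TRUE))
  expect_equal(unname(tau2[c("A", "B")]), c(0.7, 0.7))
})

test_that("model_mean_cov assembles the stated mean and covariance per model", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  bm <- model_mean_cov(model_spec("BM", sigma2 = 1, z0 = 0), tr)
  expect_equal(unname(bm$mean), rep(0, 3))
  expect_equal(bm$V, C)
  # trend mean rises with tip depth; on this (ultrametric) tree it is flat
  tre <- model_mean_cov(model_spec("trend", sigma2 = 1, z0 = 1, mu = -0.5), tr)
  expect_equal(unname(tre$mean), unname(1 - 0.5 * diag(C)))
  # trend_BM with mu < 0: tips outside the clade (more exposure) are smaller
  tr2 <- ape::read.tree(text = "(((A:1,B:1):0.5,C:1.5):0.7,D:0.4);")
  p <- paint_clade(tr2, c("A", "B"))
  mx <- model_mean_cov(model_spec("trend_BM", sigma2 = 1, z0 = 0, mu = -0.5),
                       tr2, painting = p)
  expect_gt(mx$mean[["D"]], mx$mean[["A"]])  # D has less trend exposure
  expect_error(model_mean_cov(model_spec("BM"), tr, painting = paint_all(tr)),
               "trend_BM")
  expect_error(model_spec("OU", alpha = -1), "alpha")
  expect_error(model_spec("BM", mu = 1), "shape")
})

test_that("mvn_loglik matches closed forms and the dense-inverse oracle", {
  expect_equal(mvn_loglik(c(0, 0), c(0, 0), diag(2)), -log(2 * pi))
  expect_equal(mvn_loglik(1, 0, matrix(1)), -0.5 * (log(2 * pi) + 1))
  set.seed(42)
  for (i in 1:10) {
    n <- 8
    A <- matrix(rnorm(n * n), n)
    V <- crossprod(A) + diag(n)
    x <- rnorm(n); m <- rnorm(n)
    expect_equal(mvn_loglik(x, m, V), oracle_mvn(x, m, V), tolerance = 1e-10)
  }
  expect_error(mvn_loglik(c(0, 0), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("gls_root_estimate reduces to OLS and matches normal equations", {
  set.seed(3)
  x <- rnorm(10)
  g <- gls_root_estimate(x, diag(10), matrix(1, 10, 1))
  expect_equal(unname(g$coef), mean(x))
  for (s in 1:5) {
    tr <- fossil_tree(6, seed = 30 + s)
    V <- phylo_vcv(tr)
    D <- cbind(1, ape::node.depth.edgelength(tr)[1:6])
    x <- rnorm(6)
    expect_equal(unname(gls_root_estimate(x, V, D)$coef),
                 unname(oracle_gls(x, V, D)), tolerance = 1e-9)
  }
  # ultrametric tree: depth column constant -> confounding signalled
  trU <- ape::rcoal(6)
  DU <- cbind(1, ape::node.depth.edgelength(trU)[1:6])
  expect_error(gls_root_estimate(rnorm(6), phylo_vcv(trU), DU),
               "confounded")
})

test_that("every transform collapses to the BM likelihood at its neutral value", {
  for (s in 1:5) {
    tr <- fossil_tree(7, seed = 50 + s)
    C <- phylo_vcv(tr)
    set.seed(s); x <- rnorm(7); m <- rep(0.3, 7)
    ref <- mvn_loglik(x, m, 1.2 * C)
    expect_equal(mvn_loglik(x, m, 1.2 * transform_lambda(C, 1)), ref, tolerance = 1e-6)
    expect_equal(mvn_loglik(x, m, 1.2 * phylo_vcv(transform_kappa(tr, 1))), ref,
                 tolerance = 1e-6)
    expect_equal(mvn_loglik(x, m, 1.2 * phylo_vcv(transform_delta(tr, 1))), ref,
                 tolerance = 1e-6)
    expect_equal(mvn_loglik(x, m, ou_covariance(tr, 1e-8, 1.2)), ref,
                 tolerance = 1e-6)
    mc <- model_mean_cov(model_spec("trend", sigma2 = 1.2, z0 = 0.3, mu = 0), tr)
    expect_equal(mvn_loglik(x, mc$mean, mc$V), ref, tolerance = 1e-6)
  }
})
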