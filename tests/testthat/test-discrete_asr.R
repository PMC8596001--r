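test_that("mk_loglik handles the zero-rate limits and matches enumeration", {
  tr <- ape::rtree(5)
  conc <- stats::setNames(rep("0", 5), tr$tip.label)
  expect_equal(exp(mk_loglik(tr, conc, mk_model(0))), 0.5)
  disc <- conc; disc[2] <- "1"
  expect_equal(mk_loglik(tr, disc, mk_model(0)), -Inf)

  # sum-over-node-states enumeration oracle
  enum_lik <- function(tree, idx, model) {
    ntip <- ape::Ntip(tree)
    pi0 <- c(0.5, 0.5)
    combos <- as.matrix(expand.grid(rep(list(1:2), tree$Nnode)))
    state_of <- function(node, combo)
      if (node <= ntip) idx[node] else combo[node - ntip]
    tot <- 0
    for (r in seq_len(nrow(combos))) {
      p <- pi0[combos[r, 1]]
      for (e in seq_len(nrow(tree$edge))) {
        P <- termevol:::.mk_P(model, tree$edge.length[e])
        p <- p * P[state_of(tree$edge[e, 1], combos[r, ]),
                   state_of(tree$edge[e, 2], combos[r, ])]
      }
      tot <- tot + p
    }
    log(tot)
  }
  for (s in 1:5) {
    set.seed(110 + s)
    tr <- ape::rtree(5)
    m <- mk_model(runif(1, 0.1, 2), runif(1, 0.1, 2))
    st <- simulate_mk(tr, m, seed = s)$tip_states
    idx <- match(st[tr$tip.label], m$states)
    expect_equal(mk_loglik(tr, st, m), enum_lik(tr, idx, m), tolerance = 1e-10)
  }
  expect_error(mk_loglik(tr, st <- stats::setNames("0", tr$tip.label[1]),
                         mk_model(1)), "missing tip states")
})

test_that("likelihood is invariant under state relabelling for the symmetric model", {
  for (s in 1:4) {
    set.seed(120 + s)
    tr <- ape::rtree(6)
    m <- mk_model(0.8)
    st <- simulate_mk(tr, m, seed = s)$tip_states
    flipped <- stats::setNames(ifelse(st == "0", "1", "0"), names(st))
    expect_equal(mk_loglik(tr, st, m), mk_loglik(tr, flipped, m),
                 tolerance = 1e-12)
  }
})

test_that("fit_mk flags monomorphic data and beats a dense rate grid", {
  tr <- ape::rtree(8)
  mono <- stats::setNames(rep("1", 8), tr$tip.label)
  f <- fit_mk(tr, mono)
  expect_true(f$monomorphic)
  expect_equal(f$q, 0)

  set.seed(131)
  tr <- ape::rtree(30)
  st <- simulate_mk(tr, mk_model(0.4), seed = 2)$tip_states
  f <- fit_mk(tr, st)
  grid <- exp(seq(log(1e-4), log(50), length.out = 100))
  grid_lnL <- vapply(grid, function(q) mk_loglik(tr, st, mk_model(q)),
                     numeric(1))
  expect_gte(f$lnL, max(grid_lnL) - 1e-6)
})

test_that("Mk rate recovery on larger trees lands near the truth", {
  hits <- 0
  for (s in 1:10) {
    set.seed(140 + s)
    tr <- ape::rtree(200)
    tr$edge.length <- tr$edge.length * 10  # deepen so changes accumulate
    st <- simulate_mk(tr, mk_model(0.1), seed = s)$tip_states
    if (length(unique(st)) < 2) next
    q <- fit_mk(tr, st)$q
    if (q >= 0.05 && q <= 0.2) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("unconditional branch simulation has Poisson-rate change counts", {
  m <- mk_model(0.7)
  set.seed(7)
  n_changes <- vapply(1:20000, function(i)
    length(termevol:::.mk_sim_branch(m, 2, 1L)$times), numeric(1))
  # symmetric 2-state chain: changes are a thinned Poisson; mean ~ q*t
  expect_equal(mean(n_changes), 0.7 * 2, tolerance = 0.05)
})

test_that("stochastic maps honour endpoints, normalize, and degenerate at tiny rates", {
  set.seed(150)
  tr <- ape::rtree(6)
  m <- mk_model(0.5)
  st <- simulate_mk(tr, m, seed = 3)$tip_states
  if (length(unique(st)) < 2) st[1] <- setdiff(c("0", "1"), st[1])
  sm <- stochastic_map(tr, st, m, n_maps = 200, seed = 9)
  expect_equal(unname(rowSums(sm$node_freq)), rep(1, tr$Nnode))
  # identical seed -> identical result
  sm2 <- stochastic_map(tr, st, m, n_maps = 200, seed = 9)
  expect_identical(sm$node_freq, sm2$node_freq)
  # per-map tip segments agree with observed states by construction:
  # histories' events never leave a tip in the wrong state
  h <- sm$histories[[1]]
  expect_true(all(names(h$node_states)[1:6] == as.character(1:6)))
  # concordant tips at a negligible rate: every map changeless
  conc <- stats::setNames(rep("1", 6), tr$tip.label)
  sm0 <- stochastic_map(tr, conc, mk_model(1e-10), n_maps = 50, seed = 1)
  expect_equal(sm0$mean_changes, 0)
})

test_that("uniformization fallback matches rejection sampling on a single branch", {
  m <- mk_model(0.6, 0.3)
  set.seed(160)
  rej <- replicate(4000, length(termevol:::.mk_bridge(m, 1.5, 1L, 2L)$times))
  uni <- replicate(4000,
    length(termevol:::.mk_uniformization_bridge(m, 1.5, 1L, 2L)$times))
  # both samplers draw from the same conditional change-count distribution
  expect_equal(mean(rej %% 2 == 1), 1, tolerance = 1e-12)  # parity forced
  expect_equal(mean(uni %% 2 == 1), 1, tolerance = 1e-12)
  expect_equal(mean(rej), mean(uni), tolerance = 0.08)
  expect_equal(mean(rej == 1), mean(uni == 1), tolerance = 0.05)
})

test_that("ML Mk fits agree with an independent reference implementation", {
  skip_if_not_installed("phytools")
  set.seed(170)
  tr <- ape::rtree(25)
  st <- simulate_mk(tr, mk_model(0.5), seed = 4)$tip_states
  if (length(unique(st)) < 2) st[1] <- setdiff(c("0", "1"), st[1])
  ours <- fit_mk(tr, st)
  ref <- phytools::fitMk(tr, st[tr$tip.label], model = "ER", pi = "equal")
  expect_equal(ours$lnL, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(ours$q, ref$rates[1], tolerance = 0.01)
})

test_that("histories export as simmap-style Newick readable by phytools", {
  set.seed(180)
  tr <- ape::rtree(5)
  m <- mk_model(0.6)
  st <- simulate_mk(tr, m, seed = 6)$tip_states
  if (length(unique(st)) < 2) st[1] <- setdiff(c("0", "1"), st[1])
  sm <- stochastic_map(tr, st, m, n_maps = 3, seed = 2)
  txt <- simmap_newick(tr, sm$histories[[1]])
  expect_match(txt, "^\\(.*\\{.*,.*\\}.*\\);$")
  skip_if_not_installed("phytools")
  tf <- tempfile(); writeLines(txt, tf)
  back <- phytools::read.simmap(tf, format = "phylip")
  expect_setequal(back$tip.label, tr$tip.label)
  # total time in each state per branch preserves the branch length
  expect_equal(sort(unname(rowSums(back$mapped.edge))), sort(tr$edge.length),
               tolerance = 1e-6)
  # tip-end states in the export equal the observed states
  tip_end <- vapply(seq_len(5), function(i) {
    e <- which(back$edge[, 2] == i)
    names(back$maps[[e]])[length(back$maps[[e]])]
  }, character(1))
  expect_equal(tip_end, unname(st[back$tip.label]))
})

test_that("regime paintings round-trip through their text serialization", {
  tr <- ape::rtree(8)
  p <- paint_clade(tr, tr$tip.label[1:3])
  f <- tempfile()
  write_painting(p, tr, f)
  p2 <- read_painting(f, tr)
  expect_equal(p2$edge_label, p$edge_label)
  expect_identical(trend_path_lengths(tr, p2), trend_path_lengths(tr, p))
})
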