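# Two-state Mk likelihood, ML rate estimation, and stochastic character
# mapping with posterior node-state frequencies.
#
# The two-state continuous-time Markov chain has closed-form transition
# probabilities: with rates a = q01, b = q10 and s = a + b,
#   P(t) = pi' 1 + e^{-s t} (I - pi' 1),  pi = (b/s, a/s),
# so no matrix exponential is needed. States are indexed 1, 2 internally and
# carried as the factor levels of the tip data.

#' Specify a two-state Mk model
#'
#' @param q01 Rate from the first to the second state, >= 0.
#' @param q10 Rate from the second to the first state; defaults to `q01`
#'   (equal-rates model, which for two states is also the symmetric model).
#' @param root_prior `"uniform"` (flat over states) or `"stationary"`
#'   (the chain's equilibrium frequencies).
#' @param states Character vector of the two state names.
#' @return A list of class `"mk_model"` with the rate matrix `Q`.
#' @export
mk_model <- function(q01, q10 = q01, root_prior = c("uniform", "stationary"),
                     states = c("0", "1")) {
  root_prior <- match.arg(root_prior)
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  stopifnot(length(states) == 2L)
  Q <- matrix(c(-q01, q10, q01, -q10), 2L, 2L,
              dimnames = list(states, states))
  structure(list(Q = Q, q01 = q01, q10 = q10, root_prior = root_prior,
                 states = states),
            class = "mk_model")
}

.mk_root_pi <- function(model) {
  s <- model$q01 + model$q10
  if (model$root_prior == "stationary" && s > 0)
    c(model$q10, model$q01) / s
  else c(0.5, 0.5)
}

# 2x2 transition probability matrix over time t (closed form)
.mk_P <- function(model, t) {
  s <- model$q01 + model$q10
  if (s == 0) return(diag(2L))
  pi1 <- model$q10 / s
  e <- exp(-s * t)
  matrix(c(pi1 + (1 - pi1) * e, pi1 - pi1 * e,
           (1 - pi1) - (1 - pi1) * e, (1 - pi1) + pi1 * e), 2L, 2L)
}

.mk_states_idx <- function(tree, tip_states, model) {
  if (is.null(names(tip_states))) {
    if (length(tip_states) != ape::Ntip(tree))
      stop("tip states must be named or match the number of tips")
    names(tip_states) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss))
    stop("missing tip states for: ", paste(utils::head(miss, 3L), collapse = ", "))
  st <- as.character(tip_states[tree$tip.label])
  idx <- match(st, model$states)
  if (anyNA(idx))
    stop("tip states outside {", paste(model$states, collapse = ", "), "}")
  idx
}

# Post-order conditional likelihoods; rows = nodes (tips first), cols = states.
.mk_partials <- function(tree, idx, model) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  Lk <- matrix(0, nnode, 2L)
  Lk[cbind(seq_len(ntip), idx)] <- 1
  ord <- ape::reorder.phylo(tree, "postorder")
  edge <- ord$edge; elen <- ord$edge.length
  contrib <- matrix(1, nnode, 2L)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    if (ch > ntip) Lk[ch, ] <- contrib[ch, ]
    P <- .mk_P(model, elen[e])
    contrib[par, ] <- contrib[par, ] * as.vector(P %*% Lk[ch, ])
  }
  root <- ntip + 1L
  Lk[root, ] <- contrib[root, ]
  Lk
}

#' Mk log-likelihood of binary tip states
#'
#' Felsenstein pruning with the closed-form two-state transition
#' probabilities and the model's root prior.
#'
#' @param tree A `"phylo"`.
#' @param tip_states Character/factor vector of states named by tip label.
#' @param model An `"mk_model"`.
#' @export
mk_loglik <- function(tree, tip_states, model) {
  validate_phylo(tree)
  idx <- .mk_states_idx(tree, tip_states, model)
  Lk <- .mk_partials(tree, idx, model)
  lik <- sum(.mk_root_pi(model) * Lk[ape::Ntip(tree) + 1L, ])
  if (lik <= 0) -Inf else log(lik)
}

#' Maximum-likelihood Mk rate for a binary trait
#'
#' One-dimensional bounded ML estimation of the (equal) transition rate.
#' Monomorphic data yield a zero rate with a flag.
#'
#' @param tree A `"phylo"`.
#' @param tip_states States named by tip label.
#' @param root_prior Passed to [mk_model()].
#' @param states The two state names; inferred from the data when `NULL`.
#' @return A list: `q` (ML rate), `lnL`, `model` (the fitted `"mk_model"`),
#'   `monomorphic` flag.
#' @export
fit_mk <- function(tree, tip_states, root_prior = "uniform", states = NULL) {
  validate_phylo(tree)
  st <- as.character(tip_states)
  if (is.null(states)) states <- sort(unique(st))
  if (length(states) == 1L) states <- c(states, paste0("not_", states))
  if (length(unique(st)) < 2L) {
    model <- mk_model(0, root_prior = root_prior, states = states)
    return(list(q = 0, lnL = mk_loglik(tree, tip_states, model),
                model = model, monomorphic = TRUE))
  }
  Tmax <- max(ape::node.depth.edgelength(tree))
  obj <- function(lq) {
    m <- mk_model(exp(lq), root_prior = root_prior, states = states)
    mk_loglik(tree, tip_states, m)
  }
  b <- c(log(1e-7 / Tmax), log(1000 / Tmax))
  grid <- seq(b[1], b[2], length.out = 40L)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  opt <- stats::optimize(obj, lower = grid[max(1L, i - 1L)],
                         upper = grid[min(length(grid), i + 1L)],
                         maximum = TRUE, tol = 1e-9)
  q <- exp(if (opt$objective >= vals[i]) opt$maximum else grid[i])
  model <- mk_model(q, root_prior = root_prior, states = states)
  list(q = q, lnL = mk_loglik(tree, tip_states, model), model = model,
       monomorphic = FALSE)
}

# Sample a CTMC path on one branch from a given starting state,
# unconditionally. Returns list(end, events = data.frame(time, state)).
.mk_sim_branch <- function(model, t, start) {
  rates <- c(model$q01, model$q10)
  state <- start; now <- 0
  times <- numeric(0); sts <- integer(0)
  repeat {
    r <- rates[state]
    if (r <= 0) break
    now <- now + stats::rexp(1L, r)
    if (now >= t) break
    state <- 3L - state
    times <- c(times, now); sts <- c(sts, state)
  }
  list(end = state, times = times, states = sts)
}

# Conditional branch history via rejection sampling with a uniformization
# fallback after `cap` failed attempts.
.mk_bridge <- function(model, t, start, end, cap = 1e6) {
  for (i in seq_len(cap)) {
    sim <- .mk_sim_branch(model, t, start)
    if (sim$end == end) return(sim)
  }
  .mk_uniformization_bridge(model, t, start, end)
}

# Uniformization: sample the number of virtual jumps N | endpoints, place the
# jump times as uniform order statistics, and run a discrete Markov bridge
# through R = I + Q/Lam, dropping self-transitions.
.mk_uniformization_bridge <- function(model, t, start, end) {
  Lam <- max(model$q01, model$q10)
  if (Lam <= 0) {
    if (start != end) stop("zero-rate bridge with discordant endpoints")
    return(list(end = end, times = numeric(0), states = integer(0)))
  }
  Q <- model$Q; R <- diag(2L) + Q / Lam
  Pt <- .mk_P(model, t)[start, end]
  if (Pt <= 0) stop("impossible endpoint combination on a branch")
  # P(N = n | endpoints) ~ dpois(n, Lam t) * (R^n)[start, end] / Pt
  nmax <- 10L; Rn <- list(diag(2L))
  repeat {
    for (n in seq_len(nmax)) if (length(Rn) <= n) Rn[[n + 1L]] <- Rn[[n]] %*% R
    pr <- vapply(0:nmax, function(n)
      stats::dpois(n, Lam * t) * Rn[[n + 1L]][start, end] / Pt, numeric(1))
    if (sum(pr) > 1 - 1e-12 || nmax > 1000L) break
    nmax <- nmax * 2L
  }
  N <- sample.int(nmax + 1L, 1L, prob = pmax(pr, 0)) - 1L
  if (N == 0L) return(list(end = end, times = numeric(0), states = integer(0)))
  jump_times <- sort(stats::runif(N, 0, t))
  # Markov bridge through R
  path <- integer(N)
  cur <- start
  for (j in seq_len(N)) {
    rem <- N - j
    w <- vapply(1:2, function(s) R[cur, s] * Rn[[rem + 1L]][s, end], numeric(1))
    cur <- sample.int(2L, 1L, prob = w)
    path[j] <- cur
  }
  keep <- c(path[1L] != start, diff(path) != 0)
  list(end = end, times = jump_times[keep], states = path[keep])
}

#' Stochastic character mapping under a two-state Mk model
#'
#' Samples explicit character-change histories conditional on the observed
#' tip states: a post-order pruning pass computes conditional likelihoods,
#' node states are drawn on the pre-order pass from their joint conditional
#' distribution, and each branch history is sampled conditional on its
#' endpoint states by rejection sampling (with a uniformization fallback
#' after a bounded number of retries). The per-node frequencies of sampled
#' states across maps estimate posterior ancestral-state probabilities.
#'
#' @param tree A `"phylo"`.
#' @param tip_states States named by tip label.
#' @param model An `"mk_model"`.
#' @param n_maps Number of maps (study design: 100).
#' @param seed Integer seed.
#' @param reject_cap Rejection-sampling retry cap per branch before falling
#'   back to uniformization.
#' @return A list of class `"simmap_result"`: `node_freq` (matrix, rows =
#'   internal nodes, cols = states, rows summing to 1), `histories` (list of
#'   maps, each with per-node states and per-branch event tables), `n_maps`,
#'   `model`, `mean_changes` (mean number of state changes per map).
#' @export
stochastic_map <- function(tree, tip_states, model, n_maps = 100, seed = 1,
                           reject_cap = 1e6) {
  validate_phylo(tree)
  stopifnot(n_maps >= 1)
  idx <- .mk_states_idx(tree, tip_states, model)
  ntip <- ape::Ntip(tree)
  nnode_all <- ntip + tree$Nnode
  Lk <- .mk_partials(tree, idx, model)
  root <- ntip + 1L
  pi0 <- .mk_root_pi(model)
  ord <- ape::reorder.phylo(tree, "postorder")
  edge_pre <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  elen_pre <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]

  counts <- matrix(0, tree$Nnode, 2L,
                   dimnames = list(root:nnode_all, model$states))
  histories <- vector("list", n_maps)
  total_changes <- 0

  .with_seed(seed, {
    for (m in seq_len(n_maps)) {
      node_state <- integer(nnode_all)
      wr <- pi0 * Lk[root, ]
      node_state[root] <- sample.int(2L, 1L, prob = wr)
      events <- vector("list", nrow(edge_pre))
      nchanges <- 0
      for (e in seq_len(nrow(edge_pre))) {
        par <- edge_pre[e, 1L]; ch <- edge_pre[e, 2L]
        P <- .mk_P(model, elen_pre[e])
        w <- P[node_state[par], ] * Lk[ch, ]
        node_state[ch] <- if (ch <= ntip) idx[ch]
                          else sample.int(2L, 1L, prob = w)
        if (ch <= ntip && sum(w) <= 0)
          stop("tip state impossible given sampled parent on the edge above ",
               .node_name(tree, ch))
        br <- .mk_bridge(model, elen_pre[e], node_state[par], node_state[ch],
                         cap = reject_cap)
        nchanges <- nchanges + length(br$times)
        events[[e]] <- if (length(br$times))
          data.frame(parent = par, child = ch, time = br$times,
                     state = model$states[br$states])
        else NULL
      }
      ij <- cbind(seq_len(tree$Nnode), node_state[root:nnode_all])
      counts[ij] <- counts[ij] + 1
      total_changes <- total_changes + nchanges
      histories[[m]] <- list(
        node_states = stats::setNames(model$states[node_state], seq_len(nnode_all)),
        events = do.call(rbind, events[!vapply(events, is.null, logical(1))]),
        n_changes = nchanges)
    }
  })
  structure(list(node_freq = counts / n_maps, histories = histories,
                 n_maps = n_maps, model = model,
                 mean_changes = total_changes / n_maps),
            class = "simmap_result")
}

#' @export
print.simmap_result <- function(x, ...) {
  cat("Stochastic mapping:", x$n_maps, "maps, mean",
      sprintf("%.2f", x$mean_changes), "state changes per map\n")
  cat("Root state frequencies:",
      paste(sprintf("%s = %.3f", colnames(x$node_freq), x$node_freq[1L, ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Marginal ancestral-state probabilities by enumeration
#'
#' Exact marginal posterior state probabilities at every internal node,
#' computed by summing the joint probability over all internal-state
#' assignments. Exponential in the number of internal nodes; intended as an
#' independent check of [stochastic_map()] on small trees.
#'
#' @param tree A `"phylo"` with at most 12 internal nodes.
#' @param tip_states States named by tip label.
#' @param model An `"mk_model"`.
#' @return Matrix (internal nodes x states) of marginal probabilities.
#' @export
mk_marginal_enumeration <- function(tree, tip_states, model) {
  validate_phylo(tree)
  if (tree$Nnode > 12L) stop("enumeration oracle limited to 12 internal nodes")
  idx <- .mk_states_idx(tree, tip_states, model)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nint <- tree$Nnode
  pi0 <- .mk_root_pi(model)
  combos <- as.matrix(expand.grid(rep(list(1:2), nint)))
  post <- matrix(0, nint, 2L, dimnames = list(root:(ntip + nint), model$states))
  state_of <- function(node, combo)
    if (node <= ntip) idx[node] else combo[node - ntip]
  total <- 0
  for (r in seq_len(nrow(combos))) {
    combo <- combos[r, ]
    p <- pi0[combo[1L]]
    for (e in seq_len(nrow(tree$edge))) {
      P <- .mk_P(model, tree$edge.length[e])
      p <- p * P[state_of(tree$edge[e, 1L], combo),
                 state_of(tree$edge[e, 2L], combo)]
      if (p == 0) break
    }
    if (p > 0) {
      total <- total + p
      post[cbind(seq_len(nint), combo)] <- post[cbind(seq_len(nint), combo)] + p
    }
  }
  if (total <= 0) stop("data have zero likelihood under this model")
  post / total
}

#' Export one stochastic map as simmap-style annotated Newick
#'
#' Serializes a sampled history in the brace notation used by simmap-aware
#' tools: each branch length is replaced by `{state,time:state,time...}`
#' segments, listed from the tip end toward the root as in SIMMAP v1.0.
#'
#' @param tree The `"phylo"` the map was sampled on.
#' @param history One element of a `"simmap_result"`'s `histories`.
#' @return A single Newick string.
#' @export
simmap_newick <- function(tree, history) {
  ntip <- ape::Ntip(tree)
  seg_of <- function(e) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    blen <- tree$edge.length[e]
    ev <- history$events
    ev <- if (is.null(ev)) NULL else ev[ev$parent == par & ev$child == ch, ,
                                        drop = FALSE]
    start_state <- history$node_states[[as.character(par)]]
    if (is.null(ev) || nrow(ev) == 0L)
      return(sprintf("%s,%g", start_state, blen))
    ev <- ev[order(ev$time), , drop = FALSE]
    states <- c(start_state, ev$state)
    times <- diff(c(0, ev$time, blen))
    # SIMMAP v1.0 lists segments from the tip end toward the root
    paste(sprintf("%s,%g", rev(states), rev(times)), collapse = ":")
  }
  build <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    parts <- vapply(kids, function(ch) {
      e <- which(tree$edge[, 2L] == ch)
      paste0(build(ch), ":{", seg_of(e), "}")
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(ntip + 1L), ";")
}
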