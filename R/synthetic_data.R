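# Generators for fossil-bearing birth-death trees, genus-structured species
# tables, and traits simulated under the candidate evolutionary models.
# Everything is seed-deterministic so fixtures can be rebuilt in code.

#' Simulate a fossil-bearing birth-death tree
#'
#' Forward-time constant-rate birth-death simulation starting from two crown
#' lineages, stopped the moment the extant lineage count first reaches
#' `n_extant` (so extant tips are contemporaneous at the stopping time).
#' Each extinct lineage is retained as a fossil tip, ending at its extinction
#' time, with probability `fossil_p`; with `fossil_p = 0` (or `death = 0`)
#' the result is an ultrametric tree. Whole-clade extinction triggers a
#' resample, up to `max_tries`.
#'
#' Extant tips receive genus-style labels (`G1`, `G2`, ...) and retained
#' fossil tips species-style labels (`Fossilgenus1_sp1`, ...), mirroring the
#' mixed-rank convention of [match_tree_and_traits()].
#'
#' @param birth Speciation rate, > 0 (per lineage per unit time).
#' @param death Extinction rate, >= 0.
#' @param n_extant Target number of extant tips (>= 2).
#' @param fossil_p Retention probability of each extinct lineage in \[0, 1\].
#' @param seed Integer seed (mandatory).
#' @param max_tries Resampling cap for whole-clade extinction.
#' @return A `"phylo"` with attribute `"status"`: named vector of
#'   `"modern"`/`"fossil"` per tip.
#' @export
simulate_bd_tree <- function(birth, death = 0, n_extant = 50, fossil_p = 1,
                             seed, max_tries = 100L) {
  stopifnot(birth > 0, death >= 0, n_extant >= 2, fossil_p >= 0, fossil_p <= 1,
            !missing(seed))
  .with_seed(seed, {
    for (try in seq_len(max_tries)) {
      sim <- .bd_forward(birth, death, n_extant)
      if (is.null(sim)) next
      tree <- .bd_to_phylo(sim)
      status <- attr(tree, "status")
      drop <- names(status)[status == "fossil" &
                              stats::runif(length(status)) > fossil_p]
      if (length(drop)) {
        if (length(setdiff(tree$tip.label, drop)) < 2L) next
        keep_status <- status[setdiff(tree$tip.label, drop)]
        tree <- ape::drop.tip(tree, drop)
        status <- keep_status[tree$tip.label]
        attr(tree, "status") <- status
      }
      if (sum(attr(tree, "status") == "modern") < 2L) next
      return(validate_phylo(tree))
    }
    stop("birth-death simulation failed to reach ", n_extant,
         " extant lineages in ", max_tries, " tries")
  })
}

# Forward simulation bookkeeping: one row per lineage with its parent,
# birth time, end time and fate.
.bd_forward <- function(birth, death, n_extant) {
  parent <- c(NA_integer_, NA_integer_)
  t_birth <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  fate <- c("alive", "alive")  # alive | split | dead
  alive <- c(1L, 2L)
  now <- 0
  while (length(alive) < n_extant) {
    if (length(alive) == 0L) return(NULL)
    rate <- length(alive) * (birth + death)
    now <- now + stats::rexp(1L, rate)
    lin <- alive[sample.int(length(alive), 1L)]
    if (stats::runif(1L) < birth / (birth + death)) {
      t_end[lin] <- now; fate[lin] <- "split"
      for (k in 1:2) {
        parent <- c(parent, lin); t_birth <- c(t_birth, now)
        t_end <- c(t_end, NA_real_); fate <- c(fate, "alive")
      }
      alive <- c(setdiff(alive, lin), length(parent) - 1L, length(parent))
    } else {
      t_end[lin] <- now; fate[lin] <- "dead"
      alive <- setdiff(alive, lin)
    }
  }
  # stop just before the next event so terminal branches have positive length
  now <- now + stats::rexp(1L, length(alive) * (birth + death))
  t_end[fate == "alive"] <- now
  list(parent = parent, t_birth = t_birth, t_end = t_end, fate = fate)
}

# Convert the lineage table to a phylo object. Lineages that split are
# internal nodes; alive/dead lineages are tips.
.bd_to_phylo <- function(sim) {
  n_lin <- length(sim$parent)
  is_tip <- sim$fate != "split"
  tip_ids <- which(is_tip)
  int_ids <- which(!is_tip)
  ntip <- length(tip_ids)
  # the two crown lineages hang from a virtual root node
  node_num <- integer(n_lin)
  node_num[tip_ids] <- seq_len(ntip)
  node_num[int_ids] <- ntip + 1L + seq_along(int_ids)
  root_num <- ntip + 1L
  edge <- matrix(0L, n_lin, 2L)
  elen <- numeric(n_lin)
  for (i in seq_len(n_lin)) {
    par <- sim$parent[i]
    edge[i, ] <- c(if (is.na(par)) root_num else node_num[par], node_num[i])
    elen[i] <- sim$t_end[i] - sim$t_birth[i]
  }
  status <- ifelse(sim$fate[tip_ids] == "dead", "fossil", "modern")
  n_modern <- sum(status == "modern")
  lab <- character(ntip)
  lab[status == "modern"] <- paste0("G", seq_len(n_modern))
  lab[status == "fossil"] <- paste0("Fossilgenus", seq_len(ntip - n_modern),
                                    "_sp1")
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = lab, Nnode = length(int_ids) + 1L),
                    class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree)
  attr(tree, "status") <- stats::setNames(status, lab)
  tree
}

#' Simulate tip traits under a trait-evolution model
#'
#' One exact draw from the multivariate normal implied by
#' [model_mean_cov()], via a Cholesky factor of the covariance (no
#' branch-wise discretization error; every model shares this code path).
#'
#' @param tree A `"phylo"`.
#' @param spec A `"model_spec"`.
#' @param painting Required iff `spec$name == "trend_BM"`.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_trait <- function(tree, spec, painting = NULL, seed) {
  stopifnot(!missing(seed))
  mc <- model_mean_cov(spec, tree, painting)
  if (spec$sigma2 < 1e-12) return(mc$mean)
  L <- .chol_or_die(mc$V)
  .with_seed(seed, {
    z <- stats::rnorm(length(mc$mean))
    drop(mc$mean + crossprod(L, z))
  })
}

#' Simulate a two-state Mk character history on a tree
#'
#' Draws the root state from the model's root prior and evolves the chain
#' along every branch with exponential waiting times.
#'
#' @param tree A `"phylo"`.
#' @param model An `"mk_model"`.
#' @param seed Integer seed.
#' @return List with `tip_states` (named by tip) and `node_states`.
#' @export
simulate_mk <- function(tree, model, seed) {
  stopifnot(!missing(seed))
  validate_phylo(tree)
  ntip <- ape::Ntip(tree)
  nnode_all <- ntip + tree$Nnode
  .with_seed(seed, {
    st <- integer(nnode_all)
    st[ntip + 1L] <- sample.int(2L, 1L, prob = .mk_root_pi(model))
    ord <- ape::reorder.phylo(tree, "postorder")
    pre <- rev(seq_len(nrow(ord$edge)))
    for (e in pre) {
      par <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
      st[ch] <- .mk_sim_branch(model, ord$edge.length[e], st[par])$end
    }
    list(tip_states = stats::setNames(model$states[st[seq_len(ntip)]],
                                      tree$tip.label),
         node_states = model$states[st[(ntip + 1L):nnode_all]])
  })
}

#' Simulate a genus-structured species trait table with social annotations
#'
#' Expands each modern (genus-level) tip of a simulated tree into a genus of
#' species whose ln head widths scatter around the genus value with
#' within-genus standard deviation `within_sd`; fossil tips yield single
#' species records. Worker and soldier head widths are derived from the
#' imago value through configurable proportional-disparity offsets
#' (`width_other = width_imago / (1 + d)`, `d ~ N(mean, sd)` truncated above
#' -0.9). The binary worker-type character evolves on the tree under an Mk
#' model with rate `mk_rate`; nesting type evolves under a 3-state
#' equal-rates chain; maximum colony size is log-normal around caste-linked
#' means.
#'
#' @param tree A `"phylo"` from [simulate_bd_tree()] (carries tip `status`).
#' @param genus_values Named ln-mm imago values per tip (e.g. from
#'   [simulate_trait()]).
#' @param species_per_genus Mean number of species per modern genus; actual
#'   counts are `1 + Poisson(species_per_genus - 1)`.
#' @param within_sd Within-genus standard deviation on the ln scale.
#' @param disparity_iw,disparity_iw_sd Mean and sd of the imago-worker
#'   proportional disparity.
#' @param disparity_is,disparity_is_sd Mean and sd of the imago-soldier
#'   proportional disparity.
#' @param mk_rate Transition rate of the worker-type (and nesting) chains.
#' @param seed Integer seed.
#' @return A list: `records` (trait table, one row per species x caste),
#'   `annotations` (per-genus social annotation), `tip_worker_type` (the
#'   simulated per-tip worker-type states).
#' @export
simulate_species_table <- function(tree, genus_values, species_per_genus = 3,
                                   within_sd = 0.1,
                                   disparity_iw = 0.3, disparity_iw_sd = 0.15,
                                   disparity_is = 0, disparity_is_sd = 0.2,
                                   mk_rate = 0.01, seed) {
  stopifnot(!missing(seed))
  status <- attr(tree, "status")
  if (is.null(status))
    status <- stats::setNames(rep("modern", ape::Ntip(tree)), tree$tip.label)
  if (!setequal(names(genus_values), tree$tip.label))
    stop("genus_values names must match tree tips")
  wt_model <- mk_model(mk_rate, states = c("pseudergate", "true_worker"))
  wt <- simulate_mk(tree, wt_model, seed = seed + 1L)$tip_states
  nest_states <- .simulate_er3(tree, mk_rate, seed = seed + 2L,
                               states = c("one_piece", "multiple_piece",
                                          "separate_piece"))
  .with_seed(seed, {
    recs <- list(); ann <- list()
    for (tip in tree$tip.label) {
      modern <- status[tip] == "modern"
      n_sp <- if (modern) 1L + stats::rpois(1L, max(species_per_genus - 1, 0))
              else 1L
      genus <- .genus_token(tip)
      for (s in seq_len(n_sp)) {
        sp_name <- if (modern) paste0(genus, "_sp", s) else tip
        ln_imago <- genus_values[[tip]] + if (modern)
          stats::rnorm(1L, 0, within_sd) else 0
        d_iw <- max(stats::rnorm(1L, disparity_iw, disparity_iw_sd), -0.9)
        d_is <- max(stats::rnorm(1L, disparity_is, disparity_is_sd), -0.9)
        castes <- c("imago", "worker", "soldier")
        widths <- exp(c(ln_imago, ln_imago - log1p(d_iw), ln_imago - log1p(d_is)))
        for (ci in seq_along(castes)) {
          if (!modern && castes[ci] != "imago") next  # fossils: imagoes only
          recs[[length(recs) + 1L]] <- data.frame(
            species = sp_name, genus = genus, family = "Simfamily",
            caste = castes[ci], head_width_mm = widths[ci],
            status = if (modern) "modern" else "fossil",
            worker_type = if (modern) unname(wt[tip]) else NA_character_,
            nesting_type = if (modern) unname(nest_states[tip]) else NA_character_,
            max_colony_size = if (modern)
              round(stats::rlnorm(1L, meanlog = 8, sdlog = 1.5)) else NA_real_)
        }
      }
      ann[[length(ann) + 1L]] <- data.frame(
        genus = genus, worker_type = unname(wt[tip]),
        nesting_type = unname(nest_states[tip]))
    }
    records <- do.call(rbind, recs)
    records <- records[!duplicated(records[c("species", "caste")]), ]
    list(records = validate_trait_table(records),
         annotations = unique(do.call(rbind, ann)),
         tip_worker_type = wt)
  })
}

# 3-state equal-rates chain simulated branch-wise (simulation only; the
# inference module is deliberately 2-state).
.simulate_er3 <- function(tree, rate, seed, states) {
  validate_phylo(tree)
  ntip <- ape::Ntip(tree)
  .with_seed(seed, {
    st <- integer(ntip + tree$Nnode)
    st[ntip + 1L] <- sample.int(3L, 1L)
    ord <- ape::reorder.phylo(tree, "postorder")
    for (e in rev(seq_len(nrow(ord$edge)))) {
      par <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
      cur <- st[par]; t <- ord$edge.length[e]; now <- 0
      repeat {
        if (rate <= 0) break
        now <- now + stats::rexp(1L, 2 * rate)  # leave-rate of an ER 3-chain
        if (now >= t) break
        cur <- sample(setdiff(1:3, cur), 1L)
      }
      st[ch] <- cur
    }
    stats::setNames(states[st[seq_len(ntip)]], tree$tip.label)
  })
}
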