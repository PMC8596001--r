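test_that("read_tree parses newick and nexus and validates invariants", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tr <- read_tree(tf)
  expect_equal(ape::Ntip(tr), 3L)
  dep <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(sort(dep), c(2, 2, 2))

  writeLines("((A:1,B:1):1,C:1);", tf)
  tr2 <- read_tree(tf)
  expect_false(ape::is.ultrametric(tr2))
  expect_equal(ape::node.depth.edgelength(tr2)[match("C", tr2$tip.label)], 1)

  nx <- tempfile(fileext = ".nex")
  ape::write.nexus(tr, file = nx)
  expect_equal(sort(read_tree(nx)$tip.label), c("A", "B", "C"))

  writeLines("((A:1,A:1):1,C:2);", tf)
  expect_error(read_tree(tf), "duplicate")
  writeLines("((A:1,B:1),C:2);", tf)
  expect_error(read_tree(tf), "branch length")
  writeLines("this is not a tree", tf)
  expect_error(read_tree(tf))
})

test_that("curate_measurement applies the mean > midrange > holotype priority", {
  expect_equal(curate_measurement(data.frame(min = 1, max = 2))$value, 1.5)
  expect_equal(curate_measurement(data.frame(min = 1, max = 2))$basis, "midrange")
  expect_equal(curate_measurement(data.frame(mean = c(1, 2)))$value, 1.5)
  expect_equal(curate_measurement(data.frame(mean = 1.2, min = 1, max = 2))$value, 1.2)
  expect_equal(curate_measurement(data.frame(holotype = 2.2))$basis, "holotype")
  # mixed bases across sources: per-source priority, then mean across sources
  src <- data.frame(mean = c(1.0, NA), min = c(NA, 2.0), max = c(NA, 3.0))
  expect_equal(curate_measurement(src)$value, mean(c(1.0, 2.5)))
  expect_error(curate_measurement(data.frame(mean = numeric(0))), "empty")
  expect_error(curate_measurement(data.frame(mean = -1)), "positive")
})

test_that("curate_measurement is permutation-invariant and honours subcastes", {
  src <- data.frame(mean = c(1.1, NA, 1.4), min = c(NA, 0.8, NA),
                    max = c(NA, 1.2, NA))
  base <- curate_measurement(src)$value
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(curate_measurement(src[p, ])$value, base)

  poly <- data.frame(mean = c(1.0, 2.0), subcaste = c("minor", "major"))
  expect_equal(curate_measurement(poly)$value, 2.0)
  expect_equal(curate_measurement(poly)$subcaste, "major")
  expect_equal(curate_measurement(poly, use_largest = FALSE)$value, 1.0)
})

test_that("match_tree_and_traits prunes and matches at mixed rank", {
  tr <- ape::read.tree(text = "((((Alpha:1,Beta:1):1,Fossilus_rex:0.5):1,Gamma:3):1,Delta:4);")
  ds <- match_tree_and_traits(tr, toy_records(), level = "genus")
  expect_equal(sort(names(ds$x)), c("Alpha", "Beta", "Fossilus_rex", "Gamma"))
  expect_equal(ds$dropped_tips, "Delta")
  # genus-level value is the mean of ln widths of congeners
  expect_equal(unname(ds$x["Alpha"]), mean(log(c(1, 2))))
  expect_equal(unname(ds$x["Fossilus_rex"]), log(2.5))
  expect_equal(unname(ds$status["Fossilus_rex"]), "fossil")
  # all-match identity prune
  tr2 <- ape::drop.tip(tr, "Delta")
  ds2 <- match_tree_and_traits(tr2, toy_records())
  expect_equal(length(ds2$dropped_tips), 0L)
  expect_equal(ape::Ntip(ds2$tree), 4L)
  # no overlap
  tr3 <- ape::read.tree(text = "(X:1,Y:1);")
  expect_error(match_tree_and_traits(tr3, toy_records()), "fewer than 2")
})

test_that("subsample_one_per_genus keeps fossils, is seeded, and samples uniformly", {
  rec <- toy_records()
  s1 <- subsample_one_per_genus(rec, seed = 7)
  s2 <- subsample_one_per_genus(rec, seed = 7)
  expect_identical(s1, s2)
  expect_true("Fossilus_rex" %in% s1$species)
  expect_equal(sum(s1$genus == "Alpha"), 1L)
  # singleton genera always chosen
  expect_true(all(c("Beta_a", "Gamma_a") %in% s1$species))
  # uniformity over the 2 Alpha species: chi-square on 2000 draws
  draws <- vapply(1:2000, function(i)
    subsample_one_per_genus(rec, seed = i)$species[
      subsample_one_per_genus(rec, seed = i)$genus == "Alpha"], character(1))
  tab <- table(draws)
  expect_gt(stats::chisq.test(tab, p = c(0.5, 0.5))$p.value, 1e-4)
  # unmeasured genus dropped with a warning
  rec2 <- rbind(rec, data.frame(species = "Omega_a", genus = "Omega",
                                family = "F", caste = "imago",
                                head_width_mm = NA, status = "modern"))
  expect_warning(s3 <- subsample_one_per_genus(rec2, seed = 1), "Omega")
  expect_false("Omega" %in% s3$genus)
})

test_that("phylo_vcv matches construction and the path-enumeration oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))
  for (s in 1:10) {
    tr <- fossil_tree(6, seed = s)
    expect_equal(phylo_vcv(tr), oracle_vcv(tr), tolerance = 1e-12)
  }
})

test_that("phylo_vcv is symmetric PSD and consistent under pruning", {
  for (s in 1:200) {
    set.seed(s)
    tr <- ape::rtree(sample(4:10, 1))
    C <- phylo_vcv(tr)
    expect_identical(C, t(C))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  # prune-then-vcv equals vcv-then-submatrix for subsets spanning the root
  # (dropping a whole basal clade legitimately re-roots the tree)
  for (s in 1:20) {
    set.seed(s)
    tr <- ape::rtree(8)
    root_kids <- tr$edge[tr$edge[, 1] == 9L, 2L]
    tips_under <- function(node) {
      if (node <= 8L) return(tr$tip.label[node])
      tr$tip.label[intersect(termevol:::.descendant_nodes(tr, node), 1:8)]
    }
    keep <- unlist(lapply(root_kids, function(k) {
      tt <- tips_under(k); sample(tt, min(2, length(tt)))
    }))
    sub <- ape::drop.tip(tr, setdiff(tr$tip.label, keep))
    expect_equal(phylo_vcv(sub)[sub$tip.label, sub$tip.label],
                 phylo_vcv(tr)[sub$tip.label, sub$tip.label])
  }
})

test_that("trait tables round-trip through read_trait_table in both dialects", {
  rec <- toy_records()
  for (sep in c("\t", ",")) {
    f <- tempfile()
    utils::write.table(rec, f, sep = sep, row.names = FALSE, quote = FALSE)
    back <- read_trait_table(f)
    expect_equal(back$species, rec$species)
    expect_equal(back$head_width_mm, rec$head_width_mm)
  }
  bad <- rec; bad$caste[1] <- "queen"
  f <- tempfile(); utils::write.table(bad, f, sep = "\t", row.names = FALSE)
  expect_error(read_trait_table(f), "caste")
})
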