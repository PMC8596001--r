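# End-to-end orchestration: curate -> match -> replicate-fit -> social stats
# -> ancestral-state reconstruction, with TSV/JSON reports. These functions
# are the programmatic interface to the whole workflow; scripts/acceptance.R
# drives them non-interactively.

#' Assemble a run configuration
#'
#' Validates the knobs shared by the pipeline stages. Either file paths or
#' in-memory objects may be supplied for the tree and trait table.
#'
#' @param tree A `"phylo"` or a path readable by [read_tree()].
#' @param traits A trait table data.frame or a path readable by
#'   [read_trait_table()].
#' @param caste Caste to analyse: `"imago"`, `"soldier"` or `"worker"`.
#' @param include_fossils Keep fossil records/tips (`TRUE`) or restrict to
#'   modern taxa.
#' @param models Model set for the comparison.
#' @param clade_tips Tip labels whose MRCA defines the BM regime of
#'   `trend_BM` (the higher-termite clade in the motivating analysis).
#' @param n_rep Number of genus-subsampling replicates, >= 1.
#' @param seed Integer seed.
#' @param out_dir Output directory, or `NULL` for no files.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(tree, traits, caste = c("imago", "soldier", "worker"),
                       include_fossils = TRUE, models = MODEL_NAMES,
                       clade_tips = NULL, n_rep = 100, seed = 1,
                       out_dir = NULL) {
  caste <- match.arg(caste)
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(traits)) traits <- read_trait_table(traits)
  validate_phylo(tree)
  validate_trait_table(traits)
  if (n_rep < 1) stop("n_rep must be >= 1")
  structure(list(tree = tree, traits = traits, caste = caste,
                 include_fossils = include_fossils, models = models,
                 clade_tips = clade_tips, n_rep = n_rep, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

.config_records <- function(config) {
  rec <- config$traits[config$traits$caste == config$caste, , drop = FALSE]
  if (!config$include_fossils)
    rec <- rec[rec$status == "modern", , drop = FALSE]
  if (!nrow(rec)) stop("no ", config$caste, " records under this configuration")
  rec
}

.config_tree <- function(config, records) {
  tree <- config$tree
  if (!config$include_fossils) {
    tip_is_fossil <- !(.genus_token(tree$tip.label) %in% records$genus) &
      .normalize_label(tree$tip.label) %in%
        .normalize_label(config$traits$species[config$traits$status == "fossil"])
    fossil_tips <- tree$tip.label[tip_is_fossil]
    status <- attr(tree, "status")
    if (!is.null(status))
      fossil_tips <- union(fossil_tips, names(status)[status == "fossil"])
    if (length(fossil_tips) &&
        length(setdiff(tree$tip.label, fossil_tips)) >= 2L)
      tree <- ape::drop.tip(tree, intersect(fossil_tips, tree$tip.label))
  }
  tree
}

#' Run the replicated model-comparison stage
#'
#' Filters the trait table to the configured caste (and to modern taxa when
#' `include_fossils = FALSE`, also pruning fossil tips), then runs
#' [replicate_fit()] and writes the replicate table and summary when an
#' output directory is configured.
#'
#' @param config A `"run_config"`.
#' @return The `"fit_summary"`, invisibly augmented with the resolved
#'   configuration under `$config_used`.
#' @export
run_model_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- .config_records(config)
  tree <- .config_tree(config, records)
  models <- config$models
  if (is.null(config$clade_tips)) models <- setdiff(models, "trend_BM")
  fs <- replicate_fit(records, tree, n_rep = config$n_rep, seed = config$seed,
                      models = models, clade_tips = config$clade_tips)
  fs$config_used <- config[c("caste", "include_fossils", "n_rep", "seed")]
  if (!is.null(config$out_dir)) {
    write_fit_summary(fs, config$out_dir,
                      prefix = paste0("models_", config$caste,
                                      if (config$include_fossils) "_fossil"
                                      else "_modern"))
    jsonlite::write_json(fs$config_used,
                         file.path(config$out_dir, "resolved_config.json"),
                         auto_unbox = TRUE)
  }
  fs
}

#' Run the social-complexity statistics stage
#'
#' On the modern, genus-summarized dataset: PGLS of ln imago head width on
#' worker type, nesting type and log10 colony size (each under the AIC-best
#' branch-length transform), Bartlett variance tests across the same
#' groupings on the species-level data, imago-worker and imago-soldier
#' disparity summaries with per-level intercept tests, and pairwise caste
#' correlations.
#'
#' @param config A `"run_config"` (social annotation columns required).
#' @return A list of class `"social_stats"` with elements `pgls`,
#'   `bartlett`, `disparity`, `intercepts`, `caste_cor`.
#' @export
run_social_stats <- function(config) {
  stopifnot(inherits(config, "run_config"))
  traits <- config$traits
  need <- c("worker_type", "nesting_type")
  miss <- setdiff(need, names(traits))
  if (length(miss))
    stop("missing social annotation column(s): ", paste(miss, collapse = ", "))
  modern <- traits[traits$status == "modern", , drop = FALSE]

  # genus-level table, one row per genus with per-caste mean widths (mm)
  wide <- .genus_caste_table(modern)
  imod <- modern[modern$caste == "imago", , drop = FALSE]
  ds <- match_tree_and_traits(.config_tree(config, imod), imod[!is.na(imod$head_width_mm), ],
                              level = "genus")
  gtree <- ds$tree
  fossil_tips <- gtree$tip.label[ds$status[gtree$tip.label] == "fossil"]
  if (length(fossil_tips) &&
      length(setdiff(gtree$tip.label, fossil_tips)) >= 3L)
    gtree <- ape::drop.tip(gtree, fossil_tips)
  wide <- wide[wide$genus %in% .genus_token(gtree$tip.label), , drop = FALSE]
  rownames(wide) <- gtree$tip.label[match(wide$genus, .genus_token(gtree$tip.label))]

  pgls <- list()
  if (any(!is.na(wide$worker_type)))
    pgls$worker_type <- tryCatch(
      pgls_best(log(imago) ~ worker_type, stats::na.omit(wide[c("imago", "worker_type")]), gtree),
      error = function(e) conditionMessage(e))
  if (any(!is.na(wide$nesting_type)))
    pgls$nesting_type <- tryCatch(
      pgls_best(log(imago) ~ nesting_type, stats::na.omit(wide[c("imago", "nesting_type")]), gtree),
      error = function(e) conditionMessage(e))
  if (!is.null(wide$max_colony_size) && any(!is.na(wide$max_colony_size)))
    pgls$colony_size <- tryCatch(
      pgls_best(log(imago) ~ log10(max_colony_size),
                stats::na.omit(wide[c("imago", "max_colony_size")]), gtree),
      error = function(e) conditionMessage(e))

  spec_imago <- modern[modern$caste == "imago" & !is.na(modern$head_width_mm), ]
  bartlett <- list()
  if (any(!is.na(spec_imago$worker_type)))
    bartlett$worker_type <- suppressWarnings(
      bartlett_test(log(spec_imago$head_width_mm[!is.na(spec_imago$worker_type)]),
                    spec_imago$worker_type[!is.na(spec_imago$worker_type)]))
  if (any(!is.na(spec_imago$nesting_type)))
    bartlett$nesting_type <- suppressWarnings(
      bartlett_test(log(spec_imago$head_width_mm[!is.na(spec_imago$nesting_type)]),
                    spec_imago$nesting_type[!is.na(spec_imago$nesting_type)]))

  disp <- .species_disparity(modern)
  intercepts <- NULL
  wide_d <- stats::na.omit(wide[c("imago", "worker", "worker_type")])
  if (nrow(wide_d) >= 5L && length(unique(wide_d$worker_type)) == 2L) {
    dvals <- stats::setNames(disparity(wide_d$imago, wide_d$worker),
                             rownames(wide_d))
    intercepts <- tryCatch(
      intercept_tests(dvals,
                      stats::setNames(wide_d$worker_type, rownames(wide_d)),
                      gtree),
      error = function(e) conditionMessage(e))
  }

  caste_cor <- list()
  for (pair in list(c("imago", "worker"), c("imago", "soldier"),
                    c("soldier", "worker"))) {
    nm <- paste(pair, collapse = "_")
    caste_cor[[nm]] <- tryCatch(caste_correlation(wide, pair, gtree),
                                error = function(e) conditionMessage(e))
  }

  out <- structure(list(pgls = pgls, bartlett = bartlett, disparity = disp,
                        intercepts = intercepts, caste_cor = caste_cor,
                        n_genera = nrow(wide)),
                   class = "social_stats")
  if (!is.null(config$out_dir)) .write_social_stats(out, config$out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.genus_caste_table <- function(modern) {
  ag <- stats::aggregate(head_width_mm ~ genus + caste, data = modern,
                         FUN = mean)
  wide <- stats::reshape(ag, idvar = "genus", timevar = "caste",
                         direction = "wide")
  names(wide) <- sub("^head_width_mm\\.", "", names(wide))
  for (caste in c("imago", "worker", "soldier"))
    if (is.null(wide[[caste]])) wide[[caste]] <- NA_real_
  first_non_na <- function(v) if (all(is.na(v))) NA else v[!is.na(v)][1L]
  for (col in c("worker_type", "nesting_type", "max_colony_size")) {
    if (is.null(modern[[col]])) { wide[[col]] <- NA; next }
    m <- tapply(modern[[col]], modern$genus, first_non_na)
    wide[[col]] <- unname(m[wide$genus])
  }
  wide
}

.species_disparity <- function(modern) {
  w <- stats::reshape(modern[c("species", "caste", "head_width_mm")],
                      idvar = "species", timevar = "caste",
                      direction = "wide")
  names(w) <- sub("^head_width_mm\\.", "", names(w))
  out <- list()
  for (pair in list(c("imago", "worker"), c("imago", "soldier"))) {
    if (!all(pair %in% names(w))) next
    ok <- stats::complete.cases(w[pair])
    if (!any(ok)) next
    d <- disparity(w[[pair[1L]]][ok], w[[pair[2L]]][ok])
    out[[paste(pair, collapse = "_")]] <- data.frame(
      species = w$species[ok], disparity = d)
  }
  out
}

.write_social_stats <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    n_genera = x$n_genera,
    pgls = lapply(x$pgls, function(f) if (inherits(f, "pgls_fit"))
      list(transform = f$transform, F = f$F, F_p = f$F_p, AIC = f$AIC) else f),
    bartlett = lapply(x$bartlett, function(b)
      b[c("K", "df", "p.value", "group_variances")]),
    disparity_means = lapply(x$disparity, function(d) mean(d$disparity)))
  jsonlite::write_json(summ, file.path(dir, "social_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the ancestral-state reconstruction stage
#'
#' ML Mk rate estimation for the binary worker-type character on the modern
#' genus-level tree, followed by stochastic character mapping (study design:
#' 100 maps) and a per-node state-frequency table.
#'
#' @param config A `"run_config"` (worker_type column required).
#' @param n_maps Number of stochastic maps.
#' @return A list of class `"asr_result"`: `fit` (from [fit_mk()]),
#'   `simmap` (from [stochastic_map()]), `node_freq`.
#' @export
run_asr <- function(config, n_maps = 100) {
  stopifnot(inherits(config, "run_config"))
  traits <- config$traits
  if (is.null(traits$worker_type)) stop("worker_type column is required")
  modern <- traits[traits$status == "modern" & !is.na(traits$worker_type), ]
  if (!nrow(modern)) stop("no modern records with worker_type")
  first <- function(v) v[!is.na(v)][1L]
  per_genus <- tapply(modern$worker_type, modern$genus, first)
  tree <- .config_tree(config, modern)
  keep <- tree$tip.label[.genus_token(tree$tip.label) %in% names(per_genus)]
  if (length(keep) < 3L) stop("fewer than 3 tips with worker_type data")
  tree <- ape::drop.tip(tree, setdiff(tree$tip.label, keep))
  states <- stats::setNames(unname(per_genus[.genus_token(tree$tip.label)]),
                            tree$tip.label)
  fit <- fit_mk(tree, states, states = c("pseudergate", "true_worker"))
  sm <- stochastic_map(tree, states, fit$model, n_maps = n_maps,
                       seed = config$seed)
  out <- structure(list(fit = fit, simmap = sm, node_freq = sm$node_freq,
                        monomorphic = fit$monomorphic, tree = tree),
                   class = "asr_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(node = rownames(sm$node_freq), sm$node_freq,
                 check.names = FALSE),
      file.path(config$out_dir, "asr_node_frequencies.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Reproduce the published head-width analysis from its source files
#'
#' Runs the full pipeline (curation counts, 140-tip matching, 100-replicate
#' model comparison with and without fossils, Bartlett tests, disparity
#' proportions) against the original study inputs: the species-level
#' head-width table and the 183-taxon dated tree distributed as that study's
#' supplementary data. Those files are not bundled with this package (they
#' are third-party data); place them at the paths you pass in.
#'
#' @param traits_path Path to the species-level head-width table.
#' @param tree_path Path to the dated phylogeny (Nexus or Newick).
#' @param n_rep Subsampling replicates (study design: 100).
#' @param seed Integer seed.
#' @param clade_tips Tips defining the BM regime (higher termites) for
#'   `trend_BM`.
#' @return A list with `counts` (dataset summaries), `fossil` and `modern`
#'   (`"fit_summary"` objects), `bartlett` results.
#' @export
reproduce_study <- function(traits_path, tree_path, n_rep = 100, seed = 1,
                            clade_tips = NULL) {
  if (!file.exists(traits_path))
    stop("study trait table not found at '", traits_path,
         "'; the original supplementary data files are not distributed ",
         "with this package")
  if (!file.exists(tree_path))
    stop("study tree not found at '", tree_path, "'")
  traits <- read_trait_table(traits_path)
  tree <- read_tree(tree_path)
  imago <- traits[traits$caste == "imago", ]
  counts <- list(
    n_species = length(unique(traits$species)),
    n_taxa_tree = ape::Ntip(tree),
    imago_min_mm = min(imago$head_width_mm, na.rm = TRUE),
    n_tips_matched = length(match_tree_and_traits(tree, imago)$x))
  cfg_f <- run_config(tree, traits, caste = "imago", include_fossils = TRUE,
                      n_rep = n_rep, seed = seed, clade_tips = clade_tips)
  cfg_m <- run_config(tree, traits, caste = "imago", include_fossils = FALSE,
                      n_rep = n_rep, seed = seed, clade_tips = clade_tips)
  fossil <- run_model_comparison(cfg_f)
  modern <- run_model_comparison(cfg_m)
  sp_imago <- imago[!is.na(imago$head_width_mm) & imago$status == "modern", ]
  bl <- if (any(!is.na(sp_imago$worker_type))) {
    ok <- !is.na(sp_imago$worker_type)
    list(ln = suppressWarnings(
           bartlett_test(log(sp_imago$head_width_mm[ok]), sp_imago$worker_type[ok])),
         mm = suppressWarnings(
           bartlett_test(sp_imago$head_width_mm[ok], sp_imago$worker_type[ok])))
  } else NULL
  list(counts = counts, fossil = fossil, modern = modern, bartlett = bl)
}
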