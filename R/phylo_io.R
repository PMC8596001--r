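# Tree and trait-table input, curation, and taxon matching.

#' Read a rooted, branch-length-bearing phylogeny
#'
#' Reads a tree from Newick or Nexus (TREES block) and validates the
#' invariants the downstream model machinery relies on: a single root, unique
#' tip labels, non-negative branch lengths on every edge, and at least two
#' tips. Tip labels are preserved verbatim; label normalization (underscores
#' versus spaces) happens only at matching time, see [match_tree_and_traits()].
#'
#' @param path Path to the tree file.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (sniff the first
#'   non-blank line for a `#NEXUS` header).
#' @return An object of class `"phylo"` (rooted, with `edge.length`).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_tree(tf)
#' ape::Ntip(tr)
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 5L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && grepl("^#NEXUS", toupper(trimws(first[1L]))))
      "nexus" else "newick"
  }
  tree <- switch(format,
    newick = tryCatch(suppressWarnings(ape::read.tree(path)),
                      error = function(e) stop("could not parse Newick file '",
                                               path, "': ", conditionMessage(e))),
    nexus  = tryCatch(suppressWarnings(ape::read.nexus(path)),
                      error = function(e) stop("could not parse Nexus file '",
                                               path, "': ", conditionMessage(e)))
  )
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      stop("file contains ", length(tree), " trees; expected exactly one")
    tree <- tree[[1L]]
  }
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse a tree from '", path, "'")
  validate_phylo(tree)
}

#' Validate phylogeny invariants
#'
#' Checks that `tree` is a rooted binary-or-multifurcating `"phylo"` with at
#' least two uniquely labelled tips, branch lengths on every edge, and no
#' negative branch lengths. Returns the tree invisibly unchanged so it can be
#' used in pipelines.
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  bad <- which(is.na(tree$edge.length))
  if (length(bad)) {
    lab <- .node_name(tree, tree$edge[bad[1L], 2L])
    stop("missing branch length on the edge above node ", lab)
  }
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    lab <- .node_name(tree, tree$edge[neg[1L], 2L])
    stop("negative branch length on the edge above node ", lab)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

.node_name <- function(tree, node) {
  if (node <= ape::Ntip(tree)) sprintf("tip '%s'", tree$tip.label[node])
  else sprintf("#%d (internal)", node)
}

#' Read a species-level trait table
#'
#' Reads a UTF-8 delimited text file with header columns `species`, `genus`,
#' `family`, `caste`, `head_width_mm`, `status` and optionally `worker_type`,
#' `nesting_type`, `max_colony_size`, `measurement_basis`, `n_sources`.
#' The delimiter is auto-detected from the header line (tab beats comma) or
#' forced with `sep`.
#'
#' @param path Path to the table.
#' @param sep `NULL` for auto-detection, or an explicit delimiter.
#' @return A `data.frame` with validated closed-vocabulary columns.
#' @export
read_trait_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  validate_trait_table(tab)
}

#' @rdname read_trait_table
#' @param tab A data.frame to validate in place of reading a file.
#' @export
validate_trait_table <- function(tab) {
  required <- c("species", "genus", "caste", "head_width_mm", "status")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("trait table lacks required column(s): ", paste(missing, collapse = ", "))
  .check_vocab(tab$caste, c("imago", "soldier", "worker", "pseudergate"), "caste")
  .check_vocab(tab$status, c("modern", "fossil"), "status")
  if ("worker_type" %in% names(tab))
    .check_vocab(tab$worker_type, c("true_worker", "pseudergate"), "worker_type",
                 allow_na = TRUE)
  if ("nesting_type" %in% names(tab))
    .check_vocab(tab$nesting_type,
                 c("one_piece", "multiple_piece", "separate_piece"),
                 "nesting_type", allow_na = TRUE)
  hw <- tab$head_width_mm
  if (any(!is.na(hw) & hw <= 0))
    stop("head_width_mm must be > 0; offending species: ",
         paste(utils::head(tab$species[!is.na(hw) & hw <= 0], 3L), collapse = ", "))
  if ("max_colony_size" %in% names(tab)) {
    cs <- tab$max_colony_size
    if (any(!is.na(cs) & cs <= 0)) stop("max_colony_size must be positive")
  }
  dup <- duplicated(tab[c("species", "caste")])
  if (any(dup))
    stop("more than one record per (species, caste): ",
         paste(utils::head(tab$species[dup], 3L), collapse = ", "))
  tab
}

.check_vocab <- function(x, vocab, what, allow_na = FALSE) {
  bad <- !(x %in% vocab)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad))
    stop(what, " contains value(s) outside {", paste(vocab, collapse = ", "),
         "}: ", paste(unique(x[bad])[1:min(3, sum(bad))], collapse = ", "))
  invisible(TRUE)
}

#' Curate per-source head-width reports into one representative value
#'
#' Literature sources report a species mean, a (min, max) range, or a holotype
#' value. Within each source the priority is mean > mid-range > holotype; the
#' representative value is the mean across sources of the per-source values.
#' For polymorphic castes (rows carrying a `subcaste` label), the value is
#' taken from the largest subcaste by default (majors), or the smallest when
#' `use_largest = FALSE`.
#'
#' @param sources A data.frame with one row per source report and any of the
#'   columns `mean`, `min`, `max`, `holotype` (NA where not reported), plus an
#'   optional `subcaste` column.
#' @param use_largest Use the largest subcaste when polymorphic (default).
#' @return A list with `value` (mm), `basis` (`"mean"`, `"midrange"` or
#'   `"holotype"` — the highest-priority basis that contributed),
#'   `n_sources`, and `subcaste` (or `NA`).
#' @examples
#' curate_measurement(data.frame(min = 1, max = 2))$value       # 1.5
#' curate_measurement(data.frame(mean = c(1, 2)))$value         # 1.5
#' curate_measurement(data.frame(mean = 1.2, min = 1, max = 2)) # mean wins
#' @export
curate_measurement <- function(sources, use_largest = TRUE) {
  if (!is.data.frame(sources) || nrow(sources) == 0L)
    stop("empty input: at least one source report is required")
  for (col in c("mean", "min", "max", "holotype"))
    if (is.null(sources[[col]])) sources[[col]] <- NA_real_
  if (is.null(sources$subcaste)) sources$subcaste <- NA_character_
  groups <- split(sources, ifelse(is.na(sources$subcaste), "", sources$subcaste))
  per_group <- lapply(groups, .curate_one_group)
  vals <- vapply(per_group, `[[`, numeric(1), "value")
  pick <- if (use_largest) which.max(vals) else which.min(vals)
  out <- per_group[[pick]]
  out$subcaste <- if (nzchar(names(groups)[pick])) names(groups)[pick] else NA_character_
  out
}

.curate_one_group <- function(g) {
  per_source <- numeric(nrow(g))
  basis <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    if (!is.na(g$mean[i])) {
      per_source[i] <- g$mean[i]; basis[i] <- "mean"
    } else if (!is.na(g$min[i]) && !is.na(g$max[i])) {
      per_source[i] <- (g$min[i] + g$max[i]) / 2; basis[i] <- "midrange"
    } else if (!is.na(g$holotype[i])) {
      per_source[i] <- g$holotype[i]; basis[i] <- "holotype"
    } else stop("source row ", i, " carries no usable measurement")
  }
  if (any(per_source <= 0)) stop("non-positive head width in source reports")
  rank <- c(mean = 1L, midrange = 2L, holotype = 3L)
  list(value = mean(per_source),
       basis = names(rank)[min(rank[basis])],
       n_sources = nrow(g))
}

.normalize_label <- function(x) gsub("\\s+", "_", trimws(x))

.genus_token <- function(label) sub("_.*$", "", .normalize_label(label))

#' Match a tree against a trait table
#'
#' Matches tree tips to trait records using the mixed-rank convention of the
#' study design: modern tips are matched at genus level by the genus token of
#' the tip label, fossil tips by full species name (underscores and spaces in
#' labels are normalized, with the applied mapping attached as an attribute).
#' Tips without data are pruned; records without a matching tip are dropped.
#'
#' @param tree A `"phylo"`.
#' @param records A trait table (one row per species; a single caste).
#' @param level `"genus"`: modern tips carry the per-genus mean of
#'   log head width; `"species"`: modern tips carry the value of the single
#'   species matched to the tip's genus (used with subsampled record sets).
#' @return A list of class `"genus_dataset"`: `tree` (pruned), `x` (named
#'   numeric, natural-log head width in ln mm, one per tip), `genus_species`
#'   (per-genus species lists), `status` (per-tip `"modern"`/`"fossil"`),
#'   `dropped_tips`, `dropped_records`.
#' @export
match_tree_and_traits <- function(tree, records, level = c("genus", "species")) {
  level <- match.arg(level)
  validate_phylo(tree)
  stopifnot(is.data.frame(records))
  if (any(records$head_width_mm <= 0, na.rm = TRUE))
    stop("head_width_mm must be positive")
  records <- records[!is.na(records$head_width_mm), , drop = FALSE]

  rec_species <- .normalize_label(records$species)
  rec_genus <- records$genus
  is_fossil_rec <- records$status == "fossil"

  tip_norm <- .normalize_label(tree$tip.label)
  tip_genus <- .genus_token(tree$tip.label)

  x <- rep(NA_real_, length(tip_norm))
  status <- rep(NA_character_, length(tip_norm))
  genus_species <- list()
  for (i in seq_along(tip_norm)) {
    hit <- which(is_fossil_rec & rec_species == tip_norm[i])
    if (length(hit) >= 1L) {
      x[i] <- mean(log(records$head_width_mm[hit]))
      status[i] <- "fossil"
      next
    }
    hit <- which(!is_fossil_rec & rec_genus == tip_genus[i])
    if (length(hit) == 0L) next
    status[i] <- "modern"
    vals <- log(records$head_width_mm[hit])
    x[i] <- if (level == "genus") mean(vals) else {
      if (length(hit) > 1L)
        stop("level = \"species\" but genus ", tip_genus[i],
             " has ", length(hit), " records; subsample first")
      vals
    }
    genus_species[[tip_genus[i]]] <- records$species[hit]
  }

  keep <- which(!is.na(x))
  if (length(keep) < 2L)
    stop("fewer than 2 tips match between tree and trait records")
  dropped_tips <- tree$tip.label[-keep]
  pruned <- if (length(dropped_tips)) ape::drop.tip(tree, dropped_tips) else tree
  # realign to pruned tip order
  idx <- match(.normalize_label(pruned$tip.label), tip_norm[keep])
  xx <- x[keep][idx]
  names(xx) <- pruned$tip.label
  matched_rec <- ifelse(is_fossil_rec,
                        rec_species %in% tip_norm[keep],
                        rec_genus %in% tip_genus[keep])
  out <- list(tree = pruned, x = xx,
              genus_species = genus_species,
              status = stats::setNames(status[keep][idx], pruned$tip.label),
              dropped_tips = dropped_tips,
              dropped_records = records$species[!matched_rec])
  class(out) <- "genus_dataset"
  out
}

#' @export
print.genus_dataset <- function(x, ...) {
  cat("Matched phylogenetic trait dataset:", length(x$x), "tips (",
      sum(x$status == "modern"), "modern,", sum(x$status == "fossil"),
      "fossil );", length(x$dropped_tips), "tips pruned\n")
  invisible(x)
}

#' Subsample one species per modern genus
#'
#' Draws, uniformly at random, one measured species per modern genus; fossil
#' records are always carried through unchanged. Deterministic for a fixed
#' seed. Genera whose every record lacks a measurement are dropped with a
#' warning.
#'
#' @param records A trait table (one row per species).
#' @param seed Integer seed (mandatory, for reproducible replication).
#' @return A subset of `records` with one row per modern genus plus all
#'   fossil rows.
#' @export
subsample_one_per_genus <- function(records, seed) {
  stopifnot(is.data.frame(records), !missing(seed))
  measured <- !is.na(records$head_width_mm)
  fossil <- records$status == "fossil"
  modern <- records[!fossil, , drop = FALSE]
  empty <- setdiff(unique(modern$genus), unique(modern$genus[measured[!fossil]]))
  if (length(empty))
    warning("genus with zero measured species dropped: ",
            paste(empty, collapse = ", "))
  modern <- modern[measured[!fossil], , drop = FALSE]
  withr_seed <- .with_seed(seed, {
    picks <- vapply(split(seq_len(nrow(modern)), modern$genus),
                    function(ix) if (length(ix) == 1L) ix else sample(ix, 1L),
                    integer(1))
    picks
  })
  rbind(modern[sort(withr_seed), , drop = FALSE],
        records[fossil & measured, , drop = FALSE])
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Phylogenetic covariance matrix
#'
#' Returns the matrix `C` whose entry (i, j) is the total branch length
#' shared by the root-to-tip paths of tips i and j; the diagonal holds tip
#' depths. This is the Brownian-motion covariance structure up to the rate
#' parameter. The tree need not be ultrametric.
#'
#' @param tree A `"phylo"`.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  C <- ape::vcv.phylo(tree)
  C <- (C + t(C)) / 2
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(diag(C)))
    stop("phylogenetic covariance is not positive semi-definite ",
         "(smallest eigenvalue ", format(ev_min), ")")
  C
}
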