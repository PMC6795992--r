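#' Read a posterior sample of rooted trees
#'
#' Reads a multi-tree newick file (one tree per line) or a NEXUS file with an
#' optional `translate` block (e.g. BEAST output), strips square-bracket
#' annotations, discards a burn-in fraction, and validates the set: every tree
#' must carry branch lengths in substitutions/site and all trees must share
#' one tip-label set.
#'
#' @param path Path to the tree file.
#' @param format `"newick"` (default; one tree per line) or `"nexus"`.
#' @param burn_in_fraction Proportion in `[0, 1)` of initial trees to discard
#'   (`floor(burn_in_fraction * N)` trees). Default 0.1, the conventional
#'   Bayesian MCMC burn-in.
#' @return A `posterior_trees` object: a list with elements `trees` (a
#'   `multiPhylo` of the retained trees), `burn_in_fraction`, `n_total`, and
#'   `source_path`.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines(rep("((A:0.1,B:0.1):0.05,C:0.15);", 10), tf)
#' ts <- read_trees(tf, burn_in_fraction = 0.1)
#' n_trees(ts)
#' @export
read_trees <- function(path, format = c("newick", "nexus"),
                       burn_in_fraction = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    abort("`burn_in_fraction` must be in [0, 1)")
  }
  txt <- readLines(path, warn = FALSE)
  # BEAST-style [&...] comments are irrelevant to topology and heights
  txt <- gsub("\\[[^]]*\\]", "", txt)
  if (format == "newick") {
    txt <- txt[grepl(";", txt, fixed = TRUE)]
    trees <- ape::read.tree(text = txt)
  } else {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(txt, tf)
    trees <- ape::read.nexus(tf)
  }
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (is.null(trees) || length(trees) == 0L) {
    abort(paste0("no trees parsed from ", path))
  }
  class(trees) <- "multiPhylo"
  new_posterior_trees(trees, burn_in_fraction = burn_in_fraction,
                      source_path = path)
}

#' Construct a posterior tree set from trees already in memory
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees.
#' @param burn_in_fraction Proportion of initial trees to discard.
#' @param source_path Provenance string stored on the object.
#' @return A `posterior_trees` object.
#' @export
as_posterior_trees <- function(trees, burn_in_fraction = 0,
                               source_path = "<in-memory>") {
  if (inherits(trees, "posterior_trees")) return(trees)
  if (inherits(trees, "phylo")) trees <- c(trees)
  class(trees) <- "multiPhylo"
  new_posterior_trees(trees, burn_in_fraction, source_path)
}

new_posterior_trees <- function(trees, burn_in_fraction, source_path) {
  n_total <- length(trees)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (is.null(tr$edge.length) || any(!is.finite(tr$edge.length))) {
      abort(paste0("tree ", i, " has missing or non-finite branch lengths"))
    }
    if (any(tr$edge.length < 0)) {
      abort(paste0("tree ", i, " has negative branch lengths"))
    }
    trees[[i]]$tip.label <- normalise_label(tr$tip.label)
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      abort(paste0("tip label set of tree ", i,
                   " differs from tree 1: posterior trees must share taxa"))
    }
  }
  drop <- floor(burn_in_fraction * n_total)
  if (n_total - drop < 2L) {
    abort(paste0("fewer than 2 trees remain after burn-in (", n_total, " read, ",
                 drop, " discarded)"))
  }
  kept <- trees[(drop + 1L):n_total]
  class(kept) <- "multiPhylo"
  structure(
    list(trees = kept, burn_in_fraction = burn_in_fraction,
         n_total = n_total, source_path = source_path),
    class = "posterior_trees"
  )
}

#' Number of retained (post burn-in) trees
#' @param x A `posterior_trees` object.
#' @return Integer count.
#' @export
n_trees <- function(x) {
  stopifnot(inherits(x, "posterior_trees"))
  length(x$trees)
}

#' @export
print.posterior_trees <- function(x, ...) {
  cat("Posterior tree set:", n_trees(x), "trees retained of", x$n_total,
      sprintf("(burn-in %.0f%%)\n", 100 * x$burn_in_fraction))
  cat("  tips:", length(x$trees[[1]]$tip.label), " source:", x$source_path, "\n")
  invisible(x)
}

#' Write a posterior tree set as plain newick
#'
#' One tree per line; used for round-tripping simulated sets.
#'
#' @param x A `posterior_trees` object.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths (default 15, enough to
#'   round-trip heights well below the ultrametricity tolerance).
#' @return `path`, invisibly.
#' @export
write_trees <- function(x, path, digits = 15) {
  stopifnot(inherits(x, "posterior_trees"))
  ape::write.tree(x$trees, file = path, digits = digits)
  invisible(path)
}

#' Node height in substitutions per site
#'
#' The height of a node is the mean, over its descendant tips, of the summed
#' branch lengths from the node to each tip. For an ultrametric tree all
#' root-to-tip paths agree and the mean is exact; beyond a spread tolerance a
#' warning is raised (strict-clock trees should be ultrametric up to numeric
#' noise). Tips have height 0.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param node Node number (ape numbering: tips `1..Ntip`, internals above).
#' @param tol Maximum tolerated max-minus-min root-to-tip path spread before a
#'   warning (default `1e-6`).
#' @return Height in substitutions/site (non-negative scalar).
#' @export
node_height <- function(tree, node, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (node < 1 || node > ntip + tree$Nnode) abort("`node` is not in the tree")
  if (node <= ntip) return(0)
  depths <- ape::node.depth.edgelength(tree)
  tips <- phangorn::Descendants(tree, node, type = "tips")[[1]]
  paths <- depths[tips] - depths[node]
  if (diff(range(paths)) > tol) {
    warn(sprintf(
      "node %d: root-to-tip path spread %.3g exceeds tolerance %.3g; using mean",
      node, diff(range(paths)), tol))
  }
  mean(paths)
}

#' Most recent common ancestor of a taxon set
#'
#' @param tree A `phylo` tree.
#' @param taxa Character vector of tip labels (at least 2), or a
#'   semicolon-separated string.
#' @return The MRCA node number.
#' @export
find_mrca <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- as_taxa(taxa)
  if (length(taxa) < 2L) abort("`taxa` must contain at least two labels")
  labels <- normalise_label(tree$tip.label)
  missing <- setdiff(taxa, labels)
  if (length(missing) > 0L) {
    abort(paste0("taxa not found in tree: ", paste(missing, collapse = ", ")))
  }
  ape::getMRCA(tree, match(taxa, labels))
}

#' Is a taxon set monophyletic?
#'
#' TRUE iff the descendant tip set of the taxa's MRCA equals the taxa exactly.
#'
#' @inheritParams find_mrca
#' @return Logical flag.
#' @export
is_clade_monophyletic <- function(tree, taxa) {
  taxa <- as_taxa(taxa)
  node <- find_mrca(tree, taxa)
  tips <- phangorn::Descendants(tree, node, type = "tips")[[1]]
  setequal(normalise_label(tree$tip.label)[tips], taxa)
}
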