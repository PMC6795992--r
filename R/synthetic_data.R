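#' Specify a synthetic posterior-tree simulation
#'
#' The simulator inverts the power-law clock: given a dated host topology
#' (an ultrametric tree with node times in Myr) and true clock parameters
#' `(alpha, beta)`, each internal node's true height in substitutions/site is
#' `s = exp((log t - alpha) / beta)` (natural log, t in Myr). Each simulated
#' posterior tree perturbs every internal-node height by multiplicative
#' lognormal noise with log-sd `sigma` and rebuilds ultrametric branch
#' lengths, emulating the scatter of a Bayesian posterior sample.
#'
#' @param host_tree An ultrametric `phylo` tree (branch lengths in Myr) or a
#'   newick string of one.
#' @param alpha,beta True clock parameters in natural-log space.
#' @param sigma Lognormal log-sd of the multiplicative node-height noise
#'   (>= 0).
#' @param n_trees Number of posterior trees to simulate (>= 2).
#' @param height_multipliers Optional named numeric vector of extra
#'   multiplicative offsets applied to the true heights before the per-tree
#'   noise, keyed by internal node number. Used to displace the centre of the
#'   simulated posterior away from the truth, emulating the estimation error
#'   of a real analysis (see the coverage experiment).
#' @return A `sim_spec` list, validated.
#' @export
sim_spec <- function(host_tree, alpha, beta, sigma = 0.1, n_trees = 500,
                     height_multipliers = NULL) {
  if (is.character(host_tree)) host_tree <- ape::read.tree(text = host_tree)
  stopifnot(inherits(host_tree, "phylo"))
  if (is.null(host_tree$edge.length)) abort("host tree must have branch lengths")
  if (!ape::is.ultrametric(host_tree, tol = 1e-6)) {
    abort("host tree must be ultrametric (node times in Myr)")
  }
  if (sigma < 0) abort("`sigma` must be >= 0")
  if (n_trees < 2) abort("`n_trees` must be >= 2")
  times <- node_times(host_tree)
  if (any(times[-seq_len(length(host_tree$tip.label))] <= 0)) {
    abort("internal node times must be positive")
  }
  s_true <- tdrp_height(alpha, beta, pmax(times, .Machine$double.xmin))
  s_true[times == 0] <- 0
  if (any(!is.finite(s_true))) {
    abort("alpha/beta produce non-finite heights for this tree")
  }
  structure(
    list(host_tree = host_tree, alpha = alpha, beta = beta, sigma = sigma,
         n_trees = n_trees, times = times, s_true = s_true,
         height_multipliers = height_multipliers),
    class = "sim_spec"
  )
}

# Node times (Myr before present) for every node of an ultrametric tree,
# indexed by ape node number.
node_times <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Demonstration simulation specification
#'
#' A foamy-virus-like study geometry: 11 host tips covering simian foamy
#' viruses of apes (chimpanzee, gorilla, orangutan), Old World monkeys
#' (macaques, grivet, North/South mandrill populations) and a fereungulate
#' outgroup (bovine, equine, feline FVs). Node times place the
#' mandrill North-South split at 1.1 Myr, the macaque split at 5.3 Myr, the
#' chimpanzee-gorilla split at 8.6 Myr, the basal OWMA SFV diversification at
#' 30 Myr and the simian-fereungulate separation at 100 Myr. Clock truth is
#' `alpha = 4.114`, `beta = 1.762` (natural log, Myr), realistic published
#' magnitudes for this system (about 1.32 substitutions/site per lineage at
#' 100 Myr).
#'
#' @param n_trees Number of posterior trees (default 500).
#' @param sigma Node-height noise log-sd (default 0.1).
#' @return A `sim_spec` object.
#' @export
demo_sim_spec <- function(n_trees = 500, sigma = 0.1) {
  nwk <- paste0(
    "((FFV:60,(BFV:30,EFV:30):30):40,",
    "((SFVppy:15,(SFVptr:8.6,SFVggo:8.6):6.4):15,",
    "(SFVcae:20,((SFVmcy:5.3,SFVmmu:5.3):6.7,",
    "(SFVmspN:1.1,SFVmspS:1.1):10.9):8):10):70);"
  )
  sim_spec(nwk, alpha = 4.114, beta = 1.762, sigma = sigma, n_trees = n_trees)
}

#' Simulate a posterior sample of clock trees with known truth
#'
#' For each of `n_trees` draws, every internal node height is its true height
#' times an independent lognormal factor `exp(N(0, sigma^2))`; draws that
#' would put a child above its parent are redrawn. Branch lengths are rebuilt
#' so each tree is ultrametric with consistent heights (tips at height 0).
#'
#' @param spec A [sim_spec()] object.
#' @param seed Optional integer seed; the output is a pure function of
#'   (spec, seed).
#' @return A list of class `sim_posterior`: `trees` (a `posterior_trees`
#'   object, burn-in 0) and `truth` (tibble with one row per internal node:
#'   `node`, `time` in Myr, `height` in substitutions/site, and the tip set
#'   defining the clade), plus `alpha`, `beta`, `sigma`.
#' @export
simulate_posterior_trees <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  tree <- spec$host_tree
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  internal <- ntip + seq_len(nnode)
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]

  mult <- rep(1, ntip + nnode)
  if (!is.null(spec$height_multipliers)) {
    idx <- as.integer(names(spec$height_multipliers))
    mult[idx] <- spec$height_multipliers
  }
  centre <- spec$s_true * mult

  # internal edges only: height ordering must be enforced among internals
  int_edge <- child > ntip
  trees <- vector("list", spec$n_trees)
  for (k in seq_len(spec$n_trees)) {
    # rejection sampling of the joint noise vector: any draw that puts a
    # child at or above its parent is discarded and redrawn as a block
    h <- numeric(ntip + nnode)
    guard <- 0L
    repeat {
      h[internal] <- centre[internal] * exp(rnorm(nnode, 0, spec$sigma))
      if (spec$sigma == 0 || all(h[child[int_edge]] < h[parent[int_edge]])) break
      guard <- guard + 1L
      if (guard > 10000L) abort("could not enforce child < parent heights")
    }
    if (any(h[child[int_edge]] >= h[parent[int_edge]])) {
      abort("height ordering violated: centre heights are not monotone")
    }
    tr <- tree
    tr$edge.length <- h[parent] - h[child]
    trees[[k]] <- tr
  }
  class(trees) <- "multiPhylo"

  tipsets <- phangorn::Descendants(tree, internal, type = "tips")
  truth <- tibble(
    node = internal,
    time = spec$times[internal],
    height = spec$s_true[internal],
    taxa = lapply(tipsets, function(i) sort(normalise_label(tree$tip.label[i])))
  )
  structure(
    list(trees = as_posterior_trees(trees, source_path = "<simulated>"),
         truth = truth, alpha = spec$alpha, beta = spec$beta,
         sigma = spec$sigma),
    class = "sim_posterior"
  )
}

#' True age of a clade in a simulation
#'
#' Looks up the simulated truth table by taxon set.
#'
#' @param sim A `sim_posterior` object.
#' @param taxa Character vector of tip labels (or semicolon-separated string).
#' @return True node time in Myr.
#' @export
true_clade_time <- function(sim, taxa) {
  taxa <- sort(as_taxa(taxa))
  hit <- which(vapply(sim$truth$taxa, identical, TRUE, y = taxa))
  if (length(hit) != 1L) abort("no internal node matches this taxon set")
  sim$truth$time[hit]
}

#' Simulate a region-structured alignment
#'
#' Each region evolves independently down its own tree under the simplest
#' one-parameter equal-rates substitution model (JC69, equal base
#' frequencies), then the regions are concatenated in coordinate order.
#' Hotspot segments are filled with unstructured i.i.d. uniform-ACGT columns
#' (their content only needs to occupy the coordinates). The true region
#' boundaries are recorded.
#'
#' @param layout Tibble describing the column layout in order: columns
#'   `name`, `length`, `type` (`"region"` or `"hotspot"`).
#' @param trees Named list of `phylo` trees, one per `"region"` row (branch
#'   lengths in expected substitutions/site); all trees must share a tip set.
#' @param total_length Optional check: error if `sum(layout$length)` differs.
#' @param seed Optional integer seed.
#' @return A list: `alignment` (tibble `id`, `seq`) and `regions` (tibble
#'   `name`, `start`, `end`, `type`).
#' @export
simulate_region_alignment <- function(layout, trees, total_length = NULL,
                                      seed = NULL) {
  req <- c("name", "length", "type")
  if (!all(req %in% names(layout))) {
    abort("`layout` must have columns `name`, `length`, `type`")
  }
  if (any(layout$length < 1)) abort("region lengths must be positive")
  if (!is.null(total_length) && sum(layout$length) != total_length) {
    abort(sprintf("layout lengths sum to %d, not the declared total %d",
                  sum(layout$length), total_length))
  }
  rg <- layout$name[layout$type == "region"]
  miss <- setdiff(rg, names(trees))
  if (length(miss) > 0L) {
    abort(paste0("no tree supplied for region(s): ", paste(miss, collapse = ", ")))
  }
  tipsets <- lapply(trees[rg], function(tr) sort(tr$tip.label))
  if (length(unique(tipsets)) > 1L) abort("all region trees must share a tip set")
  tips <- tipsets[[1]]
  if (!is.null(seed)) set.seed(seed)

  pieces <- vector("list", nrow(layout))
  for (k in seq_len(nrow(layout))) {
    l <- layout$length[k]
    if (layout$type[k] == "region") {
      tr <- trees[[layout$name[k]]]
      sim <- phangorn::simSeq(tr, l = l, type = "DNA")
      m <- toupper(as.character(sim))
      m <- m[match(tips, rownames(m)), , drop = FALSE]
      pieces[[k]] <- apply(m, 1, paste0, collapse = "")
    } else {
      m <- matrix(sample(c("A", "C", "G", "T"), l * length(tips),
                         replace = TRUE), nrow = length(tips))
      pieces[[k]] <- setNames(apply(m, 1, paste0, collapse = ""), tips)
    }
  }
  seqs <- do.call(paste0, pieces)
  ends <- cumsum(layout$length)
  list(
    alignment = tibble(id = tips, seq = seqs),
    regions = tibble(name = layout$name,
                     start = ends - layout$length + 1L, end = ends,
                     type = layout$type)
  )
}

#' Simulate a per-sample site-rate matrix with region structure
#'
#' Per sample and column, rates are lognormal around the column's region mean
#' (mean-corrected so the expectation equals the region mean), then each
#' sample is scaled to global mean 1 with [scale_rates()]. The truth records
#' both the configured and the scaled region means.
#'
#' @param regions Tibble: `name`, `start`, `end`, `true_mean` (> 0); the
#'   intervals must tile `1..L` in order.
#' @param n_samples Number of posterior samples (>= 1).
#' @param noise_sd Lognormal log-sd of the per-column noise (>= 0).
#' @param seed Optional integer seed.
#' @return A list: `rates` (tibble `sample`, `site`, `rate`) and `truth`
#'   (the regions tibble with `scaled_true_mean` added).
#' @export
simulate_rate_matrix <- function(regions, n_samples = 100, noise_sd = 0.3,
                                 seed = NULL) {
  req <- c("name", "start", "end", "true_mean")
  if (!all(req %in% names(regions))) {
    abort("`regions` must have columns `name`, `start`, `end`, `true_mean`")
  }
  if (any(regions$true_mean <= 0)) abort("`true_mean` must be positive")
  if (!is.null(seed)) set.seed(seed)
  L <- max(regions$end)
  site_mean <- numeric(L)
  for (k in seq_len(nrow(regions))) {
    site_mean[regions$start[k]:regions$end[k]] <- regions$true_mean[k]
  }
  rates <- tidyr::expand_grid(sample = seq_len(n_samples), site = seq_len(L)) |>
    mutate(rate = site_mean[.data$site] *
             exp(rnorm(dplyr::n(), 0, noise_sd) - noise_sd^2 / 2)) |>
    scale_rates()
  lens <- regions$end - regions$start + 1
  truth <- mutate(as_tibble(regions),
                  scaled_true_mean = .data$true_mean /
                    sum(.data$true_mean * lens / sum(lens)))
  list(rates = rates, truth = truth)
}

#' Coverage experiment for the dating pipeline
#'
#' Repeatedly simulates a full study and checks whether the 95% HPD interval
#' for a target clade covers its true age. Each replicate emulates one
#' realisation of a calibrated Bayesian analysis: (a) the true calibration
#' dates are drawn from the calibration-table distributions while the dating
#' step keeps using the published medians and sds, and (b) the centre of the
#' simulated posterior is displaced from the true heights by one lognormal
#' factor per node with the same log-sd as the within-posterior scatter
#' (flat-prior self-consistency: estimate error and posterior spread match).
#' Without (a) and (b), every source of noise would be averaged out across
#' posterior trees and the pooled interval would cover the truth essentially
#' always, telling us nothing about calibration.
#'
#' @param spec A [sim_spec()] object defining the true study geometry.
#' @param calib Calibration table whose clades exist in `spec`'s host tree;
#'   its node times are re-drawn per replicate from the date distributions.
#' @param target One-row target table ([target_table()]).
#' @param n_replicates Number of replicate studies (default 200).
#' @param seed Integer seed for the whole experiment.
#' @return Tibble with one row per replicate: `replicate`, `truth`, `median`,
#'   `hpd_lower`, `hpd_upper`, `covered`; the observed coverage is
#'   `mean(covered)`.
#' @export
run_coverage_experiment <- function(spec, calib, target, n_replicates = 200,
                                    seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  calib <- make_date_distribution(calib)
  target <- target_table(target)
  if (nrow(target) != 1L) abort("`target` must contain exactly one clade")
  if (!is.null(seed)) set.seed(seed)

  tree <- spec$host_tree
  ntip <- length(tree$tip.label)
  internal <- ntip + seq_len(tree$Nnode)
  calib_nodes <- vapply(calib$taxa, function(tx) find_mrca(tree, tx), 0L)
  target_node <- find_mrca(tree, target$taxa[[1]])
  truth_t <- spec$times[target_node]
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]

  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    # (a) truth-side calibration dates drawn from the date distributions,
    #     kept consistent with the tree's temporal ordering
    times_r <- spec$times
    for (j in seq_along(calib_nodes)) {
      nd <- calib_nodes[j]
      p <- parent_of(nd)
      upper <- if (length(p) == 1L) times_r[p] else Inf
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      lower <- max(c(0, times_r[kids][kids > ntip], 0))
      guard <- 0L
      repeat {
        d <- rtrunc_norm_pos(1, calib$mean[j], calib$sd[j])
        if (d > lower && d < upper) break
        guard <- guard + 1L
        if (guard > 10000L) abort("calibration date draw violates tree ordering")
      }
      times_r[nd] <- d
    }
    s_r <- tdrp_height(spec$alpha, spec$beta, pmax(times_r, .Machine$double.xmin))
    s_r[times_r == 0] <- 0
    # (b) posterior-centre displacement, one lognormal factor per node;
    # redrawn as a block until the displaced centres keep child < parent
    # (heights on an ultrametric tree must be monotone along every path)
    parent <- tree$edge[, 1]
    child <- tree$edge[, 2]
    int_edge <- child > ntip
    guard <- 0L
    repeat {
      displacement <- setNames(exp(rnorm(length(internal), 0, spec$sigma)),
                               internal)
      centre <- s_r
      centre[internal] <- centre[internal] * displacement
      if (all(centre[child[int_edge]] < centre[parent[int_edge]])) break
      guard <- guard + 1L
      if (guard > 10000L) abort("could not draw an order-consistent displacement")
    }
    spec_r <- spec
    spec_r$times <- times_r
    spec_r$s_true <- s_r
    spec_r$height_multipliers <- displacement
    sim <- simulate_posterior_trees(spec_r)
    fit <- suppressWarnings(run_dating(sim$trees, calib, target))
    est <- tidy(fit)
    out[[r]] <- tibble(
      replicate = r, truth = truth_t, median = est$median,
      hpd_lower = est$hpd_lower, hpd_upper = est$hpd_upper,
      covered = truth_t >= est$hpd_lower & truth_t <= est$hpd_upper
    )
  }
  bind_rows(out)
}
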