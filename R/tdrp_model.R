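# Log/antilog helpers for the configured log space. beta is base-invariant;
# alpha transforms by the factor log_b(e), so reported alpha values depend on
# the base while predicted times do not.
log_fun <- function(log_base) {
  switch(log_base, natural = log, base10 = log10,
         abort("`log_base` must be \"natural\" or \"base10\""))
}
exp_fun <- function(log_base) {
  switch(log_base, natural = exp, base10 = function(x) 10^x,
         abort("`log_base` must be \"natural\" or \"base10\""))
}

# Closed-form unweighted OLS on already-log-transformed points.
ols_fit <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  beta <- sum((x - xb) * (y - yb)) / sxx
  c(alpha = yb - beta * xb, beta = beta)
}

#' Fit the power-law clock to calibration points
#'
#' Ordinary unweighted least squares of `log t` on `log s` for the
#' time-dependent rate phenomenon (TDRP) clock `log t = alpha + beta log s`,
#' where `s` is node height in substitutions/site and `t` the node age in
#' million years. With exactly two points the fit interpolates them exactly.
#'
#' @param points Data frame with columns `s` (> 0, at least two distinct
#'   values) and `t` (> 0).
#' @param log_base Log space for reporting `alpha`: `"natural"` (default) or
#'   `"base10"`. Predictions are identical in either space.
#' @return One-row tibble with `alpha`, `beta`, `log_base`, `n_points`.
#' @examples
#' pts <- data.frame(s = c(1, exp(1)), t = c(exp(2), exp(3.5)))
#' fit_tdrp_draw(pts) # alpha = 2, beta = 1.5
#' @export
fit_tdrp_draw <- function(points, log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  if (!all(c("s", "t") %in% names(points))) {
    abort("`points` must have columns `s` and `t`")
  }
  s <- points$s
  t <- points$t
  if (length(s) < 2L) abort("at least 2 calibration points are required")
  if (any(!is.finite(s)) || any(!is.finite(t)) || any(s <= 0) || any(t <= 0)) {
    abort("calibration points must have finite, positive `s` and `t`")
  }
  if (length(unique(s)) < 2L) {
    abort("singular fit: all calibration `s` values are equal")
  }
  lg <- log_fun(log_base)
  est <- ols_fit(lg(s), lg(t))
  tibble(alpha = est[["alpha"]], beta = est[["beta"]],
         log_base = log_base, n_points = length(s))
}

#' Predict node age from node height under the power-law clock
#'
#' `t = exp_b(alpha + beta * log_b(s))`; strictly increasing in `s` for
#' `beta > 0`.
#'
#' @param alpha Intercept in the configured log space.
#' @param beta Slope (base-invariant).
#' @param s Node height(s) in substitutions/site; must be positive.
#' @param log_base Log space matching `alpha`; see [fit_tdrp_draw()].
#' @return Predicted age(s) in Myr.
#' @examples
#' predict_time(log(2), 1, 3) # 6
#' @export
predict_time <- function(alpha, beta, s, log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  if (any(!is.finite(s)) || any(s <= 0)) abort("`s` must be positive and finite")
  exp_fun(log_base)(alpha + beta * log_fun(log_base)(s))
}

#' Invert the power-law clock: node height expected at a given age
#'
#' The inverse of [predict_time()]: `s = exp_b((log_b(t) - alpha) / beta)`.
#' Used to construct noiseless calibration points and simulated tree heights.
#'
#' @inheritParams predict_time
#' @param t Age(s) in Myr; must be positive.
#' @return Node height(s) in substitutions/site.
#' @export
tdrp_height <- function(alpha, beta, t, log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  if (any(!is.finite(t)) || any(t <= 0)) abort("`t` must be positive and finite")
  if (beta == 0) abort("`beta` = 0 cannot be inverted")
  exp_fun(log_base)((log_fun(log_base)(t) - alpha) / beta)
}

# Resolve MRCA node numbers and descendant-tip index lists for a list of
# taxon sets on one tree. Returns list(nodes=..., tips=list of integer vecs).
resolve_clades <- function(tree, taxa_list) {
  labels <- normalise_label(tree$tip.label)
  nodes <- integer(length(taxa_list))
  for (j in seq_along(taxa_list)) {
    taxa <- taxa_list[[j]]
    missing <- setdiff(taxa, labels)
    if (length(missing) > 0L) {
      abort(paste0("taxa not found in tree: ", paste(missing, collapse = ", ")))
    }
    nodes[j] <- ape::getMRCA(tree, match(taxa, labels))
  }
  tips <- phangorn::Descendants(tree, nodes, type = "tips")
  list(nodes = nodes, tips = tips)
}

#' Date target clades across a posterior tree sample
#'
#' For each post-burn-in tree: extract the height `s` of every calibration
#' clade (MRCA height), pair each with one fresh host-date draw `t`, fit the
#' power-law clock by OLS in log space, and predict the age of every target
#' clade from its height in that same tree. Per-target ages are pooled across
#' trees and summarised by the median and 95% HPD interval, so host-date and
#' phylogenetic uncertainty propagate jointly.
#'
#' Trees in which any calibration or target clade has zero height are skipped
#' with a warning; if more than `max_skip_frac` of trees are skipped the run
#' aborts. Monophyly of each named clade is recorded per tree as a diagnostic
#' but the MRCA is used regardless.
#'
#' @param trees A `posterior_trees` object (or `multiPhylo`/list of `phylo`,
#'   coerced with no additional burn-in).
#' @param calib Calibration table ([calibration_table()]).
#' @param targets Target-clade table ([target_table()]).
#' @param seed Optional integer seed governing the host-date draws.
#' @param log_base Log space for `alpha`; see [fit_tdrp_draw()].
#' @param mass HPD mass (default 0.95).
#' @param max_skip_frac Abort if more than this fraction of trees is skipped
#'   (default 0.2).
#' @return A `tdrp_fit` object with elements `draws` (tibble: `tree`, `alpha`,
#'   `beta`), `target_draws` (tibble: `tree`, `clade`, `t`), `estimates`
#'   (tibble: `clade`, `median`, `hpd_lower`, `hpd_upper`, `n_draws`),
#'   `monophyly` (diagnostic tibble), plus metadata. Use [tidy()], [glance()],
#'   [tdrp_report()] and [autoplot()] on it.
#' @export
run_dating <- function(trees, calib, targets, seed = NULL,
                       log_base = c("natural", "base10"),
                       mass = 0.95, max_skip_frac = 0.2) {
  log_base <- match.arg(log_base)
  trees <- as_posterior_trees(trees)
  calib <- make_date_distribution(calib)
  targets <- target_table(targets)
  if (nrow(targets) == 0L) abort("at least one target clade is required")
  if (nrow(calib) < 2L) abort("at least 2 calibration points are required")
  if (!is.null(seed)) set.seed(seed)

  nt <- n_trees(trees)
  np <- nrow(calib)
  ntg <- nrow(targets)
  lg <- log_fun(log_base)
  ef <- exp_fun(log_base)

  # one fresh date draw per calibration point per tree, keyed to tree position
  date_draws <- matrix(0, nrow = nt, ncol = np)
  for (j in seq_len(np)) {
    date_draws[, j] <- rtrunc_norm_pos(nt, calib$mean[j], calib$sd[j])
  }

  taxa_all <- c(calib$taxa, targets$taxa)
  clade_names <- c(calib$name, targets$name)

  alpha <- numeric(nt)
  beta <- numeric(nt)
  tdraw <- matrix(NA_real_, nrow = nt, ncol = ntg)
  mono <- matrix(FALSE, nrow = nt, ncol = np + ntg)
  skipped <- logical(nt)

  res <- NULL
  ref_edge <- NULL
  ref_lab <- NULL
  for (i in seq_len(nt)) {
    tr <- trees$trees[[i]]
    # posterior samples usually share a topology; re-resolve only on change
    if (is.null(res) || !identical(tr$edge, ref_edge) ||
        !identical(tr$tip.label, ref_lab)) {
      res <- resolve_clades(tr, taxa_all)
      ref_edge <- tr$edge
      ref_lab <- tr$tip.label
    }
    depths <- ape::node.depth.edgelength(tr)
    h <- vapply(seq_along(res$nodes), function(j) {
      mean(depths[res$tips[[j]]]) - depths[res$nodes[j]]
    }, 0)
    labs <- normalise_label(tr$tip.label)
    mono[i, ] <- vapply(seq_along(res$nodes), function(j) {
      setequal(labs[res$tips[[j]]], taxa_all[[j]])
    }, TRUE)
    if (any(h <= 0)) {
      skipped[i] <- TRUE
      next
    }
    est <- ols_fit(lg(h[seq_len(np)]), lg(date_draws[i, ]))
    alpha[i] <- est[["alpha"]]
    beta[i] <- est[["beta"]]
    tdraw[i, ] <- ef(est[["alpha"]] + est[["beta"]] * lg(h[np + seq_len(ntg)]))
  }

  n_skip <- sum(skipped)
  if (n_skip > 0L) {
    warn(sprintf("%d of %d trees skipped (zero-height clade)", n_skip, nt))
  }
  if (n_skip > max_skip_frac * nt) {
    abort(sprintf("%d of %d trees skipped, exceeding max_skip_frac = %g",
                  n_skip, nt, max_skip_frac))
  }
  keep <- !skipped

  draws <- tibble(tree = which(keep), alpha = alpha[keep], beta = beta[keep])
  target_draws <- tibble(
    tree = rep(which(keep), times = ntg),
    clade = rep(targets$name, each = sum(keep)),
    t = as.vector(tdraw[keep, , drop = FALSE])
  )
  estimates <- target_draws |>
    group_by(.data$clade) |>
    summarise(
      median = stats::median(.data$t),
      hpd_lower = hpd_interval(.data$t, mass)[["lower"]],
      hpd_upper = hpd_interval(.data$t, mass)[["upper"]],
      n_draws = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(match(.data$clade, targets$name))

  monophyly <- tibble(
    clade = clade_names,
    role = rep(c("calibration", "target"), c(np, ntg)),
    prop_monophyletic = colMeans(mono[keep, , drop = FALSE])
  )

  structure(
    list(draws = draws, target_draws = target_draws, estimates = estimates,
         monophyly = monophyly, calibration = calib, targets = targets,
         log_base = log_base, mass = mass, time_unit = "Myr",
         n_trees = nt, n_skipped = n_skip),
    class = "tdrp_fit"
  )
}

#' @export
print.tdrp_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Power-law TDRP clock fit over %d posterior trees (%d skipped)\n",
    x$n_trees, x$n_skipped))
  cat(sprintf("  alpha = %.3f (95%% HPD = %.3f-%.3f), beta = %.3f (95%% HPD = %.3f-%.3f)\n",
              g$alpha, g$alpha_hpd_lower, g$alpha_hpd_upper,
              g$beta, g$beta_hpd_lower, g$beta_hpd_upper))
  cat(sprintf("  log space: %s; time unit: %s\n", x$log_base, x$time_unit))
  print(tidy(x))
  invisible(x)
}

#' Tidy per-clade time estimates from a TDRP fit
#'
#' @param x A `tdrp_fit` object.
#' @param ... Unused.
#' @return Tibble: `clade`, `median`, `hpd_lower`, `hpd_upper` (Myr),
#'   `n_draws`.
#' @export
tidy.tdrp_fit <- function(x, ...) {
  x$estimates
}

#' One-row model-level summary of a TDRP fit
#'
#' @param x A `tdrp_fit` object.
#' @param ... Unused.
#' @return One-row tibble with medians and HPD bounds for `alpha` and `beta`,
#'   tree counts, and the log space.
#' @export
glance.tdrp_fit <- function(x, ...) {
  ah <- hpd_interval(x$draws$alpha, x$mass)
  bh <- hpd_interval(x$draws$beta, x$mass)
  tibble(
    alpha = stats::median(x$draws$alpha),
    alpha_hpd_lower = ah[["lower"]], alpha_hpd_upper = ah[["upper"]],
    beta = stats::median(x$draws$beta),
    beta_hpd_lower = bh[["lower"]], beta_hpd_upper = bh[["upper"]],
    n_trees = x$n_trees, n_skipped = x$n_skipped, log_base = x$log_base
  )
}

#' Report table of dated clades
#'
#' One row per target clade with the median and 95% HPD bounds in Myr; the
#' fitted clock parameters are attached as the `"model"` attribute and shown
#' by the printing method of the fit.
#'
#' @param fit A `tdrp_fit` object.
#' @return Tibble with columns `clade`, `median`, `hpd_lower`, `hpd_upper`.
#' @export
tdrp_report <- function(fit) {
  stopifnot(inherits(fit, "tdrp_fit"))
  est <- tidy(fit)
  if (nrow(est) == 0L) abort("fit contains no target estimates")
  out <- est[, c("clade", "median", "hpd_lower", "hpd_upper")]
  attr(out, "model") <- glance(fit)
  out
}

#' Plot pooled age distributions from a TDRP fit
#'
#' Density of the pooled per-tree age draws for each target clade, with the
#' median (solid) and 95% HPD bounds (dashed) marked.
#'
#' @param object A `tdrp_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tdrp_fit <- function(object, ...) {
  est <- tidy(object)
  ggplot2::ggplot(object$target_draws, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(data = est, ggplot2::aes(xintercept = .data$median)) +
    ggplot2::geom_vline(data = est, ggplot2::aes(xintercept = .data$hpd_lower),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = est, ggplot2::aes(xintercept = .data$hpd_upper),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~clade, scales = "free") +
    ggplot2::labs(x = "age (Myr)", y = "density",
                  title = "Pooled TDRP age estimates") +
    ggplot2::theme_minimal()
}
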