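test_that("the log-log fit recovers exact power-law curves and flat lines", {
  # points on t = e^2 * s^1.5
  s <- c(1, exp(1), exp(2))
  pts <- data.frame(s = s, t = exp(2) * s^1.5)
  fit <- fit_tdrp_draw(pts)
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
  expect_equal(fit$beta, 1.5, tolerance = 1e-10)

  flat <- fit_tdrp_draw(data.frame(s = c(1, 10), t = c(10, 10)))
  expect_equal(flat$beta, 0)
  expect_equal(flat$alpha, log(10))
  flat10 <- fit_tdrp_draw(data.frame(s = c(1, 10), t = c(10, 10)), "base10")
  expect_equal(flat10$alpha, 1)

  expect_error(fit_tdrp_draw(data.frame(s = c(2, 2), t = c(1, 3))), "singular")
  expect_error(fit_tdrp_draw(data.frame(s = c(-1, 2), t = c(1, 3))), "positive")
  expect_error(fit_tdrp_draw(data.frame(s = 1, t = 1)), "at least 2")
})

test_that("the closed-form fit agrees with an independent lm() fit", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(3:12, 1)
    pts <- data.frame(s = exp(rnorm(n)), t = exp(rnorm(n, 2)))
    fit <- fit_tdrp_draw(pts)
    ref <- coef(lm(log(t) ~ log(s), data = pts))
    expect_equal(fit$alpha, unname(ref[1]), tolerance = 1e-10)
    expect_equal(fit$beta, unname(ref[2]), tolerance = 1e-10)
  }
})

test_that("predicted times are base-invariant, unit-covariant and monotone", {
  expect_equal(predict_time(0, 1, 0.5), 0.5)
  expect_equal(predict_time(0, 1, 0.5, "base10"), 0.5)
  expect_equal(predict_time(log(2), 1, 3), 6)
  # plausibility anchor: ~1.32 subs/site per lineage maps to ~100 Myr
  expect_equal(predict_time(4.114, 1.762, 1.321), 99.935, tolerance = 1e-4)
  expect_error(predict_time(1, 1, -2), "positive")

  set.seed(11)
  for (i in 1:10) {
    pts <- data.frame(s = exp(rnorm(4)), t = exp(rnorm(4, 2)))
    s_new <- exp(runif(5, -2, 2))
    f_nat <- fit_tdrp_draw(pts, "natural")
    f_b10 <- fit_tdrp_draw(pts, "base10")
    # log-base invariance of fit-then-predict
    expect_equal(predict_time(f_nat$alpha, f_nat$beta, s_new, "natural"),
                 predict_time(f_b10$alpha, f_b10$beta, s_new, "base10"),
                 tolerance = 1e-9)
    expect_equal(f_b10$beta, f_nat$beta, tolerance = 1e-9)
    expect_equal(f_b10$alpha, f_nat$alpha / log(10), tolerance = 1e-9)
    # time-unit covariance: t -> c*t shifts alpha by log(c), beta unchanged
    c_ <- 3.7
    f_sc <- fit_tdrp_draw(transform(pts, t = c_ * t), "natural")
    expect_equal(f_sc$beta, f_nat$beta, tolerance = 1e-9)
    expect_equal(f_sc$alpha, f_nat$alpha + log(c_), tolerance = 1e-9)
    expect_equal(predict_time(f_sc$alpha, f_sc$beta, s_new),
                 c_ * predict_time(f_nat$alpha, f_nat$beta, s_new),
                 tolerance = 1e-9)
    # monotonicity in s for beta > 0
    if (f_nat$beta > 0) {
      ss <- sort(s_new)
      expect_true(all(diff(predict_time(f_nat$alpha, f_nat$beta, ss)) > 0))
    }
  }
})

test_that("the clock inversion is the exact inverse of prediction", {
  t <- c(0.5, 5.3, 8.6, 100)
  s <- tdrp_height(4.114, 1.762, t)
  expect_equal(predict_time(4.114, 1.762, s), t, tolerance = 1e-12)
  expect_error(tdrp_height(1, 0, 5), "beta")
})

test_that("HPD intervals match brute-force shortest-window enumeration", {
  expect_equal(unname(hpd_interval(rep(3.5, 10))), c(3.5, 3.5))
  expect_equal(unname(hpd_interval(1:100, 0.95)), c(1, 95))
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:200, 1)
    x <- switch(1 + i %% 3,
                rnorm(n), rexp(n), sample(1:20, n, replace = TRUE))
    mass <- sample(c(0.5, 0.8, 0.95), 1)
    expect_equal(unname(hpd_interval(x, mass)), brute_hpd(x, mass))
  }
  z <- rnorm(1e5)
  hpd <- hpd_interval(z, 0.95)
  expect_equal(unname(hpd), c(-1.96, 1.96), tolerance = 0.05 / 1.96)
})

test_that("dating a noiseless posterior recovers truth exactly and deterministically", {
  spec <- demo_sim_spec(n_trees = 20, sigma = 0)
  sim <- simulate_posterior_trees(spec, seed = 1)
  exact_calib <- dplyr::mutate(demo_calibration(), lower = median, upper = median)
  fit <- run_dating(sim$trees, exact_calib, demo_targets(), seed = 2)
  expect_equal(unique(fit$draws$alpha), spec$alpha, tolerance = 1e-12)
  expect_equal(unique(fit$draws$beta), spec$beta, tolerance = 1e-12)
  est <- tidy(fit)
  expect_equal(est$median[est$clade == "mandrill-NS"],
               true_clade_time(sim, "SFVmspN;SFVmspS"), tolerance = 1e-10)
  expect_equal(est$median[est$clade == "OWMA-SFV"], 30, tolerance = 1e-10)
  expect_equal(est$hpd_lower, est$median, tolerance = 1e-10)

  # same seed, same inputs -> identical pooled summaries
  sim2 <- simulate_posterior_trees(demo_sim_spec(n_trees = 20, sigma = 0.05),
                                   seed = 9)
  f1 <- run_dating(sim2$trees, demo_calibration(), demo_targets(), seed = 4)
  f2 <- run_dating(sim2$trees, demo_calibration(), demo_targets(), seed = 4)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(glance(f1), glance(f2))
})

test_that("trees with zero-height calibration clades are skipped, capped at 20%", {
  base <- fixture_tree() # ((A,B),(C,D)), heights 1, 2, 4
  make_set <- function(n_zero, n_total) {
    trees <- lapply(seq_len(n_total), function(i) {
      tr <- base
      if (i <= n_zero) {
        cherry <- which(tr$edge[, 2] %in% 1:2) # zero out the (A,B) cherry
        tr$edge.length[cherry] <- 0
      }
      tr
    })
    class(trees) <- "multiPhylo"
    as_posterior_trees(trees)
  }
  calib <- calibration_table(data.frame(
    name = c("ab", "root"), taxa = c("A;B", "A;B;C;D"),
    median = c(1, 4), lower = c(0.9, 3.5), upper = c(1.1, 4.5)
  ))
  targets <- target_table(data.frame(name = "cd", taxa = "C;D"))

  expect_warning(fit <- run_dating(make_set(1, 10), calib, targets, seed = 1),
                 "skipped")
  expect_equal(fit$n_skipped, 1)
  expect_equal(nrow(fit$draws), 9)

  expect_error(
    suppressWarnings(run_dating(make_set(3, 10), calib, targets, seed = 1)),
    "max_skip_frac")
})

test_that("report and accessor methods expose the fitted clock", {
  sim <- simulate_posterior_trees(demo_sim_spec(n_trees = 30, sigma = 0.05),
                                  seed = 5)
  fit <- run_dating(sim$trees, demo_calibration(), demo_targets(), seed = 6)
  rep_tbl <- tdrp_report(fit)
  expect_named(rep_tbl, c("clade", "median", "hpd_lower", "hpd_upper"))
  expect_equal(nrow(rep_tbl), 2)
  expect_s3_class(attr(rep_tbl, "model"), "tbl_df")
  expect_true(all(rep_tbl$hpd_lower <= rep_tbl$hpd_upper))
  g <- glance(fit)
  expect_true(g$alpha_hpd_lower <= g$alpha & g$alpha <= g$alpha_hpd_upper)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_error(run_dating(sim$trees, demo_calibration(),
                          demo_targets()[0, ], seed = 1),
               "at least one target")
  mono <- fit$monophyly
  expect_true(all(mono$prop_monophyletic == 1)) # fixed topology, true clades
})
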