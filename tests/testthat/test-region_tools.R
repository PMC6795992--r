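test_that("consensus filtering keeps only well-supported events", {
  events <- dplyr::bind_rows(
    tibble::tibble(recombinant = "r1", start = 640, end = 1400,
                   programme = paste0("prog", 1:7), p_value = 0.01),
    tibble::tibble(recombinant = "r2", start = 100, end = 900,
                   programme = paste0("prog", 1:7),
                   p_value = c(0.01, 0.02, 0.03, 0.5, 0.6, 0.7, 0.8))
  )
  kept <- consensus_filter(events)
  expect_equal(kept$recombinant, "r1")
  expect_equal(kept$n_programmes, 7)
  expect_equal(nrow(consensus_filter(events[0, ])), 0)
})

test_that("consensus filtering is monotone in its thresholds", {
  set.seed(31)
  events <- tidyr::expand_grid(
    recombinant = paste0("r", 1:12), programme = paste0("p", 1:7)
  ) |>
    dplyr::mutate(start = rep(sample(1:2000, 12), each = 7), end = start + 100,
                  p_value = runif(dplyr::n()))
  n_kept <- function(mp, a) nrow(consensus_filter(events, mp, a))
  for (mp in 1:6) expect_gte(n_kept(mp, 0.5), n_kept(mp + 1, 0.5))
  for (a in c(0.1, 0.3, 0.6)) expect_lte(n_kept(3, a), n_kept(3, a + 0.2))
})

test_that("breakpoints cluster by single linkage with reported spans", {
  cl <- cluster_breakpoints(c(640, 700, 760, 1400, 1500), gap = 100)
  expect_equal(cl$start, c(640, 1400))
  expect_equal(cl$end, c(760, 1500))
  one <- cluster_breakpoints(42)
  expect_equal(c(one$start, one$end), c(42, 42))
  expect_equal(nrow(cluster_breakpoints(numeric(0))), 0)
})

test_that("hotspot splitting yields the flanking regions with exact lengths", {
  aln <- random_alignment(6, 2883, seed = 2)
  hs <- tibble::tibble(name = c("RH5", "RH3"),
                       start = c(631, 1369), end = c(768, 1521))
  out <- split_alignment(aln, hs,
                         region_names = c("env_LP5SU", "env_cenSU", "env_3SUTM"))
  lens <- out |> dplyr::distinct(region, start, end) |>
    dplyr::mutate(len = end - start + 1)
  expect_equal(lens$region, c("env_LP5SU", "env_cenSU", "env_3SUTM"))
  expect_equal(lens$len, c(630, 600, 1362))
  # column conservation: regions + hotspots tile the alignment exactly
  expect_equal(sum(lens$len) + sum(hs$end - hs$start + 1), 2883)
  expect_true(all(nchar(out$seq[out$region == "env_cenSU"]) == 600))
})

test_that("splitting round-trips and degenerate/invalid hotspot sets are handled", {
  aln <- random_alignment(4, 120, seed = 3)
  hs <- tibble::tibble(name = c("h1", "h2"), start = c(31, 91), end = c(40, 100))
  pieces <- split_alignment(aln, hs, keep_hotspots = TRUE)
  rebuilt <- pieces |>
    dplyr::arrange(start, match(id, aln$id)) |>
    dplyr::group_by(id) |>
    dplyr::summarise(seq = paste0(seq, collapse = ""), .groups = "drop") |>
    dplyr::arrange(match(id, aln$id))
  expect_equal(rebuilt$seq, aln$seq)

  ident <- split_alignment(aln, tibble::tibble(name = character(),
                                               start = numeric(),
                                               end = numeric()))
  expect_equal(ident$seq, aln$seq)
  expect_equal(unique(ident$region), "region_1")

  overlap <- tibble::tibble(name = c("a", "b"), start = c(10, 30), end = c(35, 50))
  expect_error(split_alignment(aln, overlap), "overlap")
})

test_that("excision blanks one record over full-alignment coordinates", {
  aln <- random_alignment(5, 700, seed = 4)
  hs <- tibble::tibble(name = "RH", start = 631, end = 668)
  exc <- tibble::tibble(id = "seq3", start = 481, end = 630)
  out <- split_alignment(aln, hs, excisions = exc,
                         region_names = c("left", "right"))
  left <- out[out$region == "left", ]
  expect_equal(substr(left$seq[left$id == "seq3"], 481, 630),
               strrep("-", 150))
  expect_equal(substr(left$seq[left$id == "seq3"], 1, 480),
               substr(aln$seq[3], 1, 480))
  expect_equal(left$seq[left$id != "seq3"],
               substr(aln$seq[-3], 1, 630)) # other records untouched
})

test_that("rate scaling normalises the mean to one, per sample when present", {
  expect_equal(scale_rates(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(scale_rates(c(1, 2, 3)), c(0.5, 1, 1.5))
  set.seed(8)
  expect_equal(mean(scale_rates(rexp(1000))), 1, tolerance = 1e-12)
  expect_error(scale_rates(rep(0, 5)), "non-positive mean")
  tb <- tidyr::expand_grid(sample = 1:3, site = 1:4) |>
    dplyr::mutate(rate = runif(12, 0.1, 2))
  sc <- scale_rates(tb)
  per <- sc |> dplyr::group_by(sample) |> dplyr::summarise(m = mean(rate))
  expect_equal(per$m, rep(1, 3), tolerance = 1e-12)
})

test_that("region rate summaries are plain means with posterior HPDs", {
  rates <- tibble::tibble(site = 1:4, rate = c(1, 1, 3, 3))
  regions <- tibble::tibble(name = c("r1", "r2"), start = c(1, 3), end = c(2, 4))
  expect_equal(region_rate_summary(rates, regions)$mean_rate, c(1, 3))

  ones <- tibble::tibble(site = 1:10, rate = rep(1, 10))
  whole <- tibble::tibble(name = "all", start = 1, end = 10)
  expect_equal(region_rate_summary(ones, whole)$mean_rate, 1)
  # after scaling, the whole alignment as one region has mean exactly 1
  set.seed(12)
  sc <- scale_rates(tibble::tibble(site = 1:50, rate = rexp(50)))
  expect_equal(region_rate_summary(sc, whole |> dplyr::mutate(end = 50))$mean_rate,
               1, tolerance = 1e-12)
  expect_error(region_rate_summary(rates,
                                   tibble::tibble(name = "x", start = 9, end = 10)),
               "no sites")

  mat <- tidyr::expand_grid(sample = 1:20, site = 1:4) |>
    dplyr::mutate(rate = c(1, 1, 3, 3)[site] * rep(runif(20, 0.5, 1.5), each = 4))
  rs <- region_rate_summary(mat, regions)
  expect_named(rs, c("region", "mean_rate", "median", "hpd_lower", "hpd_upper"))
  expect_true(all(rs$hpd_lower <= rs$median & rs$median <= rs$hpd_upper))
})

test_that("the moving average matches a hand mean filter", {
  set.seed(13)
  x <- rexp(60)
  w <- 10
  ma <- site_rate_moving_average(x, w)
  # centred window oracle; for even sizes the extra position sits forward
  for (i in c(6, 20, 54)) {
    lo <- i + w %/% 2 - w + 1
    expect_equal(ma[i], mean(x[lo:(lo + w - 1)]))
  }
  expect_true(anyNA(ma[1:3]) && anyNA(ma[56:60]))
})

test_that("rate ratios report linear and log HPDs with hand-checked values", {
  # identical focal and complement rates in every sample
  same <- tidyr::expand_grid(sample = 1:10, site = 1:6) |>
    dplyr::mutate(rate = rep(c(2, 2, 2, 2, 2, 2), 10))
  rr <- rate_ratio(same, tibble::tibble(start = 1, end = 3))
  expect_equal(rr$mean_ratio, 1)
  expect_equal(c(rr$hpd_linear_lower, rr$hpd_linear_upper), c(1, 1))
  expect_equal(c(rr$hpd_log_lower, rr$hpd_log_upper), c(0, 0))

  # two samples with ratios 2 and 0.5
  two <- tibble::tibble(
    sample = rep(1:2, each = 2), site = rep(1:2, 2),
    rate = c(2, 1, 1, 2) # focal site 1, complement site 2
  )
  rr2 <- rate_ratio(two, tibble::tibble(start = 1, end = 1))
  expect_equal(sort(rr2$ratios[[1]]), c(0.5, 2))
  expect_equal(rr2$mean_ratio, 1.25)
  expect_equal(rr2$hpd_log_lower, -rr2$hpd_log_upper) # symmetric about 0
})

test_that("lognormal ratios give an asymmetric linear HPD but a symmetric log HPD", {
  set.seed(14)
  n <- 1e4
  # one focal and one complement site whose per-sample ratio is lognormal
  rates <- tibble::tibble(
    sample = rep(seq_len(n), each = 2), site = rep(1:2, n),
    rate = as.vector(rbind(exp(rnorm(n, 0, 1)), rep(1, n)))
  )
  rr <- rate_ratio(rates, tibble::tibble(start = 1, end = 1))
  lin_down <- 1 - rr$hpd_linear_lower
  lin_up <- rr$hpd_linear_upper - 1
  expect_gt(lin_up / lin_down, 3) # strongly right-skewed on the linear scale
  log_down <- -rr$hpd_log_lower
  log_up <- rr$hpd_log_upper
  expect_equal(log_up, log_down, tolerance = 0.1) # near-symmetric in log space
  expect_error(rate_ratio(rates, tibble::tibble(start = 1, end = 2)),
               "non-empty")
})
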