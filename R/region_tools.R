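#' Read a FASTA alignment into a tibble
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id` (full header line) and `seq` (gapped
#'   sequence, case preserved).
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(id = names(x), seq = as.character(x))
}

#' Write an alignment tibble as wrapped FASTA
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60) {
  check_alignment(aln)
  x <- Biostrings::BStringSet(setNames(aln$seq, aln$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

check_alignment <- function(aln) {
  if (!all(c("id", "seq") %in% names(aln))) {
    abort("alignment must be a data frame with columns `id` and `seq`")
  }
  L <- unique(nchar(aln$seq))
  if (length(L) != 1L) abort("alignment is not rectangular: unequal sequence lengths")
  invisible(L)
}

#' Consensus-filter recombination events across detection programmes
#'
#' Keeps only events supported by at least `min_programmes` detection
#' programmes at `P < alpha`; events with weaker support are discarded from
#' downstream analysis.
#'
#' @param events Tibble with one row per (event, programme) detection:
#'   columns `recombinant`, `start`, `end` (1-based breakpoint columns),
#'   `programme`, `p_value`.
#' @param min_programmes Minimum number of supporting programmes (default 4).
#' @param alpha P-value threshold (default 0.05).
#' @return Tibble with one row per retained event: `recombinant`, `start`,
#'   `end`, `n_programmes` (supporting detections), `p_min`.
#' @export
consensus_filter <- function(events, min_programmes = 4, alpha = 0.05) {
  req <- c("recombinant", "start", "end", "programme", "p_value")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0L) {
    abort(paste0("events table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(events) == 0L) {
    return(tibble(recombinant = character(), start = numeric(),
                  end = numeric(), n_programmes = integer(),
                  p_min = numeric()))
  }
  events |>
    group_by(.data$recombinant, .data$start, .data$end) |>
    summarise(
      n_programmes = sum(.data$p_value < alpha),
      p_min = min(.data$p_value),
      .groups = "drop"
    ) |>
    filter(.data$n_programmes >= min_programmes)
}

#' Cluster breakpoints into candidate hotspots
#'
#' Single-linkage clustering on the line: consecutive sorted breakpoints at
#' most `gap` columns apart join the same cluster; each cluster is reported as
#' its (min, max) span. An automated stand-in for visual inspection of a
#' recombination event map; the default `gap` of 50 columns is a heuristic
#' and should be tuned against the event density of the data at hand.
#'
#' @param breakpoints Numeric vector of 1-based alignment columns.
#' @param gap Maximum within-cluster spacing (columns, >= 0; default 50).
#' @return Tibble: `cluster`, `start`, `end`, `n_breakpoints`; empty input
#'   gives an empty tibble.
#' @examples
#' cluster_breakpoints(c(640, 700, 760, 1400, 1500), gap = 100)
#' @export
cluster_breakpoints <- function(breakpoints, gap = 50) {
  if (gap < 0) abort("`gap` must be >= 0")
  empty <- tibble(cluster = integer(), start = numeric(), end = numeric(),
                  n_breakpoints = integer())
  if (length(breakpoints) == 0L) return(empty)
  b <- sort(breakpoints)
  id <- cumsum(c(1, diff(b) > gap))
  tibble(bp = b, cluster = id) |>
    group_by(.data$cluster) |>
    summarise(start = min(.data$bp), end = max(.data$bp),
              n_breakpoints = dplyr::n(), .groups = "drop") |>
    select("cluster", "start", "end", "n_breakpoints")
}

#' Split an alignment at recombination hotspots
#'
#' Partitions the columns of a rectangular alignment into the intervals
#' between (and outside) the given hotspots, after applying per-sequence
#' excision rules. Coordinates are 1-based inclusive and gap columns count.
#' Excision blanks the named sequence's characters with `-` over the given
#' full-alignment columns (column homology is preserved; a rectangular
#' alignment cannot lose columns for a single record), before regional
#' extraction.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param hotspots Tibble of hotspot intervals: `name`, `start`, `end`;
#'   must be sorted and non-overlapping (hard error otherwise).
#' @param excisions Optional tibble of excision rules: `id`, `start`, `end`
#'   in full-alignment coordinates.
#' @param region_names Optional character vector naming the k+1 inter-hotspot
#'   regions in coordinate order; defaults to `region_1`, `region_2`, ...
#' @param keep_hotspots If `TRUE`, the hotspot alignments are returned too
#'   (named by the hotspot `name`), so that concatenating all pieces in
#'   coordinate order reconstructs the input.
#' @return Tibble with columns `region`, `start`, `end`, `id`, `seq`; one
#'   block of rows per region, in coordinate order. The per-region interval
#'   table is attached as attribute `"regions"`.
#' @examples
#' aln <- tibble::tibble(id = c("a", "b"),
#'                       seq = c(strrep("ACGT", 25), strrep("TGCA", 25)))
#' hs <- tibble::tibble(name = "RH1", start = 41, end = 60)
#' split_alignment(aln, hs)
#' @export
split_alignment <- function(aln, hotspots, excisions = NULL,
                            region_names = NULL, keep_hotspots = FALSE) {
  L <- check_alignment(aln)
  aln <- as_tibble(aln)
  if (nrow(hotspots) > 0L) {
    if (!all(c("start", "end") %in% names(hotspots))) {
      abort("hotspots must have columns `start` and `end`")
    }
    hotspots <- arrange(as_tibble(hotspots), .data$start)
    if (any(hotspots$start < 1 | hotspots$end > L |
            hotspots$start > hotspots$end)) {
      abort("hotspot coordinates out of bounds")
    }
    if (nrow(hotspots) > 1L &&
        any(hotspots$start[-1] <= hotspots$end[-nrow(hotspots)])) {
      abort("hotspots overlap")
    }
    if (is.null(hotspots$name)) {
      hotspots$name <- paste0("hotspot_", seq_len(nrow(hotspots)))
    }
  }

  if (!is.null(excisions) && nrow(excisions) > 0L) {
    for (k in seq_len(nrow(excisions))) {
      ex <- excisions[k, ]
      i <- which(aln$id == ex$id)
      if (length(i) != 1L) {
        abort(paste0("excision names unknown or ambiguous sequence id: ", ex$id))
      }
      if (ex$start < 1 || ex$end > L || ex$start > ex$end) {
        abort("excision coordinates out of bounds")
      }
      substr(aln$seq[i], ex$start, ex$end) <-
        strrep("-", ex$end - ex$start + 1L)
    }
  }

  # complement intervals of the hotspots, in coordinate order
  bounds <- rbind(c(0L, 0L),
                  if (nrow(hotspots) > 0L) cbind(hotspots$start, hotspots$end),
                  c(L + 1L, L + 1L))
  regions <- tibble(
    start = bounds[-nrow(bounds), 2] + 1,
    end = bounds[-1, 1] - 1
  ) |> filter(.data$end >= .data$start)
  if (is.null(region_names)) {
    region_names <- paste0("region_", seq_len(nrow(regions)))
  }
  if (length(region_names) != nrow(regions)) {
    abort(sprintf("`region_names` must have length %d", nrow(regions)))
  }
  regions$name <- region_names
  regions$type <- "region"
  if (keep_hotspots && nrow(hotspots) > 0L) {
    regions <- bind_rows(
      regions,
      tibble(start = hotspots$start, end = hotspots$end,
             name = hotspots$name, type = "hotspot")
    ) |> arrange(.data$start)
  }

  out <- purrr::pmap_dfr(regions, function(start, end, name, type) {
    tibble(region = name, start = start, end = end, id = aln$id,
           seq = substr(aln$seq, start, end))
  })
  attr(out, "regions") <- regions[, c("name", "start", "end", "type")]
  out
}

#' Scale site rates to a global mean of one
#'
#' Divides rates by their mean so the average rate across all sites is 1
#' (dimensionless), the conventional presentation of site-wise relative
#' evolutionary rates. For per-posterior-sample tables each sample is scaled
#' separately.
#'
#' @param rates Either a numeric vector of per-column rates, or a tibble with
#'   columns `site`, `rate` and optionally `sample`.
#' @return Same shape as the input, scaled. All-zero input is an error.
#' @export
scale_rates <- function(rates) {
  scale1 <- function(r) {
    m <- mean(r)
    if (!is.finite(m) || m <= 0) abort("cannot scale rates: non-positive mean")
    r / m
  }
  if (is.numeric(rates)) return(scale1(rates))
  if (!all(c("site", "rate") %in% names(rates))) {
    abort("`rates` must be numeric or a data frame with `site` and `rate`")
  }
  rates <- as_tibble(rates)
  if ("sample" %in% names(rates)) {
    rates |> group_by(.data$sample) |>
      mutate(rate = scale1(.data$rate)) |> ungroup()
  } else {
    mutate(rates, rate = scale1(.data$rate))
  }
}

rates_region_sites <- function(rates, start, end) {
  sites <- rates$site >= start & rates$site <= end
  if (!any(sites)) abort(sprintf("region %d-%d contains no sites", start, end))
  sites
}

#' Per-region mean site rates
#'
#' Arithmetic mean of the scaled site rates over each region's columns. When
#' the table carries a `sample` column (per-posterior-sample rates), the
#' per-sample region means are summarised by their median and 95% HPD.
#'
#' @param rates Rate tibble (`site`, `rate`, optional `sample`), typically
#'   from [scale_rates()].
#' @param regions Tibble of intervals: `name`, `start`, `end` (1-based
#'   inclusive).
#' @param mass HPD mass (default 0.95).
#' @return Tibble: `region`, `mean_rate`, and with samples also `median`,
#'   `hpd_lower`, `hpd_upper`.
#' @export
region_rate_summary <- function(rates, regions, mass = 0.95) {
  if (!all(c("name", "start", "end") %in% names(regions))) {
    abort("`regions` must have columns `name`, `start`, `end`")
  }
  has_samples <- "sample" %in% names(rates)
  purrr::pmap_dfr(regions[, c("name", "start", "end")],
    function(name, start, end) {
      sel <- rates[rates_region_sites(rates, start, end), ]
      if (!has_samples) {
        return(tibble(region = name, mean_rate = mean(sel$rate)))
      }
      per_sample <- sel |> group_by(.data$sample) |>
        summarise(m = mean(.data$rate), .groups = "drop")
      hpd <- hpd_interval(per_sample$m, mass)
      tibble(region = name, mean_rate = mean(per_sample$m),
             median = stats::median(per_sample$m),
             hpd_lower = hpd[["lower"]], hpd_upper = hpd[["upper"]])
    })
}

#' Rate ratio between a focal region and its complement
#'
#' Per posterior sample, the ratio of the mean rate over the focal columns to
#' the mean over the complement columns. The pooled ratios are summarised by
#' their mean and by 95% HPD intervals on both the linear and the log scale
#' (a strongly right-skewed ratio distribution has an asymmetric linear HPD
#' but a near-symmetric log one).
#'
#' @param rates Rate tibble with columns `site`, `rate` and (normally)
#'   `sample`; without `sample` the single vector is treated as one sample.
#' @param focal One-or-more-row tibble of focal intervals (`start`, `end`).
#' @param complement Optional tibble of complement intervals; defaults to all
#'   sites outside the focal intervals. Must be disjoint from the focal set.
#' @param mass HPD mass (default 0.95).
#' @return One-row tibble: `n_samples`, `mean_ratio`, `hpd_linear_lower`,
#'   `hpd_linear_upper`, `hpd_log_lower`, `hpd_log_upper`, and a `ratios`
#'   list-column with the per-sample ratios.
#' @export
rate_ratio <- function(rates, focal, complement = NULL, mass = 0.95) {
  rates <- as_tibble(rates)
  if (!"sample" %in% names(rates)) rates$sample <- 1L
  sites <- sort(unique(rates$site))
  in_iv <- function(iv) {
    sel <- rep(FALSE, length(sites))
    for (k in seq_len(nrow(iv))) {
      sel <- sel | (sites >= iv$start[k] & sites <= iv$end[k])
    }
    sites[sel]
  }
  f_sites <- in_iv(focal)
  c_sites <- if (is.null(complement)) setdiff(sites, f_sites) else in_iv(complement)
  if (length(f_sites) == 0L || length(c_sites) == 0L) {
    abort("focal and complement regions must both be non-empty")
  }
  if (length(intersect(f_sites, c_sites)) > 0L) {
    abort("focal and complement regions must be disjoint")
  }
  per <- rates |>
    group_by(.data$sample) |>
    summarise(
      f = mean(.data$rate[.data$site %in% f_sites]),
      c = mean(.data$rate[.data$site %in% c_sites]),
      .groups = "drop"
    )
  zero <- per$c == 0
  if (any(zero)) {
    warn(sprintf("%d sample(s) dropped: complement mean rate is zero", sum(zero)))
    per <- per[!zero, ]
  }
  if (nrow(per) == 0L) abort("no usable samples for the rate ratio")
  ratios <- per$f / per$c
  lin <- if (length(ratios) >= 2L) hpd_interval(ratios, mass) else
    c(lower = ratios, upper = ratios)
  lgr <- log(ratios)
  lg <- if (length(ratios) >= 2L) hpd_interval(lgr, mass) else
    c(lower = lgr, upper = lgr)
  tibble(
    n_samples = length(ratios), mean_ratio = mean(ratios),
    hpd_linear_lower = lin[["lower"]], hpd_linear_upper = lin[["upper"]],
    hpd_log_lower = lg[["lower"]], hpd_log_upper = lg[["upper"]],
    ratios = list(ratios)
  )
}

#' Moving average of site rates
#'
#' Centred mean filter over a window of `window` sites (the usual smoothing
#' for site-rate profiles); positions without a full window are `NA`.
#'
#' @param rate Numeric vector of per-site rates in column order.
#' @param window Window size in sites (default 10).
#' @return Numeric vector, same length as `rate`.
#' @export
site_rate_moving_average <- function(rate, window = 10) {
  if (window < 1 || window > length(rate)) {
    abort("`window` must be between 1 and the number of sites")
  }
  as.numeric(stats::filter(rate, rep(1 / window, window), sides = 2))
}

#' Plot a site-rate profile with region averages
#'
#' Site-wise scaled rates in grey, a moving average, and horizontal segments
#' at the per-region mean rates.
#'
#' @param rates Rate tibble (`site`, `rate`); if a `sample` column is present
#'   the per-site posterior mean is plotted.
#' @param regions Region tibble (`name`, `start`, `end`).
#' @param window Moving-average window (default 10).
#' @return A ggplot object.
#' @export
plot_site_rates <- function(rates, regions, window = 10) {
  rates <- as_tibble(rates)
  if ("sample" %in% names(rates)) {
    rates <- rates |> group_by(.data$site) |>
      summarise(rate = mean(.data$rate), .groups = "drop")
  }
  rates <- arrange(rates, .data$site)
  rates$ma <- site_rate_moving_average(rates$rate, window)
  means <- region_rate_summary(rates, regions)
  means <- left_join(means, as_tibble(regions), by = c(region = "name"))
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$site)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate), colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ma), linetype = "dotted",
                       na.rm = TRUE) +
    ggplot2::geom_segment(
      data = means,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_rate, yend = .data$mean_rate),
      linewidth = 1) +
    ggplot2::labs(x = "alignment column", y = "scaled rate") +
    ggplot2::theme_minimal()
}
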