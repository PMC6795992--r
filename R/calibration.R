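#' Build a calibration table of co-speciation points
#'
#' A calibration point names a clade (taxon set) of the virus tree whose
#' divergence is assumed to mirror a dated host divergence. Host dates are
#' given as a median plus 95% interval bounds in million years (Myr).
#'
#' @param df A data frame with columns `name`, `taxa` (list of character
#'   vectors, or semicolon-separated strings), `median`, `lower`, `upper`
#'   (Myr; `lower <= median <= upper`, `median > 0`).
#' @return A tibble with normalised `taxa` list-column, validated.
#' @examples
#' calibration_table(data.frame(
#'   name = "chimp-gorilla",
#'   taxa = "SFVptr;SFVggo",
#'   median = 8.6, lower = 7.1, upper = 10.1
#' ))
#' @export
calibration_table <- function(df) {
  req <- c("name", "taxa", "median", "lower", "upper")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    abort(paste0("calibration table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  out <- as_tibble(df)
  out$taxa <- as_taxa_list(out$taxa)
  bad_n <- vapply(out$taxa, length, 1L) < 2L
  if (any(bad_n)) {
    abort(paste0("calibration point(s) with fewer than 2 taxa: ",
                 paste(out$name[bad_n], collapse = ", ")))
  }
  with(out, {
    if (any(!(lower <= median & median <= upper))) {
      abort("host date bounds must satisfy lower <= median <= upper")
    }
    if (any(median <= 0)) abort("host date medians must be positive (Myr)")
  })
  out
}

#' Read a calibration (or target) table from a delimited file
#'
#' Expects columns `name`, `taxa` (semicolon-separated labels) and, for
#' calibrations, `median`, `lower`, `upper` in Myr.
#'
#' @param path CSV file path.
#' @param calibrated If `TRUE` (default) validate as a calibration table;
#'   otherwise only `name` and `taxa` are required (a target-clade table).
#' @return A tibble with a `taxa` list-column.
#' @export
read_calibration <- function(path, calibrated = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (calibrated) calibration_table(df) else target_table(df)
}

#' Build a target-clade table
#'
#' @param df Data frame with columns `name` and `taxa` (as in
#'   [calibration_table()], but with no dates: these are the clades whose ages
#'   the fitted clock predicts).
#' @return A tibble with a normalised `taxa` list-column.
#' @export
target_table <- function(df) {
  miss <- setdiff(c("name", "taxa"), names(df))
  if (length(miss) > 0L) {
    abort(paste0("target table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  out <- as_tibble(df)[, c("name", "taxa")]
  out$taxa <- as_taxa_list(out$taxa)
  bad_n <- vapply(out$taxa, length, 1L) < 2L
  if (any(bad_n)) {
    abort(paste0("target clade(s) with fewer than 2 taxa: ",
                 paste(out$name[bad_n], collapse = ", ")))
  }
  out
}

#' Derive normal date distributions from median and 95% bounds
#'
#' The sampling distribution of each host date is normal with mean equal to
#' the reported median and standard deviation taken as the wider of the two
#' one-sided 95% half-widths divided by 1.96:
#' `sd = max((median - lower)/1.96, (upper - median)/1.96)`.
#'
#' @param df A calibration table ([calibration_table()]).
#' @return The table with `mean` and `sd` columns added (Myr).
#' @examples
#' d <- calibration_table(data.frame(name = "msp", taxa = "N;S",
#'                                   median = 0.8, lower = 0.56, upper = 1.4))
#' make_date_distribution(d)[, c("mean", "sd")]  # sd = 0.6/1.96
#' @export
make_date_distribution <- function(df) {
  df <- calibration_table(df)
  dplyr::mutate(df,
    mean = .data$median,
    sd = pmax((.data$median - .data$lower) / 1.96,
              (.data$upper - .data$median) / 1.96))
}

# Truncated-normal (support t > 0) sampler by rejection; vectorised redraws.
# All emitted draws are strictly positive because the clock takes log t.
rtrunc_norm_pos <- function(n, mean, sd) {
  if (sd == 0) {
    if (mean <= 0) abort("degenerate date distribution with non-positive mean")
    return(rep(mean, n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L) abort("date rejection sampling failed to converge")
  }
  out
}

#' Sample host divergence dates
#'
#' Draws dates independently for each calibration point from its normal
#' distribution, rejecting and redrawing non-positive values (truncation at
#' zero; the power-law clock requires `t > 0`).
#'
#' @param points A calibration table; `mean`/`sd` columns are derived with
#'   [make_date_distribution()] if absent.
#' @param n_draws Number of draws per point (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `draw`, `name`, `t` (Myr), in draw-major
#'   order: one row per draw per point.
#' @export
sample_dates <- function(points, n_draws, seed = NULL) {
  if (n_draws < 1) abort("`n_draws` must be >= 1")
  if (!all(c("mean", "sd") %in% names(points))) {
    points <- make_date_distribution(points)
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- lapply(seq_len(nrow(points)), function(i) {
    rtrunc_norm_pos(n_draws, points$mean[i], points$sd[i])
  })
  tibble(
    draw = rep(seq_len(n_draws), times = nrow(points)),
    name = rep(points$name, each = n_draws),
    t = unlist(draws)
  ) |> arrange(.data$draw, match(.data$name, points$name))
}

#' Demonstration calibration table
#'
#' Three co-speciation calibration points spanning the timescales typical of
#' simian foamy virus dating: the chimpanzee-gorilla SFV split (~8.6 Myr), the
#' Taiwanese-rhesus macaque SFV split (~5.3 Myr), and the separation of simian
#' from fereungulate (bovine/equine/feline) foamy viruses near the origin of
#' placental mammal diversification (~100 Myr). Taxa refer to the tips of
#' [demo_sim_spec()]'s host topology.
#'
#' @return A calibration tibble.
#' @export
demo_calibration <- function() {
  calibration_table(tibble(
    name = c("chimp-gorilla", "mcy-mmu", "sfv-fereungulata"),
    taxa = list(c("SFVptr", "SFVggo"),
                c("SFVmcy", "SFVmmu"),
                c("SFVptr", "SFVggo", "SFVppy", "SFVcae", "SFVmcy", "SFVmmu",
                  "SFVmspN", "SFVmspS", "BFV", "EFV", "FFV")),
    median = c(8.6, 5.3, 100),
    lower = c(7.1, 4.0, 85),
    upper = c(10.1, 6.5, 115)
  ))
}

#' Demonstration target-clade table
#'
#' Two clades whose ages the demo analysis predicts: the North/South mandrill
#' SFV split (truth ~1.1 Myr in [demo_sim_spec()]) and the basal
#' diversification of Old World monkey and ape SFVs (~30 Myr).
#'
#' @return A target tibble.
#' @export
demo_targets <- function() {
  target_table(tibble(
    name = c("mandrill-NS", "OWMA-SFV"),
    taxa = list(c("SFVmspN", "SFVmspS"),
                c("SFVptr", "SFVggo", "SFVppy", "SFVcae", "SFVmcy", "SFVmmu",
                  "SFVmspN", "SFVmspS"))
  ))
}
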