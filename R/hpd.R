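#' Highest posterior density interval
#'
#' Shortest contiguous window over the sorted samples that contains at least
#' `ceiling(mass * n)` of them; ties in width are broken by the leftmost
#' start. This is the conventional sample-based HPD (Tracer-style).
#'
#' @param samples Numeric vector of at least 2 finite values.
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(1:100)              # (1, 95)
#' hpd_interval(c(5, 5, 5))         # (5, 5)
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) abort("`samples` must contain at least 2 finite values")
  if (mass <= 0 || mass >= 1) abort("`mass` must be in (0, 1)")
  s <- sort(samples)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths) # which.min returns the first (leftmost) minimum
  c(lower = s[i], upper = s[i + m - 1L])
}
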