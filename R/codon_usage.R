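#' The 61 sense codons of the standard genetic code
#'
#' All 64 triplets over ACGT minus the three stop codons (TAA, TAG, TGA), in
#' lexicographic order. This fixed row set defines the shape of every codon
#' count table, so a three-group comparison always has
#' (61 - 1) x (3 - 1) = 120 degrees of freedom.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  all64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0), c("A", "C", "G", "T"), paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

#' Count sense codons in an alignment region
#'
#' Reads non-overlapping triplets from `region$start + frame_offset` to the
#' region end, pooled across all sequences of the group. Triplets containing
#' a gap or ambiguity character, stop codons, and the trailing partial
#' triplet are excluded from the 61-row count table but tallied as discards.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param region Optional one-row tibble/list with `start`, `end` (1-based
#'   inclusive full-alignment columns); default is the whole alignment.
#' @param frame_offset Reading-frame offset within the region: 0, 1 or 2.
#' @param group Group label recorded in the output column.
#' @return Tibble with columns `group`, `codon` (all 61 sense codons, zero
#'   rows retained), `count`; the number of discarded triplets is attached as
#'   attribute `"discarded"`.
#' @examples
#' aln <- tibble::tibble(id = "x", seq = "ATGAAA")
#' count_codons(aln)
#' @export
count_codons <- function(aln, region = NULL, frame_offset = 0, group = "group") {
  L <- check_alignment(aln)
  if (is.null(region)) region <- list(start = 1L, end = L)
  if (!frame_offset %in% 0:2) abort("`frame_offset` must be 0, 1 or 2")
  if (region$start < 1 || region$end > L || region$start > region$end) {
    abort("region out of alignment bounds")
  }
  seqs <- toupper(substr(aln$seq, region$start + frame_offset, region$end))
  codons <- sense_codons()
  counts <- setNames(integer(length(codons)), codons)
  discarded <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (s in seqs) {
    n_full <- nchar(s) %/% 3L
    if (n_full == 0L) next
    starts <- seq.int(1L, by = 3L, length.out = n_full)
    trip <- substring(s, starts, starts + 2L)
    ok <- trip %in% codons
    tb <- table(factor(trip[ok], levels = codons))
    counts <- counts + as.integer(tb)
    discarded <- discarded + sum(!ok) + (nchar(s) %% 3L > 0L)
  }
  out <- tibble(group = group, codon = codons, count = as.integer(counts))
  attr(out, "discarded") <- discarded
  out
}

#' Chi-squared comparison of codon usage across groups
#'
#' Pearson chi-squared test on the 61-sense-codon x group contingency table
#' with margin-derived expected counts and no continuity correction. Codon
#' rows with zero total are retained (contributing 0 to the statistic) and
#' the degrees of freedom are fixed by the table shape:
#' `df = (61 - 1) * (n_groups - 1)`. The P value is the upper tail of the
#' chi-squared distribution.
#'
#' @param counts Either a long tibble with columns `group`, `codon`, `count`
#'   (e.g. `dplyr::bind_rows()` of [count_codons()] outputs) or a numeric
#'   matrix with 61 codon rows and one column per group.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_groups`, `n_codons`.
#' @export
codon_chisq <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
  } else {
    req <- c("group", "codon", "count")
    if (!all(req %in% names(counts))) {
      abort("`counts` must have columns `group`, `codon`, `count`")
    }
    wide <- tidyr::pivot_wider(as_tibble(counts)[, req],
                               names_from = "group", values_from = "count",
                               values_fill = 0L)
    wide <- wide[match(sense_codons(), wide$codon), ]
    if (anyNA(wide$codon)) abort("count table must cover all 61 sense codons")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$codon
  }
  if (ncol(m) < 2L) abort("at least 2 groups are required")
  if (any(m < 0)) abort("counts must be non-negative")
  col_tot <- colSums(m)
  if (any(col_tot == 0)) {
    abort(paste0("group(s) with zero total counts: ",
                 paste(colnames(m)[col_tot == 0], collapse = ", ")))
  }
  grand <- sum(m)
  if (grand <= 0) abort("grand total must be positive")
  expected <- outer(rowSums(m), col_tot) / grand
  contrib <- (m - expected)^2 / expected
  contrib[expected == 0] <- 0 # zero rows contribute nothing but stay in df
  statistic <- sum(contrib)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  tibble(statistic = statistic, df = df,
         p_value = pchisq(statistic, df, lower.tail = FALSE),
         n_groups = ncol(m), n_codons = nrow(m))
}
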