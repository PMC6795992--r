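# Brute-force HPD oracle: enumerate every contiguous window of the sorted
# samples holding at least ceiling(mass*n) values; shortest wins, leftmost
# start breaks ties. Independent of hpd_interval()'s vectorised path.
brute_hpd <- function(samples, mass = 0.95) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(NA, NA)
  best_w <- Inf
  for (i in seq_len(n - m + 1)) {
    j <- i + m - 1
    w <- s[j] - s[i]
    if (w < best_w) { # strict: keeps the leftmost of tied widths
      best_w <- w
      best <- c(s[i], s[j])
    }
  }
  best
}

# Moments of a normal truncated to (0, Inf).
truncnorm_moments <- function(mean, sd) {
  a0 <- -mean / sd
  lambda <- dnorm(a0) / (1 - pnorm(a0))
  m <- mean + sd * lambda
  v <- sd^2 * (1 + a0 * lambda - lambda^2)
  list(mean = m, sd = sqrt(v))
}

# A small ultrametric tree fixture and a posterior set of n copies of it.
fixture_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):3,(C:2,D:2):2);")
}

fixture_tree_set <- function(n = 5) {
  trees <- rep(list(fixture_tree()), n)
  class(trees) <- "multiPhylo"
  as_posterior_trees(trees)
}

# Random rectangular alignment of given dimensions.
random_alignment <- function(n_seq, L, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = paste0("seq", seq_len(n_seq)),
    seq = vapply(seq_len(n_seq), function(i) {
      paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
  )
}
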