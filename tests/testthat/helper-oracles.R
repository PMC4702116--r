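# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: orders by brute-force permutation filtering,
# nested integrals by adaptive quadrature.

# All rank orders of a fold sequence by filtering every permutation against
# the directed interval constraints, evaluated on explicit positions.
brute_force_orders <- function(r) {
  n <- length(r)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  ok <- list()
  for (pos_order in perms(seq_len(n))) {
    # pos_order lists folds from largest position to smallest (rank order)
    x <- numeric(n)
    x[pos_order] <- n:1          # explicit integer positions
    if (position_density(x, r, L = n + 1) > 0) {
      rank <- integer(n)
      rank[pos_order] <- seq_len(n)
      ok[[length(ok) + 1L]] <- rank
    }
  }
  ok
}

# Nested quadrature for the logarithmic weight integral.
wk_quadrature <- function(x, y, k, rel.tol = 1e-10) {
  if (k == 0L) return(1)
  if (x >= 2 * y) return(0)
  f <- function(z, depth) {
    vapply(z, function(zi) {
      if (depth == k) {
        1 / zi
      } else {
        stats::integrate(function(u) f(u, depth + 1L) / zi, x, 2 * zi,
                         rel.tol = rel.tol)$value
      }
    }, 0)
  }
  stats::integrate(function(u) f(u, 1L), x, 2 * y, rel.tol = rel.tol)$value
}

# Random valid full fold sequence of length n.
random_full_sequence <- function(n) {
  r <- 1L
  s <- 1L
  while (length(r) < n) {
    ri <- sample((-s + 1L):s, 1L)
    r <- c(r, ri)
    s <- s + ri
  }
  r
}

# A small synthetic amplicon from a known reduced evolution, PD4875-like
# signal levels.
synthetic_amplicon <- function(r, ord, alpha = 155, beta = 23,
                               dispersion = 12, bins = 2000, seed = NULL) {
  cn <- copy_number_profile(r, ord)
  k <- length(cn)
  # genome order for a right-facing amplicon: excluded flank (cn 0), then
  # the BFB regions outermost-first
  cn_genome <- c(0, cn)
  widths <- c(3e6, sample(seq(1e6, 6e6, by = 5e5), k, replace = TRUE))
  boundaries <- cumsum(c(36e6, widths))
  tr <- simulate_depth(cn_genome, boundaries, alpha = alpha, beta = beta,
                       dispersion = dispersion, bins = bins, seed = seed)
  summarize_track(tr)
}
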