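# The stochastic layer: lengths of unfolded BFB products, order statistics
# of the minimum length, and likelihoods of fold sequences under uniform
# breakage.
#
# With each break uniform along the current structure, the unfolded length is
# the multiplicative process (L_n | L_{n-1}) ~ U(0, 2 L_{n-1}].  Fold m
# survives a cascade of N cycles iff L_m < min_{n > m} L_n; the minimum
# length sets the amplicon size (L_amp = L_min / 2).

#' Density of the unfolded length after n cycles
#'
#' `P(L_n = l) = log^(n-1)(2^n L / l) / (2^n (n-1)! L)` on `(0, 2^n L]`;
#' this integrates to one, has mean `L` and standard deviation
#' `L * sqrt((4/3)^n - 1)`.  `printed = TRUE` evaluates the variant with
#' `2^(n+1) L` inside the logarithm (kept for comparison; it is not a
#' normalised density).
#'
#' @param l evaluation points (vectorised).
#' @param n number of cycles (>= 1).
#' @param L initial chord length.
#' @param printed use the unnormalised log-argument variant.
#' @return Numeric vector of densities (0 outside the support).
#' @examples
#' length_pdf(0.5, 1)        # 1/2: uniform on (0, 2]
#' integrate(length_pdf, 0, 2^3, n = 3)$value  # 1
#' @export
length_pdf <- function(l, n, L = 1, printed = FALSE) {
  stopifnot(n >= 1, n == round(n), L > 0)
  l <- as.numeric(l)
  if (any(l <= 0)) stop("lengths must be positive")
  arg <- if (printed) 2^(n + 1) * L else 2^n * L
  out <- log(arg / l)^(n - 1) / (2^n * factorial(n - 1) * L)
  out[l > 2^n * L] <- 0
  out
}

#' Moments of the unfolded-length distribution
#'
#' @inheritParams length_pdf
#' @return A list with `mean` (always `L`) and `sd`.
#' @export
length_moments <- function(n, L = 1) {
  list(mean = L, sd = L * sqrt((4 / 3)^n - 1))
}

#' Simulate the unfolded-length series of a cascade
#'
#' @param n number of cycles.
#' @param L initial chord length.
#' @param seed optional integer seed.
#' @return Numeric vector `c(L_0, L_1, ..., L_n)`.
#' @examples
#' sample_lengths(5, seed = 1)
#' @export
sample_lengths <- function(n, L = 1, seed = NULL) {
  stopifnot(n >= 0, n == round(n))
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(n + 1)
  out[1] <- L
  for (i in seq_len(n)) out[i + 1] <- 2 * out[i] * stats::runif(1)
  out
}

#' Surviving folds of a length series
#'
#' Fold m survives iff its length is below every later length; survivors'
#' lengths are strictly increasing in cycle order, and the last cycle always
#' survives.
#'
#' @param lengths numeric vector `(L_1, ..., L_N)` of post-cycle lengths
#'   (no leading `L_0`).
#' @return Integer vector of surviving cycle indices.
#' @examples
#' surviving_folds(c(5, 8, 7, 6, 9))  # 1 4 5
#' @export
surviving_folds <- function(lengths) {
  N <- length(lengths)
  if (N == 0L) return(integer(0))
  later_min <- rev(cummin(rev(lengths)))
  which(lengths == later_min)
}

#' The nested logarithmic weight W_k
#'
#' `W_k(x, y) = int_x^{2y} int_x^{2z_1} ... int_x^{2z_{k-1}}
#' dz_k...dz_1 / (z_1...z_k)`, evaluated in closed form through the
#' coefficient vector `a^k = B_k B_{k-1} ... B_1` applied to powers of
#' `log(2^k y)`.  `W_0` is identically 1; the integral is empty (0) when
#' `x >= 2y` and `k >= 1`.
#'
#' @param x lower limit (> 0).
#' @param y scale (> 0).
#' @param k nesting depth (>= 0).
#' @return Numeric scalar.
#' @examples
#' wk(0.5, 1, 1)  # log(4) = log(2*1/0.5)
#' @export
wk <- function(x, y, k) {
  stopifnot(k >= 0, k == round(k), x > 0, y > 0)
  if (k == 0L) return(1)
  if (x >= 2 * y) return(0)
  a <- wk_coefficients(x, k)
  sum(a * log(2^k * y)^(0:k))
}

# a^k as a plain vector: position j+1 multiplies log^j(2^k y).
wk_coefficients <- function(x, k) {
  a <- matrix(c(-log(x), 1), ncol = 1)  # B_1
  if (k >= 2L) {
    for (r in 2:k) {
      Br <- matrix(0, nrow = r + 1, ncol = r)
      Br[1, ] <- -log(2^(r - 1) * x)^(1:r) / (1:r)
      Br[cbind(2:(r + 1), 1:r)] <- 1 / (1:r)
      a <- Br %*% a
    }
  }
  as.numeric(a)
}

# W_0(x, y), ..., W_kmax(x, y) in one pass: the coefficient vectors chain as
# a^k = B_k a^(k-1), so the whole sequence costs O(kmax^2).
wk_sequence <- function(x, y, kmax) {
  out <- numeric(kmax + 1)
  out[1] <- 1
  if (kmax == 0L) return(out)
  if (x >= 2 * y) return(out)  # empty region for every k >= 1
  a <- matrix(c(-log(x), 1), ncol = 1)
  out[2] <- sum(a * log(2 * y)^(0:1))
  if (kmax >= 2L) {
    for (r in 2:kmax) {
      Br <- matrix(0, nrow = r + 1, ncol = r)
      Br[1, ] <- -log(2^(r - 1) * x)^(1:r) / (1:r)
      Br[cbind(2:(r + 1), 1:r)] <- 1 / (1:r)
      a <- Br %*% a
      out[r + 1] <- sum(a * log(2^r * y)^(0:r))
    }
  }
  out
}

#' Density that the k-th cycle holds the minimum length
#'
#' `M_{k,N}(x, L)` is the joint density that cycle k of an N-cycle cascade
#' attains the minimum unfolded length, with value x:
#' `M_{k,N}(x, L) = W_{k-1}(x, L) (1 - sum_{i=1}^{N-k} 2^{-i}
#' W_{i-1}(x, x)) / (2^k L)`.  Summed over k and integrated over x it is a
#' probability distribution; at k = N = 1 it reduces to the uniform density
#' of a single cycle.
#'
#' @param k candidate index of the minimum (`1 <= k <= N`).
#' @param N number of cycles.
#' @param x candidate minimum length.
#' @param L initial chord length.
#' @return Numeric density (0 outside the support `0 < x <= 2L` given the
#'   earlier-cycle constraint).
#' @examples
#' min_stat_density(1, 1, 0.7, 1)  # 1/2
#' @export
min_stat_density <- function(k, N, x, L = 1) {
  stopifnot(k >= 1, k <= N, N == round(N), k == round(k), L > 0)
  if (x <= 0) return(0)
  if (k == 1L) {
    first <- if (x <= 2 * L) 1 else 0
  } else {
    first <- wk(x, L, k - 1L)  # zero when x >= 2L
  }
  if (first <= 0) return(0)
  tailsum <- 0
  i <- seq_len(N - k)
  if (length(i)) tailsum <- sum(2^(-i) * vapply(i - 1L, function(j) wk(x, x, j), 0))
  val <- first * (1 - tailsum) / (2^k * L)
  max(val, 0)
}

#' Posterior over which cycle holds the minimum length
#'
#' @param x observed minimum length.
#' @param N number of cycles.
#' @param L initial chord length.
#' @return Numeric vector of length N: `P(argmin = k | L_min = x)`.
#' @export
argmin_posterior <- function(x, N, L = 1) {
  m <- vapply(seq_len(N), min_stat_density, 0, N = N, x = x, L = L)
  m / sum(m)
}

#' Density of the minimum unfolded length
#'
#' @inheritParams argmin_posterior
#' @return `sum_k M_{k,N}(x, L)`.
#' @export
min_length_pdf <- function(x, N, L = 1) {
  vapply(x, function(xi) {
    if (xi <= 0 || xi > 2 * L) return(0)
    WL <- wk_sequence(xi, L, N - 1L)        # WL[k] = W_{k-1}(xi, L)
    Wxx <- wk_sequence(xi, xi, N - 1L)
    m <- max(N - 1L, 0L)
    # S[j + 1] = sum_{i=1}^{j} 2^{-i} W_{i-1}(xi, xi)
    S <- c(0, cumsum(2^(-seq_len(m)) * Wxx[seq_len(m)]))
    k <- seq_len(N)
    sum(WL[k] / (2^k * L) * pmax(1 - S[N - k + 1L], 0))
  }, 0)
}

#' Posterior over the number of cycles given the minimum length
#'
#' Assumes the improper uniform prior over N.  The sum over N is truncated
#' when the relative tail contribution drops below `tol`.
#'
#' @param lmin observed minimum length.
#' @param L initial chord length.
#' @param nmax hard cap on the truncation point.
#' @param tol relative tail tolerance.
#' @return A data.frame with columns `n` and `prob`.
#' @details The sum over n is truncated at relative tail `tol`, or earlier if
#'   the alternating coefficient recursion behind `W_k` exhausts double
#'   precision (the unimodal tail is cut at the first spurious increase).
#' @export
bfb_count_posterior <- function(lmin, L = 1, nmax = 300, tol = 1e-10) {
  vals <- numeric(0)
  total <- 0
  prev <- -Inf
  past_mode <- FALSE
  for (n in seq_len(nmax)) {
    v <- tryCatch(min_length_pdf(lmin, n, L), error = function(e) NaN)
    if (!is.finite(v) || v < 0) break
    if (past_mode && v > prev) break  # precision of the W recursion exhausted
    if (is.finite(prev) && v < prev) past_mode <- TRUE
    vals <- c(vals, v)
    total <- total + v
    if (past_mode && total > 0 && v / total < tol) break
    prev <- v
  }
  data.frame(n = seq_along(vals), prob = vals / sum(vals))
}

#' Density of the amplicon size
#'
#' The amplicon size is half the minimum unfolded length (the reference
#' position of the outermost surviving fold):
#' `p(L_amp) = 2 sum_k M_{k,N}(2 L_amp, L)`.
#'
#' @param s amplicon sizes (vectorised).
#' @param N number of cycles.
#' @param L initial chord length.
#' @return Numeric vector of densities.
#' @export
amplicon_size_pdf <- function(s, N, L = 1) {
  2 * min_length_pdf(2 * s, N, L)
}

#' Posterior over the number of cycles deleted between two surviving folds
#'
#' For consecutive surviving lengths `l_prev < l_next`, the number D of
#' intervening deleted cycles has `P(D = d) = I_d / sum_d I_d` with
#' `I_d = 1 - (l_next / (2 l_prev)) sum_{k=0}^{d-1} 2^{-k} W_k(l_next,
#' l_prev)`.  Supported for d >= 1; the sum is truncated at relative
#' tolerance `tol`.
#'
#' @param l_prev,l_next consecutive surviving lengths (`l_prev < l_next`).
#' @param dmax hard truncation cap.
#' @param tol relative tail tolerance.
#' @return A data.frame with columns `d` and `prob`.
#' @export
deleted_count_posterior <- function(l_prev, l_next, dmax = 200, tol = 1e-10) {
  stopifnot(l_prev > 0, l_next > l_prev)
  ratio <- l_next / (2 * l_prev)
  acc <- 0
  I <- numeric(0)
  prev <- Inf
  for (d in seq_len(dmax)) {
    w <- tryCatch(wk(l_next, l_prev, d - 1L), error = function(e) NaN)
    if (!is.finite(w)) break
    acc <- acc + 2^(-(d - 1)) * w
    I_d <- max(1 - ratio * acc, 0)
    # I_d is decreasing in d by construction; an increase means the
    # alternating W recursion has exhausted double precision
    if (I_d > prev) break
    I <- c(I, I_d)
    if (d > 2 && sum(I) > 0 && I_d / sum(I) < tol) break
    prev <- I_d
  }
  data.frame(d = seq_along(I), prob = I / sum(I))
}

#' Joint density of fold positions given a fold sequence
#'
#' Each fold is uniform on the segment it breaks, so the joint density is
#' the product of reciprocal interval widths `prod_i 1 / (x_imax - x_imin)`
#' over the fold partial order.  Positions violating the partial order have
#' density 0 (`-Inf` on the log scale).
#'
#' @param x fold positions, chronological.
#' @param r a fold sequence.
#' @param L initial chord length (bounds the first fold).
#' @param log return the log density.
#' @return Numeric scalar.
#' @examples
#' position_density(c(0.8, 0.3), c(1, 1))  # 1 / 0.8
#' @export
position_density <- function(x, r, L = 1, log = FALSE) {
  assert_fold_sequence(r)
  n <- length(r)
  stopifnot(length(x) == n)
  bounds <- fold_bounds(r)
  val <- function(lab) if (lab == 0L) 0 else if (lab == -1L) L else x[lab]
  ll <- 0
  for (i in seq_len(n)) {
    lo <- val(bounds[[i]][["lo"]]); hi <- val(bounds[[i]][["hi"]])
    if (!(lo < x[i] && x[i] < hi)) {
      return(if (log) -Inf else 0)
    }
    ll <- ll - base::log(hi - lo)
  }
  if (log) ll else exp(ll)
}

# Linear coefficients of the structure length in the fold positions:
# L_struct = sum_i coef[i] * x_i for the structure of word W (walk peaks add
# +2, troughs -2; odd word positions are peaks since the walk starts at 0).
length_coefficients <- function(r) {
  n <- length(r)
  W <- word_evolution(r)[[n]]
  coef <- numeric(n)
  sign <- rep(c(2, -2), length.out = length(W))
  for (j in seq_along(W)) coef[W[j]] <- coef[W[j]] + sign[j]
  coef
}

# Vectorised sampler of fold positions under the conditional-uniform chain.
# Returns an n_samples x n matrix; x_0 = 0 and the chord end L bound fold 1.
sample_positions <- function(r, n_samples, L = 1) {
  n <- length(r)
  bounds <- fold_bounds(r)
  X <- matrix(0, nrow = n_samples, ncol = n)
  colv <- function(lab) {
    if (lab == 0L) rep(0, n_samples)
    else if (lab == -1L) rep(L, n_samples)
    else X[, lab]
  }
  for (i in seq_len(n)) {
    lo <- colv(bounds[[i]][["lo"]]); hi <- colv(bounds[[i]][["hi"]])
    X[, i] <- lo + stats::runif(n_samples) * (hi - lo)
  }
  X
}

# Closed-form conditional step distributions for short prefixes.
step_exact <- function(r_next, r_prefix) {
  n_prev <- length(r_prefix)
  s_prev <- sum(r_prefix)
  if (n_prev == 1L) return(1 / 2)                       # both segments have width x1
  if (n_prev == 2L) {
    if (s_prev == 1L) return(1 / 2)                     # structure is a single fold again
    # s_prev == 2, word 121: outer segments width x1 (P = log(2)/2 each),
    # inner segments width x1 - x2 (P = (1 - log(2))/2 each)
    if (r_next %in% c(-1L, 2L)) return(log(2) / 2)
    return((1 - log(2)) / 2)
  }
  NULL
}

#' Conditional probability of the next fold-sequence element
#'
#' `P(r_n | r_1..r_{n-1})` is the chance, marginalised over the fold
#' positions, that the next uniform break lands on the segment indexed by
#' `r_n`: the integral of (segment width / structure length) against the
#' position density.  Closed forms are used for prefixes of up to two
#' cycles; longer prefixes are estimated by Monte-Carlo integration.
#'
#' @param r_next candidate next element.
#' @param r_prefix fold sequence so far.
#' @param n_samples Monte-Carlo sample count.
#' @param method `"auto"` (closed form when available), `"exact"` or `"mc"`.
#' @param seed optional integer seed.
#' @return Numeric probability with attributes `se` (Monte-Carlo standard
#'   error; 0 for closed forms) and `method`.
#' @examples
#' step_probability(2, c(1, 1))  # log(2)/2 ~ 0.3466
#' @export
step_probability <- function(r_next, r_prefix, n_samples = 1e5,
                             method = c("auto", "exact", "mc"), seed = NULL) {
  method <- match.arg(method)
  assert_fold_sequence(r_prefix)
  s_prev <- sum(r_prefix)
  if (!(r_next > -s_prev && r_next <= s_prev)) {
    return(structure(0, se = 0, method = "inadmissible"))
  }
  full <- c(as.integer(r_prefix), as.integer(r_next))
  if (method != "mc") {
    ex <- step_exact(r_next, r_prefix)
    if (!is.null(ex)) return(structure(ex, se = 0, method = "exact"))
    if (method == "exact") stop("no closed form for prefixes beyond two cycles")
  }
  if (!is.null(seed)) set.seed(seed)
  n_prev <- length(r_prefix)
  X <- sample_positions(r_prefix, n_samples)
  coef <- length_coefficients(r_prefix)
  len <- as.numeric(X %*% coef)
  b <- fold_bounds(full)[[n_prev + 1L]]
  colv <- function(lab) if (lab == 0L) rep(0, n_samples) else X[, lab]
  width <- abs(colv(b[["hi"]]) - colv(b[["lo"]]))
  ratio <- width / len
  structure(mean(ratio), se = stats::sd(ratio) / sqrt(n_samples), method = "mc")
}

#' Occurrence probability of a full fold sequence
#'
#' The product of the conditional step probabilities along the path, times a
#' factor 1/2 for the first cycle's duplication direction (the only cycle
#' whose two physical break placements give distinguishable products).
#'
#' @param r a full fold sequence.
#' @param n_samples Monte-Carlo samples per step.
#' @param include_initial_factor include the 1/2 first-cycle factor.
#' @param method passed to [step_probability()].
#' @param seed optional integer seed.
#' @return Numeric probability with attribute `se` (propagated Monte-Carlo
#'   standard error).
#' @examples
#' round(path_probability(c(1, 1, 1), n_samples = 1e5, seed = 1), 3)  # ~0.038
#' @export
path_probability <- function(r, n_samples = 1e6, include_initial_factor = TRUE,
                             method = c("auto", "exact", "mc"), seed = NULL) {
  method <- match.arg(method)
  assert_fold_sequence(r)
  if (!is.null(seed)) set.seed(seed)
  n <- length(r)
  p <- if (include_initial_factor) 0.5 else 1
  rel_var <- 0
  for (i in seq_len(n)[-1L]) {
    st <- step_probability(r[i], r[seq_len(i - 1L)], n_samples = n_samples,
                           method = method)
    p <- p * as.numeric(st)
    if (as.numeric(st) > 0) rel_var <- rel_var + (attr(st, "se") / as.numeric(st))^2
  }
  structure(p, se = p * sqrt(rel_var))
}
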