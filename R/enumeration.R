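# The census of BFB space: how many distinct fold sequences, evolutions and
# copy-number profiles n cycles can produce.
#
# Sequence counts follow the cumulative-sum recursions (index m = s_n):
# reduced v_{n+1,m} = sum_{k=floor((m+1)/2)}^{m-1} v_{n,k}; full sequences
# drop the upper limit.  Evolution counts have closed forms: 2^(n(n-1)/2)
# overall, prod_{i<n} (2^i - 1) for evolutions that keep every fold.

check_mode <- function(mode) match.arg(mode, c("reduced", "full"))

#' Count fold sequences of a given length
#'
#' @param n number of BFB cycles (>= 1).
#' @param mode `"reduced"` (all elements positive) or `"full"` (deleting
#'   cycles allowed).
#' @return Exact integer count (numeric).
#' @examples
#' count_sequences(5, "reduced")  # 41
#' count_sequences(6, "full")     # 1626
#' @export
count_sequences <- function(n, mode = c("reduced", "full")) {
  mode <- check_mode(mode)
  stopifnot(n >= 1, n == round(n))
  mmax <- 2^(n - 1)
  if (mmax > 2^40) stop("cumulative sums beyond 2^40 are not supported")
  v <- numeric(mmax)
  v[1L] <- 1
  if (n == 1) return(1)
  for (step in seq_len(n - 1L)) {
    nxt <- numeric(mmax)
    # tail[k] = sum_{j >= k} v[j]
    tails <- rev(cumsum(rev(v)))
    for (m in 2:min(mmax, 2^step)) {
      k0 <- (m + 1L) %/% 2L
      if (mode == "reduced") {
        if (k0 <= m - 1L) nxt[m] <- sum(v[k0:(m - 1L)])
      } else {
        nxt[m] <- if (k0 <= mmax) tails[k0] else 0
      }
    }
    if (mode == "full") nxt[1L] <- tails[1L]  # m = 1: any k >= 1
    v <- nxt
  }
  total <- sum(v)
  if (total >= 2^53) stop("count exceeds exact double precision")
  total
}

#' Enumerate fold sequences of a given length
#'
#' Exhaustive, duplicate-free depth-first enumeration under the constraint
#' `-s_{i-1} < r_i <= s_{i-1}` (reduced mode restricts to `1 <= r_i`).
#'
#' @inheritParams count_sequences
#' @return A list of integer vectors; its length equals
#'   [count_sequences()]`(n, mode)`.
#' @examples
#' enumerate_sequences(3, "reduced")  # [1,1,1] and [1,1,2]
#' @export
enumerate_sequences <- function(n, mode = c("reduced", "full")) {
  mode <- check_mode(mode)
  stopifnot(n >= 1, n == round(n))
  limit <- if (mode == "reduced") 8L else 7L
  if (n > limit) {
    stop(sprintf(
      "exhaustive %s enumeration is limited to n <= %d (counts for larger n are available via count_sequences)",
      mode, limit
    ))
  }
  res <- list()
  rec <- function(r, s) {
    if (length(r) == n) {
      res[[length(res) + 1L]] <<- r
      return(invisible(NULL))
    }
    lo <- if (mode == "reduced") 1L else -s + 1L
    for (ri in lo:s) rec(c(r, ri), s + ri)
  }
  rec(1L, 1L)
  res
}

#' Count distinct BFB evolutions
#'
#' An evolution is a fold sequence together with one linear extension of its
#' breakpoint poset.  The closed forms: `2^(n(n-1)/2)` evolutions in full
#' mode, and `prod_{i=1}^{n-1} (2^i - 1)` evolutions that retain at least one
#' copy of every fold (reduced mode).
#'
#' @inheritParams count_sequences
#' @return Exact integer count (numeric).
#' @examples
#' count_evolutions(5, "reduced")  # 315
#' count_evolutions(6, "full")     # 32768
#' @export
count_evolutions <- function(n, mode = c("reduced", "full")) {
  mode <- check_mode(mode)
  stopifnot(n >= 1, n == round(n))
  out <- if (mode == "full") {
    2^(n * (n - 1) / 2)
  } else if (n == 1) 1 else prod(2^seq_len(n - 1L) - 1)
  if (out >= 2^53) stop("count exceeds exact double precision")
  out
}

#' Limiting fraction of evolutions that retain every fold
#'
#' The proportion of n-cycle evolutions losing no fold tends to
#' `prod_{i>=1} (1 - 2^-i) ~ 0.2887880951`.
#'
#' @param imax partial product cutoff; by default terms are accumulated until
#'   they change the product by less than `tol`.
#' @param tol relative convergence tolerance.
#' @return The (partial) product.
#' @examples
#' retained_fraction_limit()          # ~0.2888
#' retained_fraction_limit(imax = 3)  # 0.328125
#' @export
retained_fraction_limit <- function(imax = NULL, tol = 1e-12) {
  prodval <- 1
  i <- 0L
  repeat {
    i <- i + 1L
    if (!is.null(imax) && i > imax) break
    term <- 1 - 2^(-i)
    prodval <- prodval * term
    if (is.null(imax) && (1 - term) < tol) break
  }
  prodval
}

profile_key <- function(cn) paste(cn, collapse = ",")

# All distinct copy-number profiles of a single reduced sequence.
profiles_of_reduced <- function(rr) {
  orders <- enumerate_orders(rr)
  keys <- character(nrow(orders))
  profs <- vector("list", nrow(orders))
  for (j in seq_len(nrow(orders))) {
    cn <- copy_number_profile(rr, orders[j, ])
    profs[[j]] <- cn
    keys[j] <- profile_key(cn)
  }
  profs[!duplicated(keys)]
}

#' Census of distinct copy-number profiles
#'
#' Enumerates every (sequence, order) evolution of `n` cycles, computes each
#' copy-number profile, and deduplicates by vector equality.  In full mode
#' the profile of an evolution is that of its surviving (reduced) structure,
#' so orders of deleted folds collapse in the deduplication.
#'
#' @inheritParams count_sequences
#' @return A list with `count` and `profiles` (list of integer vectors).
#' @examples
#' profile_census(3, "reduced")$count  # 3
#' profile_census(3, "full")$count     # 5
#' @export
profile_census <- function(n, mode = c("reduced", "full")) {
  mode <- check_mode(mode)
  if (n > 6) stop("the profile census is limited to n <= 6")
  seqs <- enumerate_sequences(n, mode)
  reduced <- lapply(seqs, function(r) as.integer(reduce_sequence(r)))
  reduced <- reduced[!duplicated(vapply(reduced, paste, "", collapse = ","))]
  seen <- new.env(parent = emptyenv())
  profiles <- list()
  for (rr in reduced) {
    for (cn in profiles_of_reduced(rr)) {
      key <- profile_key(cn)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        profiles[[length(profiles) + 1L]] <- cn
      }
    }
  }
  list(count = length(profiles), profiles = profiles)
}

#' Census table of BFB space
#'
#' Tabulates, per cycle count, the number of reduced/full fold sequences,
#' evolutions and copy-number profiles.
#'
#' @param n_max largest cycle count (profile columns need `n_max <= 6`).
#' @param profiles include the (enumeration-heavy) profile columns.
#' @return A data.frame with one row per `n`.
#' @examples
#' census_table(4)
#' @export
census_table <- function(n_max = 6, profiles = TRUE) {
  n <- seq_len(n_max)
  out <- data.frame(
    n = n,
    reduced_sequences = vapply(n, count_sequences, 0, mode = "reduced"),
    full_sequences = vapply(n, count_sequences, 0, mode = "full"),
    reduced_evolutions = vapply(n, count_evolutions, 0, mode = "reduced"),
    full_evolutions = vapply(n, count_evolutions, 0, mode = "full")
  )
  if (profiles && n_max <= 6) {
    out$reduced_profiles <- vapply(n, function(k) profile_census(k, "reduced")$count, 0)
    out$full_profiles <- vapply(n, function(k) profile_census(k, "full")$count, 0)
  }
  out
}
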