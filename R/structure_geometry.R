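# Folded structures and copy-number profiles.
#
# Model coordinates place 0 at the structure ends (the centromere-proximal
# side); fold positions are abstract non-negative reals.  A folded structure
# is the alternating walk 0 -> x_{w_1} -> x_{w_2} -> ... -> 0 read off the
# fold word, and its strands are the reference intervals between consecutive
# turning points.  The copy-number profile counts how many strands cover each
# inter-breakpoint region.

# Unordered bound labels (a, b) of the interval containing fold i, read from
# the evolving word: letters of W_{i-1} at positions s_i - 1 and s_i, with
# out-of-range positions denoting the structure ends (label 0).  Fold 1 is
# bounded by 0 and the far chord end (label -1L, position L).
fold_bounds <- function(r) {
  s <- cumsum(r)
  d <- as.integer((-1)^(s + 1))
  words <- word_evolution(r)
  out <- vector("list", length(r))
  out[[1L]] <- c(lo = 0L, hi = -1L)
  for (i in seq_along(r)[-1L]) {
    Wp <- words[[i - 1L]]
    K <- length(Wp)
    letter <- function(j) if (j < 1L || j > K) 0L else Wp[j]
    a <- letter(s[i] - 1L)
    b <- letter(s[i])
    # Lemma-style directed interval: d = -1 means the letter at s_i is the
    # lower bound, d = +1 the letter at s_i - 1.
    if (d[i] == -1L) out[[i]] <- c(lo = b, hi = a) else out[[i]] <- c(lo = a, hi = b)
  }
  out
}

#' Materialise a folded structure from a fold sequence and fold positions
#'
#' @param r a fold sequence.
#' @param positions numeric vector of reference positions, one per cycle
#'   (chronological).  Positions must satisfy the partial order implied by the
#'   sequence: each fold must land strictly inside the reference interval
#'   spanned by the segment it breaks.
#' @param L chord length (upper bound for the first fold position);
#'   default `Inf` leaves it unconstrained.
#' @return A list of class `"folded_structure"` with `turning_points`
#'   (data.frame: `label`, `position` along the end-to-end walk), `strands`
#'   (data.frame: `lo`, `hi` reference intervals, one per strand, `2 * s_n`
#'   rows) and `positions`.
#' @examples
#' fs <- build_structure(c(1, 1), c(0.8, 0.3))
#' fs$strands
#' @export
build_structure <- function(r, positions, L = Inf) {
  assert_fold_sequence(r)
  n <- length(r)
  x <- as.numeric(positions)
  if (length(x) != n) stop("need one position per cycle")
  if (any(x <= 0) || any(x >= L)) stop("positions must lie strictly inside (0, L)")
  bounds <- fold_bounds(r)
  xval <- function(lab) {
    if (lab == 0L) 0 else if (lab == -1L) L else x[lab]
  }
  for (i in seq_len(n)) {
    lo <- xval(bounds[[i]][["lo"]])
    hi <- xval(bounds[[i]][["hi"]])
    if (!(lo < x[i] && x[i] < hi)) {
      lo_lab <- bounds[[i]][["lo"]]; hi_lab <- bounds[[i]][["hi"]]
      stop(sprintf(
        "positions violate the fold partial order at cycle %d: need x[%s] < x[%d] < x[%s] (%.4g < %.4g < %.4g fails)",
        i, if (lo_lab == 0L) "ends" else lo_lab, i,
        if (hi_lab == -1L) "L" else hi_lab, lo, x[i], hi
      ))
    }
  }
  W <- word_evolution(r)[[n]]
  walk <- c(0, x[W], 0)
  m <- length(walk)
  strands <- data.frame(
    lo = pmin(walk[-m], walk[-1L]),
    hi = pmax(walk[-m], walk[-1L])
  )
  structure(
    list(
      turning_points = data.frame(label = W, position = x[W]),
      strands = strands,
      positions = x,
      sequence = as.integer(r)
    ),
    class = "folded_structure"
  )
}

#' @export
print.folded_structure <- function(x, ...) {
  cat(sprintf("folded structure: %d strands, %d folds\n",
              nrow(x$strands), nrow(x$turning_points)))
  invisible(x)
}

#' Total unfolded length of a folded structure
#'
#' The sum of strand lengths, i.e. the length of the linear DNA molecule the
#' structure unfolds into.  Equals the position-weighted integral of the
#' copy-number profile.
#'
#' @param structure a `"folded_structure"`.
#' @return A numeric scalar.
#' @examples
#' unfolded_length(build_structure(c(1, 1), c(0.8, 0.3)))  # 4*0.8 - 2*0.3
#' @export
unfolded_length <- function(structure) {
  stopifnot(inherits(structure, "folded_structure"))
  sum(structure$strands$hi - structure$strands$lo)
}

#' Copy-number profile of a BFB evolution
#'
#' Given a fold sequence and a rank order of its surviving folds (rank 1 =
#' outermost, i.e. the breakpoint farthest from the structure ends), counts
#' how many strands of the folded structure cover each region between
#' consecutive surviving breakpoints.  The profile depends on the ranks only,
#' not on the metric positions.
#'
#' @param r a fold sequence (full sequences are reduced first).
#' @param order integer permutation of `1..k` (k = number of surviving
#'   folds): `order[i]` is the rank of the i-th surviving fold.  May be
#'   omitted when k == 1.
#' @return Integer vector of length k, outermost region first; the innermost
#'   region (between the innermost breakpoint and the structure ends) is
#'   last.  Every entry is even and the last entry is always 2.
#' @examples
#' copy_number_profile(c(1, 1, 2, 2, 3), c(1, 5, 4, 2, 3))  # 16 12 14 6 2
#' copy_number_profile(c(1, 1, 2, 2, 1), c(1, 5, 2, 4, 3))  # 12 8 10 6 2
#' @export
copy_number_profile <- function(r, order = NULL) {
  rr <- reduce_sequence(r)
  k <- length(rr)
  if (is.null(order)) {
    if (k != 1L) stop("an order must be supplied when more than one fold survives")
    order <- 1L
  }
  order <- as.integer(order)
  if (length(order) != k || !identical(sort(order), seq_len(k))) {
    stop(sprintf("order must be a permutation of 1..%d (one rank per surviving fold)", k))
  }
  pos <- k + 1L - order  # rank 1 -> largest model coordinate
  # Consistency with the partial order of the reduced sequence.
  bounds <- fold_bounds(unclass(rr))
  val <- function(lab) if (lab == 0L) 0L else if (lab == -1L) k + 1L else pos[lab]
  for (i in seq_len(k)) {
    lo <- val(bounds[[i]][["lo"]]); hi <- val(bounds[[i]][["hi"]])
    if (!(lo < pos[i] && pos[i] < hi)) {
      stop(sprintf("order is inconsistent with the fold partial order at fold %d", i))
    }
  }
  W <- word_evolution(unclass(rr))[[k]]
  walk <- c(0L, pos[W], 0L)
  m <- length(walk)
  lo <- pmin(walk[-m], walk[-1L])
  hi <- pmax(walk[-m], walk[-1L])
  # Region j (outermost first) lies between positions k+1-j and k-j; probe at
  # the midpoint.
  mids <- (k:1) - 0.5
  vapply(mids, function(p) sum(lo < p & p < hi), integer(1L))
}
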