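# Seeded simulators: BFB cascades under uniform breakage, and binned
# read-depth tracks over piecewise-constant integer copy number with
# fold-back junctions at region boundaries.

#' Simulate a BFB cascade
#'
#' Each cycle breaks the current folded structure at a point uniform along
#' its length; the left (top-end) part is duplicated.  The fold-sequence
#' element is derived from the segment the break lands on, the new fold
#' position from the break's reference coordinate, and the unfolded length
#' doubles the distance from the top end to the break.
#'
#' The duplicate-left convention is applied to the first cycle too; the 1/2
#' probability of that direction choice is recorded in the
#' `initial_direction_factor` field rather than folded into the draw, so
#' both conditioned and unconditioned frequencies are available.
#'
#' @param n number of cycles (>= 1).
#' @param L initial chord length.
#' @param seed optional integer seed.
#' @return A list of class `"bfb_cascade"`: `r` (fold sequence), `s`, `d`,
#'   `x` (fold reference positions, chronological), `lengths`
#'   (`L_0 ... L_n`), `surviving` (cycle labels), `reduced` (reduced
#'   sequence), `order` (ranks of the surviving folds), `structure` (final
#'   `"folded_structure"`), `profile` (copy-number counts, outermost region
#'   first) and `initial_direction_factor` (0.5).
#' @examples
#' cascade <- simulate_cascade(5, seed = 42)
#' cascade$r
#' cascade$profile
#' @export
simulate_cascade <- function(n, L = 1, seed = NULL) {
  stopifnot(n >= 1, n == round(n), L > 0)
  if (!is.null(seed)) set.seed(seed)
  r <- integer(n)
  x <- numeric(n)
  lengths <- numeric(n + 1)
  lengths[1] <- L
  word <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L) {
      x[1] <- stats::runif(1, 0, L)
      r[1] <- 1L
      word <- 1L
      lengths[2] <- 2 * x[1]
      next
    }
    walk <- c(0, x[word], 0)
    seg_len <- abs(diff(walk))
    total <- sum(seg_len)
    brk <- stats::runif(1, 0, total)
    cum <- cumsum(seg_len)
    t_idx <- which(brk <= cum)[1L]           # strand hit, counted from the top end
    offset <- brk - c(0, cum)[t_idx]
    s_prev <- (length(word) + 1L) %/% 2L
    r[i] <- t_idx - s_prev
    # reference coordinate of the break: odd strands ascend, even descend
    x[i] <- if (t_idx %% 2L == 1L) walk[t_idx] + offset else walk[t_idx] - offset
    lengths[i + 1] <- 2 * brk
    kept <- word[seq_len(t_idx - 1L)]
    word <- c(kept, i, rev(kept))
  }
  reduced <- reduce_sequence(r)
  surviving <- attr(reduced, "labels")
  xs <- x[surviving]
  ord <- as.integer(rank(-xs))              # rank 1 = outermost
  fs <- build_structure(r, x, L = L)
  structure(
    list(
      r = fold_sequence(r), s = fold_cumulative(r), d = fold_directions(r),
      x = x, lengths = lengths, surviving = surviving,
      reduced = reduced, order = ord, structure = fs,
      profile = copy_number_profile(r, ord),
      initial_direction_factor = 0.5
    ),
    class = "bfb_cascade"
  )
}

#' @export
print.bfb_cascade <- function(x, ...) {
  cat("BFB cascade: r = [", paste(unclass(x$r), collapse = ","),
      "], surviving cycles ", paste(x$surviving, collapse = ","),
      ", profile [", paste(x$profile, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' Simulate a binned read-depth track
#'
#' Draws per-bin read counts over regions of constant integer copy number.
#' Bin means are `alpha + beta * cn`; `dispersion = 1` gives Poisson counts,
#' `dispersion > 1` negative-binomial counts with variance
#' `dispersion * mean`.
#'
#' @param cn integer copy number per region, in genome (left-to-right) order.
#' @param boundaries region boundaries, ascending, length `length(cn) + 1`.
#' @param alpha baseline signal (reads/bin) at copy number 0.
#' @param beta reads/bin per copy.
#' @param dispersion variance inflation over Poisson (>= 1).
#' @param bins bins per region (scalar or one per region).
#' @param chrom chromosome name for the emitted intervals.
#' @param seed optional integer seed.
#' @return A list of class `"depth_track"` with `bins` (data.frame: `chrom`,
#'   `start`, `end`, `depth`), `regions` (data.frame: `chrom`, `start`,
#'   `end`, `cn`) and the generating parameters.
#' @examples
#' tr <- simulate_depth(c(4, 2), c(0, 1e5, 2e5), alpha = 10, beta = 20,
#'                      dispersion = 2, bins = 50, seed = 1)
#' head(tr$bins)
#' @export
simulate_depth <- function(cn, boundaries, alpha, beta, dispersion = 1,
                           bins = 100, chrom = "chrS", seed = NULL) {
  k <- length(cn)
  stopifnot(length(boundaries) == k + 1, all(diff(boundaries) > 0),
            dispersion >= 1, beta >= 0)
  if (!is.null(seed)) set.seed(seed)
  bins <- rep_len(as.integer(bins), k)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    mu <- alpha + beta * cn[i]
    m <- bins[i]
    depth <- if (dispersion == 1) {
      stats::rpois(m, mu)
    } else {
      stats::rnbinom(m, size = mu / (dispersion - 1), mu = mu)
    }
    edges <- seq(boundaries[i], boundaries[i + 1], length.out = m + 1)
    rows[[i]] <- data.frame(
      chrom = chrom, start = floor(edges[-(m + 1)]), end = floor(edges[-1]),
      region = i, depth = depth
    )
  }
  structure(
    list(
      bins = do.call(rbind, rows),
      regions = data.frame(
        chrom = chrom, start = boundaries[-(k + 1)], end = boundaries[-1], cn = cn
      ),
      params = list(alpha = alpha, beta = beta, dispersion = dispersion)
    ),
    class = "depth_track"
  )
}

#' Summarise a depth track into an amplicon segment table
#'
#' @param track a `"depth_track"`.
#' @param folds optional fold annotations (data.frame `pos`, `facing`); by
#'   default every internal region boundary becomes a fold of unknown facing.
#' @return An [amplicon_segments()] table.
#' @export
summarize_track <- function(track, folds = NULL) {
  stopifnot(inherits(track, "depth_track"))
  reg <- track$regions
  agg_mean <- tapply(track$bins$depth, track$bins$region, mean)
  agg_var <- tapply(track$bins$depth, track$bins$region, stats::var)
  agg_n <- tapply(track$bins$depth, track$bins$region, length)
  if (is.null(folds)) {
    folds <- data.frame(pos = reg$start[-1L], facing = NA_character_)
  }
  amplicon_segments(
    chrom = reg$chrom, start = reg$start, end = reg$end,
    mean_depth = as.numeric(agg_mean), depth_var = as.numeric(agg_var),
    n_bins = as.integer(agg_n), folds = folds
  )
}

#' The packaged PD4875 chr11 amplicon summary
#'
#' Per-region mean read depths, depth variances and bin counts of the
#' six-region, five-fold amplicon on chromosome 11 of the primary breast
#' cancer sample PD4875 (right-facing: the rightmost region has the higher
#' flanking signal, so the leftmost region is outside the BFB structure).
#' The depth summaries are the published values; the genomic coordinates are
#' synthetic stand-ins (1 kb bins, region width = bin count in kb, origin
#' chr11:36,000,000) since the source coordinates are not published at bin
#' resolution.  Rankings depend on the coordinates only through relative
#' widths.
#'
#' @return An [amplicon_segments()] table with six regions and five folds.
#' @examples
#' pd4875_segments()
#' @export
pd4875_segments <- function() {
  z <- c(154.7, 519.8, 398.2, 465.2, 305.5, 186.3)
  v <- c(986.0, 6416.0, 3981.6, 4596.8, 4830.3, 2034.0)
  m <- c(5578L, 6716L, 3969L, 2536L, 8768L, 5366L)
  origin <- 36e6
  edges <- origin + c(0, cumsum(m)) * 1000
  folds <- data.frame(
    pos = edges[2:6],
    facing = c("L", "R", "L", "R", "R")
  )
  amplicon_segments(
    chrom = "chr11",
    start = edges[1:6], end = edges[2:7],
    mean_depth = z, depth_var = v, n_bins = m,
    folds = folds
  )
}
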