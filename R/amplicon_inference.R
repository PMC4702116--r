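# Ranking candidate BFB evolutions against segmented amplicon read-depth
# summaries.
#
# Each candidate (fold sequence, rank order) implies an integer copy-number
# profile c.  Region mean depths are modelled as z_i ~ N(alpha + beta c_i,
# sigma_i^2 / m_i); the Gaussian likelihood is maximised over (alpha, beta)
# by weighted least squares, and the fold-position likelihood (the
# poset-uniform product) is added on the log scale.

#' Construct an amplicon segment table
#'
#' @param chrom chromosome name (recycled).
#' @param start,end region boundaries, 0-based half-open, contiguous.
#' @param mean_depth per-region mean read depth (reads/bin).
#' @param depth_var per-region variance of bin depths (held fixed).
#' @param n_bins per-region bin counts.
#' @param folds data.frame with columns `pos` (fold breakpoint coordinates;
#'   must equal the internal region boundaries) and `facing` (`"L"`, `"R"`
#'   or `NA`).
#' @return A list of class `"amplicon_segments"` with `regions` and `folds`.
#' @export
amplicon_segments <- function(chrom, start, end, mean_depth, depth_var,
                              n_bins, folds = NULL) {
  k <- length(start)
  regions <- data.frame(
    chrom = rep_len(as.character(chrom), k),
    start = as.numeric(start), end = as.numeric(end),
    mean_depth = as.numeric(mean_depth),
    depth_var = as.numeric(depth_var),
    n_bins = as.integer(n_bins)
  )
  if (k < 2L) stop("an amplicon needs at least two regions")
  if (any(regions$end <= regions$start)) stop("regions must have positive width")
  if (any(abs(regions$start[-1L] - regions$end[-k]) > 1e-9)) {
    stop("regions must be contiguous and non-overlapping")
  }
  if (any(regions$n_bins < 1L)) stop("each region needs at least one bin")
  if (any(regions$depth_var <= 0)) stop("depth variances must be positive")
  internal <- regions$start[-1L]
  if (is.null(folds)) {
    folds <- data.frame(pos = internal, facing = NA_character_)
  }
  folds <- as.data.frame(folds)
  if (!all(c("pos", "facing") %in% names(folds))) {
    stop("folds need columns pos and facing")
  }
  folds <- folds[order(folds$pos), , drop = FALSE]
  if (nrow(folds) != k - 1L || any(abs(folds$pos - internal) > 1e-9)) {
    stop("expected one fold at each internal region boundary")
  }
  structure(list(regions = regions, folds = folds), class = "amplicon_segments")
}

#' @export
print.amplicon_segments <- function(x, ...) {
  cat(sprintf("amplicon segment table: %d regions, %d folds on %s\n",
              nrow(x$regions), nrow(x$folds), x$regions$chrom[1]))
  print(x$regions)
  invisible(x)
}

#' Orient an amplicon
#'
#' The structure ends face the flank with the higher signal (they run
#' through it toward the centromere); the opposite flanking region lies
#' beyond the outermost fold and is not part of the BFB structure.
#'
#' @param table an `"amplicon_segments"` table.
#' @return `"right"` or `"left"`; equal flanking signals raise an error
#'   asking for an explicit override.
#' @examples
#' orient_amplicon(pd4875_segments())  # "right"
#' @export
orient_amplicon <- function(table) {
  stopifnot(inherits(table, "amplicon_segments"))
  z <- table$regions$mean_depth
  first <- z[1L]; last <- z[length(z)]
  if (first == last) {
    stop("flanking regions have equal mean depth: orientation is ambiguous, supply it explicitly")
  }
  if (last > first) "right" else "left"
}

# Region rows ordered outermost-first, plus the excluded flank, for a given
# orientation.  Right-facing: ends at the right edge, outermost region is
# the leftmost BFB region (row 2); the leftmost flank is excluded.
bfb_regions <- function(table, orientation) {
  reg <- table$regions
  k <- nrow(reg)
  if (orientation == "right") {
    list(bfb = reg[2:k, , drop = FALSE], excluded = reg[1L, , drop = FALSE])
  } else {
    list(bfb = reg[(k - 1):1, , drop = FALSE], excluded = reg[k, , drop = FALSE])
  }
}

#' Gaussian log-likelihood of region mean depths for a profile
#'
#' @param table an `"amplicon_segments"` table.
#' @param profile integer copy numbers, outermost BFB region first (length =
#'   number of folds).
#' @param alpha,beta linear signal model: `mu_i = alpha + beta * c_i`.
#' @param orientation amplicon orientation; inferred when `NULL`.
#' @param baseline `"zero"` fits the excluded flank region at copy number 0
#'   (the intercept absorbs non-BFB signal); `"exclude"` drops it.
#' @return Log-likelihood of the observed region means.
#' @export
depth_loglik <- function(table, profile, alpha, beta, orientation = NULL,
                         baseline = c("zero", "exclude")) {
  baseline <- match.arg(baseline)
  dat <- depth_design(table, profile, orientation, baseline)
  mu <- alpha + beta * dat$c
  sum(stats::dnorm(dat$z, mean = mu, sd = sqrt(dat$var / dat$m), log = TRUE))
}

depth_design <- function(table, profile, orientation, baseline) {
  stopifnot(inherits(table, "amplicon_segments"))
  if (is.null(orientation)) orientation <- orient_amplicon(table)
  view <- bfb_regions(table, orientation)
  # BFB regions in genome order for "right" start at the outermost fold; the
  # profile is outermost-first, matching view$bfb row order.
  if (length(profile) != nrow(view$bfb)) {
    stop(sprintf("profile length %d does not match the %d BFB regions",
                 length(profile), nrow(view$bfb)))
  }
  z <- view$bfb$mean_depth; v <- view$bfb$depth_var; m <- view$bfb$n_bins
  cvec <- as.numeric(profile)
  if (baseline == "zero") {
    z <- c(view$excluded$mean_depth, z)
    v <- c(view$excluded$depth_var, v)
    m <- c(view$excluded$n_bins, m)
    cvec <- c(0, cvec)
  }
  list(z = z, var = v, m = m, c = cvec)
}

#' Maximum-likelihood signal fit for a copy-number profile
#'
#' Maximises the Gaussian region-mean likelihood over the intercept and
#' slope by weighted least squares (weights `m_i / sigma_i^2`), with the
#' slope constrained to be non-negative.
#'
#' @inheritParams depth_loglik
#' @return A list with `alpha`, `beta` and `loglik` (the maximised value).
#' @export
fit_depth <- function(table, profile, orientation = NULL,
                      baseline = c("zero", "exclude")) {
  baseline <- match.arg(baseline)
  dat <- depth_design(table, profile, orientation, baseline)
  w <- dat$m / dat$var
  cvec <- dat$c; z <- dat$z
  cbar <- sum(w * cvec) / sum(w)
  zbar <- sum(w * z) / sum(w)
  scc <- sum(w * (cvec - cbar)^2)
  if (scc <= 0) {
    warning("all candidate copy numbers equal: slope is unidentifiable; fitting intercept only")
    beta <- 0
  } else {
    beta <- sum(w * (cvec - cbar) * (z - zbar)) / scc
    if (beta < 0) beta <- 0
  }
  alpha <- zbar - beta * cbar
  mu <- alpha + beta * cvec
  ll <- sum(stats::dnorm(z, mean = mu, sd = sqrt(dat$var / dat$m), log = TRUE))
  list(alpha = alpha, beta = beta, loglik = ll)
}

# Model-coordinate fold positions (outermost first) for an oriented table:
# distance from the structure ends, rescaled so the outermost breakpoint is
# at 1.  L is the rescaled full observed window (the chord must reach at
# least the far window edge).
model_positions <- function(table, orientation) {
  reg <- table$regions
  pos <- table$folds$pos
  if (orientation == "right") {
    ends_at <- reg$end[nrow(reg)]
    x <- ends_at - pos
    Lraw <- ends_at - reg$start[1L]
  } else {
    ends_at <- reg$start[1L]
    x <- pos - ends_at
    Lraw <- reg$end[nrow(reg)] - ends_at
  }
  x <- sort(x, decreasing = TRUE)   # outermost first
  unit <- x[1L]
  list(x = x / unit, L = Lraw / unit)
}

#' Fold-position log-likelihood of a candidate evolution
#'
#' Maps the observed breakpoints into model coordinates (outermost
#' breakpoint = 1), assigns them to folds via the candidate's rank order,
#' and evaluates the log of the poset-uniform position density.
#'
#' @param table an `"amplicon_segments"` table.
#' @param r a (reduced) fold sequence with one element per fold.
#' @param order rank order of the folds (rank 1 = outermost).
#' @param orientation inferred when `NULL`.
#' @return Log density (`-Inf` if the order conflicts with the positions'
#'   partial order).
#' @export
position_loglik <- function(table, r, order, orientation = NULL) {
  stopifnot(inherits(table, "amplicon_segments"))
  if (is.null(orientation)) orientation <- orient_amplicon(table)
  mp <- model_positions(table, orientation)
  k <- length(order)
  if (length(mp$x) != k) stop("order length does not match the number of folds")
  xfold <- mp$x[order]              # fold i sits at the rank order[i] breakpoint
  position_density(xfold, r, L = mp$L, log = TRUE)
}

#' Rank candidate BFB evolutions against an amplicon
#'
#' Enumerates every candidate evolution (fold sequence plus linear extension
#' of its poset) for the observed number of folds, computes each copy-number
#' profile, maximises the depth likelihood over the linear signal model,
#' adds the fold-position log-likelihood, and sorts.  Candidates sharing a
#' profile share the depth likelihood exactly.
#'
#' @param table an `"amplicon_segments"` table.
#' @param mode `"reduced"` (default; candidate sequences with no deleted
#'   folds) or `"full"` (candidate sequences of `n_cycles` cycles whose
#'   surviving folds explain every observed fold; histories that delete
#'   folds need `n_cycles` larger than the fold count).
#' @param n_cycles number of candidate cycles; defaults to the number of
#'   observed folds.
#' @param top return only the best `top` candidates (all by default).
#' @param orientation `"left"`, `"right"`, or `NULL` to infer.
#' @param baseline see [depth_loglik()].
#' @return A data.frame of class `"ranked_inference"`, sorted by total
#'   log-likelihood (ties broken lexicographically by fold sequence), with
#'   columns `rank`, `sequence`, `order`, `profile`, `alpha`, `beta`,
#'   `depth_loglik`, `position_loglik`, `loglik`.
#' @examples
#' head(rank_evolutions(pd4875_segments()), 3)
#' @export
rank_evolutions <- function(table, mode = c("reduced", "full"), n_cycles = NULL,
                            top = Inf, orientation = NULL,
                            baseline = c("zero", "exclude")) {
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  stopifnot(inherits(table, "amplicon_segments"))
  if (is.null(orientation)) orientation <- orient_amplicon(table)
  n_folds <- nrow(table$folds)
  if (is.null(n_cycles)) n_cycles <- n_folds
  if (n_cycles < n_folds) stop("n_cycles cannot be below the number of observed folds")
  if (n_folds > 6L || n_cycles > 6L) {
    stop("exhaustive candidate enumeration is limited to 6 folds/cycles; pre-filter the fold list or rank candidate sequences directly")
  }
  seqs <- enumerate_sequences(n_cycles, mode)
  fit_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (r in seqs) {
    rr <- reduce_sequence(r)
    if (length(rr) != n_folds) next  # a candidate must explain every observed fold
    orders <- enumerate_orders(unclass(rr))
    for (j in seq_len(nrow(orders))) {
      ord <- orders[j, ]
      cn <- copy_number_profile(unclass(rr), ord)
      key <- paste(cn, collapse = ",")
      fit <- fit_cache[[key]]
      if (is.null(fit)) {
        fit <- fit_depth(table, cn, orientation, baseline)
        fit_cache[[key]] <- fit
      }
      pll <- position_loglik(table, unclass(rr), ord, orientation)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste(as.integer(r), collapse = ","),
        order = paste(ord, collapse = ","),
        profile = key,
        alpha = fit$alpha, beta = fit$beta,
        depth_loglik = fit$loglik, position_loglik = pll,
        loglik = fit$loglik + pll
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$loglik, out$sequence, out$order), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "sequence", "order", "profile", "alpha", "beta",
                 "depth_loglik", "position_loglik", "loglik")]
  rownames(out) <- NULL
  attr(out, "orientation") <- orientation
  attr(out, "n_candidates") <- nrow(out)
  class(out) <- c("ranked_inference", "data.frame")
  if (is.finite(top)) utils::head(out, top) else out
}
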