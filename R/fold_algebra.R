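# Fold sequences and fold words: the discrete algebra of BFB structures.
#
# A BFB cascade of n cycles is encoded by a fold sequence r = (r_1, ..., r_n):
# r_i is the signed index (counted from just after the structure midpoint) of
# the segment on which the i-th break lands.  The cumulative sums s_i track
# the segment count (2*s_i segments after cycle i) and the direction sequence
# d_i = (-1)^(s_i + 1) gives the facing of every copy of fold i relative to
# the reference.  Walking the folded structure end to end and reporting fold
# labels yields the palindromic fold word.

#' Construct and validate a fold sequence
#'
#' A fold sequence encodes one BFB cycle per element.  The first cycle always
#' creates the single initial fold (`r[1] == 1`); every later element must
#' satisfy `-s[i-1] < r[i] <= s[i-1]`, where `s` is the running cumulative sum.
#' Non-positive elements encode cycles that delete earlier folds.
#'
#' @param r integer vector, one element per BFB cycle.
#' @return An integer vector of class `"fold_sequence"`.
#' @examples
#' fold_sequence(c(1, 1, 2, -1, 3))
#' @export
fold_sequence <- function(r) {
  assert_fold_sequence(r)
  structure(as.integer(r), class = "fold_sequence")
}

#' @export
print.fold_sequence <- function(x, ...) {
  cat("fold sequence [", paste(unclass(x), collapse = ","), "]\n", sep = "")
  lab <- attr(x, "labels")
  if (!is.null(lab)) {
    cat("  surviving cycle labels: ", paste(lab, collapse = ","), "\n", sep = "")
  }
  invisible(x)
}

assert_fold_sequence <- function(r) {
  if (length(r) < 1L) stop("a fold sequence needs at least one cycle")
  if (any(!is.finite(r)) || any(r != round(r))) {
    stop("fold sequence elements must be integers")
  }
  if (r[1] != 1L) {
    stop("invalid fold sequence at index 1: the first cycle must have r = 1")
  }
  s <- cumsum(r)
  for (i in seq_along(r)[-1L]) {
    if (!(r[i] > -s[i - 1L] && r[i] <= s[i - 1L])) {
      stop(sprintf(
        "invalid fold sequence at index %d: need -%d < r <= %d but r = %d",
        i, s[i - 1L], s[i - 1L], r[i]
      ))
    }
  }
  invisible(TRUE)
}

#' Cumulative and direction sequences of a fold sequence
#'
#' `fold_cumulative()` returns the running sums `s_i` (so the structure after
#' cycle i has `2 * s_i` segments); `fold_directions()` returns
#' `d_i = (-1)^(s_i + 1)`, where +1 means all copies of fold i point away from
#' the structure ends and -1 toward them.
#'
#' @param r a fold sequence (validated integer vector).
#' @return An integer vector of the same length as `r`.
#' @examples
#' fold_cumulative(c(1, 1, 2, -1, 3))  # 1 2 4 3 6
#' fold_directions(c(1, 1, 2, -1, 3))  # 1 -1 -1 1 -1
#' @export
fold_cumulative <- function(r) {
  assert_fold_sequence(r)
  as.integer(cumsum(r))
}

#' @rdname fold_cumulative
#' @export
fold_directions <- function(r) {
  assert_fold_sequence(r)
  as.integer((-1)^(cumsum(r) + 1))
}

# All intermediate fold words W_1..W_n (chronological labels 1..n).  The word
# recursion keeps the first b_i = s_i - 1 symbols of W_{i-1}, appends the new
# label, then the kept prefix reversed.
word_evolution <- function(r) {
  s <- cumsum(r)
  W <- vector("list", length(r))
  W[[1L]] <- 1L
  for (i in seq_along(r)[-1L]) {
    b <- s[i] - 1L
    P <- W[[i - 1L]][seq_len(b)]
    W[[i]] <- c(P, i, rev(P))
  }
  W
}

#' Fold word of a fold sequence
#'
#' Builds the palindromic fold word by the prefix-duplication recursion:
#' starting from the one-letter word, cycle i keeps the first `s_i - 1`
#' symbols of the previous word, inserts the new fold label, and appends the
#' kept prefix reversed.  Labels are chronological; cycles whose folds were
#' deleted by later cycles do not appear in the final word.
#'
#' @param r a fold sequence.
#' @return An integer vector of fold labels with class `"fold_word"`; its
#'   length is `2 * s_n - 1`.
#' @examples
#' word_from_sequence(c(1, 1, 2, -1, 3))  # 1 2 4 2 1 5 1 2 4 2 1
#' format(word_from_sequence(c(1, 1, 2)))  # "1213121"
#' @export
word_from_sequence <- function(r) {
  assert_fold_sequence(r)
  w <- word_evolution(r)[[length(r)]]
  structure(as.integer(w), class = "fold_word")
}

#' Parse and format fold words
#'
#' Fold words are written as contiguous digits when every label is below 10
#' and as dot-separated integers otherwise (e.g. `"1.2.10.2.1"`).
#'
#' @param x a character scalar (for `parse_fold_word`) or a fold word / integer
#'   vector (for `format`).
#' @return `parse_fold_word` returns an integer vector of class `"fold_word"`;
#'   the format method returns a character scalar.
#' @examples
#' parse_fold_word("12421512421")
#' @export
parse_fold_word <- function(x) {
  if (is.numeric(x)) {
    return(structure(as.integer(x), class = "fold_word"))
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x)) stop("empty fold word")
  if (grepl(".", x, fixed = TRUE)) {
    sym <- suppressWarnings(as.integer(strsplit(x, ".", fixed = TRUE)[[1L]]))
  } else {
    sym <- suppressWarnings(as.integer(strsplit(x, "")[[1L]]))
  }
  if (any(is.na(sym)) || any(sym < 1L)) {
    stop("fold words contain positive integer labels only")
  }
  structure(sym, class = "fold_word")
}

#' @rdname parse_fold_word
#' @param ... ignored.
#' @export
format.fold_word <- function(x, ...) {
  if (max(x) > 9L) paste(unclass(x), collapse = ".") else paste(unclass(x), collapse = "")
}

#' @export
print.fold_word <- function(x, ...) {
  cat("fold word ", format(x), "\n", sep = "")
  invisible(x)
}

#' Reduce a fold sequence to its all-positive form
#'
#' Non-positive elements (cycles that delete earlier folds) are absorbed into
#' their predecessor, rightmost first, until only positive elements remain.
#' The operation is confluent, so the absorption order does not change the
#' result.  The reduced sequence generates the same final structure as the
#' full sequence.
#'
#' @param r a fold sequence.
#' @return A `"fold_sequence"` whose elements are all positive, with
#'   attributes `labels` (the chronological cycle label each surviving element
#'   corresponds to) and `deleted` (how many reductions each surviving element
#'   absorbed, i.e. how many earlier cycles that event directly deleted).
#' @examples
#' reduce_sequence(c(1, 1, 2, -1, 3))  # [1,1,1,3], labels 1,2,4,5
#' @export
reduce_sequence <- function(r) {
  assert_fold_sequence(r)
  v <- as.integer(r)
  lab <- seq_along(v)
  del <- integer(length(v))
  repeat {
    neg <- which(v <= 0L)
    if (!length(neg)) break
    i <- max(neg)  # i >= 2 is guaranteed: r[1] == 1
    v[i - 1L] <- v[i - 1L] + v[i]
    lab[i - 1L] <- lab[i]          # the later (deleting) event survives
    del[i - 1L] <- del[i] + 1L     # one more reduction used by that event
    keep <- -i
    v <- v[keep]; lab <- lab[keep]; del <- del[keep]
  }
  structure(v, class = "fold_sequence", labels = lab, deleted = del)
}

#' Reverse-engineer the evolution from a fold word
#'
#' Implements the unwinding algorithm: repeatedly identify the rightmost
#' uniquely occurring symbol m such that the word is `Z Y m rev(Y)`, undo the
#' fold and contract to `Z Y`, until the word is empty.  For a viable word the
#' chronological order of the (surviving) folds equals the order in which
#' their labels first appear in the word.  Arbitrary distinct labels are
#' accepted; chronology is reported in the original labels.
#'
#' @param w a fold word (integer vector, `"fold_word"`, or its text form).
#' @return A list with elements `valid` (logical), and when valid: `order`
#'   (chronological fold labels), `sequence` (the reduced fold sequence with
#'   canonical labels), `s` (its cumulative sums); when invalid: `step` (the
#'   1-based undo step at which reversal failed) and `reason`.
#' @examples
#' reverse_word("12421512421")$order  # 1 2 4 5
#' reverse_word("11211")$valid        # FALSE
#' @export
reverse_word <- function(w) {
  if (is.character(w)) w <- parse_fold_word(w)
  w <- as.integer(w)
  fail <- function(step, reason) list(valid = FALSE, step = step, reason = reason)
  if (length(w) < 1L) return(fail(1L, "empty word"))
  if (length(w) %% 2L == 0L) return(fail(1L, "even length"))
  if (!identical(w, rev(w))) return(fail(1L, "not palindromic"))
  if (any(w[-1L] == w[-length(w)])) return(fail(1L, "adjacent equal symbols"))

  U <- w
  rev_order <- integer(0)  # labels, last undone first
  svals <- integer(0)      # cumulative sums, matched to rev_order
  step <- 0L
  while (length(U)) {
    step <- step + 1L
    counts <- table(U)
    hit <- NULL
    for (p in rev(seq_along(U))) {
      m <- U[p]
      if (counts[[as.character(m)]] != 1L) next
      ylen <- length(U) - p
      if (ylen > p - 1L) next
      if (ylen > 0L &&
          !identical(U[(p + 1L):length(U)], rev(U[(p - ylen):(p - 1L)]))) next
      hit <- p
      break
    }
    if (is.null(hit)) {
      return(fail(step, "no uniquely occurring symbol closes the word"))
    }
    rev_order <- c(rev_order, U[hit])
    svals <- c(svals, hit)  # s_m = |Z Y| + 1 = position of m
    U <- U[seq_len(hit - 1L)]
  }
  ord <- rev(rev_order)
  s <- rev(svals)
  r <- diff(c(0L, s))
  # Validity is defined by reversibility: the derived sequence must rebuild
  # the word (up to chronological relabelling of the symbols).
  ok <- r[1] == 1L && all(r > 0L)
  if (ok) {
    s_chk <- cumsum(r)
    ok <- all(r[-1L] <= s_chk[-length(s_chk)])
  }
  if (ok) {
    relabel <- match(w, ord)
    ok <- identical(as.integer(word_from_sequence(r)), relabel)
  }
  if (!ok) return(fail(step, "derived sequence does not rebuild the word"))
  list(
    valid = TRUE,
    order = ord,
    sequence = structure(as.integer(r), class = "fold_sequence", labels = ord),
    s = as.integer(s)
  )
}

#' Recover the reduced fold sequence of a fold word
#'
#' Inverse of [word_from_sequence()] on reduced sequences: runs the reversal
#' algorithm and converts the per-step prefix lengths back into a fold
#' sequence.  For words produced by evolutions with deleted folds this returns
#' the reduced sequence of the surviving cycles.
#'
#' @inheritParams reverse_word
#' @return A `"fold_sequence"` with attribute `labels` giving the original
#'   word symbols in chronological order.
#' @examples
#' sequence_from_word("1213145413121")  # [1,1,2,2,1]
#' sequence_from_word("12421512421")    # [1,1,1,3], labels 1,2,4,5
#' @export
sequence_from_word <- function(w) {
  res <- reverse_word(w)
  if (!res$valid) {
    stop(sprintf("not a viable fold word (failed at undo step %d: %s)",
                 res$step, res$reason))
  }
  res$sequence
}

#' Fold sequence of the sibling daughter cell
#'
#' A bridge break at anaphase splits the doubled DNA between two daughter
#' cells: if one daughter's cascade extends `[r_1, ..., r_{n-1}]` with `r_n`,
#' the other daughter's cascade extends it with `1 - r_n`.  Exactly one of the
#' two is non-positive, so one daughter always gains and the other always
#' loses material.
#'
#' @param r a fold sequence of length at least 2.
#' @return The sibling `"fold_sequence"`.
#' @examples
#' daughter_sequence(c(1, 1, 2))      # [1,1,-1]
#' daughter_sequence(c(1, 1, 2, -1))  # [1,1,2,2]
#' @export
daughter_sequence <- function(r) {
  assert_fold_sequence(r)
  n <- length(r)
  if (n < 2L) stop("the daughter rule needs at least two cycles")
  out <- as.integer(r)
  out[n] <- 1L - out[n]
  fold_sequence(out)
}
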