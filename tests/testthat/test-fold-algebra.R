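# The discrete fold algebra: words, sequences, reduction, reversal.

test_that("word construction reproduces the worked five-cycle cascade", {
  cases <- list(
    list(r = c(1, 1, 2, -1, 3), word = "12421512421"),
    list(r = c(1, 1, 2), word = "1213121"),
    list(r = c(1, 1, 2, 2, 1), word = "1213145413121"),
    list(r = 1, word = "1")
  )
  for (cs in cases) {
    expect_identical(format(word_from_sequence(cs$r)), cs$word)
  }
})

test_that("cumulative and direction sequences follow the sign formula", {
  expect_identical(fold_cumulative(c(1, 1, 2, -1, 3)), c(1L, 2L, 4L, 3L, 6L))
  expect_identical(fold_directions(c(1, 1, 2, -1, 3)), c(1L, -1L, -1L, 1L, -1L))
  expect_identical(fold_cumulative(c(1, 1, 2)), c(1L, 2L, 4L))
  expect_identical(fold_directions(c(1, 1, 2)), c(1L, -1L, -1L))
  expect_identical(fold_cumulative(1), 1L)
  expect_identical(fold_directions(1), 1L)
})

test_that("invalid sequences are rejected with the offending index", {
  expect_error(fold_sequence(c(2, 1)), "index 1")
  expect_error(fold_sequence(c(1, 3)), "index 2")
  expect_error(fold_sequence(c(1, 1, -2)), "index 3")
  expect_error(word_from_sequence(c(1, 2)), "index 2")
})

test_that("reduction absorbs deleting cycles and tracks survivors", {
  rr <- reduce_sequence(c(1, 1, 2, -1, 3))
  expect_identical(as.integer(rr), c(1L, 1L, 1L, 3L))
  expect_identical(attr(rr, "labels"), c(1L, 2L, 4L, 5L))
  expect_identical(attr(rr, "deleted"), c(0L, 0L, 1L, 0L))
  expect_identical(as.integer(reduce_sequence(c(1, 1, 1))), c(1L, 1L, 1L))
  r3 <- reduce_sequence(c(1, 1, -1))
  expect_identical(as.integer(r3), 1L)
  expect_identical(attr(r3, "labels"), 3L)
  expect_identical(attr(r3, "deleted"), 2L)
})

test_that("a full sequence and its reduction build the same word after relabelling", {
  set.seed(41)
  for (n in 3:6) {
    for (rep in 1:20) {
      r <- random_full_sequence(n)
      rr <- reduce_sequence(r)
      w_full <- as.integer(word_from_sequence(r))
      w_red <- as.integer(word_from_sequence(as.integer(rr)))
      labels <- attr(rr, "labels")
      expect_identical(labels[w_red], w_full)
    }
  }
})

test_that("reversal recovers the evolution order and reduced sequence", {
  res <- reverse_word("12421512421")
  expect_true(res$valid)
  expect_identical(res$order, c(1L, 2L, 4L, 5L))
  expect_identical(as.integer(res$sequence), c(1L, 1L, 1L, 3L))
  expect_identical(reverse_word("12321")$order, c(1L, 2L, 3L))
  expect_identical(as.integer(sequence_from_word("1213145413121")), c(1L, 1L, 2L, 2L, 1L))
  expect_identical(as.integer(sequence_from_word("1")), 1L)
})

test_that("non-viable words are reported with the failing step", {
  bad <- reverse_word("11211")
  expect_false(bad$valid)
  expect_identical(bad$step, 1L)
  expect_false(reverse_word("1221")$valid)   # even length
  expect_false(reverse_word("123")$valid)    # not palindromic
  expect_false(reverse_word(c(1, 2, 1, 2, 1))$valid)  # 2 occurs twice, no closer
  expect_error(sequence_from_word("11211"), "viable")
})

test_that("round trips hold for every reduced sequence up to six cycles", {
  for (n in 1:6) {
    for (r in enumerate_sequences(n, "reduced")) {
      w <- word_from_sequence(r)
      s_n <- sum(r)
      expect_length(w, 2L * s_n - 1L)
      expect_identical(as.integer(w), rev(as.integer(w)))
      expect_identical(as.integer(sequence_from_word(w)), as.integer(r))
    }
  }
})

test_that("reversal succeeds on every full sequence and reports first-appearance order", {
  set.seed(42)
  for (n in 3:6) {
    for (rep in 1:25) {
      r <- random_full_sequence(n)
      w <- word_from_sequence(r)
      expect_length(w, 2L * sum(r) - 1L)
      res <- reverse_word(w)
      expect_true(res$valid)
      expect_identical(res$order, unique(as.integer(w)))
      expect_identical(res$order, attr(reduce_sequence(r), "labels"))
    }
  }
})

test_that("words with arbitrary distinct labels reverse under relabelling", {
  # the worked five-cycle word relabelled to 2,3,5,6 (chronological 2,3,5,6)
  res <- reverse_word("23532623532")
  expect_true(res$valid)
  expect_identical(res$order, c(2L, 3L, 5L, 6L))
  expect_identical(as.integer(res$sequence), c(1L, 1L, 1L, 3L))
})

test_that("the daughter rule flips the last element and conserves segments", {
  expect_identical(as.integer(daughter_sequence(c(1, 1, 2))), c(1L, 1L, -1L))
  expect_identical(as.integer(daughter_sequence(c(1, 1))), c(1L, 0L))
  expect_identical(as.integer(daughter_sequence(c(1, 1, 2, -1))), c(1L, 1L, 2L, 2L))
  expect_error(daughter_sequence(1), "two cycles")
  set.seed(43)
  for (rep in 1:30) {
    r <- random_full_sequence(sample(2:6, 1))
    d <- daughter_sequence(r)
    n <- length(r)
    expect_true(xor(r[n] <= 0, as.integer(d)[n] <= 0))
    # segment conservation: s_n(r) + s_n(daughter) = 2 s_{n-1} + 1
    expect_identical(sum(r) + sum(as.integer(d)), 2L * sum(r[-n]) + 1L)
  }
})

test_that("reduction is confluent: leftmost-first absorption gives the same result", {
  reduce_leftmost <- function(r) {
    v <- as.integer(r)
    repeat {
      neg <- which(v <= 0L)
      if (!length(neg)) break
      i <- min(neg)
      v[i - 1L] <- v[i - 1L] + v[i]
      v <- v[-i]
    }
    v
  }
  set.seed(44)
  for (rep in 1:50) {
    r <- random_full_sequence(sample(2:7, 1))
    expect_identical(as.integer(reduce_sequence(r)), reduce_leftmost(r))
  }
})

test_that("fold words format and parse with the dotted convention for labels above 9", {
  w <- structure(c(1L, 2L, 10L, 2L, 1L), class = "fold_word")
  expect_identical(format(w), "1.2.10.2.1")
  expect_identical(as.integer(parse_fold_word("1.2.10.2.1")), c(1L, 2L, 10L, 2L, 1L))
  expect_identical(as.integer(parse_fold_word("121")), c(1L, 2L, 1L))
})
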