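# Likelihood ranking of candidate evolutions against amplicon summaries.

test_that("orientation follows the higher flanking signal", {
  tab <- pd4875_segments()
  expect_identical(orient_amplicon(tab), "right")
  mirror <- amplicon_segments(
    "chr11",
    start = tab$regions$start, end = tab$regions$end,
    mean_depth = rev(tab$regions$mean_depth),
    depth_var = rev(tab$regions$depth_var),
    n_bins = rev(tab$regions$n_bins)
  )
  expect_identical(orient_amplicon(mirror), "left")
  tied <- amplicon_segments("chr1", c(0, 100), c(100, 200),
                            mean_depth = c(50, 50), depth_var = c(10, 10),
                            n_bins = c(10, 10))
  expect_error(orient_amplicon(tied), "ambiguous")
})

test_that("the weighted-least-squares fit equals a dense grid search", {
  tab <- pd4875_segments()
  cn <- c(16, 12, 14, 6, 2)
  fit <- fit_depth(tab, cn)
  grid_a <- seq(fit$alpha - 5, fit$alpha + 5, length.out = 81)
  grid_b <- seq(max(0, fit$beta - 2), fit$beta + 2, length.out = 81)
  best <- -Inf; best_ab <- c(NA, NA)
  for (a in grid_a) for (b in grid_b) {
    ll <- depth_loglik(tab, cn, a, b)
    if (ll > best) { best <- ll; best_ab <- c(a, b) }
  }
  expect_gte(fit$loglik + 1e-9, best)
  expect_lt(abs(fit$alpha - best_ab[1]), diff(grid_a[1:2]) + 1e-9)
  expect_lt(abs(fit$beta - best_ab[2]), diff(grid_b[1:2]) + 1e-9)
  # the closed form is the unconstrained optimum: gradient is numerically zero
  eps <- 1e-5
  expect_lt(abs(depth_loglik(tab, cn, fit$alpha + eps, fit$beta) -
                depth_loglik(tab, cn, fit$alpha - eps, fit$beta)), 1e-5)
  expect_lt(abs(depth_loglik(tab, cn, fit$alpha, fit$beta + eps) -
                depth_loglik(tab, cn, fit$alpha, fit$beta - eps)), 1e-5)
})

test_that("depth likelihood depends on candidates only through the profile", {
  tab <- pd4875_segments()
  f1 <- fit_depth(tab, c(16, 12, 14, 6, 2))
  # the two top candidates share the profile, hence the fit
  rk <- rank_evolutions(tab, top = 2)
  expect_equal(rk$depth_loglik[1], f1$loglik)
  expect_equal(rk$depth_loglik[2], f1$loglik)
  expect_identical(rk$profile[1], rk$profile[2])
})

test_that("a perfectly proportional profile attains a zero residual term", {
  cn <- c(8, 4, 2)
  z <- 20 * cn
  tab <- amplicon_segments("chrS", start = c(0, 1, 2, 3) * 1e6,
                           end = c(1, 2, 3, 4) * 1e6,
                           mean_depth = c(1, z), depth_var = rep(100, 4),
                           n_bins = rep(1000, 4))
  fit <- fit_depth(tab, cn, orientation = "right", baseline = "exclude")
  mu <- fit$alpha + fit$beta * cn
  expect_lt(sum((z - mu)^2), 1e-12)
})

test_that("position likelihood ranks the published top pair correctly", {
  tab <- pd4875_segments()
  a <- position_loglik(tab, c(1, 1, 2, 2, 3), c(1, 5, 4, 2, 3))
  b <- position_loglik(tab, c(1, 1, 2, 4, 1), c(1, 4, 2, 5, 3))
  expect_true(is.finite(a) && is.finite(b))
  expect_gt(a, b)
  # an order conflicting with the poset is impossible
  expect_identical(position_loglik(tab, c(1, 1, 1, 1, 1), c(2, 1, 3, 4, 5)), -Inf)
})

test_that("ranking the PD4875 amplicon reproduces the published solution", {
  tab <- pd4875_segments()
  rk <- rank_evolutions(tab)
  expect_equal(attr(rk, "n_candidates"), 315)
  expect_identical(rk$profile[1], "16,12,14,6,2")
  expect_identical(rk$sequence[1], "1,1,2,2,3")
  expect_identical(rk$order[1], "1,5,4,2,3")
  expect_identical(rk$profile[2], "16,12,14,6,2")
  expect_identical(rk$sequence[2], "1,1,2,4,1")
  expect_equal(rk$depth_loglik[1], rk$depth_loglik[2])
  expect_gt(rk$position_loglik[1], rk$position_loglik[2])
  # region II (outermost) copy number of the winner
  expect_identical(as.integer(strsplit(rk$profile[1], ",")[[1]])[1], 16L)
})

test_that("depth likelihood is invariant under candidate relabelling", {
  tab <- pd4875_segments()
  # two distinct evolutions with one shared profile: identical depth term
  rk <- rank_evolutions(tab)
  by_prof <- split(rk$depth_loglik, rk$profile)
  for (v in by_prof) expect_lt(diff(range(v)), 1e-9)
})

test_that("a single-fold amplicon has the unique trivial candidate", {
  tab <- amplicon_segments("chrS", start = c(0, 1) * 1e6,
                           end = c(1, 2) * 1e6,
                           mean_depth = c(10, 60),
                           depth_var = c(20, 80), n_bins = rep(500, 2))
  rk <- rank_evolutions(tab)
  expect_equal(nrow(rk), 1)
  expect_identical(rk$sequence, "1")
  expect_identical(rk$profile, "2")
})

test_that("true profiles are recovered from synthetic amplicons", {
  set.seed(90)
  hits1 <- 0; hits3 <- 0; total <- 50
  for (i in seq_len(total)) {
    n <- sample(4:5, 1)
    seqs <- enumerate_sequences(n, "reduced")
    r <- seqs[[sample(length(seqs), 1)]]
    orders <- enumerate_orders(r)
    ord <- orders[sample(nrow(orders), 1), ]
    truth <- paste(copy_number_profile(r, ord), collapse = ",")
    tab <- synthetic_amplicon(r, ord)
    rk <- rank_evolutions(tab)
    ranks_of_truth <- which(rk$profile == truth)
    hits1 <- hits1 + (rk$profile[1] == truth)
    hits3 <- hits3 + (length(ranks_of_truth) > 0 && min(ranks_of_truth) <= 3)
  }
  expect_gte(hits1 / total, 0.9)
  expect_equal(hits3, total)
})

test_that("oversized fold lists are refused with guidance", {
  edges <- (0:8) * 1e6
  tab <- amplicon_segments("chrS", start = edges[1:8], end = edges[2:9],
                           mean_depth = c(10, 80, 70, 90, 60, 50, 40, 30),
                           depth_var = rep(100, 8), n_bins = rep(100, 8))
  expect_error(rank_evolutions(tab), "limited to 6")
})
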