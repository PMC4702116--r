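# The stochastic layer: length distributions, order statistics of the
# minimum, and fold-sequence likelihoods.

test_that("the length density is normalised with the stated moments", {
  expect_equal(length_pdf(0.5, 1), 1 / 2)       # one cycle: uniform on (0, 2]
  expect_equal(length_pdf(3, 1), 0)             # outside the support
  for (n in c(1, 2, 4, 8)) {
    expect_lt(abs(integrate(length_pdf, 0, 2^n, n = n, rel.tol = 1e-9)$value - 1), 1e-6)
    mu <- integrate(function(l) l * length_pdf(l, n), 0, 2^n, rel.tol = 1e-9)$value
    expect_lt(abs(mu - 1), 1e-6)
    m2 <- integrate(function(l) l^2 * length_pdf(l, n), 0, 2^n, rel.tol = 1e-9)$value
    expect_lt(abs(sqrt(m2 - mu^2) - length_moments(n)$sd), 1e-5)
  }
  # the printed-variant flag exists but is not a density
  expect_gt(integrate(length_pdf, 0, 4, n = 2, printed = TRUE)$value, 1)
})

test_that("simulated lengths match the closed-form moments and distribution", {
  set.seed(71)
  reps <- 2e4
  for (n in c(5, 8)) {
    draws <- replicate(reps, sample_lengths(n)[n + 1])
    se_mean <- length_moments(n)$sd / sqrt(reps)
    expect_lt(abs(mean(draws) - 1), 3 * se_mean)
    sd_th <- length_moments(n)$sd
    expect_lt(abs(sd(draws) - sd_th) / sd_th, 0.1)
  }
  # Kolmogorov-Smirnov distance against the n = 5 closed form
  n <- 5
  draws <- sort(replicate(2e4, sample_lengths(n)[n + 1]))
  cdf_th <- vapply(quantile(draws, (1:19) / 20), function(q) {
    integrate(length_pdf, 0, q, n = n, rel.tol = 1e-8)$value
  }, 0)
  expect_lt(max(abs(cdf_th - (1:19) / 20)), 0.015)
  expect_identical(sample_lengths(0), 1)
})

test_that("sampling is reproducible by seed", {
  expect_identical(sample_lengths(6, seed = 99), sample_lengths(6, seed = 99))
  c1 <- simulate_cascade(5, seed = 99)
  c2 <- simulate_cascade(5, seed = 99)
  expect_identical(c1$r, c2$r)
  expect_identical(c1$x, c2$x)
})

test_that("survivors are the increasing-from-the-minimum subset", {
  expect_identical(surviving_folds(c(5, 8, 7, 6, 9)), c(1L, 4L, 5L))
  expect_identical(surviving_folds(1:6), 1:6)
  expect_identical(surviving_folds(6:1), 6L)
  set.seed(72)
  for (rep in 1:50) {
    l <- sample_lengths(7)[-1]
    surv <- surviving_folds(l)
    expect_identical(surv[length(surv)], 7L)
    expect_true(all(diff(l[surv]) > 0))
  }
})

test_that("the closed-form weight integral matches nested quadrature", {
  expect_equal(wk(0.5, 1, 1), log(4))
  expect_equal(wk(0.2, 0.4, 0), 1)
  expect_equal(wk(2.5, 1, 3), 0)  # empty region
  for (k in 1:4) {
    for (xy in list(c(0.5, 1), c(1, 1), c(0.3, 0.7), c(0.9, 0.6))) {
      q <- wk_quadrature(xy[1], xy[2], k)
      expect_lt(abs(wk(xy[1], xy[2], k) - q), 1e-6 * max(1, abs(q)))
    }
  }
})

test_that("minimum-order-statistic densities normalise and match simulation", {
  expect_equal(min_stat_density(1, 1, 0.7), 1 / 2)  # one cycle: uniform
  for (N in c(1, 2, 4, 6)) {
    tot <- sum(vapply(1:N, function(k) {
      integrate(function(x) vapply(x, min_stat_density, 0, k = k, N = N),
                0, 2, rel.tol = 1e-8)$value
    }, 0))
    expect_lt(abs(tot - 1), 1e-5)
  }
  # marginal argmin probabilities against Monte-Carlo frequencies
  set.seed(73)
  N <- 5; reps <- 2e4
  marg <- vapply(1:N, function(k) {
    integrate(function(x) vapply(x, min_stat_density, 0, k = k, N = N),
              0, 2, rel.tol = 1e-8)$value
  }, 0)
  am <- replicate(reps, which.min(sample_lengths(N)[-1]))
  chi <- sum((tabulate(am, N) - reps * marg)^2 / (reps * marg))
  expect_gt(pchisq(chi, N - 1, lower.tail = FALSE), 1e-4)
  # minimum-length density against the simulated minimum (KS on quantiles)
  mins <- sort(replicate(reps, min(sample_lengths(N)[-1])))
  qs <- quantile(mins, (1:19) / 20)
  cdf_th <- vapply(qs, function(q) {
    integrate(function(x) min_length_pdf(x, N), 0, q, rel.tol = 1e-7)$value
  }, 0)
  expect_lt(max(abs(cdf_th - (1:19) / 20)), 0.015)
})

test_that("argmin posterior matches conditioned simulation frequencies", {
  set.seed(74)
  N <- 5; reps <- 4e4
  sims <- t(replicate(reps, sample_lengths(N)[-1]))
  lmin <- apply(sims, 1, min)
  k_at <- apply(sims, 1, which.min)
  sel <- lmin > 0.35 & lmin < 0.45
  post <- argmin_posterior(0.4, N)
  emp <- tabulate(k_at[sel], N) / sum(sel)
  chi <- sum(sel) * sum((emp - post)^2 / post)
  expect_gt(pchisq(chi, N - 1, lower.tail = FALSE), 1e-4)
})

test_that("the amplicon size shrinks with more cycles and posteriors are proper", {
  means <- vapply(2:8, function(N) {
    integrate(function(s) s * amplicon_size_pdf(s, N), 0, 1, rel.tol = 1e-7)$value
  }, 0)
  expect_true(all(diff(means) < 0))
  cp <- bfb_count_posterior(0.05)
  expect_equal(sum(cp$prob), 1)
  expect_true(all(cp$prob >= 0))
  dp <- deleted_count_posterior(0.5, 0.9)
  expect_equal(sum(dp$prob), 1)
  expect_true(all(diff(dp$prob) <= 0))  # more deletions are never more likely
})

test_that("position densities are poset-uniform products", {
  expect_equal(position_density(0.3, 1), 1)          # single fold on unit chord
  expect_equal(position_density(c(0.8, 0.3), c(1, 1)), 1 / 0.8)
  expect_equal(position_density(c(0.8, 0.3, 0.5), c(1, 1, 2)), 1 / 0.8^2)
  expect_identical(position_density(c(0.3, 0.8), c(1, 1)), 0)
  expect_identical(position_density(c(0.3, 0.8), c(1, 1), log = TRUE), -Inf)
  expect_equal(position_density(c(0.8, 0.3), c(1, 1), log = TRUE), -log(0.8))
})

test_that("closed-form step probabilities and their normalisation", {
  expect_equal(as.numeric(step_probability(2, c(1, 1))), log(2) / 2)
  expect_equal(as.numeric(step_probability(1, c(1, 1))), (1 - log(2)) / 2)
  expect_equal(as.numeric(step_probability(1, 1)), 1 / 2)
  expect_equal(as.numeric(step_probability(3, c(1, 1))), 0)  # inadmissible
  for (prefix in list(1, c(1, 0), c(1, 1))) {
    s <- sum(prefix)
    admissible <- (-s + 1):s
    tot <- sum(vapply(admissible, function(rn) {
      as.numeric(step_probability(rn, prefix))
    }, 0))
    expect_equal(tot, 1)
  }
})

test_that("Monte-Carlo steps agree with closed forms and quadrature", {
  set.seed(75)
  mc <- step_probability(2, c(1, 1), method = "mc", n_samples = 1e5)
  expect_lt(abs(as.numeric(mc) - log(2) / 2), 4 * attr(mc, "se"))
  mc4 <- step_probability(-1, c(1, 1, 2), n_samples = 2e5)
  expect_lt(abs(as.numeric(mc4) - 0.092), 0.003)
  # per-sample widths partition the structure: admissible steps sum to ~1
  prefix <- c(1, 1, 2)
  s <- sum(prefix)
  tot <- 0; var_acc <- 0
  for (rn in (-s + 1):s) {
    st <- step_probability(rn, prefix, n_samples = 4e4)
    tot <- tot + as.numeric(st)
    var_acc <- var_acc + attr(st, "se")^2
  }
  expect_lt(abs(tot - 1), 4 * sqrt(var_acc))
})

test_that("path probabilities reproduce the published fold-path values", {
  set.seed(76)
  pa <- path_probability(c(1, 1, 1), n_samples = 2e5)
  pb <- path_probability(c(1, 1, 2, -1), n_samples = 2e5)
  # [1,1,1] is fully closed-form: 1/2 * 1/2 * (1 - log 2)/2
  expect_equal(as.numeric(pa), (1 - log(2)) / 8)
  expect_equal(round(as.numeric(pa), 3), 0.038)
  expect_lt(abs(as.numeric(pb) - 0.008), max(0.0006, 4 * attr(pb, "se")))
  # without the initial factor the three-cycle paths sum to one
  set.seed(77)
  tot <- 0
  for (r in enumerate_sequences(3, "full")) {
    tot <- tot + as.numeric(path_probability(r, n_samples = 2e4,
                                             include_initial_factor = FALSE))
  }
  expect_lt(abs(tot - 1), 0.02)
})
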