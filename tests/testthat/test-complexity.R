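# Approximate entropy core: embedding, tolerance, phi, ApEn, oracle.

test_that("embedding produces the N - m + 1 overlapping template vectors", {
  expect_equal(nrow(embed_vectors(1:5, m = 2)), 4L)

  E1 <- embed_vectors(c(1, 2, 3, 4), m = 1)
  expect_equal(dim(E1), c(4L, 1L))
  expect_equal(as.numeric(E1), c(1, 2, 3, 4))

  E2 <- embed_vectors(c(0, 1, 0, 1, 0, 1), m = 2)
  expect_equal(E2, rbind(c(0, 1), c(1, 0), c(0, 1), c(1, 0), c(0, 1)),
               ignore_attr = TRUE)

  err <- expect_error(embed_vectors(1:3, m = 2),
                      class = "electromeR_series_too_short")
  expect_match(conditionMessage(err), "N = 3")
  expect_match(conditionMessage(err), "m = 2")
})

test_that("tolerance is r_factor times the population SD", {
  expect_identical(tolerance_from_series(rep(7, 25)), 0)
  expect_equal(tolerance_from_series(c(0, 2), 0.2), 0.2)

  set.seed(421)
  x <- runif(1000)
  # independent SD route: sample SD rescaled to the population convention
  sd_pop <- sd(x) * sqrt(999 / 1000)
  expect_equal(tolerance_from_series(x, 0.2), 0.2 * sd_pop, tolerance = 1e-12)

  expect_error(tolerance_from_series(numeric(0)),
               class = "electromeR_invalid_input")
  expect_error(tolerance_from_series(1:10, r_factor = 0),
               class = "electromeR_invalid_input")
})

test_that("phi is 0 for constant series and the match rule is inclusive", {
  expect_equal(as.numeric(apen_phi(rep(2, 30), m = 2, r_absolute = 0)), 0)
  expect_equal(as.numeric(apen_phi(rep(2, 30), m = 2, r_absolute = 5)), 0)

  # pair at distance exactly r must count: templates (0), (0.5), (100)
  # with r = 0.5 -> match counts (2, 2, 1)
  phi <- apen_phi(c(0, 0.5, 100), m = 1, r_absolute = 0.5)
  expect_identical(attr(phi, "counts"), c(2L, 2L, 1L))
  expect_equal(as.numeric(phi), mean(log(c(2, 2, 1) / 3)))

  # chebyshev in m = 2: vectors (0, 1) and (0.5, 1.5) at max-norm distance
  # exactly 0.5 must match
  x <- c(0, 1, 9, 0.5, 1.5)
  phi2 <- apen_phi(x, m = 2, r_absolute = 0.5)
  cnt <- attr(phi2, "counts")
  expect_equal(cnt[1L], 2L)  # template (0,1) matches itself and (0.5,1.5)

  # excluding self-matches with an unmatched template is a named error
  err <- expect_error(
    apen_phi(c(0, 10, 20, 30), m = 1, r_absolute = 1, self_match = FALSE),
    class = "electromeR_no_match"
  )
  expect_match(conditionMessage(err), "template 1")
})

test_that("ApEn of a constant series is exactly 0 and ApEn is deterministic", {
  res <- apen(rep(3.2, 100))
  expect_identical(res$value, 0)
  expect_identical(res$r_absolute, 0)
  expect_equal(res$n_samples, 100L)
  expect_equal(res$value, res$phi_m - res$phi_m_plus_1)

  x <- mix_process(300, 0.5, seed = 5)
  expect_identical(apen(x)$value, apen(x)$value)
})

test_that("ApEn reproduces frozen golden values on the logistic map", {
  x <- logistic_series(300)
  # golden values computed once with the brute-force oracle
  expect_equal(apen(x)$value, 0.62890395204681537, tolerance = 1e-12)
  expect_equal(apen(x, apen_params(metric = "euclidean"))$value,
               0.66688723025950036, tolerance = 1e-12)
  expect_gt(apen(x)$value, 0)
})

test_that("a periodic series scores below iid noise for every seed", {
  p2 <- rep(c(0, 1), 100)
  a_periodic <- apen(p2)$value
  expect_lt(a_periodic, 0.05)
  for (s in 1:20) {
    noise <- with(list(), {set.seed(s); runif(200)})
    expect_lt(a_periodic, apen(noise)$value)
  }
})

test_that("input validation: short series, non-finite samples, small-N warning", {
  expect_error(apen(c(1, 2, 3, 4), apen_params(m = 2)),
               class = "electromeR_series_too_short")
  expect_error(apen(c(1, NA, 3, rep(1, 60))),
               class = "electromeR_nonfinite_input")
  expect_error(apen(c(1, Inf, 3, rep(1, 60))),
               class = "electromeR_nonfinite_input")
  expect_warning(apen(sin(1:30)), "biased at small N")
})

test_that("fast ApEn agrees with the brute-force oracle on seeded series", {
  set.seed(99)
  for (k in 1:30) {
    n <- sample(50:400, 1)
    x <- if (k %% 2 == 0) runif(n) else mix_process(n, runif(1), seed = k)
    for (metric in c("chebyshev", "euclidean")) {
      p <- apen_params(metric = metric)
      expect_lt(abs(apen(x, p)$value - apen_oracle(x, p)$value), 1e-10)
    }
  }
})

test_that("oracle refuses series beyond its quadratic-cost guard", {
  expect_error(apen_oracle(runif(2001)), class = "electromeR_oracle_size")
  expect_identical(apen_oracle(rep(1, 100))$value, 0)
})

test_that("ApEn is invariant to affine rescaling when r tracks the SD", {
  x <- mix_process(400, 0.4, seed = 8)
  base <- apen(x)$value
  base_e <- apen(x, apen_params(metric = "euclidean"))$value
  for (a in c(0.1, 3, 1000)) {
    for (b in c(-7, 3)) {
      expect_lt(abs(apen(a * x + b)$value - base), 1e-10)
      expect_lt(abs(apen(a * x + b,
                         apen_params(metric = "euclidean"))$value - base_e),
                1e-10)
    }
  }
})

test_that("ApEn is non-negative and finite with self-matches included", {
  for (s in 1:25) {
    x <- mix_process(150, s / 25, seed = s)
    for (metric in c("chebyshev", "euclidean")) {
      v <- apen(x, apen_params(metric = metric))$value
      expect_true(is.finite(v))
      expect_gte(v, 0)
    }
  }
})

test_that("metrics differ only through pairs inside one norm ball but not the other", {
  # vectors (0, 0.9) and (0.9, 0): chebyshev distance 0.9 <= r = 1,
  # euclidean distance 0.9 * sqrt(2) > 1
  x <- c(0, 0.9, 0, 0.9, 0, 0.9)
  c_cheb <- attr(apen_phi(x, m = 2, r_absolute = 1, metric = "chebyshev"),
                 "counts")
  c_eucl <- attr(apen_phi(x, m = 2, r_absolute = 1, metric = "euclidean"),
                 "counts")
  expect_true(all(c_eucl <= c_cheb))
  expect_true(any(c_eucl < c_cheb))
  # and the two engines agree per metric on this fixture
  xx <- rep(x, 10)
  expect_lt(abs(apen(xx)$value - apen_oracle(xx)$value), 1e-10)
})

test_that("parameter defaults and validation match the standard choice", {
  p <- apen_params()
  expect_identical(p$m, 2L)
  expect_identical(p$r_factor, 0.2)
  expect_identical(p$metric, "chebyshev")
  expect_true(p$self_match)
  expect_error(apen_params(m = 0), class = "electromeR_invalid_input")
  expect_error(apen_params(r_factor = -1), class = "electromeR_invalid_input")
})
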