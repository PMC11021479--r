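# Independence null for response polarity: Monte-Carlo vs exact closed form.

# exhaustive oracle: enumerate all 3^n label sequences and sum their
# probabilities by category
enumerate_polarity <- function(p, n) {
  labels <- c("N", "E", "S")
  grid <- expand.grid(rep(list(1:3), n))
  out <- c(pure_enhanced = 0, pure_suppressed = 0, mixed = 0, silent = 0)
  for (i in seq_len(nrow(grid))) {
    draw <- as.integer(grid[i, ])
    pr <- prod(p[draw])
    has_e <- any(draw == 2L)
    has_s <- any(draw == 3L)
    cat_i <- if (has_e && has_s) "mixed"
    else if (has_e) "pure_enhanced"
    else if (has_s) "pure_suppressed"
    else "silent"
    out[cat_i] <- out[cat_i] + pr
  }
  out
}

test_that("closed form matches exhaustive enumeration at n = 3", {
  p <- c(0.722, 0.124, 0.154)
  expect_equal(analytic_polarity_null(p, 3), enumerate_polarity(p, 3),
               tolerance = 1e-14)
  # a second, asymmetric triple
  q <- c(0.5, 0.3, 0.2)
  expect_equal(analytic_polarity_null(q, 3), enumerate_polarity(q, 3),
               tolerance = 1e-14)
})

test_that("closed form degenerates correctly at n = 1 and extreme triples", {
  p <- c(0.6, 0.25, 0.15)
  a <- analytic_polarity_null(p, 1)
  expect_equal(unname(a), c(0.25, 0.15, 0, 0.6))
  expect_equal(sum(a), 1)
  expect_equal(unname(analytic_polarity_null(c(0, 1, 0), 16)["pure_enhanced"]),
               1)
  expect_equal(unname(analytic_polarity_null(c(1, 0, 0), 16)["silent"]), 1)
})

test_that("probability triples are validated", {
  expect_error(polarity_probabilities(0.5, 0.4, 0.2), "sum to 1")
  expect_error(polarity_probabilities(-0.1, 0.6, 0.5), "\\[0, 1\\]")
  expect_error(analytic_polarity_null(c(0.7, 0.3), 16), "3 elements")
})

test_that("Monte-Carlo fractions converge to the closed form", {
  set.seed(17)
  for (i in 1:10) {
    p <- as.vector(stats::rmultinom(1, 1000, c(1, 1, 1)) / 1000)
    res <- simulate_polarity_null(p, n_odors = 16, n_boutons = 1e5,
                                  seed = 100 + i)
    se <- sqrt(res$analytic * (1 - res$analytic) / 1e5)
    expect_true(all(abs(res$fractions - res$analytic) <= 4 * se + 1e-12))
    expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
  }
})

test_that("degenerate label distributions give certain categories", {
  all_e <- simulate_polarity_null(c(0, 1, 0), seed = 1)
  expect_equal(unname(all_e$fractions["pure_enhanced"]), 1)
  all_n <- simulate_polarity_null(c(1, 0, 0), seed = 1)
  expect_equal(unname(all_n$fractions["silent"]), 1)
})

test_that("mixed probability decreases as nonresponsiveness grows", {
  # fixed enhanced:suppressed ratio, increasing p_N
  p_ns <- seq(0.1, 0.9, by = 0.1)
  mixed <- vapply(p_ns, function(pn) {
    rest <- 1 - pn
    analytic_polarity_null(c(pn, rest * 0.45, rest * 0.55), 16)[["mixed"]]
  }, numeric(1))
  expect_true(all(diff(mixed) < 0))
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_polarity_null(c(0.722, 0.124, 0.154), seed = 42)
  b <- simulate_polarity_null(c(0.722, 0.124, 0.154), seed = 42)
  expect_identical(a$fractions, b$fractions)
})
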