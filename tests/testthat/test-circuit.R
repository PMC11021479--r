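# Rate model: glomerular transduction, projection sampling, integration,
# latencies and nonmonotonicity detection.

test_that("glomerular panel sampling matches its distributional contract", {
  p <- sample_glomerular_panel(400, 3, 0.2, seed = 1)
  expect_length(p$log_affinities, 400)
  expect_length(p$efficacies, 400)
  expect_true(all(p$efficacies %in% c(0, 1)))
  # active fraction within the 99% binomial CI of 0.2
  half <- 2.576 * sqrt(0.2 * 0.8 / 400)
  expect_lt(abs(mean(p$efficacies) - 0.2), half)
  # affinities span roughly three orders of magnitude (sd 3 in natural log)
  big <- sample_glomerular_panel(10000, 3, 0.2, seed = 2)
  expect_lt(abs(sd(big$log_affinities) - 3) / 3, 0.02)
  expect_true(all(sample_glomerular_panel(10, 3, 0, seed = 3)$efficacies == 0))
  expect_identical(sample_glomerular_panel(50, seed = 9)$log_affinities,
                   sample_glomerular_panel(50, seed = 9)$log_affinities)
  expect_error(sample_glomerular_panel(0), "n_glomeruli")
  expect_error(sample_glomerular_panel(10, log_affinity_sd = -1),
               "log_affinity_sd")
})

test_that("glomerular output follows the saturating binding curve", {
  p <- sample_glomerular_panel(50, seed = 4)
  expect_equal(glomerular_output(p, 0), rep(0, 50))
  # kappa = 1, eta = 1 at c = 1 gives the half-saturation point
  p1 <- structure(list(n_glomeruli = 2L, log_affinities = c(0, 0),
                       efficacies = c(1L, 0L), seed = NULL),
                  class = "glomerular_panel")
  expect_equal(glomerular_output(p1, 1), c(0.5, 0))
  # bounded by eta and monotone nondecreasing in concentration
  cs <- 10^seq(-3, 3, length.out = 15)
  xs <- sapply(cs, function(cc) glomerular_output(p, cc))
  expect_true(all(xs >= 0 & xs <= p$efficacies + 1e-12))
  expect_true(all(diff(t(xs)) >= -1e-12))
  expect_error(glomerular_output(p, -1), "non-negative")
})

test_that("projection sampling is sparse half-normal with the derived mean drive", {
  W <- sample_projection(5000, 400, 0.1, 0.5, seed = 5)
  expect_true(all(W$weights >= 0))
  nz <- mean(W$weights > 0)
  expect_lt(abs(nz - 0.1), 2.576 * sqrt(0.1 * 0.9 / (5000 * 400)))
  # Monte-Carlo mean drive at saturating concentration: conditional on the
  # realized active glomeruli, E[drive] = sum(eta) * density * E[half-normal]
  p <- sample_glomerular_panel(400, 3, 0.2, seed = 6)
  x_sat <- p$efficacies  # x_i -> eta_i as c -> Inf
  drives <- as.vector(W$weights %*% x_sat)
  expected <- sum(x_sat) * 0.1 * 0.5 * sqrt(2 / pi)
  expect_lt(abs(mean(drives) - expected) / expected, 0.03)
  # unconditional closed form n_g * density * activation_prob * scale *
  # sqrt(2/pi) = 3.19: the realized mean sits within the binomial spread of
  # the active-glomerulus count (sd ~10% of the mean)
  expect_lt(abs(mean(drives) - 3.19) / 3.19, 0.3)
  # degenerate scale: dense matrix of near-zero positives
  W0 <- sample_projection(20, 10, 1, 1e-12, seed = 7)
  expect_true(all(W0$weights > 0 & W0$weights < 1e-10))
  expect_error(sample_projection(10, 10, density = 0), "density")
})

test_that("heterogeneous interneuron jitter has the requested spread", {
  pop <- make_heterogeneous_interneurons(n_interneurons = 500,
                                         jitter_sd = 0.2, seed = 8)
  expect_equal(pop$n_interneurons, 500)
  for (par in list(pop$w_inh / 1, pop$beta / 2, pop$v_thr / 2000)) {
    expect_lt(abs(sd(par) - 0.2), 0.03)
    expect_lt(abs(mean(par) - 1), 0.03)
  }
  base <- c(w_inh = 1, beta = 2, v_thr = 2000)
  flat <- make_heterogeneous_interneurons(base, 10, 0, seed = 9)
  expect_true(all(flat$w_inh == 1 & flat$beta == 2 & flat$v_thr == 2000))
  one <- make_heterogeneous_interneurons(base, 1, 0, seed = 10)
  expect_identical(unclass(one), unclass(interneuron_population(1, 2, 2000)))
})

test_that("integrator fixed points match the analytic steady states", {
  # inhibition frozen off (v_thr = Inf): u_ss = W x
  spec_off <- small_circuit(n_cortical = 80, n_glomeruli = 40,
                            v_thr = Inf)
  tr <- simulate_circuit(spec_off, 10)
  drive <- as.vector(spec_off$projection$weights %*% tr$x)
  expect_lt(max(abs(tr$u[, ncol(tr$u)] - drive)), 1e-3)
  # all-zero at zero concentration
  tr0 <- simulate_circuit(spec_off, 0)
  expect_true(all(tr0$u == 0) && all(tr0$v == 0))
  expect_true(all(tr0$u[, 1] == 0) && all(tr0$v[, 1] == 0))
  # inhibition frozen fully on (v_thr = -Inf): u_ss = W x - w_inh
  spec_on <- small_circuit(n_cortical = 80, n_glomeruli = 40,
                           w_inh = 1, v_thr = -Inf)
  tr1 <- simulate_circuit(spec_on, 10)
  drive1 <- as.vector(spec_on$projection$weights %*% tr1$x)
  expect_lt(max(abs(tr1$u[, ncol(tr1$u)] - (drive1 - 1))), 1e-3)
  # rectification invariant
  expect_identical(tr1$y, pmax(tr1$u, 0))
})

test_that("halving dt leaves steady-state responses unchanged to 1e-3", {
  spec1 <- small_circuit(n_cortical = 60, n_glomeruli = 30, dt = 0.01)
  spec2 <- small_circuit(n_cortical = 60, n_glomeruli = 30, dt = 0.005)
  s1 <- steady_state_response(simulate_circuit(spec1, 5))
  s2 <- steady_state_response(simulate_circuit(spec2, 5))
  rel <- abs(s1 - s2) / pmax(abs(s2), 1e-8)
  expect_lt(max(rel[s2 > 1e-6]), 1e-3)
})

test_that("heterogeneous population with zero jitter reproduces the homogeneous trace", {
  hom <- small_circuit(n_cortical = 50, n_glomeruli = 25, seed = 11)
  het <- small_circuit(
    n_cortical = 50, n_glomeruli = 25, seed = 11,
    interneurons = make_heterogeneous_interneurons(
      c(w_inh = 1, beta = 2, v_thr = 2000 * 50 / 5000),
      n_interneurons = 500, jitter_sd = 0, seed = 12))
  tr_hom <- simulate_circuit(hom, 3)
  tr_het <- simulate_circuit(het, 3)
  expect_equal(tr_het$u, tr_hom$u, tolerance = 1e-12)
  expect_equal(tr_het$v[1, ], tr_hom$v[1, ], tolerance = 1e-12)
})

test_that("latency recovers the first-order half-rise time and NA sentinel", {
  spec <- small_circuit(n_cortical = 60, n_glomeruli = 30, v_thr = Inf)
  tr <- simulate_circuit(spec, 10)
  lat <- response_latency(tr)
  steady <- steady_state_response(tr)
  # u(t) = a (1 - e^{-t/tau}) crosses a/2 at tau ln 2
  expect_true(all(abs(lat[steady > 0.01] - log(2)) <= spec$dt + 1e-9))
  expect_true(all(is.na(lat[steady == 0])))
  expect_error(response_latency(tr, fraction = 1.5), "fraction")
})

test_that("without inhibition every dose-response curve is monotone", {
  spec <- small_circuit(n_cortical = 60, n_glomeruli = 30, w_inh = 0)
  dr <- dose_response(spec, 10^seq(-2, 2, length.out = 8))
  expect_true(all(dr$responses >= 0))
  expect_true(all(apply(dr$responses, 1, function(r) all(diff(r) >= -1e-9))))
  expect_equal(sum(detect_nonmonotonicity(dr$responses)$nonmonotonic), 0)
  expect_error(dose_response(spec, c(2, 1)), "increasing")
})

test_that("heterogeneous inhibition smooths individual dose-response curves", {
  # global inhibition pins the summed activity at threshold, so the
  # population-mean curve plateaus (monotone) in both variants; the
  # smoothing shows in single neurons, whose concentration-step drops are
  # smaller when inhibition recruits gradually across jittered thresholds
  grid <- default_concentration_grid(18)
  hom <- small_circuit(n_cortical = 300, n_glomeruli = 400, seed = 13)
  het <- small_circuit(
    n_cortical = 300, n_glomeruli = 400, seed = 13,
    interneurons = make_heterogeneous_interneurons(
      c(w_inh = 1, beta = 2, v_thr = 2000 * 300 / 5000),
      n_interneurons = 500, jitter_sd = 0.2, seed = 14))
  resp_hom <- dose_response(hom, grid)$responses
  resp_het <- dose_response(het, grid)$responses
  max_step_drop <- function(resp)
    mean(apply(resp, 1, function(r) max(c(0, -diff(r)))))
  expect_lt(max_step_drop(resp_het), max_step_drop(resp_hom))
  # both population-mean curves are monotone nondecreasing
  expect_true(all(diff(colMeans(resp_hom)) > -1e-9))
  expect_true(all(diff(colMeans(resp_het)) > -1e-9))
})

test_that("nonmonotonicity detection flags dips below the running maximum", {
  expect_false(detect_nonmonotonicity(c(0.1, 0.5, 0.9))$nonmonotonic)
  r <- detect_nonmonotonicity(c(0.1, 0.5, 0.2, 0.6, 0.9), rel_tol = 0.1)
  expect_true(r$nonmonotonic)
  expect_equal(r$dip_index, 3L)
  expect_false(detect_nonmonotonicity(c(0, 0, 0, 0))$nonmonotonic)
  expect_error(detect_nonmonotonicity(c(1, 2)), "at least 3")
  m <- rbind(c(0.1, 0.5, 0.9), c(1, 0.2, 1))
  flags <- detect_nonmonotonicity(m)
  expect_identical(flags$nonmonotonic, c(FALSE, TRUE))
})
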