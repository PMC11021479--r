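# Stimulus panels and synthetic tensor generators.

test_that("mixture panel has the standard composition and is reproducible", {
  panel <- make_mixture_panel(seed = 1)
  expect_equal(n_stimuli(panel), 100L)
  expect_equal(as.vector(table(panel$n_components)[c("1", "2", "4", "8", "12")]),
               c(16L, 24L, 20L, 20L, 20L))
  expect_true(all(vapply(panel$components,
                         function(s) all(s %in% 1:16), logical(1))))
  keys <- vapply(panel$components, paste, character(1), collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  again <- make_mixture_panel(seed = 1)
  expect_identical(panel$components, again$components)
  expect_false(identical(panel$components,
                         make_mixture_panel(seed = 2)$components))
})

test_that("concentration panel is log-spaced and strictly increasing", {
  panel <- make_concentration_panel()
  expect_equal(n_stimuli(panel), 8L)
  conc <- panel$rel_concentration
  expect_true(all(diff(conc) > 0))
  expect_equal(conc[8] / conc[1], 1000)
  expect_equal(diff(log10(conc)), rep(diff(log10(conc))[1], 7))
  two <- make_concentration_panel(2)
  expect_equal(two$rel_concentration, c(1e-3, 1))
  expect_error(make_concentration_panel(1), "n_steps")
})

test_that("OSN generator is seed-deterministic and null without sensitivity", {
  panel <- make_mixture_panel(seed = 3)
  par <- osn_params(n_rois = 60, seed = 5)
  t1 <- simulate_osn_tensor(panel, par)
  t2 <- simulate_osn_tensor(panel, osn_params(n_rois = 60, seed = 5))
  expect_identical(t1$amplitudes, t2$amplitudes)
  expect_identical(t1$blank_amplitudes, t2$blank_amplitudes)
  # zero sensitivity: nothing but noise survives classification beyond the
  # false-positive rate
  null_par <- osn_params(n_rois = 200, sensitivity_prob = 0, seed = 6)
  null_t <- simulate_osn_tensor(panel, null_par)
  cl <- classify_responses(null_t)
  frac_resp <- mean(cl$labels != "nonresponsive")
  expect_lt(frac_resp, 0.01)
})

test_that("OSN response density grows sublinearly with mixture size", {
  panel <- make_mixture_panel(seed = 7)
  osn <- simulate_osn_tensor(panel, osn_params(seed = 7))
  cl <- classify_responses(osn)
  density_by_size <- vapply(c(1, 2, 4, 8, 12), function(sz) {
    cols <- panel$n_components == sz
    mean(cl$labels[, cols] != "nonresponsive")
  }, numeric(1))
  expect_true(all(diff(density_by_size) > 0))
  # diminishing returns: per-component gain shrinks as mixtures grow
  gain_small <- (density_by_size[2] - density_by_size[1]) / (2 - 1)
  gain_large <- (density_by_size[5] - density_by_size[4]) / (12 - 8)
  expect_gt(gain_small, gain_large)
})

test_that("OSN concentration tuning is monotone with sigmoidal recruitment", {
  panel <- make_concentration_panel()
  par <- osn_params(n_rois = 100, trial_noise_sd = 1e-6, seed = 8)
  tensor <- simulate_osn_tensor(panel, par)
  tm <- apply(tensor$amplitudes, c(1, 2), mean)
  expect_true(all(apply(abs(tm), 1, function(r) all(diff(r) >= -1e-4))))
  # population activity recruits with concentration
  pop <- colMeans(abs(tm))
  expect_gt(pop[8], pop[1])
})

test_that("bouton direct mode has stimulus-independent density and conserved polarity", {
  panel <- make_mixture_panel(seed = 9)
  par <- bouton_params(n_rois = 400, seed = 9)
  tensor <- simulate_bouton_tensor(panel, par)
  # designed responder fraction: every stimulus within (a hair beyond) the
  # 99% binomial CI of the target density, with no trend across sizes
  design_frac <- colMeans(tensor$truth != 0)
  half <- 2.576 * sqrt(0.278 * (1 - 0.278) / 400)
  expect_true(all(abs(design_frac - 0.278) < half + 0.02))
  expect_lt(abs(mean(design_frac) - 0.278), 0.01)
  by_size <- vapply(c(1, 2, 4, 8, 12), function(sz)
    mean(design_frac[panel$n_components == sz]), numeric(1))
  expect_lt(max(by_size) - min(by_size), 0.05)
  # conserved per-ROI polarity: designed tuning is never mixed
  sign_ok <- apply(tensor$truth, 1, function(r)
    all(r >= 0) || all(r <= 0))
  expect_true(all(sign_ok))
  pol <- polarity_class(classify_responses(tensor))
  expect_lt(mean(pol == "mixed"), 0.35)
  expect_identical(simulate_bouton_tensor(panel, par)$amplitudes,
                   tensor$amplitudes)
})

test_that("bouton tensors are less reliable across trials than OSN tensors", {
  panel <- make_mixture_panel(seed = 10)
  osn <- simulate_osn_tensor(panel, osn_params(seed = 10))
  bouton <- simulate_bouton_tensor(panel, bouton_params(seed = 10))
  rel_osn <- mean(within_stimulus_reliability(
    representational_similarity(osn, "trial")), na.rm = TRUE)
  rel_bouton <- mean(within_stimulus_reliability(
    representational_similarity(bouton, "trial")), na.rm = TRUE)
  expect_gt(rel_osn, rel_bouton)
  expect_gt(rel_osn, 0.65)
  expect_lt(rel_bouton, 0.65)
})

test_that("circuit-derived bouton tensors inherit nonmonotonic tuning", {
  panel <- make_concentration_panel()
  spec <- small_circuit(n_cortical = 300, n_glomeruli = 100, seed = 11,
                        duration = 15)
  par <- bouton_params(n_rois = 200, trial_noise_sd = 0.02,
                       derive_from_circuit = spec, seed = 11)
  tensor <- simulate_bouton_tensor(panel, par)
  expect_identical(tensor$population_label, "bouton")
  tm <- apply(tensor$amplitudes, c(1, 2), mean)
  flags <- detect_nonmonotonicity(tm)
  expect_gt(sum(flags$nonmonotonic), 0)
  # mixture panels are not supported in circuit mode
  expect_error(
    simulate_bouton_tensor(make_mixture_panel(seed = 1), par),
    "concentration")
})

test_that("adjacent-concentration similarity increases with concentration", {
  panel <- make_concentration_panel()
  osn <- simulate_osn_tensor(panel, osn_params(n_rois = 300, seed = 12))
  sim <- stimulus_level(representational_similarity(osn, "trial"))
  adjacent <- sim$entries[cbind(1:7, 2:8)]
  # rising trend: the top end of the series is more similar than the bottom
  expect_gt(mean(adjacent[5:7]), mean(adjacent[1:3]))
  expect_gt(cor(seq_along(adjacent), adjacent, method = "spearman"), 0)
})
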