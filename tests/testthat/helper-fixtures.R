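# Shared fixtures: small panels, hand-built tensors and a desk-sized
# circuit whose inhibition threshold is scaled to its population size.

tiny_panel <- function(n = 4L) {
  stimulus_panel(
    id = sprintf("od%02d", seq_len(n)),
    kind = rep("odorant", n),
    components = as.list(seq_len(n))
  )
}

# tensor with fully controlled amplitudes: base (ROI x stimulus) repeated
# over trials plus optional fixed offsets, blanks with known spread
manual_tensor <- function(base, n_trials = 3L, blank_sd = 0.1,
                          n_blanks = 6L, noise_sd = 0, seed = 1L,
                          label = "OSN") {
  set.seed(seed)
  n_r <- nrow(base)
  n_s <- ncol(base)
  amp <- array(rep(base, times = n_trials),
               dim = c(n_r, n_s, n_trials))
  if (noise_sd > 0) {
    amp <- amp + array(rnorm(length(amp), 0, noise_sd), dim = dim(amp))
  }
  blanks <- matrix(rnorm(n_r * n_blanks, 0, blank_sd), nrow = n_r)
  response_tensor(amp, blanks, tiny_panel(n_s), population_label = label)
}

small_circuit <- function(n_cortical = 200L, n_glomeruli = 100L,
                          w_inh = 1, beta = 2, v_thr = NULL,
                          dt = 0.01, duration = 20, seed = 7L,
                          interneurons = NULL) {
  panel <- sample_glomerular_panel(n_glomeruli, seed = seed)
  proj <- sample_projection(n_cortical, n_glomeruli, seed = seed + 1L)
  if (is.null(v_thr)) v_thr <- 2000 * n_cortical / 5000
  if (is.null(interneurons)) {
    interneurons <- interneuron_population(w_inh, beta, v_thr)
  }
  circuit_spec(panel, proj, interneurons, dt = dt, duration = duration)
}
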