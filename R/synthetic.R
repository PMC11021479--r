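# Synthetic response-tensor generators. They emulate the statistical
# structure the analyses assume: OSN response density grows sublinearly
# with mixture size and sigmoidally with concentration; bouton response
# density is stimulus-independent; boutons are noisier across trials; a
# minority of responses in both populations are suppressed.

#' Parameters for the OSN tensor generator
#'
#' Samples each ROI's per-component sensitivity profile (sparse, log-normal
#' magnitudes), a tuning polarity (a minority of ROIs respond with
#' suppression), and per-ROI Hill midpoints for concentration series.
#' Mixture responses pass the summed component drive through a saturating
#' nonlinearity (\code{additive_saturating}, default) or a
#' competitive-binding rule in which some bound components fail to activate
#' (\code{antagonistic}); both make density grow sublinearly with mixture
#' size.
#'
#' @param n_rois number of ROIs (default 400)
#' @param n_components component alphabet size (default 16)
#' @param sensitivity_prob probability an ROI is sensitive to a given
#'   component (default 0.15)
#' @param sensitivity_meanlog,sensitivity_sdlog log-normal parameters of the
#'   non-zero sensitivities
#' @param mixture_rule "additive_saturating" or "antagonistic"
#' @param agonist_prob probability a bound component activates (antagonistic
#'   rule only; default 0.6)
#' @param hill_slope Hill coefficient for concentration tuning (default 1.5)
#' @param hill_midpoint_range log-uniform range of per-ROI Hill midpoints,
#'   in relative-concentration units (default 0.003 to 0.3)
#' @param suppressed_fraction fraction of ROIs with suppressed (negative)
#'   tuning (default 0.1)
#' @param trial_noise_sd additive Gaussian trial noise, dF/F units
#'   (default 0.13, set so that within-stimulus trial reliability is about
#'   0.78)
#' @param n_trials trials per stimulus (default 3)
#' @param n_blank_trials blank trials per ROI (default 6)
#' @param seed integer seed or NULL
#' @return an object of class \code{osn_params} carrying the sampled
#'   sensitivity matrix, polarity signs and Hill midpoints
#' @export
osn_params <- function(n_rois = 400L, n_components = 16L,
                       sensitivity_prob = 0.15,
                       sensitivity_meanlog = log(0.6),
                       sensitivity_sdlog = 0.8,
                       mixture_rule = c("additive_saturating",
                                        "antagonistic"),
                       agonist_prob = 0.6,
                       hill_slope = 1.5,
                       hill_midpoint_range = c(0.003, 0.3),
                       suppressed_fraction = 0.1,
                       trial_noise_sd = 0.13,
                       n_trials = 3L, n_blank_trials = 6L, seed = NULL) {
  n_rois <- check_count(n_rois, "n_rois")
  n_components <- check_count(n_components, "n_components")
  sensitivity_prob <- check_prob(sensitivity_prob, "sensitivity_prob")
  suppressed_fraction <- check_prob(suppressed_fraction,
                                    "suppressed_fraction")
  trial_noise_sd <- check_positive(trial_noise_sd, "trial_noise_sd")
  n_trials <- check_count(n_trials, "n_trials")
  n_blank_trials <- check_count(n_blank_trials, "n_blank_trials")
  mixture_rule <- match.arg(mixture_rule)
  with_seed(derive_seed(seed, "osn"), {
    sens <- matrix(
      stats::rlnorm(n_rois * n_components, sensitivity_meanlog,
                    sensitivity_sdlog) *
        (stats::runif(n_rois * n_components) < sensitivity_prob),
      nrow = n_rois, ncol = n_components
    )
    agonist <- matrix(
      stats::runif(n_rois * n_components) < agonist_prob,
      nrow = n_rois, ncol = n_components
    )
    sign <- ifelse(stats::runif(n_rois) < suppressed_fraction, -1, 1)
    lo <- log(hill_midpoint_range[1L])
    hi <- log(hill_midpoint_range[2L])
    midpoints <- exp(stats::runif(n_rois, lo, hi))
    structure(
      list(n_rois = n_rois, n_components = n_components,
           sensitivity = sens, agonist = agonist, sign = sign,
           hill_midpoints = midpoints, hill_slope = hill_slope,
           mixture_rule = mixture_rule,
           suppressed_fraction = suppressed_fraction,
           trial_noise_sd = trial_noise_sd, n_trials = n_trials,
           n_blank_trials = n_blank_trials, seed = seed),
      class = "osn_params"
    )
  })
}

# noiseless ROI x stimulus response matrix for OSN-like tuning
osn_noiseless <- function(panel, params) {
  n_s <- n_stimuli(panel)
  out <- matrix(0, params$n_rois, n_s)
  for (s in seq_len(n_s)) {
    comps <- panel$components[[s]]
    if (panel$kind[s] == "concentration_step") {
      a <- params$sensitivity[, comps[1L]]
      c_rel <- panel$rel_concentration[s]
      h <- params$hill_slope
      out[, s] <- a * c_rel^h / (c_rel^h + params$hill_midpoints^h)
    } else {
      sub <- params$sensitivity[, comps, drop = FALSE]
      total <- rowSums(sub)
      if (params$mixture_rule == "additive_saturating") {
        out[, s] <- total / (1 + total)
      } else {
        act <- rowSums(sub * params$agonist[, comps, drop = FALSE])
        out[, s] <- act / (1 + total)
      }
    }
  }
  out * params$sign
}

#' Simulate an OSN response tensor
#'
#' Builds the noiseless tuning of every ROI to every stimulus (see
#' \code{\link{osn_params}}), then adds i.i.d. Gaussian trial noise; blank
#' trials are pure noise around zero.
#'
#' @param panel a \code{stimulus_panel}
#' @param params an \code{osn_params}
#' @return a \code{response_tensor} with population label "OSN"
#' @export
#' @examples
#' panel <- make_mixture_panel(seed = 1)
#' tensor <- simulate_osn_tensor(panel, osn_params(n_rois = 50, seed = 1))
simulate_osn_tensor <- function(panel, params) {
  stopifnot(inherits(panel, "stimulus_panel"),
            inherits(params, "osn_params"))
  base <- osn_noiseless(panel, params)
  with_seed(derive_seed(params$seed, "osn") + 1L, {
    build_tensor(base, params, panel, "OSN")
  })
}

# shared trial/blank assembly (expects an active seed context)
build_tensor <- function(base, params, panel, label) {
  n_r <- nrow(base)
  n_s <- ncol(base)
  n_t <- params$n_trials
  amp <- array(rep(base, times = n_t), dim = c(n_r, n_s, n_t)) +
    array(stats::rnorm(n_r * n_s * n_t, 0, params$trial_noise_sd),
          dim = c(n_r, n_s, n_t))
  blanks <- matrix(stats::rnorm(n_r * params$n_blank_trials, 0,
                                params$trial_noise_sd),
                   nrow = n_r)
  response_tensor(amp, blanks, panel, population_label = label,
                  truth = base)
}

#' Parameters for the bouton tensor generator
#'
#' In direct mode each stimulus independently recruits a random subset of
#' ROIs at a stimulus-independent target density, with log-normal response
#' magnitudes and a conserved per-ROI polarity. In circuit mode responses
#' are produced by simulating the bulb-to-cortex circuit on the panel's
#' concentration series (see \code{\link{simulate_bouton_tensor}}).
#'
#' @param n_rois number of ROIs (default 800)
#' @param response_density per-stimulus probability that an ROI responds
#'   (default 0.278, the pooled responding fraction per odorant)
#' @param enhanced_prop probability an ROI's conserved polarity is enhanced
#'   rather than suppressed (default 0.446)
#' @param amp_meanlog,amp_sdlog log-normal parameters of response magnitudes
#' @param decorrelate if TRUE (default) each stimulus recruits an
#'   independent ROI subset; if FALSE, recruitment probability varies by ROI
#'   so tuning is correlated across stimuli
#' @param trial_noise_sd additive Gaussian trial noise (default 0.25, set so
#'   that within-stimulus trial reliability is about 0.53)
#' @param n_trials trials per stimulus (default 3)
#' @param n_blank_trials blank trials per ROI (default 6)
#' @param derive_from_circuit optional \code{circuit_spec}; when given,
#'   responses come from the rate model instead of the direct sampler
#' @param circuit_concentrations model-unit concentrations for the panel's
#'   steps (default log-spaced 1e-3 to 1e3)
#' @param seed integer seed or NULL
#' @return an object of class \code{bouton_params}
#' @export
bouton_params <- function(n_rois = 800L, response_density = 0.278,
                          enhanced_prop = 0.446,
                          amp_meanlog = log(0.4), amp_sdlog = 0.5,
                          decorrelate = TRUE,
                          trial_noise_sd = 0.25,
                          n_trials = 3L, n_blank_trials = 6L,
                          derive_from_circuit = NULL,
                          circuit_concentrations = NULL, seed = NULL) {
  n_rois <- check_count(n_rois, "n_rois")
  response_density <- check_prob(response_density, "response_density")
  if (response_density == 0 || response_density == 1) {
    stop("`response_density` must be in (0, 1)", call. = FALSE)
  }
  enhanced_prop <- check_prob(enhanced_prop, "enhanced_prop")
  trial_noise_sd <- check_positive(trial_noise_sd, "trial_noise_sd")
  n_trials <- check_count(n_trials, "n_trials")
  n_blank_trials <- check_count(n_blank_trials, "n_blank_trials")
  if (!is.null(derive_from_circuit)) {
    stopifnot(inherits(derive_from_circuit, "circuit_spec"))
  }
  structure(
    list(n_rois = n_rois, response_density = response_density,
         enhanced_prop = enhanced_prop, amp_meanlog = amp_meanlog,
         amp_sdlog = amp_sdlog, decorrelate = decorrelate,
         trial_noise_sd = trial_noise_sd, n_trials = n_trials,
         n_blank_trials = n_blank_trials,
         derive_from_circuit = derive_from_circuit,
         circuit_concentrations = circuit_concentrations, seed = seed),
    class = "bouton_params"
  )
}

#' Simulate a bouton (cortical feedback) response tensor
#'
#' Direct mode: every stimulus recruits ROIs at the same target density, so
#' response density, sparseness and mixture-mixture similarity are flat
#' across stimulus classes by construction; per-ROI polarity is conserved
#' across the panel. Circuit mode (when \code{params$derive_from_circuit}
#' is set and the panel is a concentration series): bouton responses are the
#' steady-state outputs of the rate model at each concentration, rescaled to
#' dF/F-like units, which inherits the model's nonmonotonic tuning.
#'
#' @param panel a \code{stimulus_panel}
#' @param params a \code{bouton_params}
#' @return a \code{response_tensor} with population label "bouton"
#' @export
simulate_bouton_tensor <- function(panel, params) {
  stopifnot(inherits(panel, "stimulus_panel"),
            inherits(params, "bouton_params"))
  if (!is.null(params$derive_from_circuit)) {
    return(bouton_tensor_from_circuit(panel, params))
  }
  n_r <- params$n_rois
  n_s <- n_stimuli(panel)
  with_seed(derive_seed(params$seed, "bouton"), {
    sign <- ifelse(stats::runif(n_r) < params$enhanced_prop, 1, -1)
    if (params$decorrelate) {
      p_respond <- matrix(params$response_density, n_r, n_s)
    } else {
      # per-ROI propensity with the target mean density
      prop <- stats::rbeta(n_r, 2, 2)
      prop <- prop * params$response_density / mean(prop)
      p_respond <- matrix(pmin(prop, 1), n_r, n_s)
    }
    mask <- matrix(stats::runif(n_r * n_s), n_r, n_s) < p_respond
    amp <- matrix(stats::rlnorm(n_r * n_s, params$amp_meanlog,
                                params$amp_sdlog), n_r, n_s)
    base <- sign * (mask * amp)
    build_tensor(base, params, panel, "bouton")
  })
}

bouton_tensor_from_circuit <- function(panel, params) {
  if (!all(panel$kind == "concentration_step")) {
    stop("circuit mode requires a concentration-series panel",
         call. = FALSE)
  }
  spec <- params$derive_from_circuit
  if (params$n_rois > spec$n_cortical) {
    stop("`n_rois` exceeds the circuit's cortical population",
         call. = FALSE)
  }
  conc <- params$circuit_concentrations
  if (is.null(conc)) {
    conc <- 10^seq(-3, 3, length.out = n_stimuli(panel))
  }
  if (length(conc) != n_stimuli(panel)) {
    stop("`circuit_concentrations` must match the panel length",
         call. = FALSE)
  }
  curves <- dose_response(spec, conc)
  with_seed(derive_seed(params$seed, "bouton"), {
    rois <- sample.int(spec$n_cortical, params$n_rois)
    base <- curves$responses[rois, , drop = FALSE]
    peak <- max(base)
    if (peak > 0) base <- base / peak  # rescale to dF/F-like units
    build_tensor(base, params, panel, "bouton")
  })
}
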