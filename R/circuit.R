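# Bulb-to-cortex rate model with global activity-dependent inhibition.
#
# Glomerular output follows receptor-binding saturation,
#   x_i(c) = eta_i * kappa_i c / (1 + kappa_i c),
# and cortical voltages integrate
#   tau du_j/dt = -u_j - <w_inh sigma(beta (v - v_thr))> + sum_i W_ji x_i
#   tau dv_k/dt = -v_k + sum_j max(u_j, 0)
# with the logistic sigma. All times are expressed in units of the membrane
# time constant tau, so tau never appears explicitly in the integrator.

#' Sample a glomerular panel
#'
#' Draws per-glomerulus binding affinities and binary activation efficacies
#' for one odorant. Log-affinities are i.i.d. normal with mean zero, so the
#' default standard deviation of 3 (natural log) spans roughly three orders
#' of magnitude of affinity; efficacies are i.i.d. Bernoulli, so with the
#' default probability 0.2 an odorant drives about 20% of glomeruli at
#' saturating concentration.
#'
#' @param n_glomeruli number of glomeruli (default 400)
#' @param log_affinity_sd standard deviation of the natural-log affinities
#'   (default 3)
#' @param activation_prob Bernoulli probability that a glomerulus is
#'   activated by the odorant (default 0.2)
#' @param seed integer seed for reproducibility, or NULL
#' @return an object of class \code{glomerular_panel} with fields
#'   \code{n_glomeruli}, \code{log_affinities}, \code{efficacies}, \code{seed}
#' @export
#' @examples
#' panel <- sample_glomerular_panel(400, seed = 1)
#' mean(panel$efficacies)  # ~0.2
sample_glomerular_panel <- function(n_glomeruli = 400L, log_affinity_sd = 3,
                                    activation_prob = 0.2, seed = NULL) {
  n_glomeruli <- check_count(n_glomeruli, "n_glomeruli")
  log_affinity_sd <- check_positive(log_affinity_sd, "log_affinity_sd")
  activation_prob <- check_prob(activation_prob, "activation_prob")
  with_seed(seed, {
    structure(
      list(
        n_glomeruli = n_glomeruli,
        log_affinities = stats::rnorm(n_glomeruli, 0, log_affinity_sd),
        efficacies = stats::rbinom(n_glomeruli, 1L, activation_prob),
        seed = seed
      ),
      class = "glomerular_panel"
    )
  })
}

#' Glomerular output at a given odorant concentration
#'
#' Evaluates the saturating binding curve
#' \eqn{x_i(c) = \eta_i \kappa_i c / (1 + \kappa_i c)} for every glomerulus.
#' Each output lies in \[0, eta_i\] and is monotone nondecreasing in
#' concentration.
#'
#' @param panel a \code{glomerular_panel}
#' @param concentration scalar odorant concentration, >= 0 (in units of
#'   inverse affinity)
#' @return numeric vector of length \code{panel$n_glomeruli}
#' @export
glomerular_output <- function(panel, concentration) {
  stopifnot(inherits(panel, "glomerular_panel"))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    stop("`concentration` must be a single non-negative number",
         call. = FALSE)
  }
  kappa <- exp(panel$log_affinities)
  panel$efficacies * kappa * concentration / (1 + kappa * concentration)
}

#' Sample the bulb-to-cortex projection matrix
#'
#' Entries are independently zero with probability \code{1 - density};
#' non-zero entries are drawn from a positive half-normal distribution with
#' the given scale. The sparse random projection gives each cortical neuron
#' a distinct mix of glomerular inputs.
#'
#' @param n_cortical number of cortical neurons (rows; default 5000)
#' @param n_glomeruli number of glomeruli (columns; default 400)
#' @param density probability that an entry is non-zero (default 0.1)
#' @param scale half-normal scale of the non-zero entries (default 0.5)
#' @param seed integer seed or NULL
#' @return an object of class \code{projection_matrix} with fields
#'   \code{weights} (dense n_cortical x n_glomeruli matrix), \code{density},
#'   \code{scale}, \code{seed}
#' @export
sample_projection <- function(n_cortical = 5000L, n_glomeruli = 400L,
                              density = 0.1, scale = 0.5, seed = NULL) {
  n_cortical <- check_count(n_cortical, "n_cortical")
  n_glomeruli <- check_count(n_glomeruli, "n_glomeruli")
  density <- check_prob(density, "density")
  if (density == 0) stop("`density` must be > 0", call. = FALSE)
  scale <- check_positive(scale, "scale")
  with_seed(seed, {
    n <- n_cortical * n_glomeruli
    w <- abs(stats::rnorm(n, 0, scale)) *
      (stats::runif(n) < density)
    structure(
      list(
        weights = matrix(w, nrow = n_cortical, ncol = n_glomeruli),
        density = density, scale = scale, seed = seed
      ),
      class = "projection_matrix"
    )
  })
}

#' Construct an interneuron population
#'
#' @param w_inh inhibitory weight(s), >= 0
#' @param beta sigmoid steepness(es), > 0
#' @param v_thr activation threshold(s)
#' @return an object of class \code{interneuron_population} holding equal-
#'   length parameter vectors and \code{n_interneurons}
#' @export
interneuron_population <- function(w_inh = 1, beta = 2, v_thr = 2000) {
  n <- max(length(w_inh), length(beta), length(v_thr))
  w_inh <- rep_len(as.numeric(w_inh), n)
  beta <- rep_len(as.numeric(beta), n)
  v_thr <- rep_len(as.numeric(v_thr), n)
  if (any(w_inh < 0)) stop("all `w_inh` must be >= 0", call. = FALSE)
  if (any(beta <= 0)) stop("all `beta` must be > 0", call. = FALSE)
  structure(
    list(w_inh = w_inh, beta = beta, v_thr = v_thr, n_interneurons = n),
    class = "interneuron_population"
  )
}

#' Jitter interneuron parameters to form a heterogeneous population
#'
#' Each interneuron's (w_inh, beta, v_thr) is the base triple scaled
#' elementwise by independent factors \eqn{1 + \epsilon},
#' \eqn{\epsilon \sim N(0, jitter\_sd^2)}. Negative products (vanishingly
#' rare at the default sd of 0.2) are clipped to zero, since negative
#' weights or thresholds are unphysical.
#'
#' @param base named numeric vector or list with elements \code{w_inh},
#'   \code{beta}, \code{v_thr}
#' @param n_interneurons population size (default 500)
#' @param jitter_sd standard deviation of the multiplicative jitter
#'   (default 0.2)
#' @param seed integer seed or NULL
#' @return an \code{interneuron_population}
#' @export
make_heterogeneous_interneurons <- function(base = c(w_inh = 1, beta = 2,
                                                     v_thr = 2000),
                                            n_interneurons = 500L,
                                            jitter_sd = 0.2, seed = NULL) {
  n_interneurons <- check_count(n_interneurons, "n_interneurons")
  if (!is.numeric(jitter_sd) || jitter_sd < 0) {
    stop("`jitter_sd` must be >= 0", call. = FALSE)
  }
  base <- as.list(base)
  with_seed(seed, {
    jit <- function(x) {
      out <- x * (1 + stats::rnorm(n_interneurons, 0, jitter_sd))
      pmax(out, 0)
    }
    w <- jit(base$w_inh)
    b <- jit(base$beta)
    # a beta jittered exactly to 0 would be degenerate; keep it positive
    b[b == 0] <- .Machine$double.eps
    interneuron_population(w, b, jit(base$v_thr))
  })
}

#' Assemble a circuit specification
#'
#' Bundles the glomerular panel, projection matrix and interneuron
#' population with the integration settings. Times (dt, duration,
#' latencies) are in units of the membrane time constant tau.
#'
#' @param panel a \code{glomerular_panel}
#' @param projection a \code{projection_matrix}; its column count must equal
#'   \code{panel$n_glomeruli}
#' @param interneurons an \code{interneuron_population}
#' @param dt forward-Euler step, in units of tau; must be in (0, 0.1]
#' @param duration total simulated time, in units of tau; must be >= 10
#' @return an object of class \code{circuit_spec}
#' @export
circuit_spec <- function(panel, projection,
                         interneurons = interneuron_population(),
                         dt = 0.01, duration = 20) {
  stopifnot(inherits(panel, "glomerular_panel"),
            inherits(projection, "projection_matrix"),
            inherits(interneurons, "interneuron_population"))
  if (ncol(projection$weights) != panel$n_glomeruli) {
    stop("projection has ", ncol(projection$weights),
         " columns but the panel has ", panel$n_glomeruli, " glomeruli",
         call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0 || dt > 0.1) {
    stop("`dt` must be in (0, 0.1] (units of tau)", call. = FALSE)
  }
  if (!is.numeric(duration) || duration < 10) {
    stop("`duration` must be >= 10 (units of tau)", call. = FALSE)
  }
  structure(
    list(
      n_cortical = nrow(projection$weights),
      panel = panel, projection = projection, interneurons = interneurons,
      dt = dt, duration = duration
    ),
    class = "circuit_spec"
  )
}

# One forward-Euler integration from zero initial conditions under a
# constant glomerular drive. Shared by simulate_circuit (full trace) and
# dose_response (summary only) so the heavy loop exists once.
euler_integrate <- function(spec, drive, keep_trace = TRUE,
                            guard = 1e6) {
  dt <- spec$dt
  n_steps <- as.integer(round(spec$duration / dt))
  time_grid <- seq(0, by = dt, length.out = n_steps + 1L)
  inter <- spec$interneurons
  n_c <- spec$n_cortical
  n_i <- inter$n_interneurons

  u <- numeric(n_c)
  v <- numeric(n_i)
  if (keep_trace) {
    u_tr <- matrix(0, n_c, n_steps + 1L)
    v_tr <- matrix(0, n_i, n_steps + 1L)
  }
  # summary accumulators: steady state = mean of y over the final 20% of
  # timepoints; latency = first crossing of a fraction of steady state
  tail_start <- n_steps + 1L - as.integer(ceiling(0.2 * (n_steps + 1L))) + 1L
  y_sum_tail <- numeric(n_c)
  y_hist <- if (!keep_trace) matrix(0, n_c, n_steps + 1L) else NULL

  for (k in seq_len(n_steps)) {
    y <- pmax(u, 0)
    inh <- mean(inter$w_inh *
                  stats::plogis(inter$beta * (v - inter$v_thr)))
    sum_y <- sum(y)
    u <- u + dt * (-u - inh + drive)
    v <- v + dt * (-v + sum_y)
    if (anyNA(u) || max(abs(u)) > guard) {
      stop("numerical instability: |u| exceeded ", guard,
           "; reduce `dt`", call. = FALSE)
    }
    if (keep_trace) {
      u_tr[, k + 1L] <- u
      v_tr[, k + 1L] <- v
    } else {
      y_hist[, k + 1L] <- pmax(u, 0)
    }
    if (k + 1L >= tail_start) y_sum_tail <- y_sum_tail + pmax(u, 0)
  }

  n_tail <- n_steps + 2L - tail_start
  steady <- y_sum_tail / n_tail

  if (keep_trace) {
    list(time_grid = time_grid, u = u_tr, v = v_tr, steady = steady)
  } else {
    list(time_grid = time_grid, y = y_hist, steady = steady)
  }
}

#' Simulate the circuit at one concentration
#'
#' Integrates the cortical and interneuron voltage dynamics by forward Euler
#' from zero initial conditions under a step glomerular input switched on at
#' t = 0 and held constant. The global inhibition applied to every cortical
#' neuron is the interneuron-population mean of the individual
#' \eqn{w_{inh} \sigma(\beta (v_k - v_{thr}))} terms, which reduces to the
#' single-interneuron term for a homogeneous population.
#'
#' @param spec a \code{circuit_spec}
#' @param concentration odorant concentration, >= 0
#' @return an object of class \code{simulation_trace} with fields
#'   \code{time_grid}, \code{u} (cortical voltages, neurons x timepoints),
#'   \code{v} (interneuron voltages), \code{y} (rectified outputs),
#'   \code{x} (constant glomerular input), \code{concentration}
#' @export
simulate_circuit <- function(spec, concentration) {
  stopifnot(inherits(spec, "circuit_spec"))
  x <- glomerular_output(spec$panel, concentration)
  drive <- as.vector(spec$projection$weights %*% x)
  res <- euler_integrate(spec, drive, keep_trace = TRUE)
  structure(
    list(
      time_grid = res$time_grid, u = res$u, v = res$v,
      y = pmax(res$u, 0), x = x, concentration = concentration,
      dt = spec$dt
    ),
    class = "simulation_trace"
  )
}

#' Steady-state response of each cortical neuron
#'
#' The response readout is the mean rectified output over the final 20% of
#' the trace, which is robust to residual oscillation from the inhibitory
#' loop.
#'
#' @param trace a \code{simulation_trace}
#' @return numeric vector, one value per cortical neuron
#' @export
steady_state_response <- function(trace) {
  stopifnot(inherits(trace, "simulation_trace"))
  n_t <- ncol(trace$y)
  tail_idx <- seq.int(n_t - ceiling(0.2 * n_t) + 1L, n_t)
  rowMeans(trace$y[, tail_idx, drop = FALSE])
}

#' Response latency of cortical neurons
#'
#' Latency is the first time at which the rectified output reaches the given
#' fraction (default half) of its steady-state value, in units of tau.
#' Neurons with zero steady-state response get NA (no response).
#'
#' @param trace a \code{simulation_trace}
#' @param neuron neuron index or vector of indices; NULL (default) for all
#' @param fraction threshold fraction of steady state, in (0, 1)
#' @return numeric vector of latencies (NA where the neuron never responds)
#' @export
response_latency <- function(trace, neuron = NULL, fraction = 0.5) {
  stopifnot(inherits(trace, "simulation_trace"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  steady <- steady_state_response(trace)
  if (is.null(neuron)) neuron <- seq_along(steady)
  latency_from_history(trace$y[neuron, , drop = FALSE], trace$time_grid,
                       steady[neuron], fraction)
}

# first-crossing latencies given a rectified-output history matrix
latency_from_history <- function(y, time_grid, steady, fraction) {
  thr <- fraction * steady
  out <- rep(NA_real_, length(steady))
  resp <- which(steady > 0)
  if (length(resp)) {
    hit <- y[resp, , drop = FALSE] >= thr[resp]
    idx <- apply(hit, 1L, function(r) which(r)[1L])
    out[resp] <- time_grid[idx]
  }
  out
}

#' Dose-response curves over a concentration grid
#'
#' Runs the circuit at each concentration and records every neuron's
#' steady-state response and latency.
#'
#' @param spec a \code{circuit_spec}
#' @param concentrations strictly increasing positive concentrations
#' @return an object of class \code{dose_response_curve} with
#'   \code{concentrations}, \code{responses} (neurons x concentrations) and
#'   \code{latencies} (same shape; NA where a neuron never responds)
#' @export
dose_response <- function(spec, concentrations) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (!is.numeric(concentrations) || length(concentrations) < 1L ||
      any(concentrations <= 0) || is.unsorted(concentrations,
                                              strictly = TRUE)) {
    stop("`concentrations` must be strictly increasing and positive",
         call. = FALSE)
  }
  n_c <- spec$n_cortical
  k <- length(concentrations)
  responses <- matrix(0, n_c, k)
  latencies <- matrix(NA_real_, n_c, k)
  for (j in seq_len(k)) {
    x <- glomerular_output(spec$panel, concentrations[j])
    drive <- as.vector(spec$projection$weights %*% x)
    res <- euler_integrate(spec, drive, keep_trace = FALSE)
    responses[, j] <- res$steady
    latencies[, j] <- latency_from_history(res$y, res$time_grid,
                                           res$steady, 0.5)
  }
  structure(
    list(concentrations = concentrations, responses = responses,
         latencies = latencies),
    class = "dose_response_curve"
  )
}

#' Default log-spaced concentration grid
#'
#' 24 points log-spaced over 1e-3 to 1e3 in affinity-relative units,
#' covering roughly three orders of magnitude on either side of the median
#' affinity.
#'
#' @param n number of points (default 24)
#' @param cmin,cmax grid endpoints
#' @return numeric vector
#' @export
default_concentration_grid <- function(n = 24L, cmin = 1e-3, cmax = 1e3) {
  10^seq(log10(cmin), log10(cmax), length.out = n)
}

#' Detect nonmonotonic dose-response curves
#'
#' A curve is nonmonotonic when some response falls below an earlier
#' (lower-concentration) response by more than \code{rel_tol} times the
#' curve maximum — the rise-dip-recover signature of activity-dependent
#' global inhibition. The reported dip is the point with the deepest drop
#' below the running maximum.
#'
#' @param responses numeric vector (one neuron's responses over increasing
#'   concentrations) or a neurons x concentrations matrix
#' @param rel_tol dip depth threshold relative to the curve maximum
#'   (default 0.1)
#' @return for a vector: list with \code{nonmonotonic} (logical),
#'   \code{dip_index} (NA when monotonic), \code{depth}; for a matrix: a
#'   data.frame with one row per neuron
#' @export
detect_nonmonotonicity <- function(responses, rel_tol = 0.1) {
  if (is.matrix(responses)) {
    rows <- lapply(seq_len(nrow(responses)), function(i) {
      r <- detect_nonmonotonicity(responses[i, ], rel_tol)
      data.frame(neuron = i, nonmonotonic = r$nonmonotonic,
                 dip_index = r$dip_index, depth = r$depth)
    })
    return(do.call(rbind, rows))
  }
  if (length(responses) < 3L) {
    stop("need at least 3 concentration points", call. = FALSE)
  }
  run_max <- cummax(responses)
  depth <- c(0, run_max[-length(responses)] - responses[-1L])
  peak <- max(responses)
  deepest <- max(depth)
  flag <- peak > 0 && deepest > rel_tol * peak
  list(
    nonmonotonic = flag,
    dip_index = if (flag) which.max(depth) else NA_integer_,
    depth = deepest
  )
}
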