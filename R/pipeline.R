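# Calcium-response analysis: blank-trial significance classification,
# polarity classes, tuning breadth, sparseness, ranked tuning curves,
# representational similarity, trial reliability and mixture overlap.

#' Construct a response tensor
#'
#' Container for dF/F response amplitudes (the mean signal in a fixed window
#' after odorant onset, one value per ROI x stimulus x trial) together with
#' blank (no-odorant) trial amplitudes and the stimulus panel.
#'
#' @param amplitudes numeric array, ROI x stimulus x trial; no missing values
#' @param blank_amplitudes numeric matrix, ROI x blank trial (>= 1 column)
#' @param panel a \code{stimulus_panel} with one entry per stimulus
#' @param roi_ids optional character vector of ROI identifiers
#' @param population_label "OSN" or "bouton"
#' @param truth optional ROI x stimulus matrix of noiseless (ground-truth)
#'   responses, attached by the synthetic generators; kept in memory only
#' @return an object of class \code{response_tensor}
#' @export
response_tensor <- function(amplitudes, blank_amplitudes, panel,
                            roi_ids = NULL,
                            population_label = c("OSN", "bouton"),
                            truth = NULL) {
  population_label <- match.arg(population_label)
  stopifnot(is.array(amplitudes), length(dim(amplitudes)) == 3L)
  if (anyNA(amplitudes)) stop("`amplitudes` must have no missing values",
                              call. = FALSE)
  blank_amplitudes <- as.matrix(blank_amplitudes)
  if (nrow(blank_amplitudes) != dim(amplitudes)[1L] ||
      ncol(blank_amplitudes) < 1L) {
    stop("`blank_amplitudes` must have one row per ROI and >= 1 column",
         call. = FALSE)
  }
  stopifnot(inherits(panel, "stimulus_panel"))
  if (n_stimuli(panel) != dim(amplitudes)[2L]) {
    stop("panel has ", n_stimuli(panel), " stimuli but amplitudes have ",
         dim(amplitudes)[2L], call. = FALSE)
  }
  if (is.null(roi_ids)) {
    roi_ids <- sprintf("roi%04d", seq_len(dim(amplitudes)[1L]))
  }
  if (!is.null(truth) && !identical(dim(truth), dim(amplitudes)[1:2])) {
    stop("`truth` must be an ROI x stimulus matrix", call. = FALSE)
  }
  structure(
    list(amplitudes = amplitudes, blank_amplitudes = blank_amplitudes,
         panel = panel, roi_ids = roi_ids,
         population_label = population_label, truth = truth),
    class = "response_tensor"
  )
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat(sprintf("<response_tensor> %s: %d ROIs x %d stimuli x %d trials, %d blank trials\n",
              x$population_label, d[1L], d[2L], d[3L],
              ncol(x$blank_amplitudes)))
  invisible(x)
}

#' Classify responses against blank-trial noise
#'
#' Each ROI's response threshold is its blank-trial mean plus/minus
#' \code{n_sd} blank-trial standard deviations. The across-trial mean
#' amplitude for each ROI-stimulus pair is labelled \code{enhanced} when it
#' exceeds the upper threshold, \code{suppressed} when it falls below the
#' lower threshold, and \code{nonresponsive} otherwise (strict
#' inequalities). ROIs whose blank trials have zero variance fall back to a
#' threshold built from the pooled blank distribution of all ROIs.
#'
#' @param tensor a \code{response_tensor}
#' @param n_sd number of blank-trial standard deviations (default 3)
#' @return an object of class \code{classified_responses} with \code{labels}
#'   (ROI x stimulus character matrix), \code{thresholds} (ROI x 2 matrix of
#'   low/high), \code{trial_mean}, and \code{pooled_fallback} (logical per
#'   ROI)
#' @export
classify_responses <- function(tensor, n_sd = 3) {
  stopifnot(inherits(tensor, "response_tensor"))
  if (!is.numeric(n_sd) || n_sd < 0) {
    stop("`n_sd` must be >= 0", call. = FALSE)
  }
  blanks <- tensor$blank_amplitudes
  bm <- rowMeans(blanks)
  bs <- apply(blanks, 1L, stats::sd)
  bs[is.na(bs)] <- 0  # single blank trial
  fallback <- bs == 0
  if (any(fallback)) {
    pooled_sd <- stats::sd(as.vector(blanks))
    if (is.na(pooled_sd) || pooled_sd == 0) {
      warning("all blank trials are constant; zero-width thresholds used")
      pooled_sd <- 0
    }
    bs[fallback] <- pooled_sd
  }
  lo <- bm - n_sd * bs
  hi <- bm + n_sd * bs
  trial_mean <- apply(tensor$amplitudes, c(1L, 2L), mean)
  labels <- matrix("nonresponsive", nrow(trial_mean), ncol(trial_mean))
  labels[trial_mean > hi] <- "enhanced"
  labels[trial_mean < lo] <- "suppressed"
  dimnames(labels) <- list(tensor$roi_ids, panel_ids(tensor$panel))
  structure(
    list(labels = labels,
         thresholds = cbind(low = lo, high = hi),
         trial_mean = trial_mean,
         n_sd = n_sd,
         pooled_fallback = fallback),
    class = "classified_responses"
  )
}

#' Keep ROIs with at least one significant response
#'
#' Mirrors the inclusion rule that only ROIs with at least one odorant
#' response significantly above or below baseline enter further analysis.
#' Suppressed responses count as significant.
#'
#' @param classified a \code{classified_responses}
#' @return integer vector of retained ROI indices (possibly empty, with a
#'   warning)
#' @export
filter_rois <- function(classified) {
  stopifnot(inherits(classified, "classified_responses"))
  keep <- unname(which(rowSums(classified$labels != "nonresponsive") > 0L))
  if (length(keep) == 0L) {
    warning("no ROI has a significant response at n_sd = ",
            classified$n_sd)
  }
  keep
}

#' Response-polarity class of each ROI
#'
#' An ROI is \code{pure_enhanced} when it has at least one enhanced and no
#' suppressed response across the panel, \code{pure_suppressed} in the
#' mirror case, \code{mixed} when it has both, and \code{silent} when it has
#' neither.
#'
#' @param classified a \code{classified_responses}
#' @param roi optional ROI index/indices; NULL (default) for all ROIs
#' @return character vector of polarity classes
#' @export
polarity_class <- function(classified, roi = NULL) {
  stopifnot(inherits(classified, "classified_responses"))
  lab <- classified$labels
  if (!is.null(roi)) lab <- lab[roi, , drop = FALSE]
  n_e <- rowSums(lab == "enhanced")
  n_s <- rowSums(lab == "suppressed")
  out <- rep("silent", nrow(lab))
  out[n_e > 0 & n_s == 0] <- "pure_enhanced"
  out[n_s > 0 & n_e == 0] <- "pure_suppressed"
  out[n_e > 0 & n_s > 0] <- "mixed"
  out
}

#' Number of effective odorants per ROI
#'
#' Counts stimuli that drove a response significantly above or below
#' baseline.
#'
#' @inheritParams polarity_class
#' @return integer vector of counts
#' @export
effective_odorant_count <- function(classified, roi = NULL) {
  stopifnot(inherits(classified, "classified_responses"))
  lab <- classified$labels
  if (!is.null(roi)) lab <- lab[roi, , drop = FALSE]
  out <- as.integer(rowSums(lab != "nonresponsive"))
  names(out) <- rownames(lab)
  out
}

# Treves-Rolls style activity ratio: (mean r)^2 / mean(r^2).
sparseness_ratio <- function(r) {
  if (any(r < 0)) {
    stop("sparseness expects non-negative response magnitudes",
         call. = FALSE)
  }
  if (all(r == 0)) {
    warning("all-zero response vector; sparseness undefined")
    return(NA_real_)
  }
  mean(r)^2 / mean(r^2)
}

#' Population sparseness for one stimulus
#'
#' \eqn{PS_j = (\sum_i r_{ij}/n)^2 / \sum_i (r_{ij}^2/n)} over the \eqn{n}
#' ROIs. Values near 1 indicate uniform activity across the population;
#' the minimum 1/n is attained when a single ROI carries all the activity.
#' Inputs are non-negative response magnitudes (take absolute values first
#' so suppressed responses contribute).
#'
#' @param responses non-negative response magnitudes, one per ROI
#' @return sparseness in (0, 1], or NA with a warning for an all-zero vector
#' @export
population_sparseness <- function(responses) sparseness_ratio(responses)

#' Lifetime sparseness for one ROI
#'
#' Same functional form as \code{\link{population_sparseness}} applied
#' across the \eqn{m} stimuli for a single ROI. Values near 1 mean the ROI
#' responds uniformly to all stimuli; values near 1/m mean narrow tuning.
#'
#' @param responses non-negative response magnitudes, one per stimulus
#' @return sparseness in (0, 1], or NA with a warning for an all-zero vector
#' @export
lifetime_sparseness <- function(responses) sparseness_ratio(responses)

#' Sparseness report for a response matrix
#'
#' Computes population sparseness per stimulus (over ROIs) and lifetime
#' sparseness per ROI (over stimuli). By default the absolute trial-mean
#' amplitude is used so suppressed responses contribute magnitude; set
#' \code{signed = TRUE} to pass amplitudes through unchanged (requires
#' non-negative inputs).
#'
#' @param trial_mean ROI x stimulus matrix of trial-mean amplitudes
#' @param signed if FALSE (default), absolute values are taken first
#' @return list with \code{population_sparseness} (per stimulus),
#'   \code{lifetime_sparseness} (per ROI), \code{n} (ROIs), \code{m}
#'   (stimuli)
#' @export
sparseness_report <- function(trial_mean, signed = FALSE) {
  m <- as.matrix(trial_mean)
  if (!signed) m <- abs(m)
  list(
    population_sparseness = suppressWarnings(
      apply(m, 2L, sparseness_ratio)),
    lifetime_sparseness = suppressWarnings(
      apply(m, 1L, sparseness_ratio)),
    n = nrow(m), m = ncol(m)
  )
}

#' Ranked, normalized tuning curve
#'
#' Rank-orders the absolute response values in descending order and
#' normalizes to the largest, so the first element is always 1. Ties keep
#' their original stimulus order (stable sort).
#'
#' @param responses numeric vector of responses (any sign)
#' @return normalized descending curve, or all-NA vector with a warning when
#'   every response is zero
#' @export
ranked_tuning_curve <- function(responses) {
  a <- abs(responses)
  mx <- max(a)
  if (mx == 0) {
    warning("all responses are zero; ranked curve undefined")
    return(rep(NA_real_, length(a)))
  }
  a[order(-a)] / mx
}

#' Distance of each stimulus's ranked population curve from the mean curve
#'
#' For each stimulus the population responses are rank-ordered and
#' normalized (\code{\link{ranked_tuning_curve}} across ROIs), then each
#' curve's mean absolute deviation from the across-stimulus mean curve is
#' returned. Small distances mean the population activity distribution is
#' similar for every stimulus.
#'
#' @param curves stimulus x rank matrix of ranked population curves, or a
#'   ROI x stimulus trial-mean matrix with \code{from_matrix = TRUE}
#' @param from_matrix build the ranked curves from a ROI x stimulus matrix
#' @return numeric vector, one distance per stimulus
#' @export
curve_distance <- function(curves, from_matrix = FALSE) {
  if (from_matrix) {
    m <- as.matrix(curves)
    curves <- t(apply(m, 2L, ranked_tuning_curve))
  }
  curves <- as.matrix(curves)
  if (nrow(curves) < 2L) {
    stop("need at least 2 stimulus curves", call. = FALSE)
  }
  mean_curve <- colMeans(curves)
  apply(curves, 1L, function(cv) mean(abs(cv - mean_curve)))
}

#' Representational similarity matrix
#'
#' Pearson correlation between population response vectors (all retained
#' ROIs) for every pair of stimulus-trial columns (\code{level = "trial"})
#' or trial-averaged stimulus columns (\code{level = "stimulus_mean"}).
#' Zero-variance population vectors give NA entries.
#'
#' @param tensor a \code{response_tensor}
#' @param level "trial" or "stimulus_mean"
#' @param rois optional ROI indices to retain (e.g. from
#'   \code{\link{filter_rois}}); default all
#' @return an object of class \code{similarity_matrix} with \code{entries},
#'   \code{stimulus} (stimulus id per column), \code{trial} (trial index per
#'   column or NA), \code{level}
#' @export
representational_similarity <- function(tensor,
                                        level = c("trial", "stimulus_mean"),
                                        rois = NULL) {
  stopifnot(inherits(tensor, "response_tensor"))
  level <- match.arg(level)
  amp <- tensor$amplitudes
  if (!is.null(rois)) amp <- amp[rois, , , drop = FALSE]
  if (dim(amp)[1L] < 2L) {
    stop("need at least 2 ROIs for population correlations", call. = FALSE)
  }
  ids <- panel_ids(tensor$panel)
  n_s <- dim(amp)[2L]
  n_t <- dim(amp)[3L]
  if (level == "trial") {
    # columns ordered stimulus-major: s1 t1..tT, s2 t1..tT, ...
    m <- matrix(aperm(amp, c(1L, 3L, 2L)), nrow = dim(amp)[1L])
    stim <- rep(ids, each = n_t)
    trial <- rep(seq_len(n_t), times = n_s)
  } else {
    m <- apply(amp, c(1L, 2L), mean)
    stim <- ids
    trial <- rep(NA_integer_, n_s)
  }
  entries <- suppressWarnings(stats::cor(m))
  structure(
    list(entries = entries, stimulus = stim, trial = trial, level = level,
         n_rois = dim(amp)[1L]),
    class = "similarity_matrix"
  )
}

#' Mean trial-to-trial correlation within each stimulus
#'
#' Averages the off-diagonal entries of each stimulus's trial block in a
#' trial-level similarity matrix — the representation reliability metric.
#'
#' @param sim a trial-level \code{similarity_matrix}
#' @return named numeric vector, one value per stimulus (NA where a stimulus
#'   has a single trial or only undefined correlations)
#' @export
within_stimulus_reliability <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (sim$level != "trial") {
    stop("within-stimulus reliability needs a trial-level matrix",
         call. = FALSE)
  }
  stim <- unique(sim$stimulus)
  out <- vapply(stim, function(s) {
    idx <- which(sim$stimulus == s)
    if (length(idx) < 2L) return(NA_real_)
    block <- sim$entries[idx, idx]
    mean(block[upper.tri(block)], na.rm = TRUE)
  }, numeric(1L))
  names(out) <- stim
  out
}

#' Collapse a trial-level similarity matrix to stimulus level
#'
#' Averages the entries across all trial pairs for each stimulus pair
#' (off-diagonal trial pairs for a stimulus with itself).
#'
#' @param sim a trial-level \code{similarity_matrix}
#' @return a stimulus-level \code{similarity_matrix}
#' @export
stimulus_level <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (sim$level != "trial") return(sim)
  stim <- unique(sim$stimulus)
  k <- length(stim)
  out <- matrix(NA_real_, k, k, dimnames = list(stim, stim))
  for (a in seq_len(k)) {
    for (b in seq_len(a)) {
      ia <- which(sim$stimulus == stim[a])
      ib <- which(sim$stimulus == stim[b])
      block <- sim$entries[ia, ib, drop = FALSE]
      if (a == b) {
        vals <- block[upper.tri(block)]
      } else {
        vals <- block
      }
      out[a, b] <- out[b, a] <- mean(vals, na.rm = TRUE)
    }
  }
  diag(out)[is.nan(diag(out))] <- 1
  structure(
    list(entries = out, stimulus = stim,
         trial = rep(NA_integer_, k), level = "stimulus_mean",
         n_rois = sim$n_rois),
    class = "similarity_matrix"
  )
}

#' Leaf ordering from hierarchical clustering of a similarity matrix
#'
#' Average-linkage agglomerative clustering on the distance 1 - r. The
#' returned permutation can be applied to another population's matrix (e.g.
#' order boutons by the OSN-derived clustering) with
#' \code{\link{reorder_similarity}}. NA entries (undefined correlations) are
#' treated as zero correlation.
#'
#' @param sim a stimulus-level \code{similarity_matrix} or a square
#'   correlation matrix
#' @return integer permutation of the stimuli (dendrogram leaf order)
#' @export
hierarchical_order <- function(sim) {
  m <- if (inherits(sim, "similarity_matrix")) sim$entries else as.matrix(sim)
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square",
                               call. = FALSE)
  m[is.na(m)] <- 0
  d <- stats::as.dist(1 - m)
  stats::hclust(d, method = "average")$order
}

#' Reorder a similarity matrix by a stimulus permutation
#'
#' @param sim a \code{similarity_matrix} or square matrix
#' @param order integer permutation (rows and columns permuted identically)
#' @return object of the same type, reordered
#' @export
reorder_similarity <- function(sim, order) {
  if (inherits(sim, "similarity_matrix")) {
    sim$entries <- sim$entries[order, order]
    sim$stimulus <- sim$stimulus[order]
    sim$trial <- sim$trial[order]
    return(sim)
  }
  as.matrix(sim)[order, order]
}

#' Component overlap between two mixtures
#'
#' Shared-component fraction |a intersect b| / max(|a|, |b|) (default), or
#' the Jaccard index |a intersect b| / |a union b|.
#'
#' @param a,b non-empty component sets (vectors of component ids)
#' @param method "max" (default) or "jaccard"
#' @return overlap fraction in \[0, 1\]
#' @export
mixture_overlap <- function(a, b, method = c("max", "jaccard")) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("component sets must be non-empty", call. = FALSE)
  }
  shared <- length(intersect(a, b))
  if (method == "max") shared / max(length(a), length(b))
  else shared / length(union(a, b))
}

#' Compare correlations between high- and low-overlap mixture pairs
#'
#' Restricts to stimuli of the given mixture sizes, splits all pairs at the
#' overlap threshold (>= threshold vs below), and returns the two samples of
#' pairwise stimulus-level correlations with their means.
#'
#' @param sim a stimulus-level \code{similarity_matrix} aligned with
#'   \code{panel}
#' @param panel the \code{stimulus_panel}
#' @param threshold overlap threshold (default 0.75)
#' @param sizes mixture sizes to include (default c(8, 12))
#' @param method overlap definition, see \code{\link{mixture_overlap}}
#' @return list with \code{high}, \code{low} (correlation vectors),
#'   \code{mean_high}, \code{mean_low} (NA when a group is empty), and
#'   \code{n_high}, \code{n_low}
#' @export
overlap_group_comparison <- function(sim, panel, threshold = 0.75,
                                     sizes = c(8L, 12L),
                                     method = c("max", "jaccard")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "stimulus_panel"))
  m <- if (inherits(sim, "similarity_matrix")) {
    if (sim$level == "trial") sim <- stimulus_level(sim)
    sim$entries
  } else as.matrix(sim)
  if (nrow(m) != n_stimuli(panel)) {
    stop("similarity matrix and panel sizes differ", call. = FALSE)
  }
  idx <- which(panel$n_components %in% sizes)
  high <- numeric(0)
  low <- numeric(0)
  if (length(idx) >= 2L) {
    for (a in seq_along(idx)[-1L]) {
      for (b in seq_len(a - 1L)) {
        ov <- mixture_overlap(panel$components[[idx[a]]],
                              panel$components[[idx[b]]], method = method)
        r <- m[idx[a], idx[b]]
        if (is.na(r)) next
        if (ov >= threshold) high <- c(high, r) else low <- c(low, r)
      }
    }
  }
  list(
    high = high, low = low,
    mean_high = if (length(high)) mean(high) else NA_real_,
    mean_low = if (length(low)) mean(low) else NA_real_,
    n_high = length(high), n_low = length(low)
  )
}
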