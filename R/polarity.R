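# Null model for response-polarity classes: if an ROI's responses to the
# odorant panel were drawn independently from the pooled response-label
# distribution, what fraction of ROIs would be purely enhanced, purely
# suppressed or mixed by chance?

#' Validate a polarity probability triple
#'
#' @param p_nonresponsive,p_enhanced,p_suppressed label probabilities; must
#'   be in \[0, 1\] and sum to 1 (tolerance 1e-9)
#' @return named numeric vector of the three probabilities
#' @export
polarity_probabilities <- function(p_nonresponsive, p_enhanced,
                                   p_suppressed) {
  p <- c(nonresponsive = p_nonresponsive, enhanced = p_enhanced,
         suppressed = p_suppressed)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  p
}

#' Exact category probabilities under the independence null
#'
#' With n i.i.d. label draws per ROI, the chance that an ROI is purely
#' enhanced (at least one enhanced, no suppressed) is
#' \eqn{(p_N + p_E)^n - p_N^n}; purely suppressed is the mirror image;
#' silent is \eqn{p_N^n}; mixed takes the remainder.
#'
#' @param probs a triple from \code{\link{polarity_probabilities}} (or the
#'   three probabilities in that order)
#' @param n_odors number of independent draws per ROI (default 16)
#' @return named numeric vector with elements \code{pure_enhanced},
#'   \code{pure_suppressed}, \code{mixed}, \code{silent} (sums to 1)
#' @export
#' @examples
#' analytic_polarity_null(polarity_probabilities(0.722, 0.124, 0.154))
analytic_polarity_null <- function(probs, n_odors = 16L) {
  if (length(probs) != 3L) stop("`probs` must have 3 elements",
                                call. = FALSE)
  probs <- polarity_probabilities(probs[[1L]], probs[[2L]], probs[[3L]])
  n_odors <- check_count(n_odors, "n_odors")
  p_n <- probs[["nonresponsive"]]
  p_e <- probs[["enhanced"]]
  p_s <- probs[["suppressed"]]
  silent <- p_n^n_odors
  pure_e <- (p_n + p_e)^n_odors - silent
  pure_s <- (p_n + p_s)^n_odors - silent
  mixed <- 1 - pure_e - pure_s - silent
  c(pure_enhanced = pure_e, pure_suppressed = pure_s,
    mixed = mixed, silent = silent)
}

#' Monte-Carlo polarity null model
#'
#' For each simulated ROI, draws \code{n_odors} response labels i.i.d. from
#' the given probabilities and classifies the ROI as purely enhanced (at
#' least one enhanced, no suppressed), purely suppressed, mixed (both), or
#' silent (all nonresponsive). Reports the category fractions over all
#' simulated ROIs with 99\% binomial confidence half-widths
#' \eqn{2.576 \sqrt{\hat p (1 - \hat p) / n}}.
#'
#' @inheritParams analytic_polarity_null
#' @param n_boutons number of simulated ROIs (default 10000)
#' @param seed integer seed or NULL
#' @return an object of class \code{polarity_null_result} with
#'   \code{fractions}, \code{ci99}, \code{counts}, \code{analytic} (the
#'   closed-form probabilities), \code{n_boutons}, \code{n_odors},
#'   \code{seed}
#' @export
#' @examples
#' simulate_polarity_null(c(0.722, 0.124, 0.154), seed = 1)
simulate_polarity_null <- function(probs, n_odors = 16L,
                                   n_boutons = 10000L, seed = NULL) {
  if (length(probs) != 3L) stop("`probs` must have 3 elements",
                                call. = FALSE)
  probs <- polarity_probabilities(probs[[1L]], probs[[2L]], probs[[3L]])
  n_odors <- check_count(n_odors, "n_odors")
  n_boutons <- check_count(n_boutons, "n_boutons")
  counts <- with_seed(derive_seed(seed, "polarity"), {
    # label counts per simulated ROI; rows: nonresponsive/enhanced/suppressed
    stats::rmultinom(n_boutons, n_odors, probs)
  })
  n_e <- counts[2L, ]
  n_s <- counts[3L, ]
  cat_counts <- c(
    pure_enhanced = sum(n_e > 0L & n_s == 0L),
    pure_suppressed = sum(n_s > 0L & n_e == 0L),
    mixed = sum(n_e > 0L & n_s > 0L),
    silent = sum(n_e == 0L & n_s == 0L)
  )
  fractions <- cat_counts / n_boutons
  ci99 <- 2.576 * sqrt(fractions * (1 - fractions) / n_boutons)
  structure(
    list(fractions = fractions, ci99 = ci99, counts = cat_counts,
         analytic = analytic_polarity_null(probs, n_odors),
         n_boutons = n_boutons, n_odors = n_odors, probs = probs,
         seed = seed),
    class = "polarity_null_result"
  )
}

#' @export
print.polarity_null_result <- function(x, ...) {
  cat(sprintf(
    "<polarity_null_result> %d ROIs x %d draws (p = %.3f/%.3f/%.3f N/E/S)\n",
    x$n_boutons, x$n_odors, x$probs[1L], x$probs[2L], x$probs[3L]))
  for (k in names(x$fractions)) {
    cat(sprintf("  %-16s %6.2f%% +/- %.2f%%  (analytic %6.2f%%)\n", k,
                100 * x$fractions[[k]], 100 * x$ci99[[k]],
                100 * x$analytic[[k]]))
  }
  invisible(x)
}
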