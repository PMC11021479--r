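# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded sampling inside
#' package functions does not disturb the caller's random stream. A NULL
#' seed evaluates the expression under the current stream.
#'
#' @param seed integer seed or NULL
#' @param code expression to evaluate
#' @return the value of \code{code}
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Named sub-streams derived from one user-facing seed, so the glomerular
# panel, projection matrix, interneurons and generators can be regenerated
# independently. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  offsets <- c(
    panel = 101L, projection = 211L, interneurons = 307L,
    mixtures = 401L, osn = 503L, bouton = 601L, polarity = 701L
  )
  if (is.null(seed)) return(NULL)
  if (!stream %in% names(offsets)) {
    stop("unknown seed stream: ", stream, call. = FALSE)
  }
  (as.integer(seed) %% 1000003L) * 2017L + offsets[[stream]]
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  as.numeric(x)
}
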