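# Stimulus panels: monomolecular odorants, mixtures drawn from a 16-odorant
# alphabet, and log-spaced concentration series.

#' Construct a stimulus panel
#'
#' @param id character stimulus identifiers
#' @param kind one of "odorant", "mixture", "concentration_step" per stimulus
#' @param components list of integer component sets (subsets of the
#'   component alphabet; singletons for monomolecular odorants)
#' @param concentration_level integer step index for concentration series
#'   (NA otherwise)
#' @param rel_concentration relative concentration per stimulus (NA for
#'   fixed-concentration panels)
#' @param n_components_alphabet size of the component alphabet (default 16)
#' @return an object of class \code{stimulus_panel}
#' @export
stimulus_panel <- function(id, kind, components,
                           concentration_level = rep(NA_integer_,
                                                     length(id)),
                           rel_concentration = rep(NA_real_, length(id)),
                           n_components_alphabet = 16L) {
  stopifnot(length(id) == length(kind),
            length(id) == length(components),
            length(id) == length(concentration_level),
            length(id) == length(rel_concentration))
  if (!all(kind %in% c("odorant", "mixture", "concentration_step"))) {
    stop("unknown stimulus kind", call. = FALSE)
  }
  comp_ok <- vapply(components, function(s) {
    length(s) >= 1L && all(s %in% seq_len(n_components_alphabet)) &&
      !anyDuplicated(s)
  }, logical(1L))
  if (!all(comp_ok)) {
    stop("component sets must be non-empty distinct subsets of 1..",
         n_components_alphabet, call. = FALSE)
  }
  structure(
    list(id = as.character(id), kind = kind,
         components = lapply(components, function(s) sort(as.integer(s))),
         n_components = vapply(components, length, integer(1L)),
         concentration_level = as.integer(concentration_level),
         rel_concentration = as.numeric(rel_concentration),
         n_components_alphabet = as.integer(n_components_alphabet)),
    class = "stimulus_panel"
  )
}

#' @export
print.stimulus_panel <- function(x, ...) {
  tab <- table(x$n_components)
  cat(sprintf("<stimulus_panel> %d stimuli; sizes: %s\n", n_stimuli(x),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Number of stimuli in a panel
#' @param panel a \code{stimulus_panel}
#' @return integer count
#' @export
n_stimuli <- function(panel) length(panel$id)

panel_ids <- function(panel) panel$id

#' Build the standard odorant-mixture panel
#'
#' 16 monomolecular odorants plus 84 mixtures drawn from the same 16
#' components: 24 two-part, 20 four-part, 20 eight-part and 20 twelve-part
#' mixtures (100 stimuli total). Component sets are sampled uniformly
#' without replacement within each size class, so all sets are distinct.
#'
#' @param seed integer seed or NULL
#' @param n_components alphabet size (default 16)
#' @param size_counts named integer vector: mixtures per size class
#' @return a \code{stimulus_panel}
#' @export
#' @examples
#' panel <- make_mixture_panel(seed = 1)
#' table(panel$n_components)
make_mixture_panel <- function(seed = NULL, n_components = 16L,
                               size_counts = c("2" = 24L, "4" = 20L,
                                               "8" = 20L, "12" = 20L)) {
  n_components <- check_count(n_components, "n_components")
  with_seed(derive_seed(seed, "mixtures"), {
    comps <- as.list(seq_len(n_components))
    kinds <- rep("odorant", n_components)
    for (sz_name in names(size_counts)) {
      sz <- as.integer(sz_name)
      want <- size_counts[[sz_name]]
      seen <- character(0)
      sets <- vector("list", want)
      got <- 0L
      while (got < want) {
        s <- sort(sample.int(n_components, sz))
        key <- paste(s, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          got <- got + 1L
          sets[[got]] <- s
        }
      }
      comps <- c(comps, sets)
      kinds <- c(kinds, rep("mixture", want))
    }
    sizes <- vapply(comps, length, integer(1L))
    ids <- sprintf("%s%02d_%03d",
                   ifelse(kinds == "odorant", "od", "mx"),
                   sizes, seq_along(comps))
    stimulus_panel(ids, kinds, comps,
                   n_components_alphabet = n_components)
  })
}

#' Build a log-spaced concentration series panel
#'
#' One odorant presented at \code{n_steps} log-spaced relative
#' concentrations. The default spans three orders of magnitude between the
#' extremes (relative concentration 1e-3 to 1), matching a 0.08\%-80\%
#' liquid-dilution series.
#'
#' @param n_steps number of concentration steps (default 8, >= 2)
#' @param c_min,c_max relative concentration extremes
#' @param component component id of the odorant (default 1)
#' @return a \code{stimulus_panel} of kind "concentration_step"
#' @export
make_concentration_panel <- function(n_steps = 8L, c_min = 1e-3, c_max = 1,
                                     component = 1L) {
  n_steps <- check_count(n_steps, "n_steps", min = 2L)
  c_min <- check_positive(c_min, "c_min")
  c_max <- check_positive(c_max, "c_max")
  if (c_max <= c_min) stop("`c_max` must exceed `c_min`", call. = FALSE)
  conc <- 10^seq(log10(c_min), log10(c_max), length.out = n_steps)
  stimulus_panel(
    id = sprintf("conc_%02d", seq_len(n_steps)),
    kind = rep("concentration_step", n_steps),
    components = rep(list(as.integer(component)), n_steps),
    concentration_level = seq_len(n_steps),
    rel_concentration = conc
  )
}
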