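# On-disk formats: a response tensor is stored as a directory of plain-text
# files — amplitudes.csv and blanks.csv in long format with full floating
# point precision, panel.json for the stimulus panel, meta.json for
# dimensions and labels. Analysis outputs export to flat CSV.

fmt_full <- function(x) sprintf("%.17g", x)

write_panel_json <- function(panel, path) {
  obj <- list(
    id = panel$id, kind = panel$kind,
    components = panel$components,
    concentration_level = panel$concentration_level,
    rel_concentration = panel$rel_concentration,
    n_components_alphabet = panel$n_components_alphabet
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
}

read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  n <- length(obj$id)
  lvl <- obj$concentration_level
  if (is.null(lvl)) lvl <- rep(NA_integer_, n)
  rel <- obj$rel_concentration
  if (is.null(rel)) rel <- rep(NA_real_, n)
  stimulus_panel(
    id = obj$id, kind = obj$kind,
    components = lapply(obj$components, as.integer),
    concentration_level = as.integer(lvl),
    rel_concentration = as.numeric(rel),
    n_components_alphabet = obj$n_components_alphabet
  )
}

#' Write a response tensor to a directory
#'
#' Serializes the tensor as plain-text files: \code{amplitudes.csv} (long
#' format: roi, stimulus, trial, amplitude), \code{blanks.csv} (roi, trial,
#' amplitude), \code{panel.json} and \code{meta.json}. Amplitudes are
#' written with 17 significant digits so the round-trip is bitwise exact.
#'
#' @param tensor a \code{response_tensor}
#' @param path directory to create/overwrite
#' @return \code{path}, invisibly
#' @export
write_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "response_tensor"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(tensor$amplitudes)
  long <- data.frame(
    roi = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    stimulus = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    trial = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    amplitude = fmt_full(as.vector(tensor$amplitudes))
  )
  utils::write.csv(long, file.path(path, "amplitudes.csv"),
                   row.names = FALSE, quote = FALSE)
  nb <- ncol(tensor$blank_amplitudes)
  blanks <- data.frame(
    roi = rep(seq_len(d[1L]), times = nb),
    trial = rep(seq_len(nb), each = d[1L]),
    amplitude = fmt_full(as.vector(tensor$blank_amplitudes))
  )
  utils::write.csv(blanks, file.path(path, "blanks.csv"),
                   row.names = FALSE, quote = FALSE)
  write_panel_json(tensor$panel, file.path(path, "panel.json"))
  jsonlite::write_json(
    list(n_rois = d[1L], n_stimuli = d[2L], n_trials = d[3L],
         n_blank_trials = nb, roi_ids = tensor$roi_ids,
         population_label = tensor$population_label),
    file.path(path, "meta.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read a response tensor written by \code{\link{write_tensor}}
#'
#' @param path tensor directory
#' @return a \code{response_tensor}
#' @export
read_tensor <- function(path) {
  need <- c("amplitudes.csv", "blanks.csv", "panel.json", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("tensor directory is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  long <- utils::read.csv(file.path(path, "amplitudes.csv"))
  if (nrow(long) != meta$n_rois * meta$n_stimuli * meta$n_trials) {
    stop("amplitudes.csv row count does not match meta.json dimensions",
         call. = FALSE)
  }
  amp <- array(NA_real_, dim = c(meta$n_rois, meta$n_stimuli,
                                 meta$n_trials))
  amp[cbind(long$roi, long$stimulus, long$trial)] <- long$amplitude
  blong <- utils::read.csv(file.path(path, "blanks.csv"))
  blanks <- matrix(NA_real_, meta$n_rois, meta$n_blank_trials)
  blanks[cbind(blong$roi, blong$trial)] <- blong$amplitude
  panel <- read_panel_json(file.path(path, "panel.json"))
  response_tensor(amp, blanks, panel, roi_ids = meta$roi_ids,
                  population_label = meta$population_label)
}

#' Export classification results to CSV
#'
#' One row per ROI-stimulus pair with the trial-mean amplitude, label and
#' thresholds.
#'
#' @param classified a \code{classified_responses}
#' @param path output CSV file
#' @return \code{path}, invisibly
#' @export
write_classified_csv <- function(classified, path) {
  stopifnot(inherits(classified, "classified_responses"))
  lab <- classified$labels
  out <- data.frame(
    roi = rep(rownames(lab), times = ncol(lab)),
    stimulus = rep(colnames(lab), each = nrow(lab)),
    trial_mean = as.vector(classified$trial_mean),
    label = as.vector(lab),
    threshold_low = rep(classified$thresholds[, "low"], times = ncol(lab)),
    threshold_high = rep(classified$thresholds[, "high"],
                         times = ncol(lab))
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a dose-response curve set to CSV
#'
#' One row per neuron and concentration, with the steady-state response,
#' latency (NA when the neuron never responds) and the neuron's
#' nonmonotonicity flag.
#'
#' @param curve a \code{dose_response_curve}
#' @param path output CSV file
#' @param rel_tol dip threshold for \code{\link{detect_nonmonotonicity}}
#' @return \code{path}, invisibly
#' @export
write_dose_response_csv <- function(curve, path, rel_tol = 0.1) {
  stopifnot(inherits(curve, "dose_response_curve"))
  flags <- detect_nonmonotonicity(curve$responses, rel_tol)$nonmonotonic
  n <- nrow(curve$responses)
  k <- length(curve$concentrations)
  out <- data.frame(
    neuron_id = rep(seq_len(n), times = k),
    concentration = rep(curve$concentrations, each = n),
    response = as.vector(curve$responses),
    latency = as.vector(curve$latencies),
    nonmonotonic_flag = rep(flags, times = k)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
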