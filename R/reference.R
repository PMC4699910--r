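#' Reference step-length power-law fits for 33 off-food recordings
#'
#' Bundled summary table of truncated power-law fits to the step-length
#' distributions of 33 wild-type (N2) C. elegans recordings made off food
#' with the original tracker hardware (cut-off angle 40 degrees, first 20
#' minutes of each recording). Columns: recording length in minutes, total
#' step count, smallest and largest step (mm), estimated lower cut-off (mm),
#' tail size, maximum-likelihood exponent, and the distance between the
#' empirical and fitted distributions. Recordings labelled A-F are the six
#' whose exponents fall in the Levy regime.
#'
#' @return data.frame with columns `id`, `label`, `length_min`, `n_step`,
#'   `min_step`, `max_step`, `est_xmin`, `n_tail`, `est_alpha`, `distance`.
#' @export
reference_fits <- function() {
  path <- system.file("extdata", "n2_offfood_fits.csv", package = "wormpath",
                      mustWork = TRUE)
  utils::read.csv(path, colClasses = c(label = "character"))
}
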