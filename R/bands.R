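#' Frequency band definitions
#'
#' The five analysis bands used throughout the pipeline: theta1 (4-6 Hz),
#' theta2 (6-8 Hz), alpha1 (8-10 Hz), alpha2 (10-13 Hz) and beta (13-20 Hz).
#' Delta and gamma are excluded by design.
#'
#' @return A data frame with columns `name`, `low`, `high` (Hz).
#' @export
#' @examples
#' meg_bands()
meg_bands <- function() {
  data.frame(
    name = c("theta1", "theta2", "alpha1", "alpha2", "beta"),
    low  = c(4, 6, 8, 10, 13),
    high = c(6, 8, 10, 13, 20),
    stringsAsFactors = FALSE
  )
}

#' Construct a single band specification
#'
#' @param name Band label.
#' @param low,high Band edges in Hz; `0 < low < high` required.
#' @return A list of class `meg_band`.
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.numeric(low), is.numeric(high))
  if (!(low > 0 && high > low)) {
    stop_megspect("band edges must satisfy 0 < low < high",
                  "megspect_invalid_band")
  }
  structure(list(name = name, low = low, high = high), class = "meg_band")
}
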