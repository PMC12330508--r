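#' Default haemodynamic response parameters
#'
#' Standard double-gamma shape: a gamma response peaking near 5 s minus a
#' scaled gamma undershoot peaking near 15 s.
#'
#' @param shape1,rate1 Gamma shape/rate of the positive lobe.
#' @param shape2,rate2 Gamma shape/rate of the undershoot.
#' @param undershoot Undershoot amplitude ratio.
#' @return A list of HRF parameters.
#' @export
hrf_params <- function(shape1 = 6, rate1 = 1, shape2 = 16, rate2 = 1,
                       undershoot = 1 / 6) {
  list(shape1 = shape1, rate1 = rate1, shape2 = shape2, rate2 = rate2,
       undershoot = undershoot)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Normalized to unit peak; `h(0) = 0` and the response is integrable.
#'
#' @param t Time in seconds (`t >= 0`).
#' @param params See [hrf_params()].
#' @return HRF amplitude at `t` (unit peak).
#' @examples
#' canonical_hrf(0)            # 0
#' which.max(canonical_hrf(seq(0, 30, 0.1)))  # peak near 5 s
#' @export
canonical_hrf <- function(t, params = hrf_params()) {
  stopifnot(all(t >= 0))
  raw <- function(x) {
    stats::dgamma(x, shape = params$shape1, rate = params$rate1) -
      params$undershoot *
        stats::dgamma(x, shape = params$shape2, rate = params$rate2)
  }
  peak <- max(raw(seq(0, 30, by = 0.01)))
  raw(t) / peak
}
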