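#' Beer-Lambert seabed light under a macroalgal canopy
#'
#' Light reaching the seabed below a canopy is modelled as the surface
#' illuminance attenuated exponentially by the water column and by the
#' canopy:
#' \deqn{I_c = I_s \, e^{-k_w z - k_a T_{AI}}}
#'
#' Units of `I_s` are carried opaquely (lux for the loggers this package
#' targets, but any consistent intensity unit works: the downstream index is
#' a ratio).
#'
#' @param I_s surface light intensity (>= 0).
#' @param k_w attenuation coefficient of seawater, per metre (>= 0).
#' @param z water depth above the sensor, metres (>= 0). `z = 0` means the
#'   sensor is at or above the water line and the water term vanishes.
#' @param k_a canopy attenuation coefficient, per unit thallus area index
#'   (>= 0).
#' @param tai thallus area index, m2 frond per m2 seabed (>= 0); may exceed
#'   1 in multilayered canopies.
#' @return Seabed intensity, same unit as `I_s`. Vectorised with recycling.
#' @seealso [seabed_light_open()], [attenuation_index()]
#' @export
#' @examples
#' seabed_light_canopy(1000, k_w = 0.3, z = 1, k_a = 0.7, tai = 2)
seabed_light_canopy <- function(I_s, k_w, z, k_a, tai) {
  check_nonneg(I_s = I_s, k_w = k_w, z = z, k_a = k_a, tai = tai)
  I_s * exp(-k_w * z - k_a * tai)
}

#' Beer-Lambert seabed light on open rock
#'
#' The no-canopy counterpart of [seabed_light_canopy()]:
#' \deqn{I_o = I_s \, e^{-k_w z}}
#'
#' @inheritParams seabed_light_canopy
#' @return Seabed intensity on open substrate, same unit as `I_s`.
#' @export
seabed_light_open <- function(I_s, k_w, z) {
  check_nonneg(I_s = I_s, k_w = k_w, z = z)
  I_s * exp(-k_w * z)
}

#' Canopy attenuation index ln(I_o / I_c)
#'
#' The biomass proxy at the core of the method. For sensors at the same
#' depth in the same water body the surface-light and water-column terms
#' cancel, so \eqn{\ln(I_o/I_c) = k_a T_{AI}} under the Beer-Lambert model.
#' Timestamps where either sensor is missing or at/below `threshold`
#' (night readings of zero make the log ratio undefined) yield `NA`, never
#' an error. Negative indices (canopy sensor brighter than the open mean,
#' possible in noisy data) are retained, not clipped, so later smoothing is
#' unbiased.
#'
#' @param I_o open-rock reference intensity (>= 0 or `NA`).
#' @param I_c under-canopy intensity (>= 0 or `NA`).
#' @param threshold zero-light threshold (same unit, default 0): values
#'   less than or equal to it are treated as no-signal and give `NA`.
#'   Raise it for sensors with a known noise floor.
#' @return Dimensionless index vector, `NA` where undefined.
#' @export
#' @examples
#' attenuation_index(100, 100)            # 0: no canopy signal
#' attenuation_index(c(100, 50), c(0, 10))  # NA, log(5)
attenuation_index <- function(I_o, I_c, threshold = 0) {
  check_nonneg(I_o = I_o, I_c = I_c)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  ok <- night_zero_mask(I_o, I_c, threshold)
  out <- rep(NA_real_, length(ok))
  out[ok] <- log(I_o[ok] / I_c[ok])
  out
}

#' Valid-light mask for the attenuation index
#'
#' `TRUE` where both the open and canopy readings are present and strictly
#' above `threshold`, i.e. where `ln(I_o/I_c)` is defined. Missing values
#' and night zeros fail the mask.
#'
#' @inheritParams attenuation_index
#' @return Logical vector (recycled to the common length).
#' @export
night_zero_mask <- function(I_o, I_c, threshold = 0) {
  n <- max(length(I_o), length(I_c))
  I_o <- rep_len(I_o, n)
  I_c <- rep_len(I_c, n)
  !is.na(I_o) & !is.na(I_c) & I_o > threshold & I_c > threshold
}

# stop() on negative or non-finite values; NA allowed (propagates as missing)
check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (is.logical(x) && all(is.na(x))) next  # bare NA counts as missing
    if (!is.numeric(x))
      stop("'", nm, "' must be numeric", call. = FALSE)
    bad <- !is.na(x) & (x < 0 | !is.finite(x))
    if (any(bad))
      stop("'", nm, "' must be finite and >= 0", call. = FALSE)
  }
  invisible(TRUE)
}
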