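#' Optical configuration for the forward-scatter simulator
#'
#' Defaults describe a HeNe-class laser diode (633 nm) illuminating the colony
#' with a Gaussian beam and a bare CMOS sensor placed a few centimetres behind
#' the dish; no imaging lens is modelled. The colony is treated as a thin
#' phase object with refractive-index contrast `delta_n` against the medium.
#'
#' @param wavelength laser wavelength in nanometres.
#' @param delta_n refractive-index contrast of colony vs medium
#'   (dimensionless; 0.04 is typical for cells in culture medium).
#' @param z propagation (dish-to-sensor) distance in millimetres.
#' @param beam_radius Gaussian illumination 1/e^2 intensity radius in
#'   micrometres.
#' @param peak_counts expected detector counts at the brightest pixel, used to
#'   scale shot noise in [simulate_pattern()].
#' @param detector_bits detector quantization depth (bits).
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelength = 633, delta_n = 0.04, z = 20,
                           beam_radius = 600, peak_counts = 5000,
                           detector_bits = 16L) {
  stop_if_not_scalar_pos(wavelength, "wavelength")
  stop_if_not_scalar_pos(z, "z")
  stop_if_not_scalar_pos(beam_radius, "beam_radius")
  if (delta_n <= 0) stop("`delta_n` must be positive", call. = FALSE)
  structure(list(wavelength = wavelength, delta_n = delta_n, z = z,
                 beam_radius = beam_radius, peak_counts = peak_counts,
                 detector_bits = as.integer(detector_bits)),
            class = "optical_config")
}

#' Thin-phase-object transmittance of a colony
#'
#' The colony modulates the optical phase in proportion to its thickness:
#' `t(x, y) = a(x, y) * exp(i * 2 * pi * delta_n * h(x, y) / lambda)` with the
#' wavelength converted to micrometres and a (default unit) absorption factor.
#'
#' @param phantom a `colony_phantom`.
#' @param config an [optical_config()].
#' @param absorption amplitude transmission factor inside the colony in
#'   `(0, 1]`; 1 models a pure phase object.
#' @return A complex matrix, the transmitted field for unit plane-wave
#'   illumination.
#' @export
transmittance <- function(phantom, config = optical_config(),
                          absorption = 1) {
  if (!inherits(config, "optical_config"))
    stop("`config` must be an optical_config()", call. = FALSE)
  if (absorption <= 0 || absorption > 1)
    stop("`absorption` must lie in (0, 1]", call. = FALSE)
  lambda_um <- config$wavelength / 1000
  a <- ifelse(phantom$support_mask, absorption, 1)
  a * exp(2i * pi * config$delta_n * phantom$height_map / lambda_um)
}

#' Propagate a complex field to the detector plane
#'
#' Multiplies the field by the chosen illumination profile and propagates it
#' over `config$z` by the band-limited angular-spectrum method: the exact
#' scalar transfer function `exp(i 2 pi z / lambda * sqrt(1 - (lambda f)^2))`
#' is applied in the FFT domain, evanescent components are dropped, and
#' spatial frequencies beyond the Matsushima band limit
#' `f_lim = 1 / (lambda * sqrt((2 z / L)^2 + 1))` (with `L` the field width)
#' are zeroed to prevent sampling-induced wrap-around. Within that bandwidth
#' propagation is unitary, so energy is conserved to machine precision for
#' band-limited inputs; fields with steeper phase gradients (e.g. sharp colony
#' rims) legitimately lose the energy that would miss a finite sensor.
#'
#' @param field square complex (or numeric) matrix, the field just after the
#'   specimen for unit plane-wave illumination.
#' @param pixel_pitch sample spacing of `field` in micrometres.
#' @param config an [optical_config()].
#' @param illumination `"gaussian"` (beam radius from `config`) or `"plane"`.
#' @param label optional class label carried into the result.
#' @return An object of class `scatter_pattern`: `intensity` (non-negative
#'   matrix, |field|^2 at the detector), `pixel_pitch`, `config`, `label`.
#' @export
propagate <- function(field, pixel_pitch, config = optical_config(),
                      illumination = c("gaussian", "plane"), label = NULL) {
  illumination <- match.arg(illumination)
  if (!is.matrix(field) || nrow(field) != ncol(field))
    stop("`field` must be a square matrix", call. = FALSE)
  stop_if_not_scalar_pos(pixel_pitch, "pixel_pitch")
  n <- nrow(field)
  if (illumination == "gaussian") {
    g <- grid_coords(n, pixel_pitch)
    field <- field * exp(-(g$r^2) / config$beam_radius^2)
  }
  lambda <- config$wavelength / 1000          # um
  z <- config$z * 1000                        # um
  fx <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * pixel_pitch)
  # handle odd n as well
  if (n %% 2 == 1) fx <- c(0:((n - 1) / 2), -((n - 1) / 2):-1) / (n * pixel_pitch)
  FX <- matrix(fx, n, n)
  FY <- t(FX)
  arg <- 1 - lambda^2 * (FX^2 + FY^2)
  H <- exp(2i * pi * (z / lambda) * sqrt(pmax(arg, 0)))
  H[arg <= 0] <- 0                            # evanescent cutoff
  flim <- 1 / (lambda * sqrt((2 * z / (n * pixel_pitch))^2 + 1))
  H[abs(FX) > flim | abs(FY) > flim] <- 0     # Matsushima band limit
  out <- fft(fft(field) * H, inverse = TRUE) / n^2
  structure(list(intensity = Mod(out)^2, pixel_pitch = pixel_pitch,
                 config = config, label = label),
            class = "scatter_pattern")
}

#' @export
print.scatter_pattern <- function(x, ...) {
  cat(sprintf(
    "<scatter_pattern> %dx%d px @ %.3g um/px%s, total energy %.4g\n",
    nrow(x$intensity), ncol(x$intensity), x$pixel_pitch,
    if (!is.null(x$label)) paste0(", label ", x$label) else "",
    sum(x$intensity)))
  invisible(x)
}

#' Simulate a detector-recorded forward-scatter pattern
#'
#' Composes [transmittance()] and [propagate()] (Gaussian illumination),
#' applies Poisson shot noise scaled so the brightest pixel expects
#' `config$peak_counts` photons, and quantizes to the detector bit depth.
#' With `peak_counts = Inf` (or `noise = FALSE`) the result is the noiseless
#' propagated intensity after quantization only.
#'
#' @param phantom a `colony_phantom`.
#' @param config an [optical_config()].
#' @param seed optional RNG seed making the pattern a pure function of
#'   `(phantom, config, seed)`.
#' @param noise apply shot noise? Default `TRUE`.
#' @return A `scatter_pattern` whose `intensity` holds integer detector
#'   counts in `[0, 2^bits - 1]`; `label` is copied from the phantom.
#' @export
simulate_pattern <- function(phantom, config = optical_config(), seed = NULL,
                             noise = TRUE) {
  tfield <- transmittance(phantom, config)
  pat <- propagate(tfield, phantom$params$pixel_pitch, config,
                   illumination = "gaussian", label = phantom$label)
  I <- pat$intensity
  peak <- max(I)
  if (peak <= 0) stop("propagated intensity is identically zero",
                      call. = FALSE)
  maxcount <- 2^config$detector_bits - 1
  if (noise && is.finite(config$peak_counts) && config$peak_counts > 0) {
    sc <- config$peak_counts / peak
    I <- with_seed_if(seed,
      matrix(rpois(length(I), I * sc), nrow(I)) / sc)
  }
  pat$intensity <- matrix(round(I / max(I, 1e-300) * maxcount), nrow(I))
  pat
}

#' Angular asymmetry index of a scatter pattern
#'
#' Quantifies how far a pattern departs from circular symmetry.
#' `"annular"` (default) averages, over radial annuli, the coefficient of
#' variation of intensity around each annulus, weighting annuli by their total
#' energy; a perfectly circularly symmetric pattern scores 0. `"rotation"`
#' returns the relative L1 difference between the pattern and its 90-degree
#' rotation. Good (symmetric) colonies score lower than lumpy bad colonies.
#'
#' @param x a `scatter_pattern` or numeric matrix.
#' @param method `"annular"` or `"rotation"`.
#' @param bin_px radial bin width in pixels for the annular method.
#' @return A single non-negative number.
#' @export
asymmetry_index <- function(x, method = c("annular", "rotation"),
                            bin_px = 4) {
  method <- match.arg(method)
  I <- if (inherits(x, "scatter_pattern")) x$intensity else x
  if (method == "rotation") {
    s <- sum(abs(I))
    if (s == 0) return(0)
    return(sum(abs(I - rot90_mat(I))) / s)
  }
  nr <- nrow(I); nc <- ncol(I)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+"))
  bin <- floor(r / bin_px)
  mu <- tapply(I, bin, mean)
  sg <- tapply(I, bin, sd)
  tot <- tapply(I, bin, sum)
  ok <- !is.na(sg) & mu > 0 & as.numeric(names(mu)) > 1
  if (!any(ok)) return(0)
  sum((sg[ok] / mu[ok]) * tot[ok]) / sum(tot[ok])
}

#' Azimuthally averaged radial intensity profile
#'
#' @param x a `scatter_pattern` or numeric matrix.
#' @param center `(row, col)` of the optical axis; default geometric centre.
#' @param bin_px radial bin width in pixels.
#' @return A data.frame with `radius_px` (bin centre) and `intensity`.
#' @export
radial_profile <- function(x, center = NULL, bin_px = 1) {
  I <- if (inherits(x, "scatter_pattern")) x$intensity else x
  nr <- nrow(I); nc <- ncol(I)
  center <- center %||% c((nr + 1) / 2, (nc + 1) / 2)
  r <- sqrt(outer((seq_len(nr) - center[1])^2,
                  (seq_len(nc) - center[2])^2, "+"))
  bin <- floor(r / bin_px)
  mu <- tapply(I, bin, mean)
  data.frame(radius_px = (as.numeric(names(mu)) + 0.5) * bin_px,
             intensity = as.numeric(mu))
}
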