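#' Parameters for the synthetic colony phantom generator
#'
#' The generator emulates the two morphological classes used in manual hESC
#' colony grading. A *good* colony is a uniform flat plateau with a clear
#' (raised-cosine) rim and an almost circular boundary; a *bad* colony has an
#' irregular boundary and lumpy, non-uniformly stacked surface structures.
#' Class height statistics default to the confocal z-stack measurements the
#' generator is calibrated against: mean colony thickness 53 um (sd 4.2) for
#' good colonies and 44 um (sd 13.9) for bad ones. `height_mean`/`height_sd`
#' parameterise the distribution of the *per-colony mean thickness* over the
#' footprint (the quantity a z-stack height measurement reports); each
#' phantom's profile is rescaled so its area-mean thickness equals the drawn
#' value exactly.
#'
#' @param class_label `"good"` or `"bad"`; selects the class defaults below.
#' @param grid_size pixels per side of the square simulation grid.
#' @param pixel_pitch micrometres per pixel.
#' @param colony_radius_mean,colony_radius_sd mean/sd of the colony boundary
#'   radius in micrometres.
#' @param height_mean,height_sd mean/sd of the per-colony mean thickness in
#'   micrometres (class default: 53/4.2 good, 44/13.9 bad). Draws are
#'   truncated-normal on (0, Inf) via the inverse CDF.
#' @param edge_irregularity rms relative amplitude (in `[0, 1]`) of the
#'   low-order Fourier perturbation of the boundary radius (class default:
#'   0.03 good, 0.25 bad).
#' @param lump_count_mean expected number of Gaussian surface lumps (Poisson
#'   distributed; class default: 0 good, 6 bad).
#' @param lump_height_sd sd in micrometres of the signed lump amplitudes
#'   (class default: 0 good, 12 bad).
#' @param lump_sigma_range length-2 range (um) from which each lump's Gaussian
#'   width is drawn uniformly.
#' @param rim_width width of the raised-cosine rim as a fraction of the local
#'   boundary radius.
#' @param edge_floor relative height of the colony boundary (fraction of the
#'   plateau height) at which the rim ends in a clean cliff. Colonies are
#'   cellular: their edge is at least one cell layer thick, not a vanishing
#'   wedge, and the clear-edged morphology of good colonies shows a sharp
#'   boundary.
#'
#' @return An object of class `phantom_params`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @examples
#' p <- phantom_params("bad", grid_size = 128, pixel_pitch = 8)
#' p$height_mean
#' @export
phantom_params <- function(class_label = c("good", "bad"),
                           grid_size = 512L,
                           pixel_pitch = 2,
                           colony_radius_mean = 400,
                           colony_radius_sd = 40,
                           height_mean = NULL,
                           height_sd = NULL,
                           edge_irregularity = NULL,
                           lump_count_mean = NULL,
                           lump_height_sd = NULL,
                           lump_sigma_range = c(30, 80),
                           rim_width = 0.12,
                           edge_floor = 0.25) {
  class_label <- match.arg(class_label)
  good <- class_label == "good"
  height_mean       <- height_mean       %||% if (good) 53 else 44
  height_sd         <- height_sd         %||% if (good) 4.2 else 13.9
  edge_irregularity <- edge_irregularity %||% if (good) 0.03 else 0.25
  lump_count_mean   <- lump_count_mean   %||% if (good) 0 else 6
  lump_height_sd    <- lump_height_sd    %||% if (good) 0 else 12

  stop_if_not_scalar_pos(grid_size, "grid_size")
  stop_if_not_scalar_pos(pixel_pitch, "pixel_pitch")
  stop_if_not_scalar_pos(colony_radius_mean, "colony_radius_mean")
  stop_if_not_scalar_pos(height_mean, "height_mean")
  if (edge_irregularity < 0 || edge_irregularity > 1)
    stop("`edge_irregularity` must lie in [0, 1]", call. = FALSE)
  if (height_sd < 0 || colony_radius_sd < 0 || lump_height_sd < 0 ||
      lump_count_mean < 0)
    stop("sd and count parameters must be non-negative", call. = FALSE)
  if (rim_width <= 0 || rim_width >= 1)
    stop("`rim_width` must lie in (0, 1)", call. = FALSE)
  if (edge_floor < 0 || edge_floor >= 1)
    stop("`edge_floor` must lie in [0, 1)", call. = FALSE)

  structure(list(
    class_label = class_label,
    grid_size = as.integer(grid_size), pixel_pitch = pixel_pitch,
    colony_radius_mean = colony_radius_mean,
    colony_radius_sd = colony_radius_sd,
    height_mean = height_mean, height_sd = height_sd,
    edge_irregularity = edge_irregularity,
    lump_count_mean = lump_count_mean, lump_height_sd = lump_height_sd,
    lump_sigma_range = lump_sigma_range, rim_width = rim_width,
    edge_floor = edge_floor
  ), class = "phantom_params")
}

#' Generate one synthetic colony phantom
#'
#' Builds a 2-D height map `h(x, y)` (um of optical thickness) on the
#' parameter grid. The boundary radius is perturbed by a random low-order
#' Fourier series, `R(theta) = R0 (1 + e * P(theta))` with `P` normalised to
#' unit rms, the profile is a flat plateau with a raised-cosine rim, and
#' (for lumpy classes) Poisson-many signed Gaussian bumps are added inside the
#' footprint before clipping at zero. Finally the map is rescaled so the mean
#' thickness over the footprint equals the drawn per-colony height `H`.
#'
#' @param params a [phantom_params()] object.
#' @param seed optional integer; if given, the phantom is a pure function of
#'   `(params, seed)` and the caller's RNG stream is left untouched.
#'
#' @return An object of class `colony_phantom`: list with `height_map`
#'   (matrix, um), `support_mask` (logical matrix), `label`, and `params`.
#' @examples
#' ph <- generate_phantom(phantom_params("good", grid_size = 64,
#'                                       pixel_pitch = 16), seed = 1)
#' range(ph$height_map)
#' @export
generate_phantom <- function(params, seed = NULL) {
  if (!inherits(params, "phantom_params"))
    stop("`params` must be created by phantom_params()", call. = FALSE)
  with_seed_if(seed, generate_phantom_impl(params))
}

generate_phantom_impl <- function(params) {
  n <- params$grid_size
  g <- grid_coords(n, params$pixel_pitch)

  R0 <- rtruncnorm_pos(1, params$colony_radius_mean, params$colony_radius_sd,
                       lower = params$colony_radius_mean * 0.2)
  H <- rtruncnorm_pos(1, params$height_mean, params$height_sd)

  # boundary perturbation: Fourier orders 2..6, unit-rms, scaled by e
  if (params$edge_irregularity > 0) {
    ak <- rnorm(5); phk <- runif(5, 0, 2 * pi)
    rms <- sqrt(sum(ak^2) / 2)
    pert <- 0
    for (k in 1:5) pert <- pert + ak[k] * cos((k + 1) * g$theta + phk[k])
    Rtheta <- R0 * pmax(1 + params$edge_irregularity * pert / rms, 0.2)
  } else {
    Rtheta <- matrix(R0, n, n)
  }

  u <- g$r / Rtheta
  w <- params$rim_width
  ef <- params$edge_floor
  profile <- matrix(0, n, n)
  inside <- u < 1
  plateau <- u <= 1 - w
  rim <- inside & !plateau
  profile[plateau] <- 1
  # raised-cosine roll-off from the plateau to a one-cell-layer edge floor,
  # ending in a clean cliff at the boundary (clear colony edge)
  profile[rim] <- ef + (1 - ef) *
    0.5 * (1 + cos(pi * (u[rim] - (1 - w)) / w))
  support <- inside
  if (!any(support))
    stop("degenerate phantom: colony footprint is empty", call. = FALSE)

  h <- profile
  n_lumps <- if (params$lump_count_mean > 0) rpois(1, params$lump_count_mean)
             else 0L
  if (n_lumps > 0) {
    for (i in seq_len(n_lumps)) {
      rr <- sqrt(runif(1)) * 0.85 * R0
      tt <- runif(1, 0, 2 * pi)
      sg <- runif(1, params$lump_sigma_range[1], params$lump_sigma_range[2])
      amp <- rnorm(1, 0, params$lump_height_sd) / max(H, 1e-9)
      h <- h + amp *
        exp(-((g$X - rr * cos(tt))^2 + (g$Y - rr * sin(tt))^2) / (2 * sg^2))
    }
    h[!support] <- 0
    h <- pmax(h, 0)
  }

  mh <- mean(h[support])
  if (mh <= 0) { # pathological lump cancellation: fall back to bare profile
    h <- profile
    mh <- mean(h[support])
  }
  h <- h * (H / mh)

  structure(list(height_map = h, support_mask = support,
                 label = params$class_label, params = params),
            class = "colony_phantom")
}

#' @export
print.colony_phantom <- function(x, ...) {
  cat(sprintf(
    "<colony_phantom> %s, %dx%d px @ %.3g um/px, mean thickness %.1f um, peak %.1f um\n",
    x$label, nrow(x$height_map), ncol(x$height_map), x$params$pixel_pitch,
    mean(x$height_map[x$support_mask]), max(x$height_map)))
  invisible(x)
}

#' Generate a labelled phantom dataset
#'
#' Deterministically (given `seed`) generates `n_good + n_bad` phantoms in a
#' shuffled label order.
#'
#' @param n_good,n_bad counts per class (non-negative).
#' @param good_params,bad_params [phantom_params()] for each class.
#' @param seed integer seed controlling both the shuffle and every phantom.
#' @return A list of `colony_phantom` objects.
#' @export
generate_dataset <- function(n_good, n_bad,
                             good_params = phantom_params("good"),
                             bad_params = phantom_params("bad"),
                             seed = NULL) {
  if (n_good < 0 || n_bad < 0)
    stop("`n_good` and `n_bad` must be non-negative", call. = FALSE)
  if (n_good + n_bad == 0) return(list())
  with_seed_if(seed, {
    labels <- sample(rep(c("good", "bad"), c(n_good, n_bad)))
    lapply(labels, function(lb) {
      generate_phantom_impl(if (lb == "good") good_params else bad_params)
    })
  })
}

#' Convert a phantom to a confocal-style z-stack
#'
#' Slice `k` of the stack samples the axial midplane `z = (k - 1/2) * z_step`:
#' a pixel carries unit signal in that slice iff the local colony thickness
#' exceeds the midplane height. Optional additive Gaussian noise is clipped at
#' zero. The number of slices covers the tallest point of the phantom plus one
#' empty slice.
#'
#' @param phantom a `colony_phantom`.
#' @param z_step axial slice spacing in micrometres (> 0).
#' @param noise_sd additive Gaussian noise sd (signal amplitude is 1).
#' @param seed optional RNG seed for the noise.
#' @return An object of class `zstack`: list with `volume` (array
#'   `[y, x, z]`), `z_step`, `label`.
#' @export
phantom_to_zstack <- function(phantom, z_step = 2, noise_sd = 0, seed = NULL) {
  stop_if_not_scalar_pos(z_step, "z_step")
  h <- phantom$height_map
  n_slices <- max(2L, as.integer(ceiling(max(h) / z_step)) + 1L)
  vol <- array(0, dim = c(nrow(h), ncol(h), n_slices))
  for (k in seq_len(n_slices)) {
    vol[, , k] <- (h > (k - 0.5) * z_step) * 1
  }
  if (noise_sd > 0) {
    vol <- with_seed_if(seed,
      pmax(vol + array(rnorm(length(vol), 0, noise_sd), dim = dim(vol)), 0))
  }
  structure(list(volume = vol, z_step = z_step, label = phantom$label),
            class = "zstack")
}

#' Simulate a two-channel Oct-4/DAPI fluorescence image pair
#'
#' Scatters `n_nuclei` point nuclei uniformly over the colony footprint, each
#' with a Gamma-distributed brightness. Every nucleus contributes to the DAPI
#' (DNA) channel; an independent Bernoulli(`true_positive_fraction`) subset
#' contributes to the Oct-4 channel with the *same* brightness, so the
#' integrated Oct-4/DAPI ratio estimates the pluripotent fraction. Both
#' channels are blurred with a Gaussian PSF and optionally degraded with
#' clipped Gaussian noise.
#'
#' @param phantom a `colony_phantom` providing the footprint.
#' @param true_positive_fraction probability in `[0, 1]` that a nucleus is
#'   Oct-4 positive.
#' @param n_nuclei number of nuclei; default scales with footprint area
#'   (about one nucleus per 250 pixels).
#' @param psf_sigma Gaussian PSF sd in pixels.
#' @param noise_sd additive Gaussian noise sd per channel.
#' @param seed optional RNG seed.
#' @return An object of class `fluor_pair`: `oct4_channel`, `dapi_channel`
#'   (matrices), `support_mask`, `true_positive_fraction`, `label`.
#' @export
generate_fluorescence_pair <- function(phantom, true_positive_fraction,
                                       n_nuclei = NULL, psf_sigma = 2,
                                       noise_sd = 0, seed = NULL) {
  if (!is.numeric(true_positive_fraction) ||
      true_positive_fraction < 0 || true_positive_fraction > 1)
    stop("`true_positive_fraction` must lie in [0, 1]", call. = FALSE)
  mask <- phantom$support_mask
  npx <- sum(mask)
  if (npx == 0) stop("phantom has an empty footprint", call. = FALSE)
  n_nuclei <- as.integer(n_nuclei %||% max(50L, round(npx / 250)))

  with_seed_if(seed, {
    cells <- sample(which(mask), n_nuclei, replace = TRUE)
    bright <- rgamma(n_nuclei, shape = 25, rate = 25)
    pos <- runif(n_nuclei) < true_positive_fraction
    d <- dim(mask)
    dapi_delta <- matrix(0, d[1], d[2])
    oct4_delta <- matrix(0, d[1], d[2])
    for (i in seq_len(n_nuclei)) {
      dapi_delta[cells[i]] <- dapi_delta[cells[i]] + bright[i]
      if (pos[i]) oct4_delta[cells[i]] <- oct4_delta[cells[i]] + bright[i]
    }
    ker <- gaussian_kernel_fft(d[1], d[2], psf_sigma)
    dapi <- fft_convolve(dapi_delta, ker)
    oct4 <- fft_convolve(oct4_delta, ker)
    if (noise_sd > 0) {
      dapi <- pmax(dapi + matrix(rnorm(length(dapi), 0, noise_sd), d[1]), 0)
      oct4 <- pmax(oct4 + matrix(rnorm(length(oct4), 0, noise_sd), d[1]), 0)
    }
    structure(list(oct4_channel = oct4, dapi_channel = dapi,
                   support_mask = mask,
                   true_positive_fraction = true_positive_fraction,
                   label = phantom$label),
              class = "fluor_pair")
  })
}

# unit-sum Gaussian kernel in FFT (wrap-around) layout
gaussian_kernel_fft <- function(nr, nc, sigma) {
  dy <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dx <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  k <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))
  k / sum(k)
}

fft_convolve <- function(img, kernel_fftlayout) {
  out <- Re(fft(fft(img) * fft(kernel_fftlayout), inverse = TRUE)) /
    length(img)
  pmax(out, 0)
}
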