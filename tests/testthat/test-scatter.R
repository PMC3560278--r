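test_that("transmittance implements the thin phase object", {
  zero <- make_slab_phantom(0)
  cfg <- optical_config()
  t0 <- transmittance(zero, cfg)
  expect_true(all(abs(t0 - 1) < 1e-12))

  # slab of thickness lambda / (2 delta_n) imposes a uniform pi phase
  lam_um <- cfg$wavelength / 1000
  slab <- make_slab_phantom(lam_um / (2 * cfg$delta_n))
  ts <- transmittance(slab, cfg)
  expect_true(all(abs(Mod(ts) - 1) < 1e-12))
  expect_true(all(abs(ts[slab$support_mask] - (-1 + 0i)) < 1e-9))

  # phase profile proportional to the height map (unwrapped regime)
  dome <- generate_phantom(small_params("good", height_mean = 4,
                                        height_sd = 0,
                                        edge_irregularity = 0,
                                        lump_count_mean = 0), seed = 1)
  td <- transmittance(dome, cfg)
  expected_phase <- 2 * pi * cfg$delta_n * dome$height_map / lam_um
  expect_equal(Arg(td), expected_phase, tolerance = 1e-9)
  expect_equal(which.max(Arg(td)), which.max(dome$height_map))
})

test_that("hard circular aperture reproduces the Airy first minimum", {
  n <- 1024; pitch <- 1; D <- 20
  cfg <- optical_config(wavelength = 633, z = 1.58)
  cy <- (n + 1) / 2
  r <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cy)^2, "+")) * pitch
  aperture <- pmin(pmax((D / 2 - r) / pitch + 0.5, 0), 1) # antialiased edge
  pat <- propagate(aperture, pitch, cfg, illumination = "plane")
  # near-unitary: the band limit clips only a sliver of the aperture's
  # spectral tail at this geometry
  expect_equal(sum(pat$intensity), sum(aperture^2), tolerance = 1e-3)
  prof <- radial_profile(pat)
  expect_first_min <- 1.22 * (cfg$wavelength / 1000) * (cfg$z * 1000) / D
  w <- prof$radius_px > 0.6 * expect_first_min &
    prof$radius_px < 1.4 * expect_first_min
  measured <- prof$radius_px[w][which.min(prof$intensity[w])]
  expect_lt(abs(measured - expect_first_min), 1 * pitch)
})

test_that("propagation is unitary on band-limited fields and quadratic in amplitude", {
  set.seed(42)
  f <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64)
  cfg <- optical_config(z = 5)
  # first pass band-limits the field; a second pass must conserve energy
  # band-limit the field explicitly, then check propagation is unitary on it
  n <- 64; pitch <- 4
  fx <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * pitch)
  FX <- matrix(fx, n, n); FY <- t(FX)
  lam <- cfg$wavelength / 1000; z <- cfg$z * 1000
  flim <- 1 / (lam * sqrt((2 * z / (n * pitch))^2 + 1))
  mask <- abs(FX) <= flim & abs(FY) <= flim &
    (1 - lam^2 * (FX^2 + FY^2)) > 0
  fbl <- fft(fft(f) * mask, inverse = TRUE) / n^2
  p2 <- propagate(fbl, pitch, cfg, illumination = "plane")
  expect_equal(sum(p2$intensity), sum(Mod(fbl)^2), tolerance = 1e-9)
  # linearity: scaling the field by c scales intensity by c^2
  p3 <- propagate(3 * fbl, pitch, cfg, illumination = "plane")
  expect_equal(p3$intensity, 9 * p2$intensity, tolerance = 1e-9)
  expect_error(propagate(matrix(1, 4, 6), 4, cfg), "square")
})

test_that("colony phantoms keep most energy on the detector", {
  cfg <- optical_config()
  for (lab in c("good", "bad")) {
    ph <- generate_phantom(phantom_params(lab), seed = 5)
    f <- transmittance(ph, cfg)
    g <- colonyscatter:::grid_coords(nrow(f), ph$params$pixel_pitch)
    beam <- exp(-(g$r^2) / cfg$beam_radius^2)
    pat <- propagate(f, ph$params$pixel_pitch, cfg)
    # steep rims scatter a few percent past the numerical bandwidth
    expect_gt(sum(pat$intensity) / sum(Mod(f * beam)^2), 0.9)
  }
})

test_that("circularly symmetric phantoms give circularly symmetric patterns", {
  ph <- generate_phantom(small_params("good", height_sd = 0,
                                      edge_irregularity = 0,
                                      lump_count_mean = 0,
                                      colony_radius_sd = 0), seed = 1)
  pat <- simulate_pattern(ph, optical_config(), noise = FALSE)
  expect_lt(asymmetry_index(pat, method = "rotation"), 1e-6)
})

test_that("detector simulation is seeded and reduces to propagation without noise", {
  ph <- generate_phantom(small_params("bad"), seed = 9)
  cfg <- optical_config()
  p1 <- simulate_pattern(ph, cfg, seed = 1)
  p2 <- simulate_pattern(ph, cfg, seed = 1)
  expect_identical(p1$intensity, p2$intensity)
  expect_identical(p1$label, "bad")

  quiet <- simulate_pattern(ph, cfg, noise = FALSE)
  ref <- propagate(transmittance(ph, cfg), ph$params$pixel_pitch, cfg,
                   label = ph$label)
  maxcount <- 2^cfg$detector_bits - 1
  expect_lt(max(abs(quiet$intensity / maxcount -
                      ref$intensity / max(ref$intensity))), 1 / maxcount)
})

test_that("scatter asymmetry separates the morphology classes", {
  cfg <- optical_config()
  idx <- function(lab, seeds) vapply(seeds, function(s) {
    ph <- generate_phantom(small_params(lab), seed = s)
    asymmetry_index(simulate_pattern(ph, cfg, seed = s))
  }, numeric(1))
  a_good <- idx("good", 1:12)
  a_bad <- idx("bad", 101:112)
  pooled_sd <- sqrt((var(a_good) + var(a_bad)) / 2)
  expect_gt(mean(a_bad) - mean(a_good), pooled_sd)
})
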