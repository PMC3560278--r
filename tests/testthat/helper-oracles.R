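# Independent oracles and small fixture builders used across test files.

# Pseudo-Zernike radial polynomial by the direct alternating factorial sum.
# Exact (in double precision) for n <= ~8; used as the low-order oracle for
# the recurrence-based implementation.
pz_radial_direct <- function(n, m, rho) {
  m <- abs(m)
  s <- 0:(n - m)
  coef <- (-1)^s * exp(lgamma(2 * n + 2 - s) - lgamma(s + 1) -
                         lgamma(n - m - s + 1) - lgamma(n + m + 2 - s))
  out <- numeric(length(rho))
  for (i in seq_along(s)) out <- out + coef[i] * rho^(n - s[i])
  out
}

# Brute-force pseudo-Zernike moments: explicit per-moment loop over in-disk
# pixels with the factorial-sum radial polynomial. Independent of the
# package's cached-basis path.
brute_pzm <- function(img, n_max) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  radius <- min(nr, nc) / 2
  dy <- matrix(seq_len(nr) - cy, nr, nc)
  dx <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
  rho <- sqrt(dy^2 + dx^2) / radius
  keep <- rho <= 1
  f <- img[keep] / max(img[keep])
  r <- rho[keep]
  th <- atan2(dx[keep], dy[keep])
  dA <- 1 / radius^2
  out <- complex(0)
  ids <- character(0)
  for (n in 0:n_max) for (m in 0:n) {
    R <- pz_radial_direct(n, m, r)
    A <- (n + 1) / pi * sum(f * R * exp(-1i * m * th)) * dA
    out <- c(out, A)
    ids <- c(ids, sprintf("pzm_n%02d_m%02d", n, m))
  }
  names(out) <- ids
  out
}

# hand-built flat-slab phantom (bypasses the generator)
make_slab_phantom <- function(height, n = 64, pitch = 16, radius_px = 24) {
  cy <- (n + 1) / 2
  r <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cy)^2, "+"))
  mask <- r <= radius_px
  h <- matrix(0, n, n)
  h[mask] <- height
  structure(list(height_map = h, support_mask = mask, label = "good",
                 params = phantom_params("good", grid_size = n,
                                         pixel_pitch = pitch)),
            class = "colony_phantom")
}

# compact generator settings used when full 512-px fields are unnecessary
small_params <- function(class_label, ...) {
  phantom_params(class_label, grid_size = 128L, pixel_pitch = 8, ...)
}

# single connected component check by flood fill (4-connectivity)
is_connected_mask <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(FALSE)
  nr <- nrow(mask)
  visited <- logical(length(mask))
  queue <- idx[1]
  visited[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    row <- (cur - 1) %% nr + 1
    nb <- c(if (row > 1) cur - 1, if (row < nr) cur + 1, cur - nr, cur + nr)
    nb <- nb[nb >= 1 & nb <= length(mask)]
    nb <- nb[mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(visited[idx])
}
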