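#' Disk mapping for moment computation
#'
#' Defines how a rectangular pattern is mapped onto the unit disk before
#' pseudo-Zernike moments are computed: the geometric image centre becomes the
#' origin and the inscribed circle becomes the unit circle (both overridable).
#'
#' @param center `(row, col)` of the disk centre in pixels; `NULL` means the
#'   geometric image centre `((nr + 1)/2, (nc + 1)/2)`.
#' @param radius disk radius in pixels; `NULL` means the inscribed circle.
#' @param normalization `"max-one"` (divide by the in-disk maximum) or
#'   `"unit-integral"` (unit integral over the unit disk).
#' @return An object of class `disk_mapping`.
#' @export
disk_mapping <- function(center = NULL, radius = NULL,
                         normalization = c("max-one", "unit-integral")) {
  normalization <- match.arg(normalization)
  structure(list(center = center, radius = radius,
                 normalization = normalization),
            class = "disk_mapping")
}

#' Map a pattern onto the unit disk
#'
#' Restricts the image to pixels whose centres fall inside the mapped unit
#' disk, normalises the intensities per the mapping, and attaches the polar
#' coordinates `rho` in `[0, 1]`, `theta` in `[-pi, pi)` of each retained
#' pixel.
#'
#' @param x a `scatter_pattern` or numeric matrix.
#' @param mapping a [disk_mapping()].
#' @return An object of class `disk_image`: `values`, `rho`, `theta`, `idx`
#'   (linear pixel indices), `dim`, `center`, `radius`, `normalization`.
#' @export
map_to_disk <- function(x, mapping = disk_mapping()) {
  I <- if (inherits(x, "scatter_pattern")) x$intensity else x
  if (!is.matrix(I)) stop("`x` must be a matrix or scatter_pattern",
                          call. = FALSE)
  nr <- nrow(I); nc <- ncol(I)
  center <- mapping$center %||% c((nr + 1) / 2, (nc + 1) / 2)
  radius <- mapping$radius %||% (min(nr, nc) / 2)
  if (radius <= 0) stop("disk radius must be positive", call. = FALSE)
  if (center[1] - radius < 0.5 - 1e-9 || center[1] + radius > nr + 0.5 + 1e-9 ||
      center[2] - radius < 0.5 - 1e-9 || center[2] + radius > nc + 0.5 + 1e-9)
    stop("disk does not fit inside the image bounds", call. = FALSE)
  dy <- matrix(seq_len(nr) - center[1], nr, nc)
  dx <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  rho <- sqrt(dy^2 + dx^2) / radius
  idx <- which(rho <= 1)
  vals <- I[idx]
  if (mapping$normalization == "max-one") {
    mx <- max(vals)
    if (mx <= 0) stop("disk image is identically zero", call. = FALSE)
    vals <- vals / mx
  } else {
    dA <- 1 / radius^2
    s <- sum(vals) * dA
    if (s <= 0) stop("disk image integrates to zero", call. = FALSE)
    vals <- vals / s
  }
  structure(list(values = vals, rho = rho[idx],
                 theta = atan2(dx[idx], dy[idx]),
                 idx = idx, dim = c(nr, nc), center = center, radius = radius,
                 normalization = mapping$normalization),
            class = "disk_image")
}

#' Pseudo-Zernike radial polynomial
#'
#' Evaluates `R_nm(rho)`, the radial part of the pseudo-Zernike basis on the
#' unit disk, defined by the alternating factorial sum
#' `sum_s (-1)^s (2n+1-s)! / (s! (n-|m|-s)! (n+|m|+1-s)!) rho^(n-s)`.
#' For numerical stability at high order the implementation evaluates the
#' equivalent Jacobi form `rho^|m| P^(0, 2|m|+1)_(n-|m|)(2 rho - 1)` by the
#' three-term recurrence; the monomial sum loses roughly twelve digits to
#' cancellation by n = 17. `R_nn(rho) = rho^n`, and for fixed m the
#' polynomials are orthogonal on `[0, 1]` with weight `rho`:
#' `integral R_nm R_n'm rho drho = delta_nn' / (2n + 2)`.
#'
#' @param n non-negative integer order.
#' @param m integer repetition with `|m| <= n`.
#' @param rho numeric vector of radii in `[0, 1]`.
#' @return Numeric vector `R_nm(rho)`.
#' @examples
#' pzm_radial(1, 0, c(0, 0.5, 1))  # 3*rho - 2
#' @export
pzm_radial <- function(n, m, rho) {
  if (n < 0 || n != round(n)) stop("`n` must be a non-negative integer",
                                   call. = FALSE)
  m <- abs(m)
  if (m > n) stop("|m| must not exceed n", call. = FALSE)
  if (any(rho < -1e-12 | rho > 1 + 1e-12))
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  rho <- pmin(pmax(rho, 0), 1)
  rho^m * jacobi_shifted(n - m, 2 * m + 1, rho)
}

# P^(0, b)_k evaluated at x = 2*rho - 1 by the standard three-term recurrence
jacobi_shifted <- function(k, b, rho) {
  x <- 2 * rho - 1
  a <- 0
  pkm1 <- rep(1, length(x))
  if (k == 0) return(pkm1)
  pk <- (a + b + 2) / 2 * x + (a - b) / 2
  if (k == 1) return(pk)
  for (j in 2:k) {
    c1 <- 2 * j * (j + a + b) * (2 * j + a + b - 2)
    c2 <- (2 * j + a + b - 1) * (a^2 - b^2)
    c3 <- (2 * j + a + b - 2) * (2 * j + a + b - 1) * (2 * j + a + b)
    c4 <- 2 * (j + a - 1) * (j + b - 1) * (2 * j + a + b)
    pnew <- ((c2 + c3 * x) * pk - c4 * pkm1) / c1
    pkm1 <- pk
    pk <- pnew
  }
  pk
}

# ordered (n, m) table for a given maximum order: n ascending, m ascending
pzm_index_table <- function(n_max) {
  n <- rep.int(0:n_max, 0:n_max + 1L)
  m <- unlist(lapply(0:n_max, seq.int, from = 0), use.names = FALSE)
  data.frame(n = n, m = m,
             id = sprintf("pzm_n%02d_m%02d", n, m))
}

#' Number of pseudo-Zernike magnitude features up to a given order
#'
#' `(n_max + 1) * (n_max + 2) / 2` features: one magnitude per pair
#' `0 <= m <= n <= n_max` (negative repetitions are conjugates and carry no
#' extra magnitude information). The default pipeline order 17 yields 171.
#'
#' @param n_max maximum order.
#' @return Integer feature count.
#' @export
pzm_feature_count <- function(n_max) {
  as.integer((n_max + 1) * (n_max + 2) / 2)
}

# one-slot basis cache: radial matrices and angular harmonics per geometry
.pzm_cache <- new.env(parent = emptyenv())

pzm_basis <- function(disk, n_max) {
  key <- paste(disk$dim[1], disk$dim[2], disk$center[1], disk$center[2],
               signif(disk$radius, 12), n_max, sep = "_")
  hit <- .pzm_cache$basis
  if (!is.null(hit) && identical(hit$key, key)) return(hit)
  rho <- disk$rho
  theta <- disk$theta
  per_m <- vector("list", n_max + 1L)
  for (m in 0:n_max) {
    ks <- 0:(n_max - m)
    Rm <- matrix(0, length(rho), length(ks))
    rm <- rho^m
    for (k in ks) Rm[, k + 1L] <- rm * jacobi_shifted(k, 2 * m + 1, rho)
    per_m[[m + 1L]] <- list(R = Rm, c = cos(m * theta), s = sin(m * theta))
  }
  out <- list(key = key, per_m = per_m, n_max = n_max)
  .pzm_cache$basis <- out
  out
}

#' Compute pseudo-Zernike moments of a disk-mapped image
#'
#' Discretises `A_nm = (n + 1) / pi * integral f(rho, theta) R_nm(rho)
#' exp(-i m theta) dA` by midpoint pixel sampling over the in-disk pixels,
#' with the pixel area expressed in unit-disk units (`1 / radius^2`). The
#' magnitudes `|A_nm|` are invariant under image rotation. Basis matrices are
#' cached per disk geometry, so repeated extraction over a batch of patterns
#' with identical geometry costs one basis build.
#'
#' @param disk a `disk_image` from [map_to_disk()].
#' @param n_max maximum moment order (default 17, giving 171 magnitudes).
#' @return An object of class `pzm_set`: `n_max`, `index` (data.frame of
#'   `n`, `m`, `id`), `moments` (complex, ordered n ascending then m
#'   ascending), `magnitudes` (named numeric).
#' @export
compute_pzm <- function(disk, n_max = 17L) {
  if (!inherits(disk, "disk_image"))
    stop("`disk` must come from map_to_disk()", call. = FALSE)
  if (n_max < 0 || n_max != round(n_max))
    stop("`n_max` must be a non-negative integer", call. = FALSE)
  if (length(disk$values) == 0)
    stop("empty disk image", call. = FALSE)
  basis <- pzm_basis(disk, n_max)
  f <- disk$values
  dA <- 1 / disk$radius^2
  tab <- pzm_index_table(n_max)
  mom <- complex(nrow(tab))
  for (m in 0:n_max) {
    B <- basis$per_m[[m + 1L]]
    re <- crossprod(B$R, f * B$c)[, 1]
    im <- -crossprod(B$R, f * B$s)[, 1]
    ns <- m:n_max
    rows <- match(paste(ns, m), paste(tab$n, tab$m))
    mom[rows] <- ((ns + 1) / pi) * dA * complex(real = re, imaginary = im)
  }
  mags <- Mod(mom)
  names(mags) <- tab$id
  structure(list(n_max = as.integer(n_max), index = tab, moments = mom,
                 magnitudes = mags),
            class = "pzm_set")
}

#' Extract a pseudo-Zernike feature vector from one scatter pattern
#'
#' The standard preprocessing for detector patterns: log-compression
#' `log(1 + I)` to tame the bright central lobe, mapping onto the unit disk
#' with max-one normalisation, then pseudo-Zernike magnitudes up to `n_max`.
#'
#' @param pattern a `scatter_pattern` or numeric matrix.
#' @param n_max maximum moment order.
#' @param mapping a [disk_mapping()]; the default uses the geometric centre
#'   and inscribed circle.
#' @param log_compress apply `log1p` before disk normalisation?
#' @return Named numeric vector of `pzm_feature_count(n_max)` magnitudes with
#'   attributes `label` (if the pattern carries one) and `n_max`.
#' @export
extract_features <- function(pattern, n_max = 17L, mapping = disk_mapping(),
                             log_compress = TRUE) {
  I <- if (inherits(pattern, "scatter_pattern")) pattern$intensity
       else pattern
  if (log_compress) I <- log1p(I)
  disk <- map_to_disk(I, mapping)
  v <- compute_pzm(disk, n_max)$magnitudes
  attr(v, "label") <- if (inherits(pattern, "scatter_pattern"))
    pattern$label else NULL
  attr(v, "n_max") <- as.integer(n_max)
  v
}

#' Feature table for a batch of patterns
#'
#' @param patterns list of `scatter_pattern` objects (or matrices).
#' @param source_ids optional character ids, default `pattern_001`, ...
#' @inheritParams extract_features
#' @return A data.frame with columns `source_id`, `label`, then one column
#'   per pseudo-Zernike magnitude.
#' @export
extract_feature_table <- function(patterns, n_max = 17L,
                                  mapping = disk_mapping(),
                                  log_compress = TRUE, source_ids = NULL) {
  stopifnot(is.list(patterns))
  if (length(patterns) == 0) {
    empty <- as.data.frame(matrix(numeric(0), 0, pzm_feature_count(n_max)))
    names(empty) <- pzm_index_table(n_max)$id
    return(cbind(data.frame(source_id = character(0),
                            label = character(0)), empty))
  }
  source_ids <- source_ids %||%
    sprintf("pattern_%03d", seq_along(patterns))
  rows <- lapply(patterns, extract_features, n_max = n_max,
                 mapping = mapping, log_compress = log_compress)
  mat <- do.call(rbind, rows)
  labels <- vapply(patterns, function(p) {
    lb <- if (inherits(p, "scatter_pattern")) p$label else NULL
    if (is.null(lb)) NA_character_ else lb
  }, character(1))
  data.frame(source_id = source_ids, label = labels, mat,
             check.names = FALSE, row.names = NULL)
}

# split a feature table / matrix into a plain numeric matrix + labels
feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    drop_cols <- intersect(c("source_id", "label"), names(x))
    m <- as.matrix(x[setdiff(names(x), drop_cols)])
    list(x = m, labels = if ("label" %in% names(x)) x$label else NULL,
         source_id = if ("source_id" %in% names(x)) x$source_id else NULL)
  } else {
    list(x = as.matrix(x), labels = NULL, source_id = NULL)
  }
}

#' Fisher-criterion feature ranking
#'
#' Scores each feature `j` by `F(j) = (mu_good - mu_bad)^2 /
#' (s2_good + s2_bad + eps)` with per-class sample means and (n-1) variances,
#' ranks features by descending score (ties broken by lower feature index),
#' and marks the top `k` for selection. `F` is invariant under a common shift
#' of both classes and its ranking under common positive rescaling.
#'
#' @param features_good,features_bad numeric matrices (rows = patterns) or
#'   feature tables from [extract_feature_table()]; at least two rows each.
#' @param k number of features to select (default 161, the standard pipeline
#'   size; capped checks are performed at selection time).
#' @param eps variance-regularisation constant guarding zero-variance
#'   features.
#' @return An object of class `fisher_ranking`: `scores`, `ranking`
#'   (permutation of feature indices, best first), `selected_mask`, `k`,
#'   `feature_ids`.
#' @export
fisher_scores <- function(features_good, features_bad, k = 161L,
                          eps = 1e-12) {
  G <- feature_matrix(features_good)$x
  B <- feature_matrix(features_bad)$x
  if (ncol(G) != ncol(B))
    stop("feature dimension mismatch between classes", call. = FALSE)
  if (nrow(G) < 2 || nrow(B) < 2)
    stop("need at least two samples per class for Fisher scores",
         call. = FALSE)
  mu_g <- colMeans(G); mu_b <- colMeans(B)
  v_g <- apply(G, 2, var); v_b <- apply(B, 2, var)
  scores <- (mu_g - mu_b)^2 / (v_g + v_b + eps)
  p <- length(scores)
  k <- min(as.integer(k), p)
  ranking <- order(-scores, seq_len(p))
  mask <- logical(p)
  mask[ranking[seq_len(k)]] <- TRUE
  ids <- colnames(G) %||% sprintf("f%03d", seq_len(p))
  structure(list(scores = unname(scores), ranking = ranking,
                 selected_mask = mask, k = k, feature_ids = ids),
            class = "fisher_ranking")
}

#' Select the top-ranked features
#'
#' @param ranking a `fisher_ranking`.
#' @param x feature matrix or feature table whose feature columns match the
#'   ranking dimension.
#' @param k how many features to keep (default the ranking's `k`, itself
#'   161 by default); must not exceed the total feature count.
#' @return The same type as `x` restricted to the `k` best features, columns
#'   ordered by descending Fisher score; feature ids preserved.
#' @export
select_features <- function(ranking, x, k = NULL) {
  if (!inherits(ranking, "fisher_ranking"))
    stop("`ranking` must come from fisher_scores()", call. = FALSE)
  k <- as.integer(k %||% ranking$k)
  p <- length(ranking$scores)
  if (k < 1 || k > p)
    stop(sprintf("`k` must lie in [1, %d]", p), call. = FALSE)
  keep <- ranking$ranking[seq_len(k)]
  if (is.data.frame(x)) {
    meta <- intersect(c("source_id", "label"), names(x))
    featcols <- setdiff(names(x), meta)
    if (length(featcols) != p)
      stop("feature dimension does not match the ranking", call. = FALSE)
    return(x[c(meta, featcols[keep])])
  }
  x <- as.matrix(x)
  if (ncol(x) != p)
    stop("feature dimension does not match the ranking", call. = FALSE)
  x[, keep, drop = FALSE]
}
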