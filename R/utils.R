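# internal helpers shared across modules

# run expr under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL means "use whatever RNG state is current"
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

check_label <- function(label) {
  if (!is.character(label) || length(label) != 1L ||
      !label %in% c("good", "bad"))
    stop("`class_label` must be \"good\" or \"bad\"", call. = FALSE)
  label
}

# centred pixel coordinates in micrometres for an n x n grid
grid_coords <- function(n, pitch) {
  x <- (seq_len(n) - (n + 1) / 2) * pitch
  X <- matrix(x, n, n)           # varies along rows
  list(X = X, Y = t(X), r = sqrt(X^2 + t(X)^2), theta = atan2(t(X), X))
}

# 90 deg counter-clockwise rotation of a matrix
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# truncated-normal draw on (lower, Inf) by inverse-CDF (no resampling)
rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(max(mean, lower), n))
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
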