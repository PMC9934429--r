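# Small vector/angle helpers shared across the package. All coordinates are
# in nm, all angles in degrees unless a function says otherwise.

vec_norm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @export
wrap180 <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

# Rodrigues rotation matrix about a (not necessarily unit) axis, angle in
# degrees, right-hand rule.
rotation_about <- function(axis, angle_deg) {
  k <- unitize(axis)
  a <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3L], -k[2L],
                -k[3L], 0, k[1L],
                k[2L], -k[1L], 0), nrow = 3L)
  diag(3L) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Apply a 3x3 rotation to an n x 3 coordinate matrix.
rotate_coords <- function(xyz, R) {
  out <- xyz %*% t(R)
  dimnames(out) <- dimnames(xyz)
  out
}

translate_coords <- function(xyz, v) {
  out <- sweep(xyz, 2L, v, "+")
  dimnames(out) <- dimnames(xyz)
  out
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Boltzmann constant in kcal mol^-1 K^-1.
KB_KCAL <- 0.0019872

# Centered moving average; window forced odd; edges use shrunken windows.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L) stop("smoothing window must be >= 1", call. = FALSE)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Polynomial rolling hash of a character string, returned as 8 hex digits.
# Used to stamp run reports with a configuration fingerprint without
# external dependencies; not cryptographic.
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}
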