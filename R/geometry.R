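# Helix-axis models and inter-helix descriptors: global axis from the
# leading/trailing 4-residue centers, segmented local axes k_j from
# consecutive 4-residue group centers, the signed crossing angle Omega
# (negative = left-handed packing), lateral separation L, the N/C terminal
# distance difference delta-d, and the rotation reference vector h_ref.

#' Global helix axis from end-group centers
#'
#' The axis is the normalized vector from the center of the first four
#' backbone beads (N-terminal) to the center of the last four (C-terminal),
#' so it always points N to C.
#'
#' @param beads n x 3 backbone coordinate matrix (nm), beads ordered N to C,
#'   n >= 8.
#' @return list with `axis` (unit vector), `n_center`, `c_center` (nm).
#' @export
global_axis <- function(beads) {
  beads <- as.matrix(beads)
  n <- nrow(beads)
  if (n < 8L)
    stop("need at least 8 beads to define the global helix axis", call. = FALSE)
  nc <- colMeans(beads[1:4, , drop = FALSE])
  cc <- colMeans(beads[(n - 3L):n, , drop = FALSE])
  list(axis = unitize(cc - nc), n_center = nc, c_center = cc)
}

#' Segmented local axes from 4-residue group centers
#'
#' The chain is divided into consecutive groups of four residues; group j
#' spans residues 4(j-1)+1 .. 4j. For the default 28-residue chain (25 TMD
#' residues plus 3 linker residues) this yields exactly 7 group centers and
#' 6 direction vectors k_j, each pointing from center j to center j+1
#' (N to C). The k_j tolerate helix bending: a bent helix's local axes track
#' the bend while the global axis does not.
#'
#' @param beads n x 3 backbone coordinate matrix, beads ordered N to C.
#' @param strict if TRUE (default), require exactly 28 beads; if FALSE, any
#'   multiple of 4 (>= 8 beads) is grouped the same way.
#' @return list with `centers` (m x 3 matrix) and `k` (m-1 x 3 matrix of
#'   unit vectors).
#' @export
segment_axes <- function(beads, strict = TRUE) {
  beads <- as.matrix(beads)
  n <- nrow(beads)
  if (strict && n != 28L)
    stop(sprintf("expected 28 beads (25 TMD + 3 linker residues), got %d; use strict = FALSE to generalize",
                 n), call. = FALSE)
  if (n < 8L || n %% 4L != 0L)
    stop("bead count must be a multiple of 4 and >= 8", call. = FALSE)
  m <- n %/% 4L
  centers <- t(vapply(seq_len(m), function(j)
    colMeans(beads[(4L * (j - 1L) + 1L):(4L * j), , drop = FALSE]),
    numeric(3L)))
  k <- t(vapply(seq_len(m - 1L), function(j)
    unitize(centers[j + 1L, ] - centers[j, ]), numeric(3L)))
  list(centers = centers, k = k)
}

#' Signed crossing angle between two helices
#'
#' The magnitude is acos(h1 . h2) for the unit global axes h1, h2, mapped to
#' the acute equivalent so |Omega| < 90 degrees (if the axes subtend more
#' than 90 degrees, one is flipped before signing). The sign encodes packing
#' handedness: negative for a left-handed overlay, positive for a
#' right-handed one. Operationally, with c the common-perpendicular
#' direction from helix A to helix B, sign(Omega) = -sign((h1 x h2) . c);
#' the constant is calibrated so a constructed canonical left-handed pair
#' returns a negative angle.
#'
#' Near-parallel axes (|Omega| < 0.5 degrees after acute mapping) are
#' reported as 0 with `degenerate = TRUE`.
#'
#' @param beadsA,beadsB backbone coordinate matrices of the two helices.
#' @return list with `omega` (signed degrees, |omega| < 90) and `degenerate`.
#' @export
crossing_angle <- function(beadsA, beadsB) {
  axA <- global_axis(beadsA)
  axB <- global_axis(beadsB)
  h1 <- axA$axis
  h2 <- axB$axis
  if (sum(h1 * h2) < 0) h2 <- -h2     # acute mapping: |Omega| < 90
  cosang <- max(-1, min(1, sum(h1 * h2)))
  ang <- rad2deg(acos(cosang))
  if (ang < 0.5)
    return(list(omega = 0, degenerate = TRUE))
  sep <- colMeans(as.matrix(beadsB)) - colMeans(as.matrix(beadsA))
  s <- -sign(sum(cross3(h1, h2) * sep))
  if (s == 0) s <- 1
  list(omega = s * ang, degenerate = FALSE)
}

#' Lateral helix separation L
#'
#' `center` mode (default) is the distance between the backbone-bead
#' centroids of the two helices, which matches the scale of reported packed
#' dimer separations (~1 nm); `min_pair` is the minimum distance over all
#' inter-helix bead pairs.
#'
#' @param beadsA,beadsB backbone coordinate matrices (nm).
#' @param mode `"center"` or `"min_pair"`.
#' @return separation in nm.
#' @export
lateral_separation <- function(beadsA, beadsB,
                               mode = c("center", "min_pair")) {
  mode <- match.arg(mode)
  A <- as.matrix(beadsA); B <- as.matrix(beadsB)
  if (!nrow(A) || !nrow(B)) stop("empty bead selection", call. = FALSE)
  if (mode == "center") {
    vec_norm(colMeans(A) - colMeans(B))
  } else {
    sqrt(max(0, min(cross_dist2(A, B))))
  }
}

#' N/C-termini distance difference delta-d
#'
#' delta_d = ||N_A - N_B|| - ||C_A - C_B||, where N and C are the 4-residue
#' end centers of each helix. Positive when the N-termini are farther apart
#' than the C-termini (the dimer is "opened" at the N side).
#'
#' @param beadsA,beadsB backbone coordinate matrices (nm).
#' @return delta-d in nm.
#' @export
delta_d <- function(beadsA, beadsB) {
  axA <- global_axis(beadsA)
  axB <- global_axis(beadsB)
  vec_norm(axA$n_center - axB$n_center) - vec_norm(axA$c_center - axB$c_center)
}

#' Rotation reference vector h_ref
#'
#' The reference line from which residue rotation angles are measured. When
#' the crossing angle is away from zero (|Omega| >= `fallback_threshold`),
#' h_ref is parallel to h1 x h2, oriented so it points from the target helix
#' toward its partner. Near-parallel helices make that cross product
#' unreliable, so for |Omega| < `fallback_threshold` (default 14.4 degrees)
#' h_ref is instead the vector from the target helix midpoint (center of the
#' four central residues, residues 777-780 for the default 765-792
#' numbering) to the partner's axis, which is perpendicular to the partner
#' axis by construction.
#'
#' @param beadsA,beadsB backbone coordinate matrices.
#' @param target `"A"` or `"B"`: the helix whose rotation is being measured.
#' @param omega signed crossing angle in degrees; computed from the beads
#'   when NULL.
#' @param fallback_threshold switch-over |Omega| in degrees.
#' @return unit reference vector (length-3 numeric).
#' @export
reference_vector <- function(beadsA, beadsB, target = c("A", "B"),
                             omega = NULL, fallback_threshold = 14.4) {
  target <- match.arg(target)
  A <- as.matrix(beadsA); B <- as.matrix(beadsB)
  if (is.null(omega)) omega <- crossing_angle(A, B)$omega
  tgt <- if (target == "A") A else B
  par <- if (target == "A") B else A
  if (abs(omega) >= fallback_threshold) {
    h1 <- global_axis(A)$axis
    h2 <- global_axis(B)$axis
    v <- cross3(h1, h2)
    if (vec_norm(v) < 1e-9)
      stop("degenerate geometry: helix axes are parallel outside the fallback regime",
           call. = FALSE)
    v <- unitize(v)
    if (sum(v * (colMeans(par) - colMeans(tgt))) < 0) v <- -v
    v
  } else {
    mid <- helix_midpoint(tgt)
    axP <- global_axis(par)
    p0 <- (axP$n_center + axP$c_center) / 2
    w <- mid - p0
    foot <- p0 + sum(w * axP$axis) * axP$axis
    unitize(foot - mid)
  }
}

# Center of the four central residues (residues 777-780 when 28 beads are
# numbered 765-792); generalizes to the middle 4 beads for other lengths.
helix_midpoint <- function(beads) {
  n <- nrow(beads)
  if (n < 4L) return(colMeans(beads))
  start <- floor((n - 4L) / 2) + 1L
  colMeans(beads[start:(start + 3L), , drop = FALSE])
}

#' Per-frame dimer geometry
#'
#' Computes the signed crossing angle, lateral separation and delta-d for
#' one frame.
#'
#' @param frame a `bead_frame`.
#' @param L_mode separation mode passed to [lateral_separation()].
#' @return list with `omega`, `L`, `delta_d`, `degenerate`.
#' @export
frame_geometry <- function(frame, L_mode = "center") {
  ca <- crossing_angle(frame$A, frame$B)
  list(omega = ca$omega,
       L = lateral_separation(frame$A, frame$B, mode = L_mode),
       delta_d = delta_d(frame$A, frame$B),
       degenerate = ca$degenerate)
}
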