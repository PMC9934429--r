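# Per-residue rotation angles about the segmented local helix axes, and the
# helix-level unwrapped rotation time series (dtheta_A, dtheta_B).

# k-vector index for residue i: residues 1-24 use j = ceil(i/4); residues
# 25+ reuse the last vector k_6 (there is no k_7 for the trailing group).
residue_group <- function(i, n_k) pmin(ceiling(i / 4), n_k)

#' Rotation angle of one residue about its local helix axis
#'
#' The bead is projected onto the plane perpendicular to the local axis
#' direction `k` (the radial vector is bead minus its perpendicular foot on
#' the line through `axis_point` along `k`). The angle is measured from the
#' purified reference h_perp = normalize(h_ref - (h_ref . k) k) to that
#' radial vector, signed positive counterclockwise when viewed from the
#' C-terminal side (looking along -k).
#'
#' @param bead length-3 coordinate (nm).
#' @param axis_point a point on the local axis line (nm).
#' @param k unit local axis direction (N to C).
#' @param h_ref rotation reference vector (see [reference_vector()]).
#' @return angle in degrees in (-180, 180], or NA if the bead lies on the
#'   axis (projection norm < 1e-6 nm).
#' @export
residue_angle <- function(bead, axis_point, k, h_ref) {
  k <- unitize(k)
  w <- bead - axis_point
  r <- w - sum(w * k) * k
  if (vec_norm(r) < 1e-6) return(NA_real_)
  hp <- h_ref - sum(h_ref * k) * k
  if (vec_norm(hp) < 1e-9) return(NA_real_)
  hp <- unitize(hp)
  r <- unitize(r)
  rad2deg(atan2(sum(cross3(hp, r) * k), sum(hp * r)))
}

# All residue angles for one helix in one frame. 'residues' are internal
# indices (1 = first selected residue). Returns named numeric vector.
helix_residue_angles <- function(beads, h_ref, residues = 1:25,
                                 strict = TRUE) {
  seg <- segment_axes(beads, strict = strict)
  n_k <- nrow(seg$k)
  vapply(residues, function(i) {
    j <- residue_group(i, n_k)
    residue_angle(beads[i, ], seg$centers[j, ], seg$k[j, ], h_ref)
  }, numeric(1L))
}

# Residue angles for both helices of a frame (list A=, B=).
frame_residue_angles <- function(frame, residues = 1:25, strict = TRUE,
                                 fallback_threshold = 14.4) {
  om <- crossing_angle(frame$A, frame$B)$omega
  hA <- reference_vector(frame$A, frame$B, "A", omega = om,
                         fallback_threshold = fallback_threshold)
  hB <- reference_vector(frame$A, frame$B, "B", omega = om,
                         fallback_threshold = fallback_threshold)
  list(A = helix_residue_angles(frame$A, hA, residues, strict),
       B = helix_residue_angles(frame$B, hB, residues, strict))
}

#' Helix rotation of a frame relative to a reference frame
#'
#' Per-residue angle differences theta_s,i - theta_0,i are wrapped into
#' (-180, 180] and averaged over the analyzed residues (default the 25 TMD
#' residues), separately for each helix. Residues with undefined angles are
#' dropped from the average; a frame with more than `max_undefined` dropped
#' residues per helix is marked unreliable.
#'
#' For rotations that may exceed 180 degrees over a trajectory use
#' [rotation_timeseries()], which unwraps cumulatively.
#'
#' @param frame,ref_frame `bead_frame`s with identical selections.
#' @param residues internal residue indices to average over.
#' @param max_undefined tolerated undefined residues per helix.
#' @param strict passed to [segment_axes()].
#' @return list with `dtheta_A`, `dtheta_B` (degrees) and `reliable`.
#' @export
frame_rotation <- function(frame, ref_frame, residues = 1:25,
                           max_undefined = 5L, strict = TRUE) {
  th_s <- frame_residue_angles(frame, residues, strict)
  th_0 <- frame_residue_angles(ref_frame, residues, strict)
  avg <- function(a, b) {
    d <- wrap180(a - b)
    list(mean = mean(d, na.rm = TRUE), n_undef = sum(is.na(d)))
  }
  dA <- avg(th_s$A, th_0$A)
  dB <- avg(th_s$B, th_0$B)
  list(dtheta_A = dA$mean, dtheta_B = dB$mean,
       reliable = dA$n_undef <= max_undefined && dB$n_undef <= max_undefined)
}

#' Helix rotation time series over a trajectory
#'
#' Per-residue angles are unwrapped along time (successive differences
#' wrapped into (-180, 180] and cumulatively summed) before averaging over
#' residues, so rotations beyond +/-180 degrees (e.g. a 300-degree ramp) are
#' reported as such rather than aliased. Frame 0 defines zero.
#'
#' @param frames a `dimer_frames` trajectory (>= 2 frames).
#' @param residues internal residue indices averaged per helix.
#' @param strict passed to [segment_axes()].
#' @param fallback_threshold |Omega| below which the midpoint reference is
#'   used (see [reference_vector()]).
#' @return object of class `rotation_series`: list with `time`, `dtheta_A`,
#'   `dtheta_B` (numeric vectors, degrees) and `residue_A`, `residue_B`
#'   (frames x residues matrices of unwrapped per-residue traces).
#' @export
rotation_timeseries <- function(frames, residues = 1:25, strict = TRUE,
                                fallback_threshold = 14.4) {
  if (length(frames) < 2L)
    stop("need at least 2 frames for a rotation time series", call. = FALSE)
  nf <- length(frames)
  thA <- matrix(NA_real_, nf, length(residues))
  thB <- matrix(NA_real_, nf, length(residues))
  for (s in seq_len(nf)) {
    th <- frame_residue_angles(frames[[s]], residues, strict,
                               fallback_threshold)
    thA[s, ] <- th$A
    thB[s, ] <- th$B
  }
  unwrap <- function(m) {
    for (c in seq_len(ncol(m))) {
      x <- m[, c]
      d <- wrap180(diff(x))
      m[, c] <- c(0, cumsum(d))
    }
    m
  }
  uA <- unwrap(thA)
  uB <- unwrap(thB)
  structure(list(time = vapply(seq_len(nf), function(s) frames[[s]]$time,
                               numeric(1L)),
                 dtheta_A = rowMeans(uA, na.rm = TRUE),
                 dtheta_B = rowMeans(uB, na.rm = TRUE),
                 residue_A = uA, residue_B = uB),
            class = "rotation_series")
}

#' @export
print.rotation_series <- function(x, ...) {
  cat(sprintf(
    "rotation_series: %d frames; final dtheta_A = %.1f deg, dtheta_B = %.1f deg\n",
    length(x$time), x$dtheta_A[length(x$time)], x$dtheta_B[length(x$time)]))
  invisible(x)
}

#' @export
plot.rotation_series <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$dtheta_A, x$dtheta_B), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "time", ylab = expression(Delta * theta ~ "(deg)"),
                    ...)
  graphics::legend("topleft", legend = c("helix A", "helix B"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
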