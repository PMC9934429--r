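#' Ideal helix parameters
#'
#' Describes an idealized alpha-helical backbone with one bead per residue
#' (a MARTINI BB bead or a C-alpha trace): a constant axial rise, a constant
#' twist per residue, and a fixed bead distance from the helical axis.
#'
#' Defaults are the canonical alpha-helix backbone values: 0.15 nm rise and
#' 100 degrees twist per residue, with the backbone bead 0.23 nm off-axis.
#'
#' @param n_res number of residues (beads), >= 1.
#' @param rise axial translation per residue in nm, > 0.
#' @param twist rotation per residue in degrees, in (0, 360).
#' @param radius bead distance from the helix axis in nm, >= 0.
#' @return an object of class `helix_spec`.
#' @seealso [build_ideal_helix()]
#' @export
helix_spec <- function(n_res = 28L, rise = 0.15, twist = 100, radius = 0.23) {
  n_res <- as.integer(n_res)
  if (is.na(n_res) || n_res < 1L)
    stop("'n_res' must be an integer >= 1", call. = FALSE)
  stopifnot_scalar(rise, "rise", positive = TRUE)
  stopifnot_scalar(radius, "radius", nonneg = TRUE)
  stopifnot_scalar(twist, "twist")
  if (twist <= 0 || twist >= 360)
    stop("'twist' must lie strictly between 0 and 360 degrees", call. = FALSE)
  structure(list(n_res = n_res, rise = rise, twist = twist, radius = radius),
            class = "helix_spec")
}

#' Dimer pose parameters
#'
#' The controllable analogue of the measured dimer descriptors: inter-axis
#' separation (cf. lateral separation L), signed crossing angle (negative =
#' left-handed packing), per-helix spin about its own axis (cf. the helix
#' rotation angles), and an axial slide of helix B relative to A.
#'
#' @param separation inter-axis center distance in nm, >= 0.
#' @param crossing signed target crossing angle in degrees, |crossing| < 90.
#' @param spinA,spinB rotation of each helix about its own axis, degrees,
#'   positive counterclockwise viewed from the C-terminal side.
#' @param slide axial offset of helix B relative to helix A, nm.
#' @return an object of class `dimer_pose`.
#' @export
dimer_pose <- function(separation = 1.0, crossing = 0, spinA = 0, spinB = 0,
                       slide = 0) {
  stopifnot_scalar(separation, "separation", nonneg = TRUE)
  stopifnot_scalar(crossing, "crossing")
  if (abs(crossing) >= 90)
    stop("|crossing| must be < 90 degrees", call. = FALSE)
  stopifnot_scalar(spinA, "spinA")
  stopifnot_scalar(spinB, "spinB")
  stopifnot_scalar(slide, "slide")
  structure(list(separation = separation, crossing = crossing,
                 spinA = spinA, spinB = spinB, slide = slide),
            class = "dimer_pose")
}

#' Scripted trajectory description
#'
#' Waypoints are poses at strictly increasing times; frames between
#' waypoints are obtained by linear interpolation of every pose parameter
#' (angles are authored unwrapped, so a spin ramp 0 -> 300 really sweeps 300
#' degrees). Gaussian positional noise and a smooth single-mode axis bend
#' emulate the bending and wiggling of real transmembrane helices.
#'
#' @param waypoints data.frame with columns `time`, `separation`, `crossing`,
#'   `spinA`, `spinB`, `slide`; times strictly increasing. Missing pose
#'   columns default to the [dimer_pose()] defaults.
#' @param noise_sd isotropic Gaussian positional noise sd in nm, >= 0.
#' @param bend_amplitude amplitude in nm of a half-sine bow applied to each
#'   helix axis (0 = straight helices).
#' @param seed integer random seed; equal seeds give bit-identical output.
#' @return an object of class `trajectory_script`.
#' @export
trajectory_script <- function(waypoints, noise_sd = 0, bend_amplitude = 0,
                              seed = 1L) {
  if (!is.data.frame(waypoints) || nrow(waypoints) < 1L)
    stop("'waypoints' must be a data.frame with at least one row", call. = FALSE)
  if (!"time" %in% names(waypoints))
    stop("'waypoints' must have a 'time' column", call. = FALSE)
  defaults <- unclass(dimer_pose())
  for (nm in names(defaults))
    if (!nm %in% names(waypoints)) waypoints[[nm]] <- defaults[[nm]]
  if (nrow(waypoints) > 1L && any(diff(waypoints$time) <= 0))
    stop("waypoint times must be strictly increasing", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(bend_amplitude, "bend_amplitude", nonneg = TRUE)
  # validate each waypoint pose
  for (r in seq_len(nrow(waypoints)))
    dimer_pose(waypoints$separation[r], waypoints$crossing[r],
               waypoints$spinA[r], waypoints$spinB[r], waypoints$slide[r])
  structure(list(waypoints = waypoints[order(waypoints$time), , drop = FALSE],
                 noise_sd = noise_sd, bend_amplitude = bend_amplitude,
                 seed = as.integer(seed)),
            class = "trajectory_script")
}

#' Build an ideal helix backbone
#'
#' Bead i (i = 1..n_res, ordered N to C) is placed at axial position
#' (i-1) * rise along +z, azimuth (i-1) * twist, at `radius` from the z axis.
#' The construction axis is +z through the origin.
#'
#' @param spec a [helix_spec()].
#' @param first_resno residue number of the first bead (rownames of the
#'   returned matrix carry residue numbers).
#' @return an n_res x 3 coordinate matrix (nm), rows named by residue number.
#' @export
build_ideal_helix <- function(spec = helix_spec(), first_resno = 765L) {
  if (!inherits(spec, "helix_spec")) spec <- do.call(helix_spec, as.list(spec))
  i <- seq_len(spec$n_res) - 1L
  ang <- deg2rad(i * spec$twist)
  xyz <- cbind(x = spec$radius * cos(ang),
               y = spec$radius * sin(ang),
               z = i * spec$rise)
  rownames(xyz) <- as.character(first_resno + i)
  xyz
}

# Tilt directions used to realize a signed crossing angle: helix A is tilted
# by +crossing/2 and helix B by -crossing/2 about the inter-axis
# perpendicular (+x, pointing A -> B). Calibrated so that a negative
# 'crossing' yields a left-handed overlay as reported by crossing_angle().
pose_axis_directions <- function(crossing) {
  RA <- rotation_about(c(1, 0, 0), crossing / 2)
  RB <- rotation_about(c(1, 0, 0), -crossing / 2)
  list(RA = RA, RB = RB,
       axisA = as.numeric(RA %*% c(0, 0, 1)),
       axisB = as.numeric(RB %*% c(0, 0, 1)))
}

#' Assemble a two-helix dimer frame from a pose
#'
#' Each helix is spun about its own axis, centered, tilted symmetrically by
#' +/- crossing/2 about the inter-axis perpendicular (so neither helix is
#' privileged), and the helices are separated along x with helix A at
#' -separation/2 and helix B at +separation/2; helix B is finally slid along
#' its own (tilted) axis. On noise-free input the analyzed descriptors
#' reproduce the pose within the documented tolerances.
#'
#' @param helixA,helixB n x 3 backbone coordinate matrices from
#'   [build_ideal_helix()].
#' @param pose a [dimer_pose()].
#' @param time time stamp attached to the frame.
#' @return a `bead_frame`: list with elements `A`, `B` (coordinate matrices,
#'   nm, rownames = residue numbers) and `time`.
#' @export
assemble_dimer <- function(helixA, helixB, pose = dimer_pose(), time = 0) {
  if (!inherits(pose, "dimer_pose")) pose <- do.call(dimer_pose, as.list(pose))
  place <- function(xyz, spin, R, xoff) {
    xyz <- rotate_coords(xyz, rotation_about(c(0, 0, 1), spin))
    xyz <- translate_coords(xyz, -colMeans(xyz))
    xyz <- rotate_coords(xyz, R)
    translate_coords(xyz, c(xoff, 0, 0))
  }
  tilt <- pose_axis_directions(pose$crossing)
  A <- place(helixA, pose$spinA, tilt$RA, -pose$separation / 2)
  B <- place(helixB, pose$spinB, tilt$RB, +pose$separation / 2)
  if (pose$slide != 0)
    B <- translate_coords(B, pose$slide * tilt$axisB)
  d2min <- max(0, min(cross_dist2(A, B)))
  if (sqrt(d2min) < 0.1)
    warning(sprintf("beads of the two helices overlap (min distance %.3f nm)",
                    sqrt(d2min)), call. = FALSE)
  bead_frame(A, B, time)
}

# squared distances between all rows of A and B (nA x nB matrix)
cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

#' Construct a bead frame
#'
#' @param A,B n x 3 coordinate matrices (nm) for the two helices, beads
#'   ordered N to C, rownames carrying residue numbers.
#' @param time time stamp.
#' @return object of class `bead_frame`.
#' @export
bead_frame <- function(A, B, time = 0) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != 3L || ncol(B) != 3L)
    stop("bead coordinate matrices must have 3 columns", call. = FALSE)
  structure(list(A = A, B = B, time = as.numeric(time)), class = "bead_frame")
}

#' Generate a scripted trajectory
#'
#' Poses are linearly interpolated between waypoints at multiples of `dt`;
#' the axis bend and Gaussian noise are applied after posing. The same seed
#' always produces bit-identical coordinates.
#'
#' @param script a [trajectory_script()].
#' @param dt frame interval (same unit as waypoint times), > 0.
#' @param helixA,helixB optional pre-built helices (default: ideal 28-residue
#'   helices numbered 765-792).
#' @return object of class `dimer_frames`: a list of `bead_frame`s with
#'   attributes `dt` and `seed`.
#' @export
generate_trajectory <- function(script, dt = 1,
                                helixA = build_ideal_helix(),
                                helixB = build_ideal_helix()) {
  if (!inherits(script, "trajectory_script"))
    stop("'script' must be a trajectory_script", call. = FALSE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  wp <- script$waypoints
  times <- if (nrow(wp) == 1L) wp$time[1L] else
    seq(wp$time[1L], wp$time[nrow(wp)], by = dt)
  interp <- function(col) {
    if (nrow(wp) == 1L) rep(wp[[col]], length(times)) else
      stats::approx(wp$time, wp[[col]], xout = times)$y
  }
  sep <- interp("separation"); crs <- interp("crossing")
  spA <- interp("spinA"); spB <- interp("spinB"); sld <- interp("slide")
  set.seed(script$seed)
  frames <- vector("list", length(times))
  for (s in seq_along(times)) {
    fr <- suppressWarnings(assemble_dimer(
      helixA, helixB,
      dimer_pose(sep[s], crs[s], spA[s], spB[s], sld[s]),
      time = times[s]))
    if (script$bend_amplitude > 0) {
      tilt <- pose_axis_directions(crs[s])
      fr$A <- bend_helix(fr$A, tilt$axisA, script$bend_amplitude)
      fr$B <- bend_helix(fr$B, tilt$axisB, script$bend_amplitude)
    }
    if (script$noise_sd > 0) {
      fr$A <- fr$A + matrix(stats::rnorm(length(fr$A), 0, script$noise_sd),
                            ncol = 3L)
      fr$B <- fr$B + matrix(stats::rnorm(length(fr$B), 0, script$noise_sd),
                            ncol = 3L)
    }
    frames[[s]] <- fr
  }
  dimer_frames(frames, dt = dt, seed = script$seed)
}

# Half-sine bow: displace bead i by amplitude * sin(pi * (i-1)/(n-1)) along
# a fixed direction perpendicular to the helix axis, so the segment axes k_j
# measurably deviate from the global axis while the ends stay put.
bend_helix <- function(xyz, axis, amplitude) {
  n <- nrow(xyz)
  if (n < 2L) return(xyz)
  perp <- c(0, 1, 0) - sum(c(0, 1, 0) * axis) * axis
  if (vec_norm(perp) < 1e-8) perp <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
  perp <- unitize(perp)
  disp <- amplitude * sin(pi * (seq_len(n) - 1L) / (n - 1L))
  xyz + disp %o% perp
}

#' Construct a trajectory (sequence of bead frames)
#'
#' @param frames list of `bead_frame` objects.
#' @param dt frame interval.
#' @param seed seed recorded for provenance (NA if unknown).
#' @return object of class `dimer_frames`.
#' @export
dimer_frames <- function(frames, dt = 1, seed = NA_integer_) {
  if (!length(frames) || !all(vapply(frames, inherits, TRUE, "bead_frame")))
    stop("'frames' must be a non-empty list of bead_frame objects",
         call. = FALSE)
  structure(frames, dt = dt, seed = seed, class = "dimer_frames")
}

#' @export
print.dimer_frames <- function(x, ...) {
  n <- length(x)
  cat(sprintf("dimer_frames: %d frame%s, %d + %d beads, time %g..%g\n",
              n, if (n == 1L) "" else "s",
              nrow(x[[1L]]$A), nrow(x[[1L]]$B),
              x[[1L]]$time, x[[n]]$time))
  invisible(x)
}

#' @export
`[.dimer_frames` <- function(x, i) {
  dimer_frames(unclass(x)[i], dt = attr(x, "dt"), seed = attr(x, "seed"))
}
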