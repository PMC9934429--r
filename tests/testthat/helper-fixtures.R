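# Shared fixture builders. All fixtures are generated in code; tolerances
# follow the synthetic round-trip contracts (2 deg for angles, 0.05 nm for
# distances) unless a test states a tighter construction-level bound.

ideal_pair <- function() list(A = build_ideal_helix(), B = build_ideal_helix())

# Scripted single-parameter ramp trajectory at an otherwise fixed pose.
ramp_traj <- function(param, from, to, n_frames = 25, crossing = -50,
                      separation = 1.0, noise_sd = 0, seed = 1L) {
  wp <- data.frame(time = c(0, n_frames - 1), crossing = crossing,
                   separation = separation, spinA = 0, spinB = 0, slide = 0)
  wp[[param]] <- c(from, to)
  generate_trajectory(trajectory_script(wp, noise_sd = noise_sd, seed = seed),
                      dt = 1)
}

# Apply one rigid motion to both helices of a frame.
rigid_transform <- function(frame, axis = c(1, 2, 3), angle = 40,
                            shift = c(0.7, -1.1, 2.3)) {
  R <- helixdimer:::rotation_about(axis, angle)
  bead_frame(sweep(frame$A %*% t(R), 2, shift, "+"),
             sweep(frame$B %*% t(R), 2, shift, "+"),
             time = frame$time)
}

# Crossing-angle waypoint series used for event tests: values are the
# narrated pivot excursions (-6.4 -> -51 -> 4.6, then 4.6 -> -44 -> 27).
pivot_omega_series <- function() {
  c(rep(-6.4, 20), seq(-6.4, -51, length.out = 15),
    seq(-51, 4.6, length.out = 18), rep(4.6, 20))
}

two_pivot_omega_series <- function() {
  c(pivot_omega_series(), seq(4.6, -44, length.out = 15),
    seq(-44, 27, length.out = 20), rep(27, 15))
}

# Synthetic contact pair lists with a prescribed overlap k out of n: shared
# pairs use chain-A residues 765..., distinct pairs use disjoint partners.
pair_list_fixture <- function(k, n = 30L, offset = 0L) {
  res_A <- rep(765:789, length.out = n)
  res_B <- c(765 + seq_len(k),                    # shared block
             765 + 12 + offset + seq_len(n - k))  # list-specific block
  structure(data.frame(res_A = res_A, res_B = res_B,
                       score = seq(n, 1) + 0.5),
            class = c("pair_list", "data.frame"))
}
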