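test_that("ideal helix construction has the prescribed rise, twist and radius", {
  # single-residue case: one bead at 'radius' from the construction axis
  one <- build_ideal_helix(helix_spec(n_res = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(sqrt(sum(one[1, 1:2]^2)), 0.23, tolerance = 1e-12)

  h <- build_ideal_helix(helix_spec(n_res = 28, rise = 0.15, twist = 100))
  # brute-force axial gaps between consecutive beads
  expect_equal(unname(diff(h[, "z"])), rep(0.15, 27), tolerance = 1e-12)
  # trigonometric oracle: planar angle about the construction axis
  h10 <- build_ideal_helix(helix_spec(n_res = 10, twist = 100))
  az <- atan2(h10[, "y"], h10[, "x"]) * 180 / pi
  dz <- ((diff(az) + 180) %% 360) - 180
  expect_equal(unname(dz + ifelse(dz < 0, 360, 0)), rep(100, 9),
               tolerance = 1e-9)
  # beads ordered N -> C along +z
  expect_true(all(diff(h[, "z"]) > 0))
})

test_that("helix and pose specs validate their invariants", {
  expect_error(helix_spec(n_res = 0), "n_res")
  expect_error(helix_spec(rise = -0.1), "rise")
  expect_error(helix_spec(twist = 360), "twist")
  expect_error(dimer_pose(separation = -1), "separation")
  expect_error(dimer_pose(crossing = 95), "crossing")
  expect_error(trajectory_script(data.frame(time = c(0, 0))), "increasing")
  expect_error(trajectory_script(data.frame(time = 0), noise_sd = -1),
               "noise_sd")
})

test_that("assembled dimers reproduce the pose on noise-free input", {
  p <- ideal_pair()
  # parallel placement reports omega = 0 (degenerate flagged)
  fr0 <- assemble_dimer(p$A, p$B, dimer_pose(crossing = 0, slide = 0))
  g0 <- frame_geometry(fr0)
  expect_lt(abs(g0$omega), 0.5)
  # analyzer round trip at a left-handed pose
  fr <- assemble_dimer(p$A, p$B, dimer_pose(crossing = -30))
  expect_equal(frame_geometry(fr)$omega, -30, tolerance = 1)
  # construction oracle for the separation
  fr12 <- assemble_dimer(p$A, p$B, dimer_pose(separation = 1.2))
  expect_equal(frame_geometry(fr12)$L, 1.2, tolerance = 0.05)
  # overlapping beads warn but do not fail
  expect_warning(assemble_dimer(p$A, p$B, dimer_pose(separation = 0)),
                 "overlap")
})

test_that("trajectory generation interpolates poses and is seed-reproducible", {
  # constant script with no noise: all frames identical
  tr <- generate_trajectory(trajectory_script(
    data.frame(time = c(0, 5), crossing = -25), seed = 3), dt = 1)
  expect_length(tr, 6L)
  expect_identical(tr[[1]]$A, {a <- tr[[6]]$A; a})
  # spin ramp recovered by the analyzer at the scripted endpoint
  tr2 <- ramp_traj("spinB", 0, 180, n_frames = 21)
  rs <- rotation_timeseries(tr2)
  expect_equal(rs$dtheta_B[21], 180, tolerance = 2)
  # identical seeds give identical coordinates, different seeds differ
  s <- trajectory_script(data.frame(time = c(0, 4), crossing = -25),
                         noise_sd = 0.03, seed = 11)
  t1 <- generate_trajectory(s, dt = 1)
  t2 <- generate_trajectory(s, dt = 1)
  expect_identical(lapply(t1, unclass), lapply(t2, unclass))
  s2 <- trajectory_script(data.frame(time = c(0, 4), crossing = -25),
                          noise_sd = 0.03, seed = 12)
  expect_false(identical(generate_trajectory(s2, dt = 1)[[2]]$A, t1[[2]]$A))
  expect_error(generate_trajectory(s, dt = 0), "dt")
})

test_that("noise-free scripted descriptors match the script end to end", {
  # round-trip contract: 2 deg for angles, 0.05 nm for distances
  wp <- data.frame(time = c(0, 10), crossing = c(-40, -20),
                   separation = c(1.0, 1.4), spinA = c(0, 60),
                   spinB = c(0, -45), slide = 0)
  tr <- generate_trajectory(trajectory_script(wp, seed = 5), dt = 1)
  d <- analyze_frames(tr)
  expect_equal(d$omega_deg, seq(-40, -20, length.out = 11), tolerance = 2)
  expect_equal(d$L_nm, seq(1.0, 1.4, length.out = 11), tolerance = 0.05)
  expect_equal(d$dtheta_A_deg[11], 60, tolerance = 2)
  expect_equal(d$dtheta_B_deg[11], -45, tolerance = 2)
  expect_equal(abs(d$delta_d_nm), rep(0, 11), tolerance = 0.05)
})

test_that("axis bending perturbs segment axes away from the global axis", {
  s <- trajectory_script(data.frame(time = c(0, 2), crossing = -25),
                         bend_amplitude = 0.15, seed = 9)
  tr <- generate_trajectory(s, dt = 1)
  seg <- segment_axes(tr[[1]]$A)
  ga <- global_axis(tr[[1]]$A)$axis
  dots <- seg$k %*% ga
  expect_gt(max(acos(pmin(1, dots)) * 180 / pi), 2)  # bent local axes
  h90 <- build_ideal_helix(helix_spec(twist = 90))
  expect_true(all(segment_axes(h90)$k %*% global_axis(h90)$axis > 0.999))
})
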