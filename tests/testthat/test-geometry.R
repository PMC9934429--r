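test_that("global axis matches the end-group construction and is equivariant", {
  h <- build_ideal_helix()
  ax <- global_axis(h)
  # direct averaging oracle for the end centers
  expect_equal(ax$n_center, colMeans(h[1:4, ]), tolerance = 1e-12)
  expect_equal(ax$c_center, colMeans(h[25:28, ]), tolerance = 1e-12)
  expect_gt(abs(sum(ax$axis * c(0, 0, 1))), 0.999)
  # rigid rotation equivariance
  R <- helixdimer:::rotation_about(c(2, -1, 1), 73)
  axR <- global_axis(h %*% t(R))
  expect_equal(axR$axis, as.numeric(R %*% ax$axis), tolerance = 1e-9)
  expect_error(global_axis(h[1:7, ]), "at least 8")
})

test_that("segmentation of a 28-residue chain yields 7 centers and 6 vectors", {
  seg <- segment_axes(build_ideal_helix())
  expect_equal(nrow(seg$centers), 7L)
  expect_equal(nrow(seg$k), 6L)
  # straight helix: all k mutually parallel (twist 90 puts every 4-residue
  # group center exactly on the construction axis)
  seg90 <- segment_axes(build_ideal_helix(helix_spec(twist = 90)))
  expect_true(all(seg90$k %*% t(seg90$k) > 0.999))
  # the canonical 100-degree twist stays within a fraction of a degree
  expect_true(all(seg$k %*% t(seg$k) > cos(4 * pi / 180)))
  expect_error(segment_axes(build_ideal_helix(helix_spec(n_res = 24))),
               "28 beads")
  expect_equal(nrow(segment_axes(build_ideal_helix(helix_spec(n_res = 24)),
                                 strict = FALSE)$k), 5L)
})

test_that("a kinked chain's segment axes track each arm", {
  # two straight arms joined after residue 14, bent by 40 degrees
  h <- build_ideal_helix()
  R <- helixdimer:::rotation_about(c(1, 0, 0), 40)
  pivot <- h[14, ]
  bent <- h
  bent[15:28, ] <- sweep(sweep(h[15:28, ], 2, pivot) %*% t(R), 2, pivot, "+")
  seg <- segment_axes(bent)
  arm1 <- global_axis(bent[1:14, ])$axis   # construction oracle per arm
  arm2 <- global_axis(bent[15:28, ])$axis
  expect_true(all(seg$k[1:3, ] %*% arm1 > 0.99))
  expect_true(all(seg$k[4:6, ] %*% arm2 > 0.99))
})

test_that("crossing angle is signed by handedness and bounded by 90", {
  p <- ideal_pair()
  for (cr in c(-50, -25, -10, 10, 25, 50)) {
    fr <- assemble_dimer(p$A, p$B, dimer_pose(crossing = cr))
    got <- crossing_angle(fr$A, fr$B)
    expect_false(got$degenerate)
    expect_equal(got$omega, cr, tolerance = 1)
    expect_lt(abs(got$omega), 90)
  }
  # identical axes: degenerate parallel case
  fr0 <- assemble_dimer(p$A, p$B, dimer_pose(crossing = 0))
  expect_true(crossing_angle(fr0$A, fr0$B)$degenerate)
  # mirror reflection flips the sign, preserves magnitude
  fr <- assemble_dimer(p$A, p$B, dimer_pose(crossing = -30))
  mirror <- function(m) m %*% diag(c(1, -1, 1))
  expect_equal(crossing_angle(mirror(fr$A), mirror(fr$B))$omega,
               -crossing_angle(fr$A, fr$B)$omega, tolerance = 1e-9)
})

test_that("lateral separation modes agree with brute-force oracles", {
  p <- ideal_pair()
  fr <- assemble_dimer(p$A, p$B, dimer_pose(separation = 1.2, crossing = 0))
  expect_equal(lateral_separation(fr$A, fr$B, "center"), 1.2,
               tolerance = 0.01)
  # brute-force all-pairs oracle for min_pair
  brute <- min(apply(fr$A, 1, function(a)
    min(sqrt(colSums((t(fr$B) - a)^2)))))
  expect_equal(lateral_separation(fr$A, fr$B, "min_pair"), brute,
               tolerance = 1e-9)
  # identical sets: zero in both modes
  expect_equal(lateral_separation(fr$A, fr$A, "center"), 0)
  expect_equal(lateral_separation(fr$A, fr$A, "min_pair"), 0)
  # min_pair never exceeds center mode on random rigid arrangements
  set.seed(42)
  for (i in 1:10) {
    frx <- assemble_dimer(p$A, p$B,
                          dimer_pose(separation = runif(1, 0.8, 3),
                                     crossing = runif(1, -60, 60),
                                     spinA = runif(1, 0, 360),
                                     slide = runif(1, -0.5, 0.5)))
    expect_lte(lateral_separation(frx$A, frx$B, "min_pair"),
               lateral_separation(frx$A, frx$B, "center"))
  }
})

test_that("delta_d reports N/C opening with the right sign and symmetries", {
  p <- ideal_pair()
  fr <- assemble_dimer(p$A, p$B, dimer_pose(separation = 1.2, crossing = 0))
  # mirror-symmetric parallel dimer
  expect_equal(delta_d(fr$A, fr$B), 0, tolerance = 1e-9)
  # V-pose opened at the N-termini: tilt each helix about its C-end center
  open_about_c <- function(beads, angle) {
    R <- helixdimer:::rotation_about(c(0, 1, 0), angle)
    cc <- global_axis(beads)$c_center
    sweep(sweep(beads, 2, cc) %*% t(R), 2, cc, "+")
  }
  A2 <- open_about_c(fr$A, 15)
  B2 <- open_about_c(fr$B, -15)
  # oracle: apply the same rotations to the end centers directly
  nA <- global_axis(fr$A)$n_center; cA <- global_axis(fr$A)$c_center
  nB <- global_axis(fr$B)$n_center; cB <- global_axis(fr$B)$c_center
  RA <- helixdimer:::rotation_about(c(0, 1, 0), 15)
  RB <- helixdimer:::rotation_about(c(0, 1, 0), -15)
  nA2 <- as.numeric(RA %*% (nA - cA)) + cA
  nB2 <- as.numeric(RB %*% (nB - cB)) + cB
  gap <- sqrt(sum((nA2 - nB2)^2)) - sqrt(sum((cA - cB)^2))
  expect_gt(gap, 0.3)
  expect_equal(delta_d(A2, B2), gap, tolerance = 0.01)
  # reversing both chains' N/C labeling flips the sign exactly
  expect_equal(delta_d(A2[28:1, ], B2[28:1, ]), -delta_d(A2, B2),
               tolerance = 1e-12)
  # swapping helix labels leaves delta_d unchanged
  expect_equal(delta_d(B2, A2), delta_d(A2, B2), tolerance = 1e-12)
})

test_that("rotation reference vector obeys both regime contracts", {
  p <- ideal_pair()
  fr <- assemble_dimer(p$A, p$B, dimer_pose(crossing = -30))
  h <- reference_vector(fr$A, fr$B, "A")
  # cross-product regime: perpendicular to both global axes
  expect_lt(abs(sum(h * global_axis(fr$A)$axis)), 1e-6)
  expect_lt(abs(sum(h * global_axis(fr$B)$axis)), 1e-6)
  # orientation: toward the partner, over randomized poses, both regimes
  set.seed(7)
  for (i in 1:12) {
    frx <- assemble_dimer(p$A, p$B,
                          dimer_pose(separation = runif(1, 0.9, 2),
                                     crossing = runif(1, -60, 60),
                                     spinB = runif(1, 0, 360)))
    for (tgt in c("A", "B")) {
      hx <- reference_vector(frx$A, frx$B, tgt)
      to_partner <- if (tgt == "A") colMeans(frx$B) - colMeans(frx$A)
                    else colMeans(frx$A) - colMeans(frx$B)
      expect_gt(sum(hx * to_partner), 0)
    }
  }
  # fallback regime (|omega| < 14.4): perpendicular to the partner axis
  fr5 <- assemble_dimer(p$A, p$B, dimer_pose(crossing = 5))
  h5 <- reference_vector(fr5$A, fr5$B, "A")
  expect_lt(abs(sum(h5 * global_axis(fr5$B)$axis)), 1e-6)
})

test_that("descriptors are invariant under rigid motion and label swap", {
  p <- ideal_pair()
  fr <- assemble_dimer(p$A, p$B,
                       dimer_pose(separation = 1.1, crossing = -35,
                                  spinB = 120, slide = 0.2))
  g <- frame_geometry(fr)
  set.seed(13)
  for (i in 1:5) {
    frR <- rigid_transform(fr, axis = rnorm(3), angle = runif(1, 0, 360),
                           shift = rnorm(3))
    gR <- frame_geometry(frR)
    expect_equal(gR$omega, g$omega, tolerance = 1e-6)
    expect_equal(gR$L, g$L, tolerance = 1e-9)
    expect_equal(gR$delta_d, g$delta_d, tolerance = 1e-9)
  }
  # A/B swap: omega and L unchanged
  expect_equal(crossing_angle(fr$B, fr$A)$omega, g$omega, tolerance = 1e-9)
  expect_equal(lateral_separation(fr$B, fr$A), g$L, tolerance = 1e-12)
})
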