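test_that("pivot detection fires on the narrated excursion and not on small ones", {
  om <- pivot_omega_series()
  for (th in c(40, 45)) {
    ev <- detect_pivots(om, threshold = th)
    expect_equal(nrow(ev), 1L)
    expect_gte(ev$excursion_deg, 44)
    expect_equal(ev$omega_peak, -51, tolerance = 1)
  }
  # constant series: nothing
  expect_equal(nrow(detect_pivots(rep(-20, 40))), 0L)
  # 30-degree excursion is below a 45-degree threshold
  bump <- c(rep(0, 15), seq(0, -30, length.out = 10),
            seq(-30, 0, length.out = 10), rep(0, 15))
  expect_equal(nrow(detect_pivots(bump, threshold = 45)), 0L)
  expect_error(detect_pivots(om, threshold = -5), "threshold")
  expect_error(detect_pivots(om[1:2]), "3 frames")
})

test_that("detector recall and precision are perfect away from the threshold", {
  mk_bump <- function(depth) c(rep(0, 10), seq(0, -depth, length.out = 12),
                               seq(-depth, 0, length.out = 12), rep(0, 10))
  th <- 45
  for (depth in c(th + 10, th + 30))     # recall
    expect_equal(nrow(detect_pivots(mk_bump(depth), threshold = th)), 1L)
  for (depth in c(th - 10, th - 25))     # precision
    expect_equal(nrow(detect_pivots(mk_bump(depth), threshold = th)), 0L)
  # monotone in threshold
  om <- two_pivot_omega_series()
  counts <- vapply(c(20, 35, 50, 60, 75), function(th)
    nrow(detect_pivots(om, threshold = th)), integer(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("reversing a single excursion preserves the detected pivot", {
  om <- pivot_omega_series()
  fwd <- detect_pivots(om, threshold = 45)
  t_rev <- seq_along(om) - 1
  rev_ev <- detect_pivots(rev(om), time = t_rev, threshold = 45)
  expect_equal(nrow(rev_ev), 1L)
  expect_equal(rev_ev$excursion_deg, fwd$excursion_deg, tolerance = 1e-9)
  expect_equal(rev_ev$omega_peak, fwd$omega_peak)
  # start/end swap on the reversed time axis
  expect_equal(sort(c(rev_ev$start_time, rev_ev$end_time)),
               sort(max(t_rev) - c(fwd$end_time, fwd$start_time)))
})

test_that("handedness flips require exiting the dead band on both sides", {
  # all-negative series: no flips
  expect_equal(nrow(detect_handedness_flips(rep(-25, 30))), 0L)
  # the narrated pivot ends inside the +5 deg dead band: no flip
  expect_equal(nrow(detect_handedness_flips(pivot_omega_series())), 0L)
  # -30 -> +30: one flip near the scripted crossing time
  f1 <- c(rep(-30, 10), seq(-30, 30, length.out = 21), rep(30, 10))
  e1 <- detect_handedness_flips(f1)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$start_time, 19.5, tolerance = 1)   # zero crossing
  # -30 -> +30 -> -30: two flips
  f2 <- c(f1, seq(30, -30, length.out = 21), rep(-30, 10))
  expect_equal(nrow(detect_handedness_flips(f2)), 2L)
})

test_that("event rotation attribution labels the rotating helix", {
  om <- two_pivot_omega_series()
  n <- length(om)
  t <- seq_len(n) - 1
  # helix B spins 180 during the first excursion, helix A during the second
  dB <- c(rep(0, 20), seq(0, 180, length.out = 33), rep(180, n - 53))
  dA <- c(rep(0, 73), seq(0, 180, length.out = 35), rep(180, n - 108))
  series <- structure(list(time = t, dtheta_A = dA, dtheta_B = dB),
                      class = "rotation_series")
  ev <- associate_rotations(detect_pivots(om, time = t, threshold = 45),
                            series)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$label, c("B-rotating", "A-rotating"))
  expect_equal(ev$dtheta_B_deg[1], 180, tolerance = 5)
  expect_equal(ev$dtheta_A_deg[2], 180, tolerance = 5)
  # total rotations after the two-stage mechanism
  expect_equal(c(dA[n], dB[n]), c(180, 180))
  # a pivot with no spin is labeled "neither"
  quiet <- structure(list(time = t, dtheta_A = rep(0, n),
                          dtheta_B = rep(0, n)),
                     class = "rotation_series")
  ev0 <- associate_rotations(detect_pivots(om, time = t, threshold = 45),
                             quiet)
  expect_true(all(ev0$label == "neither"))
  # events outside the series time base are dropped with a warning
  short <- structure(list(time = t[1:10], dtheta_A = dA[1:10],
                          dtheta_B = dB[1:10]),
                     class = "rotation_series")
  expect_warning(
    dropped <- associate_rotations(detect_pivots(om, time = t,
                                                 threshold = 45), short),
    "dropped")
  expect_equal(nrow(dropped), 0L)
})

test_that("full synthetic round trip reproduces the two-stage mechanism", {
  wp <- data.frame(time = c(0, 20, 35, 53, 70, 85, 105, 120),
                   crossing = c(-6.4, -6.4, -51, 4.6, 4.6, -44, 27, 27),
                   spinA = c(0, 0, 0, 0, 0, 0, 180, 180),
                   spinB = c(0, 0, 90, 180, 180, 180, 180, 180),
                   separation = c(1.0, 1.0, 1.4, 1.0, 1.0, 1.4, 1.0, 1.0))
  tr <- generate_trajectory(trajectory_script(wp, seed = 42), dt = 1)
  d <- analyze_frames(tr)
  piv <- detect_pivots(d$omega_deg, time = d$time, threshold = 45)
  expect_equal(nrow(piv), 2L)
  series <- structure(list(time = d$time, dtheta_A = d$dtheta_A_deg,
                           dtheta_B = d$dtheta_B_deg),
                      class = "rotation_series")
  lab <- associate_rotations(piv, series)
  expect_equal(lab$label, c("B-rotating", "A-rotating"))
  expect_equal(lab$dtheta_B_deg[1], 180, tolerance = 5)
  expect_equal(lab$dtheta_A_deg[2], 180, tolerance = 5)
  expect_equal(d$dtheta_A_deg[nrow(d)], 180, tolerance = 5)
  expect_equal(d$dtheta_B_deg[nrow(d)], 180, tolerance = 5)
})
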