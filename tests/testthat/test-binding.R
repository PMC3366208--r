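test_that("binding parameters validate and support the legacy zone alias", {
  p <- binding_params()
  expect_equal(p$capture_axis_distance, 15)
  expect_equal(p$zone, 12)
  expect_equal(p$align_tolerance, 1.0)
  expect_false(p$initial_attraction)
  expect_warning(p2 <- binding_params(zone = 0.7), "legacy")
  expect_equal(p2$zone, 7)
  expect_error(binding_params(zone = 20), "zone")
  expect_error(binding_params(align_tolerance = -1), "positive")
})

test_that("the binding transition is total and follows the capture rules", {
  p <- binding_params()
  # outside 15 nm: stays (or becomes) free from every state
  for (s in 0:2)
    expect_equal(binding_transition(s, 16, 15, 15, p)$state, 0L)
  # within capture but not oriented: loose
  expect_equal(binding_transition(0L, 14, 15, 15, p)$state, 1L)
  # free heads are captured first, never promoted in the same frame
  expect_equal(binding_transition(0L, 5, 4, 4, p)$state, 1L)
  # loose, in zone, oriented, in contact: tight
  expect_equal(binding_transition(1L, 5, 4, 4, p)$state, 2L)
  # oriented but hovering above the contact distance: stays loose
  expect_equal(binding_transition(1L, 9, 8, 8, p)$state, 1L)
  # tight is re-evaluated with the same criteria (no hysteresis)
  expect_equal(binding_transition(2L, 5, 4, 4, p)$state, 2L)
  expect_equal(binding_transition(2L, 5, 6, 4, p)$state, 1L)
  # binding forbidden during recovery
  expect_equal(binding_transition(0L, 5, 4, 4, p,
                                  binding_allowed = FALSE)$state, 0L)
  # totality: every (state, geometry) pair yields exactly one new state
  set.seed(41)
  for (i in 1:200) {
    s <- sample(0:2, 1)
    g <- runif(3, 0, 20)
    ns <- binding_transition(s, g[1], g[2], g[3], p)$state
    expect_true(ns %in% 0:2)
  }
})

test_that("alignment angles match an independent rotation oracle", {
  ring <- build_actin_ring()
  d <- build_myosin_dimer(6L)
  # reference pose: aligned foot over unit 1
  X <- myowalk:::ideal_bound_pose(ring, d$halves[[1]], 1L)
  al <- compute_alignment(X, ring)
  expect_equal(al$yaw, 0, tolerance = 1e-6)
  expect_equal(al$roll, 0, tolerance = 1e-6)
  # rotating the foot about the outward radial by an angle yields that yaw
  set.seed(42)
  for (ang in c(-1.2, -0.4, 0.7, pi / 2)) {
    fc <- myowalk:::foot_centroid(X)
    Xr <- X
    Xr[1:3, ] <- rotate_about(X[1:3, ], al$r_hat, ang, pivot = fc)
    al2 <- compute_alignment(Xr, ring)
    expect_equal(al2$yaw, ang, tolerance = 1e-6)
    expect_equal(al2$roll, 0, tolerance = 1e-6)
  }
  # rolling about the foot axis yields that roll
  for (ang in c(-0.9, 0.3, 1.1)) {
    fc <- myowalk:::foot_centroid(X)
    Xr <- X
    Xr[1:3, ] <- rotate_about(X[1:3, ], al$frame$x_f, ang, pivot = fc)
    al2 <- compute_alignment(Xr, ring)
    expect_equal(al2$roll, ang, tolerance = 1e-6)
    expect_equal(abs(al2$yaw), 0, tolerance = 1e-6)
  }
  # far from the track the alignment is undefined
  Xfar <- sweep(X, 2, c(0, 0, 40), `+`)
  expect_error(compute_alignment(Xfar, ring), "capture")
})

test_that("powerstroke arithmetic: 25 eligible frames of 0.05 rad", {
  p <- binding_params()
  h <- list(state = 2L, swung = FALSE, swing = 0)
  nfr <- 0
  while (!h$swung) {
    h <- powerstroke_step(h, p, aligned = TRUE)
    nfr <- nfr + 1
    if (nfr > 100) break
  }
  expect_equal(nfr, ceiling(p$powerstroke_total / p$powerstroke_step))  # 25
  expect_equal(h$swing, p$powerstroke_total)
  # one increment is 0.05 rad = 2.86 degrees
  expect_equal(p$powerstroke_step * 180 / pi, 2.86, tolerance = 0.01)
  # saturated stroke: further calls are no-ops
  h2 <- powerstroke_step(h, p, aligned = TRUE)
  expect_equal(h2$swing, h$swing)
  expect_true(h2$swung)
  # losing alignment mid-swing flags the revert to loose
  hm <- list(state = 2L, swung = FALSE, swing = 0.3)
  hm <- powerstroke_step(hm, p, aligned = FALSE)
  expect_true(hm$revert)
  expect_equal(hm$swing, 0.3)
})

test_that("recovery arithmetic: 13 frames at double rate, binding forbidden", {
  p <- binding_params()
  h <- list(state = 0L, swung = TRUE, swing = p$powerstroke_total)
  nfr <- 0
  repeat {
    h <- recovery_step(h, p)
    nfr <- nfr + 1
    if (!h$swung) break
    expect_false(h$binding_allowed)
    if (nfr > 50) break
  }
  expect_equal(nfr, ceiling(p$powerstroke_total / p$recovery_step))  # 13
  expect_true(h$binding_allowed)
  # a never-swung head is untouched
  h0 <- recovery_step(list(state = 0L, swung = FALSE, swing = 0), p)
  expect_equal(h0$swing, 0)
  expect_true(h0$binding_allowed)
})

test_that("ratchet release frees the swung trailing head in place", {
  # leading head just attained tight with the trailing head swung
  expect_equal(ratchet_release(states = c(2L, 2L), swungs = c(FALSE, TRUE),
                               upos = c(10, 4),
                               just_tight = c(TRUE, FALSE)), 2L)
  # no release when the trailing head has not swung
  expect_equal(ratchet_release(c(2L, 2L), c(FALSE, FALSE), c(10, 4),
                               c(TRUE, FALSE)), 0L)
  # no release when the newly tight head is the trailing one
  expect_equal(ratchet_release(c(2L, 2L), c(TRUE, FALSE), c(10, 4),
                               c(FALSE, TRUE)), 0L)
})
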