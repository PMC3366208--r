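test_that("actin ring geometry: circumference, closure, half repeats", {
  ring <- build_actin_ring(52L, 5.70, 36)
  expect_equal(ring$circumference, 296.4)
  expect_equal(ring$circumference / pi, 94.3, tolerance = 0.01)  # > 90 nm
  expect_equal(ring$n_half_repeats, 8L)
  expect_equal(ring$half_repeat, 52 * 5.70 / 8)
  # total accumulated twist closes with no seam
  expect_equal((ring$n_dimers * ring$twist_per_unit) %% 360, 0)
  # cyclic indexing: unit 53 is unit 1
  expect_equal(wrap_unit(53L, 52L), 1L)
  # neighbour geometry identical across the seam: the rigid transform
  # from unit i to unit i+1 has the same chord length and turning angle
  # everywhere, including (52, 1)
  chord <- function(i, j) myowalk:::vnorm(ring$unit_centers[i, ] -
                                            ring$unit_centers[j, ])
  chords <- vapply(seq_len(52), function(i)
    chord(i, wrap_unit(i + 1L, 52L)), 0)
  expect_equal(max(chords) - min(chords), 0, tolerance = 1e-9)
})

test_that("ring construction errors on degenerate inputs", {
  expect_error(build_actin_ring(6L), "too small")
  expect_error(build_actin_ring(52L, -1), "positive")
})

test_that("leg length table is exactly reproduced", {
  for (niq in c(2L, 4L, 6L)) {
    d <- build_myosin_dimer(niq)
    expect_equal(d$leg_length,
                 c(`2` = 9.3, `4` = 14.60, `6` = 19.90)[[as.character(niq)]])
    expect_equal(length(myowalk:::half_node_index(niq)$segs), niq)
  }
  expect_error(build_myosin_dimer(3L), "must be 2, 4 or 6")
  # maximal two-leg span for the shortest model
  expect_equal(2 * build_myosin_dimer(2L)$leg_length, 18.6)
})

test_that("the two halves are congruent up to the hinge reflection", {
  for (niq in c(2L, 6L)) {
    d <- build_myosin_dimer(niq)
    D1 <- as.matrix(dist(d$halves[[1]]$X))
    D2 <- as.matrix(dist(d$halves[[2]]$X))
    expect_equal(D1, D2, tolerance = 1e-9)
    idx <- myowalk:::half_node_index(niq)
    expect_equal(d$halves[[1]]$X[idx$hinge, ], d$halves[[2]]$X[idx$hinge, ],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("initial placement: bound half in capture range, partner free", {
  ring <- build_actin_ring()
  d <- place_dimer_initial(ring, build_myosin_dimer(6L), 1L)
  expect_lt(d$ring_axis_distance[1], 15)
  expect_gt(d$ring_axis_distance[2], 15)
  idx <- myowalk:::half_node_index(6L)
  expect_equal(d$halves[[1]]$X[idx$hinge, ], d$halves[[2]]$X[idx$hinge, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  # rotational symmetry of the start unit choice: pairwise geometry of
  # foot vs bound unit is identical at units 1 and 27
  d2 <- place_dimer_initial(ring, build_myosin_dimer(6L), 27L)
  f1 <- myowalk:::foot_centroid(d$halves[[1]]$X)
  f2 <- myowalk:::foot_centroid(d2$halves[[1]]$X)
  expect_equal(myowalk:::vnorm(f1 - ring$unit_centers[1, ]),
               myowalk:::vnorm(f2 - ring$unit_centers[27, ]),
               tolerance = 1e-9)
})

test_that("hierarchy containment holds for ring and dimer", {
  ring <- build_actin_ring(52L)
  h <- as_hierarchy(ring)
  expect_true(check_containment(h))
  d <- place_dimer_initial(ring, build_myosin_dimer(4L), 1L)
  for (mol in as_hierarchy(d)) expect_true(check_containment(mol))
  # alpha sticks are drawn thicker than beta sticks
  expect_gt(myowalk:::ALPHA_STICK_RADIUS, myowalk:::BETA_STICK_RADIUS)
})
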