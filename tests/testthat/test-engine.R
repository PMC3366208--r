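test_that("random_move respects damping, including the frozen sentinel", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0))
  set.seed(21)
  # infinite translation damping: position centroid unchanged by translation,
  # zero rotation step: nothing moves at all
  mv <- move_spec(0.1, 0, damping_translation = Inf)
  expect_equal(random_move(X, mv), X)
  # translation magnitude is exactly step / damping
  mv <- move_spec(0.1, 0, damping_translation = 5)
  Y <- random_move(X, mv)
  expect_equal(myowalk:::vnorm(Y[1, ] - X[1, ]), 0.02, tolerance = 1e-12)
  # displacement is rigid (both rows move identically under translation)
  expect_equal(Y[1, ] - X[1, ], Y[2, ] - X[2, ], tolerance = 1e-12)
  expect_error(move_spec(-1, 0), ">= 0")
  expect_error(move_spec(0.1, 0.1, damping_translation = 0.5), ">= 1")
})

test_that("free-state moves are isotropic with constant step magnitude", {
  set.seed(22)
  mv <- move_spec(0.5, 0)
  disp <- t(replicate(4000, {
    random_move(c(0, 0, 0), mv)
  }))
  mags <- sqrt(rowSums(disp^2))
  expect_equal(max(mags) - min(mags), 0, tolerance = 1e-12)
  expect_lt(myowalk:::vnorm(colMeans(disp)), 0.02)
})

test_that("damping schedule follows the binding state", {
  expect_equal(damping_schedule(0L), c(1, 1))
  expect_equal(damping_schedule(1L, in_zone = FALSE), c(5, 1))
  expect_equal(damping_schedule(1L, in_zone = TRUE), c(Inf, 10))
  expect_equal(damping_schedule(2L), c(Inf, 100))
})

test_that("apply_restraint contract: dead-band, capped step, reaction", {
  a <- c(0, 0, 0); b <- c(0, 0, 5)
  # satisfied restraint: no change
  r <- apply_restraint(a, b, target = 5)
  expect_equal(r$a, a); expect_equal(r$b, b)
  # far pair: separation reduced by at most the correction step, split
  # equally (equal and opposite reaction)
  r <- apply_restraint(a, b, target = 2, correction_step = 0.25)
  expect_equal(r$a + r$b - a - b, c(0, 0, 0), tolerance = 1e-12)
  expect_lte(5 - myowalk:::vnorm(r$a - r$b), 0.25 + 1e-12)
  expect_gt(5 - myowalk:::vnorm(r$a - r$b), 0)
  # immobile flag routes the full shift to one side
  r <- apply_restraint(a, b, target = 2, mobile_a = FALSE)
  expect_equal(r$a, a)
  expect_false(isTRUE(all.equal(r$b, b)))
  # one-sided (attractive) restraint ignores compression
  r <- apply_restraint(a, b, target = 8, one_sided = TRUE)
  expect_equal(r$a, a); expect_equal(r$b, b)
  # coincident endpoints are perturbed, not left degenerate
  set.seed(23)
  r <- apply_restraint(c(1, 1, 1), c(1, 1, 1), target = 2)
  expect_gt(myowalk:::vnorm(r$a - r$b), 0)
  expect_error(apply_restraint(a, b, target = -1), ">= 0")
})

test_that("batched restraints preserve reaction symmetry over many pairs", {
  set.seed(24)
  X <- matrix(rnorm(30, sd = 4), 10, 3)
  tab <- cbind(sample(10, 20, TRUE), sample(10, 20, TRUE),
               runif(20, 1, 6), 0.25, 0)
  tab <- tab[tab[, 1] != tab[, 2], , drop = FALSE]
  delta <- myowalk:::apply_restraints_batch(X, tab, 0.05)
  expect_equal(colSums(delta), c(0, 0, 0), tolerance = 1e-12)
})

test_that("hinge restoration follows the state table and restores", {
  # both free -> both move to the midpoint; bound/free -> free side moves;
  # tight/loose -> loose side; ties -> seeded random choice
  expect_equal(hinge_restore_side(0L, 0L), 0L)
  expect_equal(hinge_restore_side(2L, 0L), 2L)
  expect_equal(hinge_restore_side(0L, 2L), 1L)
  expect_equal(hinge_restore_side(2L, 1L), 2L)
  expect_equal(hinge_restore_side(1L, 2L), 1L)
  expect_equal(hinge_restore_side(2L, 2L, u = 0.3), 1L)
  expect_equal(hinge_restore_side(1L, 1L, u = 0.7), 2L)
  # reproducible tie-break from the seeded stream
  set.seed(25); s1 <- replicate(20, hinge_restore_side(2L, 2L))
  set.seed(25); s2 <- replicate(20, hinge_restore_side(2L, 2L))
  expect_identical(s1, s2)

  ring <- build_actin_ring()
  d <- place_dimer_initial(ring, build_myosin_dimer(6L), 1L)
  idx <- myowalk:::half_node_index(6L)
  # separate the halves, then restore with both free: points coincide
  d$halves[[2]]$X <- sweep(d$halves[[2]]$X, 2, c(0, 0, 4), `+`)
  d2 <- maintain_hinge(d)
  expect_equal(d2$halves[[1]]$X[idx$hinge, ], d2$halves[[2]]$X[idx$hinge, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  # tight + loose: only the loose half is translated
  d$halves[[1]]$state <- 2L; d$halves[[2]]$state <- 1L
  d3 <- maintain_hinge(d)
  expect_equal(d3$halves[[1]]$X, d$halves[[1]]$X, tolerance = 1e-12)
  expect_equal(d3$halves[[1]]$X[idx$hinge, ], d3$halves[[2]]$X[idx$hinge, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a satisfied frame is a fixed point with zero random steps", {
  # with all random steps zero and all restraints satisfied, one frame
  # leaves the pose unchanged
  cfg <- quick_config(6L, max_frames = 3L)
  for (nm in names(cfg$move)) cfg$move[[nm]] <- 0
  tr1 <- run_sim(cfg, seed = 1)
  fs <- attr(tr1, "final_state")
  cfg$stop$max_frames <- 30L
  tr2 <- run_sim(cfg, seed = 1)
  fs2 <- attr(tr2, "final_state")
  # the bound head starts in the restraint-satisfied seated pose: after
  # the initial capture settles, further frames do not move it
  expect_equal(fs$half1, fs2$half1, tolerance = 0.3)
})
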