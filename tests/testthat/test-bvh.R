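test_that("BVH contact sets equal brute force on random sphere scenes", {
  set.seed(31)
  for (rep in 1:6) {
    na <- sample(20:50, 1); nb <- sample(20:50, 1)
    A <- matrix(runif(na * 3, 0, 30), na, 3); ra <- runif(na, 0.5, 3)
    B <- matrix(runif(nb * 3, 0, 30), nb, 3); rb <- runif(nb, 0.5, 3)
    ta <- bvh_build(A, ra)
    tb <- bvh_build(B, rb)
    got <- bvh_contacts(ta, tb)
    want <- brute_force_contacts(A, ra, B, rb)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(got), key(want))
  }
})

test_that("separated trees are pruned after a single volume test", {
  A <- matrix(runif(60, 0, 10), 20, 3)
  B <- matrix(runif(60, 100, 110), 20, 3)
  ta <- bvh_build(A, rep(1, 20)); tb <- bvh_build(B, rep(1, 20))
  got <- bvh_contacts(ta, tb)
  expect_equal(nrow(got), 0)
  expect_equal(attr(got, "n_tests"), 1L)
})

test_that("grouped (molecule/domain) builds keep parent containment", {
  set.seed(32)
  C <- matrix(rnorm(36, sd = 5), 12, 3); r <- runif(12, 0.5, 2)
  tree <- bvh_build(C, r, groups = list(1:4, 5:8, 9:12))
  for (k in seq_along(tree$radius)) {
    kids <- tree$children[[k]]
    for (kid in kids) {
      d <- myowalk:::vnorm(tree$center[kid, ] - tree$center[k, ])
      expect_lte(d + tree$radius[kid], tree$radius[k] + 1e-9)
    }
  }
})

test_that("steric resolution pushes overlapping spheres apart, split equally", {
  A <- matrix(c(0, 0, 0), 1, 3); B <- matrix(c(3, 0, 0), 1, 3)
  ta <- bvh_build(A, 2); tb <- bvh_build(B, 2)
  res <- resolve_steric(ta, tb)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$delta_a[1, ], c(-0.5, 0, 0), tolerance = 1e-12)
  expect_equal(res$delta_b[1, ], c(0.5, 0, 0), tolerance = 1e-12)
  # applying the corrections removes the overlap
  expect_equal(myowalk:::vnorm((A[1, ] + res$delta_a[1, ]) -
                                 (B[1, ] + res$delta_b[1, ])), 4)
  # non-overlapping spheres: zero corrections
  res2 <- resolve_steric(bvh_build(A, 1), bvh_build(B, 1))
  expect_equal(nrow(res2$pairs), 0)
  expect_true(all(res2$delta_a == 0) && all(res2$delta_b == 0))
})
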