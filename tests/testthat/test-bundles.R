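# straight-line fiber along x at a given y offset, matched 1 mm sampling
straightFiber <- function(y = 0, z = 0, n = 11L)
  cbind(seq(0, n - 1), y, z)

test_that("mean closest distance has its closed forms", {
  a <- straightFiber(0)
  expect_equal(meanClosestDistance(a, a), 0)
  for (d in c(0.5, 2, 3.7))
    expect_equal(meanClosestDistance(a, straightFiber(d)), d,
                 tolerance = 1e-9)
  b <- straightFiber(1.3, 0.4)
  expect_equal(meanClosestDistance(a, b), meanClosestDistance(b, a))
})

test_that("Hausdorff dominates mean closest distance and matches the
           reference implementation", {
  skip_if_not_installed("pracma")
  withr::with_seed(77L, {
    for (rep in 1:50) {
      a <- matrix(rnorm(3 * sample(4:20, 1), sd = 10), ncol = 3)
      b <- matrix(rnorm(3 * sample(4:20, 1), sd = 10), ncol = 3)
      h <- hausdorffDistance(a, b)
      expect_gte(h, meanClosestDistance(a, b) - 1e-12)
      expect_equal(h, pracma::hausdorff_dist(a, b), tolerance = 1e-9)
    }
  })
})

test_that("fiber resampling fixes the arc-length step", {
  p <- rbind(c(0, 0, 0), c(10, 0, 0))
  r <- resampleFiber(p, step = 1)
  expect_equal(nrow(r), 11L)
  expect_equal(r[, 1], 0:10)
  # end point always kept
  r2 <- resampleFiber(p, step = 3)
  expect_equal(r2[nrow(r2), ], c(10, 0, 0))
})

test_that("backbone bundles respect the partition", {
  labels <- c("3" = 2L, "7" = 2L, "9" = 4L, "5" = 1L)
  a <- rbind(c(3L, 7L), c(3L, 9L), c(NA, NA), c(5L, 5L))
  atlas <- backboneBundles(a, labels, scale = 2L)
  asg <- bundleAssignments(atlas)
  expect_equal(asg$bundle[1], 2L)         # both endpoints labelled 2
  expect_true(is.na(asg$bundle[2]))       # cross-block fiber unbundled
  expect_true(is.na(asg$bundle[3]))
  expect_true(asg$backbone[1])
  expect_equal(atlas@scale, 2L)
})

test_that("classification honours threshold, ties and idempotence", {
  # two single-fiber bundles 7 mm apart
  back <- list(straightFiber(0), straightFiber(7))
  probes <- list(straightFiber(2),      # 2 mm from bundle 1
                 straightFiber(20),     # 13 mm from everything
                 straightFiber(3.5))    # equidistant -> smaller label
  fs <- fiberSet(c(back, probes))
  labels <- c("1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L)
  pairs <- rbind(c(1L, 2L), c(3L, 4L),
                 c(NA, NA), c(NA, NA), c(NA, NA))
  atlas <- backboneBundles(pairs, labels, threshold = 4)
  full <- classifyFibers(atlas, fs)
  asg <- bundleAssignments(full)
  expect_equal(asg$bundle[3], 1L)
  expect_equal(asg$distance[3], 2, tolerance = 1e-9)
  expect_true(is.na(asg$bundle[4]))
  expect_equal(asg$bundle[5], 1L)         # tie goes to the smaller label
  # no assignment beyond the threshold; backbone members untouched
  expect_true(all(asg$distance[!is.na(asg$bundle)] <= 4 + 1e-9))
  expect_true(all(asg$backbone[1:2]))
  expect_true(validObject(full))
  # idempotent: re-running changes nothing
  again <- classifyFibers(full, fs)
  expect_identical(bundleAssignments(again), asg)
})

test_that("center-linkage classification is available", {
  back <- list(straightFiber(0), straightFiber(2))
  probe <- list(straightFiber(0.5))
  fs <- fiberSet(c(back, probe))
  labels <- c("1" = 1L, "2" = 1L)
  pairs <- rbind(c(1L, 2L), c(1L, 2L), c(NA, NA))
  atlas <- backboneBundles(pairs, labels, threshold = 4)
  full <- classifyFibers(atlas, fs, linkage = "center")
  expect_equal(bundleAssignments(full)$bundle[3], 1L)
})

test_that("bundle center minimizes the worst Hausdorff distance", {
  f <- list(straightFiber(0), straightFiber(1), straightFiber(5))
  # max Hausdorff: f1 -> 5, f2 -> 4, f3 -> 5 (brute force over members)
  expect_equal(bundleCenter(f), 2L)
  expect_equal(bundleCenter(f[1]), 1L)
})

test_that("cross-subject consistency is zero for identical bundles", {
  centers <- list(list("1" = straightFiber(0), "2" = straightFiber(9)),
                  list("1" = straightFiber(0), "2" = straightFiber(9)))
  cc <- crossSubjectConsistency(centers)
  expect_equal(cc$perBundle$meanHausdorff, c(0, 0))
  expect_equal(cc$scaleMean, 0)
  # translated subject: every bundle moves by the same Hausdorff distance
  centers[[2]] <- lapply(centers[[2]], function(p) p + 3)
  cc2 <- crossSubjectConsistency(centers)
  expect_equal(cc2$perBundle$meanHausdorff, rep(sqrt(27), 2),
               tolerance = 1e-9)
  cc3 <- crossSubjectConsistency(centers, averaging = "reference")
  expect_equal(cc3$scaleMean, cc2$scaleMean, tolerance = 1e-9)
  expect_error(crossSubjectConsistency(centers[1]), "two subjects")
})

test_that("per-bundle scalar comparison is a Welch t-test", {
  a <- cbind(b1 = c(1, 2, 3), b2 = c(0.3, 0.4, 0.5))
  b <- cbind(b1 = c(1, 2, 3), b2 = c(0.6, 0.8, 0.7))
  out <- bundleScalarTest(a, b, scalarName = "FA")
  expect_equal(out$statistic[1], 0)
  expect_equal(out$p.value[1], 1)
  ref <- t.test(a[, 2], b[, 2])
  expect_equal(out$statistic[2], unname(ref$statistic))
  expect_equal(out$p.value[2], ref$p.value)
  expect_equal(out$df[2], unname(ref$parameter))
  expect_false(any(out$exactDifference))
})

test_that("zero-variance groups are flagged, not fatal", {
  a <- cbind(b1 = c(0, 0, 0, 0))
  b <- cbind(b1 = c(1, 1, 1, 1))
  out <- bundleScalarTest(a, b)
  expect_true(out$exactDifference)
  expect_true(is.na(out$statistic))
  same <- bundleScalarTest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(bundleScalarTest(a[1, , drop = FALSE], b), "at least 2")
})
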