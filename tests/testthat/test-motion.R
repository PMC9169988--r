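test_that("motion_map implements mean absolute deviation over the window", {
  # constant sequence: zero deviation everywhere
  const <- frame_sequence(rep(list(matrix(7, 5, 5)), 4))
  expect_equal(max(motion_map(const, 0, 3)), 0)

  # hand arithmetic: values (10, 10, 40), mean 20, sum |dev| = 40, denom 2
  fs <- frame_sequence(list(matrix(10, 1, 1), matrix(10, 1, 1), matrix(40, 1, 1)))
  expect_equal(as.numeric(motion_map(fs, 0, 2)), 20)
  # squared alternative is the sample variance: (100+100+400)/2 = 300
  expect_equal(as.numeric(motion_map(fs, 0, 2, deviation = "squared")), 300)

  expect_error(motion_map(fs, 2, 2), "empty time range")
  expect_error(motion_map(fs, 2, 1), "empty time range")
})

test_that("motion_map matches the brute-force oracle and is shift-invariant", {
  for (seed in 1:5) {
    fs <- random_sequence(seed)
    tb <- sample(0:5, 1)
    tl <- tb + sample(2:4, 1)
    expect_equal(
      unclass(motion_map(fs, tb, tl)), oracle_motion(fs, tb, tl),
      tolerance = 1e-9, ignore_attr = TRUE
    )
    # adding a constant to every pixel of every frame changes nothing
    fs2 <- frame_sequence(lapply(fs$frames, function(f) f * 0.9))
    sh2 <- frame_sequence(lapply(fs2$frames, function(f) f + 20))
    expect_equal(unclass(motion_map(fs2, tb, tl)), unclass(motion_map(sh2, tb, tl)),
      tolerance = 1e-9
    )
  }
})

test_that("score_map composes flanking motion windows and clamps boundaries", {
  fs <- random_sequence(11, T = 7)
  s <- score_map(fs, 3, k_max = 2)
  manual <- unclass(motion_map(fs, 2, 3)) + unclass(motion_map(fs, 1, 3)) +
    unclass(motion_map(fs, 3, 4)) + unclass(motion_map(fs, 3, 5))
  expect_equal(unclass(s), manual, tolerance = 1e-12, ignore_attr = TRUE)

  # first frame: only forward windows contribute
  s0 <- score_map(fs, 0, k_max = 2)
  fwd <- unclass(motion_map(fs, 0, 1)) + unclass(motion_map(fs, 0, 2))
  expect_equal(unclass(s0), fwd, tolerance = 1e-12, ignore_attr = TRUE)

  # last frame: only backward windows
  s6 <- score_map(fs, 6, k_max = 2)
  bwd <- unclass(motion_map(fs, 5, 6)) + unclass(motion_map(fs, 4, 6))
  expect_equal(unclass(s6), bwd, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(score_map(frame_sequence(list(matrix(0, 3, 3))), 0),
    "single-frame"
  )
  # constant sequence scores zero
  const <- frame_sequence(rep(list(matrix(3, 4, 4)), 5))
  expect_equal(max(score_map(const, 2)), 0)
})

test_that("binarize thresholds strictly above the interpolated quantile", {
  set.seed(7)
  s <- matrix(sample(0:9999), 100, 100)
  b <- binarize(s)
  expect_equal(sum(b), 100) # scores 9900..9999 exceed the 99th quantile 9899.01
  expect_setequal(s[b == 1], 9900:9999)

  # degenerate maps: all equal / all zero give no POI
  expect_equal(sum(binarize(matrix(5, 10, 10))), 0)
  expect_equal(sum(binarize(matrix(0, 10, 10))), 0)
  expect_error(binarize(s, quantile = 1), "quantile")

  # 1-count is at most 1% of pixels plus ties, for any input
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rexp(50 * 40), 50, 40)
    m[sample(2000, 300)] <- 1 # heavy ties
    b <- binarize(m)
    thr <- quantile(as.vector(m), 0.99, type = 7, names = FALSE)
    expect_lte(sum(b), ceiling(0.01 * 2000) + sum(m == thr))
  }
})

test_that("gaussian kernel is normalized, symmetric, and flattens as sigma grows", {
  k <- make_gaussian_kernel(2, 1)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(k[3, 3], 0.16210282, tolerance = 1e-6)
  expect_equal(unclass(k), t(unclass(k)), ignore_attr = TRUE)
  expect_equal(unclass(k), unclass(k)[5:1, 5:1], ignore_attr = TRUE)
  expect_true(all(k > 0))
  flat <- make_gaussian_kernel(2, 100)
  expect_equal(as.vector(flat), rep(1 / 25, 25), tolerance = 1e-3)
  expect_error(make_gaussian_kernel(2, 0), "invalid sigma")
  expect_error(make_gaussian_kernel(0, 1), "half_width")
})

test_that("edge kernel weights must cancel", {
  g <- make_edge_kernel()
  expect_equal(sum(g), 0)
  expect_error(make_edge_kernel(matrix(1, 3, 3)), "sum to 0")
})

test_that("refine removes isolated pixels but keeps block interiors", {
  b <- matrix(0, 40, 40)
  b[5, 5] <- 1
  expect_equal(sum(refine(b)), 0) # max response 0.162 < 0.5

  blk <- matrix(0, 40, 40)
  blk[10:20, 10:20] <- 1
  r <- refine(blk)
  # full kernel support inside the block sums to 1 >= 0.5
  expect_true(all(r[12:18, 12:18] == 1))

  expect_equal(sum(refine(matrix(0, 20, 20))), 0)

  # never creates a 1 farther than half_width (Chebyshev) from an existing 1
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rbinom(900, 1, 0.1), 30, 30)
    r <- refine(m)
    ones <- which(m == 1, arr.ind = TRUE)
    new <- which(r == 1, arr.ind = TRUE)
    if (nrow(new) > 0 && nrow(ones) > 0) {
      cheb <- apply(new, 1, function(p) {
        min(pmax(abs(ones[, 1] - p[1]), abs(ones[, 2] - p[2])))
      })
      expect_lte(max(cheb), 2)
    }
  }
})

test_that("poi_contour keeps exactly the region boundaries", {
  sq <- matrix(0, 30, 30)
  sq[11:20, 11:20] <- 1
  ct <- poi_contour(sq)
  expect_equal(sum(ct), 36) # perimeter of a 10x10 square
  inner <- ct[13:18, 13:18]
  expect_equal(sum(inner), 0)

  expect_equal(sum(poi_contour(matrix(0, 10, 10))), 0)

  single <- matrix(0, 10, 10)
  single[5, 5] <- 1
  expect_equal(sum(poi_contour(single)), 1) # its own contour

  # contour is always a subset of the refined map's 1-pixels
  for (seed in 1:5) {
    set.seed(seed)
    m <- refine(matrix(rbinom(1600, 1, 0.3), 40, 40))
    ct <- poi_contour(m)
    expect_true(all(m[ct == 1] == 1))
  }
})
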