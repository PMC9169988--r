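test_that("standardized_error normalizes by the frame diagonal", {
  tr <- linear_traj(20, 3, 4)
  expect_equal(standardized_error(tr, tr, c(848, 480))$error, rep(0, 20))

  pred <- trajectory_table(frame = 0L, animal = 0L, x = 0, y = 0)
  truth <- trajectory_table(frame = 0L, animal = 0L, x = 848, y = 480)
  expect_equal(standardized_error(pred, truth, c(848, 480))$error, 1)

  # random tables match the hand-looped oracle
  set.seed(31)
  pred <- trajectory_table(
    frame = rep(0:19, 2), animal = rep(0:1, each = 20),
    x = runif(40, 0, 848), y = runif(40, 0, 480)
  )
  truth <- trajectory_table(
    frame = rep(0:19, 2), animal = rep(0:1, each = 20),
    x = runif(40, 0, 848), y = runif(40, 0, 480)
  )
  got <- standardized_error(pred, truth, c(848, 480))
  expect_equal(got$error, oracle_std_error(pred, truth, c(848, 480)),
    tolerance = 1e-12
  )
  # symmetric in pred/truth and invariant to joint translation
  expect_equal(
    standardized_error(truth, pred, c(848, 480))$error,
    got$error,
    tolerance = 1e-12
  )
  shift <- function(t) dplyr::mutate(t, x = x + 5, y = y + 7)
  expect_equal(
    standardized_error(shift(pred), shift(truth), c(848, 480))$error,
    got$error,
    tolerance = 1e-12
  )

  expect_error(
    standardized_error(pred, dplyr::filter(truth, frame < 10), c(848, 480)),
    "mismatch"
  )
})

test_that("to_cm applies the printed calibration linearly", {
  expect_equal(to_cm(0.1), 26.29)
  expect_equal(to_cm(0), 0)
  expect_equal(to_cm(0.2), 52.58)
  a <- 0.03
  b <- 0.11
  expect_equal(to_cm(a + b), to_cm(a) + to_cm(b), tolerance = 1e-12)
  sc <- calibration_scale()
  expect_equal(sc$cm_per_px, 262.9 / sqrt(848^2 + 480^2), tolerance = 1e-12)
  expect_error(to_cm(-0.1), "error")
})

test_that("pairwise_distance reports per-frame separations in px and cm", {
  a <- linear_traj(50, 1, 0)
  b <- linear_traj(50, 1, 0, x0 = 30, y0 = 40, animal = 1L)
  traj <- dplyr::bind_rows(a, b)
  d <- pairwise_distance(traj, 0, 1)
  expect_equal(d$distance, rep(50, 50)) # 3-4-5 triangle

  same <- dplyr::bind_rows(a, dplyr::mutate(a, animal = 1L))
  expect_equal(pairwise_distance(same, 0, 1)$distance, rep(0, 50))

  sc <- calibration_scale()
  dcm <- pairwise_distance(traj, 0, 1, scale = sc)
  expect_equal(dcm$distance, rep(50 * 262.9 / sqrt(848^2 + 480^2), 50),
    tolerance = 1e-12
  )
  expect_error(pairwise_distance(traj, 0, 9), "unknown animal")
})

test_that("movement metrics follow closed forms", {
  tr <- linear_traj(101, 3, 4)
  mv <- movement_per_frame(tr, 0)
  expect_equal(mv$movement, rep(5, 100))

  still <- linear_traj(10, 0, 0)
  expect_equal(movement_per_frame(still, 0)$movement, rep(0, 9))

  acc <- accumulated_movement(tr, 0)
  expect_equal(acc$accumulated[100], 500)
  expect_true(all(diff(acc$accumulated) >= 0))
  expect_equal(diff(c(0, acc$accumulated)), mv$movement)

  expect_error(movement_per_frame(tr, 5), "unknown animal")
})

test_that("movement metrics are invariant to rigid translation", {
  set.seed(4)
  tr <- trajectory_table(
    frame = 0:49, animal = 0L,
    x = cumsum(runif(50, 0, 3)) + 10, y = cumsum(runif(50, 0, 2)) + 20
  )
  shifted <- dplyr::mutate(tr, x = x + 123, y = y + 45)
  expect_equal(
    movement_per_frame(tr, 0)$movement,
    movement_per_frame(shifted, 0)$movement,
    tolerance = 1e-12
  )
})

test_that("movement_correlation matches the textbook Pearson formula", {
  mk_traj <- function(mov_a, mov_b) {
    T <- length(mov_a) + 1
    dplyr::bind_rows(
      trajectory_table(frame = 0:(T - 1), animal = 0L, x = cumsum(c(50, mov_a)), y = 50),
      trajectory_table(frame = 0:(T - 1), animal = 1L, x = cumsum(c(50, mov_b)), y = 100)
    )
  }
  set.seed(12)
  ma <- runif(60, 0.5, 3)
  mb <- runif(60, 0.5, 3)
  traj <- mk_traj(ma, mb)
  got <- movement_correlation(traj, 0, 1)
  r_hand <- sum((ma - mean(ma)) * (mb - mean(mb))) /
    sqrt(sum((ma - mean(ma))^2) * sum((mb - mean(mb))^2))
  expect_equal(got$estimate, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt((60 - 2) / (1 - r_hand^2))
  expect_equal(got$p.value, 2 * pt(-abs(tstat), 60 - 2), tolerance = 1e-12)

  # series vs itself: r = 1
  expect_equal(movement_correlation(mk_traj(ma, ma), 0, 1)$estimate, 1)
  # series vs its negation about a constant: r = -1
  expect_equal(movement_correlation(mk_traj(ma, 4 - ma), 0, 1)$estimate, -1)
  # positive affine rescaling leaves r unchanged
  expect_equal(movement_correlation(mk_traj(2 * ma + 1, mb), 0, 1)$estimate,
    got$estimate,
    tolerance = 1e-12
  )
  # degenerate: constant movement has no variance
  expect_error(
    movement_correlation(mk_traj(rep(2, 60), mb), 0, 1),
    "degenerate movement series"
  )
})

test_that("activity_heatmap is per-pixel variance scaled to [0, 1]", {
  static <- frame_sequence(rep(list(matrix(9, 8, 8)), 5))
  expect_equal(max(activity_heatmap(static)), 0)

  frames <- rep(list(matrix(100, 6, 6)), 4)
  for (i in seq_along(frames)) frames[[i]][3, 4] <- ifelse(i %% 2 == 0, 0, 255)
  fs <- frame_sequence(frames)
  hm <- activity_heatmap(fs)
  expect_equal(hm[3, 4], 1)
  expect_equal(sum(hm == 1), 1)

  fs <- random_sequence(8, T = 6, H = 12, W = 15)
  expect_equal(unclass(activity_heatmap(fs)), oracle_heatmap(fs),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_error(activity_heatmap(frame_sequence(list(matrix(0, 4, 4)))), "one frame")
})

test_that("lost frames propagate as missing values in analytics", {
  tr <- dplyr::bind_rows(
    trajectory_table(frame = 0:9, animal = 0L, x = 1:10, y = 0, confidence = c(rep(1, 5), 0.1, rep(1, 4))),
    trajectory_table(frame = 0:9, animal = 1L, x = 2 * (1:10), y = 5, confidence = 1)
  )
  attr(tr, "config") <- tracker_config()
  d <- pairwise_distance(tr, 0, 1)
  expect_true(is.na(d$distance[6]))
  expect_equal(sum(is.na(d$distance)), 1)
  mv <- movement_per_frame(tr, 0)
  expect_true(all(is.na(mv$movement[5:6])))
})

test_that("evaluate_tracking summarises per-animal precision in three units", {
  pred <- dplyr::bind_rows(
    linear_traj(10, 1, 0),
    linear_traj(10, 1, 0, y0 = 50, animal = 1L)
  )
  truth <- dplyr::mutate(pred, x = x + 3, y = y + 4) # constant 5 px error
  ev <- evaluate_tracking(pred, truth, frame_size = c(848, 480))
  expect_equal(nrow(ev), 3)
  diag_px <- sqrt(848^2 + 480^2)
  expect_equal(ev$mean_px, rep(5, 3), tolerance = 1e-9)
  expect_equal(ev$median_std, rep(5 / diag_px, 3), tolerance = 1e-12)
  expect_equal(ev$mean_cm, rep(5 / diag_px * 262.9, 3), tolerance = 1e-9)
})
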