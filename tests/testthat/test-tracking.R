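test_that("init_tracker captures the template crop and clips at frame edges", {
  f <- matrix(runif(100 * 120, 0, 255), 100, 120)
  cfg <- tracker_config(box = c(41, 41))
  st <- init_tracker(f, c(60, 50), cfg)
  expect_equal(dim(st$payload$crop), c(41, 41))
  expect_equal(st$confidence, 1)
  expect_false(st$lost)

  corner <- init_tracker(f, c(0, 0), cfg)
  expect_equal(dim(corner$payload$crop), c(21, 21)) # clipped at (0,0)

  expect_error(init_tracker(f, c(-5, 10), cfg), "start position out of bounds")
})

test_that("template_ncc stays put on identical frames with confidence 1", {
  fs <- square_scene(T = 2, dx = 0, dy = 0)
  cfg <- tracker_config(box = c(15, 15))
  st <- init_tracker(fs$frames[[1]], c(20, 30), cfg)
  st2 <- step_tracker(st, fs$frames[[2]], cfg)
  expect_equal(st2$center, c(20, 30))
  expect_equal(st2$confidence, 1, tolerance = 1e-12)
})

test_that("template_ncc is translation-covariant within the search radius", {
  cfg <- tracker_config(box = c(15, 15))
  for (shift in list(c(2, 0), c(0, 3), c(4, 2), c(-3, 1))) {
    fs <- square_scene(T = 2, dx = shift[1], dy = shift[2])
    st <- init_tracker(fs$frames[[1]], c(20, 30), cfg)
    st2 <- step_tracker(st, fs$frames[[2]], cfg)
    expect_equal(st2$center, c(20, 30) + shift, tolerance = 0.5)
  }
})

test_that("a blob displaced beyond the search radius is flagged lost", {
  cfg <- tracker_config(box = c(15, 15), search_radius = 5)
  fs <- square_scene(T = 2, dx = 40, dy = 0)
  st <- init_tracker(fs$frames[[1]], c(20, 30), cfg)
  st2 <- step_tracker(st, fs$frames[[2]], cfg)
  expect_lt(st2$confidence, cfg$confidence_floor)
  expect_true(st2$lost)
  # a lost tracker freezes: stepping again changes nothing
  st3 <- step_tracker(st2, fs$frames[[2]], cfg)
  expect_identical(st3, st2)
})

test_that("track_sequence follows scripted linear motion within 2 px", {
  fs <- square_scene(T = 15, dx = 2, dy = 1)
  traj <- track_sequence(fs, data.frame(x = 20, y = 30),
    tracker_config(box = c(15, 15))
  )
  expect_equal(nrow(traj), 15)
  truth_x <- 20 + 2 * (0:14)
  truth_y <- 30 + 1 * (0:14)
  expect_true(all(abs(traj$x - truth_x) < 2))
  expect_true(all(abs(traj$y - truth_y) < 2))
  expect_equal(count_supervisions(traj), 0)
})

test_that("a static scene tracks in place with zero supervisions", {
  fs <- square_scene(T = 20, dx = 0, dy = 0)
  traj <- track_sequence(fs, data.frame(x = 20, y = 30),
    tracker_config(box = c(15, 15))
  )
  expect_true(all(traj$x == 20 & traj$y == 30))
  expect_equal(count_supervisions(traj), 0)
})

test_that("supervision re-seeds a lost tracker and is counted", {
  # blob teleports at frame 8, far beyond the search radius
  jump <- 45
  frames <- c(
    square_scene(T = 8, dx = 0, dy = 0)$frames,
    lapply(square_scene(T = 7, x0 = 20 + jump, dx = 0, dy = 0)$frames, identity)
  )
  fs <- frame_sequence(frames)
  cfg <- tracker_config(box = c(15, 15), search_radius = 10)
  unsup <- track_sequence(fs, data.frame(x = 20, y = 30), cfg)
  expect_true(any(unsup$confidence < cfg$confidence_floor))

  sup <- data.frame(frame = 8L, animal = 0L, x = 20 + jump, y = 30)
  traj <- track_sequence(fs, data.frame(x = 20, y = 30), cfg, sup)
  expect_equal(count_supervisions(traj), 1)
  late <- dplyr::filter(traj, frame >= 8)
  expect_true(all(abs(late$x - (20 + jump)) < 2))
  # once lost and before supervision, centres freeze below the floor
  frozen <- dplyr::filter(unsup, frame >= 9)
  expect_true(all(frozen$x == frozen$x[1]))
  expect_true(all(frozen$confidence < cfg$confidence_floor))

  expect_error(
    track_sequence(fs, data.frame(x = 20, y = 30), cfg,
      data.frame(frame = 2L, animal = 7L, x = 1, y = 1)
    ),
    "unknown animal"
  )
})

test_that("count_supervisions equals the number of events applied", {
  fs <- square_scene(T = 12, dx = 0, dy = 0)
  cfg <- tracker_config(box = c(15, 15))
  sup <- data.frame(frame = c(3L, 6L, 9L), animal = 0L, x = 20, y = 30)
  traj <- track_sequence(fs, data.frame(x = 20, y = 30), cfg, sup)
  expect_equal(count_supervisions(traj), 3)
})

test_that("tracking is deterministic", {
  sim <- render_scene(pen_preset("two_blob", n_frames = 25))
  starts <- dplyr::filter(sim$truth, frame == 0)[, c("x", "y")]
  t1 <- track_sequence(sim$frames, starts, tracker_config())
  t2 <- track_sequence(sim$frames, starts, tracker_config())
  expect_identical(tidy(t1), tidy(t2))
})

test_that("sparse_flow tracks a calm blob and reports point-convergence confidence", {
  sim <- render_scene(pen_preset("one_blob", n_frames = 30))
  starts <- dplyr::filter(sim$truth, frame == 0)[, c("x", "y")]
  traj <- track_sequence(sim$frames, starts, tracker_config("sparse_flow"))
  err <- standardized_error(traj, dplyr::filter(sim$truth, frame < 30))
  expect_lt(mean(err$error), 0.02)
  expect_true(all(traj$confidence >= 0 & traj$confidence <= 1))
})

test_that("external tracker adapters run through the same contract", {
  register_tracker("mock_drift",
    init = function(frame, center, config, animal_id) {
      list(payload = list())
    },
    step = function(state, frame, config) {
      state$center <- state$center + c(1, 0)
      state$confidence <- 0.9
      state
    }
  )
  fs <- square_scene(T = 5, dx = 0, dy = 0)
  traj <- track_sequence(fs, data.frame(x = 20, y = 30),
    tracker_config("mock_drift", box = c(15, 15))
  )
  expect_equal(traj$x, 20 + 0:4)
  expect_equal(traj$y, rep(30, 5))
})

test_that("glance summarises a tracking run", {
  fs <- square_scene(T = 10, dx = 0, dy = 0)
  traj <- track_sequence(fs, data.frame(x = 20, y = 30), tracker_config(box = c(15, 15)))
  g <- glance(traj)
  expect_equal(g$n_frames, 10)
  expect_equal(g$n_animals, 1)
  expect_equal(g$n_supervisions, 0)
  expect_gte(g$mean_confidence, 0.9)
})
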