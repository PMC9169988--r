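# Independent brute-force oracles and tiny fixture builders shared by tests.
# Oracles are deliberately naive (triple loops, textbook formulas) so they
# stay independent of the vectorized implementations they check.

random_sequence <- function(seed, T = 10, H = 20, W = 20) {
  set.seed(seed)
  frame_sequence(lapply(seq_len(T), function(i) {
    matrix(runif(H * W, 0, 255), H, W)
  }))
}

oracle_motion <- function(seq, t_b, t_l) {
  f <- seq$frames
  H <- nrow(f[[1]])
  W <- ncol(f[[1]])
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      v <- vapply(f[(t_b + 1):(t_l + 1)], function(m) m[r, c], numeric(1))
      out[r, c] <- sum(abs(v - mean(v))) / (t_l - t_b)
    }
  }
  out
}

oracle_score <- function(seq, t0, k_max = 2) {
  T <- length(seq$frames)
  out <- matrix(0, nrow(seq$frames[[1]]), ncol(seq$frames[[1]]))
  for (k in seq_len(k_max)) {
    tb <- max(0, t0 - k)
    if (tb < t0) out <- out + oracle_motion(seq, tb, t0)
    tl <- min(T - 1, t0 + k)
    if (tl > t0) out <- out + oracle_motion(seq, t0, tl)
  }
  out
}

oracle_std_error <- function(pred, truth, frame_size) {
  diag_px <- sqrt(frame_size[1]^2 + frame_size[2]^2)
  out <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    j <- which(truth$frame == pred$frame[i] & truth$animal == pred$animal[i])
    out[i] <- sqrt((pred$x[i] - truth$x[j])^2 + (pred$y[i] - truth$y[j])^2) / diag_px
  }
  out
}

oracle_heatmap <- function(seq) {
  f <- seq$frames
  T <- length(f)
  H <- nrow(f[[1]])
  W <- ncol(f[[1]])
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      out[r, c] <- var(vapply(f, function(m) m[r, c], numeric(1)))
    }
  }
  rng <- range(out)
  if (diff(rng) > 0) (out - rng[1]) / diff(rng) else out * 0
}

# constant-velocity trajectory fixture: one animal, velocity (vx, vy) px/frame
linear_traj <- function(T, vx, vy, x0 = 0, y0 = 0, animal = 0L) {
  trajectory_table(
    frame = seq_len(T) - 1L, animal = animal,
    x = x0 + vx * (seq_len(T) - 1), y = y0 + vy * (seq_len(T) - 1)
  )
}

# a small moving-square scene rendered by hand (independent of pen_sim):
# a dark 9x9 square on flat background, translating (dx, dy) px/frame
square_scene <- function(T = 10, H = 60, W = 80, x0 = 20, y0 = 30, dx = 2, dy = 0) {
  frames <- lapply(seq_len(T) - 1, function(t) {
    f <- matrix(200, H, W)
    cx <- x0 + dx * t
    cy <- y0 + dy * t
    f[(cy - 4):(cy + 4) + 1, (cx - 4):(cx + 4) + 1] <- 40
    # fixed texture so templates are matchable
    f[(cy - 2):(cy + 2) + 1, (cx - 2):(cx + 2) + 1] <-
      40 + outer(1:5, 1:5, function(a, b) 7 * a + 13 * b)
    f
  })
  frame_sequence(frames)
}
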