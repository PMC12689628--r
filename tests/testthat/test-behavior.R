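test_that("instantaneous velocity matches designed paths and the window oracle", {
  fr <- 25
  still <- trajectory(rep(10, 100), rep(10, 100), fr)
  v <- instant_velocity(still)
  expect_true(all(is.na(v[1:3])))
  expect_true(all(v[-(1:3)] == 0))

  # straight line at 10 cm/s
  n <- 250
  line <- trajectory(seq(0, by = 10 / fr, length.out = n),
                     rep(5, n), fr, arena = c(200, 50))
  vl <- instant_velocity(line)
  expect_equal(unname(vl[-(1:3)]), rep(10, n - 3), tolerance = 1e-12)

  # sinusoidal path vs brute-force finite-difference oracle
  t <- seq_len(300) / fr
  x <- 25 + 10 * sin(t); y <- 25 + 8 * cos(1.3 * t)
  tr <- trajectory(x, y, fr)
  expect_equal(instant_velocity(tr), oracle_window_speed(x, y, fr),
               tolerance = 1e-9)

  expect_error(instant_velocity(trajectory(1:2, 1:2, fr)), "window")
})

test_that("episode detection thresholds strictly and reports average running speed", {
  fr <- 25; n <- 60 * fr
  run <- trajectory(seq(0, by = 10 / fr, length.out = n), rep(5, n), fr,
                    arena = c(10 / 25 * n + 5, 50))
  out <- detect_episodes(run)
  expect_equal(out$summary$n_episodes, 1)
  expect_equal(out$summary$avg_running_speed_cm_s, 10, tolerance = 1e-9)
  expect_equal(out$summary$running_time_s, (n - 3) / fr)

  slow <- trajectory(seq(0, by = 4 / fr, length.out = n), rep(5, n), fr,
                     arena = c(4 / 25 * n + 5, 50))
  out_s <- detect_episodes(slow)
  expect_equal(out_s$summary$n_episodes, 0)
  expect_true(is.na(out_s$summary$avg_running_speed_cm_s))

  # exactly at threshold is not running (strict inequality); the speed
  # series is supplied directly so the boundary is hit exactly
  at <- trajectory(rep(1, n), rep(1, n), fr, arena = c(50, 50))
  out_at <- detect_episodes(at, speed = rep(5, n), threshold = 5)
  expect_equal(out_at$summary$n_episodes, 0)
  out_above <- detect_episodes(at, speed = rep(5 + 1e-9, n), threshold = 5)
  expect_equal(out_above$summary$n_episodes, 1)
})

test_that("raising the threshold never increases running time", {
  tr <- gen_trajectory(data.frame(duration_s = c(20, 20, 20),
                                  speed_cm_s = c(12, 3, 7)),
                       arena = c(400, 400), seed = 61)
  sp <- instant_velocity(tr)
  times <- vapply(c(0, 2, 5, 8, 12),
                  function(th) detect_episodes(tr, sp, th)$summary$running_time_s,
                  numeric(1))
  expect_true(all(diff(times) <= 0))
  # threshold 0 spans all moving frames
  expect_equal(times[1], sum(!is.na(sp) & sp > 0) / tr$frame_rate)
})

test_that("episode boundaries match the programmed speed profile within one frame", {
  fr <- 25
  tr <- gen_trajectory(data.frame(duration_s = c(20, 20, 20),
                                  speed_cm_s = c(10, 2, 8)),
                       frame_rate = fr, arena = c(400, 400), seed = 62)
  sp <- instant_velocity(tr)
  out <- detect_episodes(tr, sp)
  # brute-force scan oracle on the speed series itself
  run <- !is.na(sp) & sp > 5
  brute_starts <- which(diff(c(FALSE, run)) == 1)
  expect_equal(out$episodes$start_frame, brute_starts)
  # segment boundaries at frames 500/1000/1500; window smears <= window length
  expect_equal(nrow(out$episodes), 2)
  expect_lt(abs(out$episodes$end_frame[1] - (500 + 4)), 5)
  expect_lt(abs(out$episodes$start_frame[2] - 1000), 5)
})

test_that("generated trajectories have the programmed path length and center time counts correctly", {
  tr <- gen_trajectory(data.frame(duration_s = 60, speed_cm_s = 10),
                       arena = c(200, 200), seed = 63)
  d <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  expect_lt(abs(d - 600) / 600, 0.01)

  frozen <- gen_trajectory(data.frame(duration_s = 10, speed_cm_s = 0),
                           seed = 64)
  expect_equal(length(unique(frozen$x)), 1L)

  # entirely central vs wall-hugging trajectories
  centre <- trajectory(rep(25, 100), rep(25, 100), 25)
  expect_equal(center_time(centre), 4)
  wall <- trajectory(rep(0.5, 100), rep(0.5, 100), 25)
  expect_equal(center_time(wall), 0)

  # random walk vs brute-force point-in-rectangle count
  with_test_seed(65, {
    x <- runif(500, 0, 50); y <- runif(500, 0, 50)
    tr2 <- trajectory(x, y, 25)
    manual <- sum(x >= 12.5 & x <= 37.5 & y >= 12.5 & y <= 37.5) / 25
    expect_equal(center_time(tr2), manual)
  })
})

test_that("total distance of a smooth path is robust to frame-rate resampling", {
  t50 <- seq(0, 30, by = 1 / 50); t25 <- seq(0, 30, by = 1 / 25)
  path <- function(t) list(x = 25 + 15 * sin(0.3 * t),
                           y = 25 + 15 * cos(0.22 * t))
  p50 <- path(t50); p25 <- path(t25)
  d50 <- sum(sqrt(diff(p50$x)^2 + diff(p50$y)^2))
  d25 <- sum(sqrt(diff(p25$x)^2 + diff(p25$y)^2))
  expect_lt(abs(d50 - d25) / d50, 0.02)
})

test_that("trajectory CSV round-trips including dialects", {
  tr <- gen_trajectory(data.frame(duration_s = 5, speed_cm_s = 6), seed = 66)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f, frame_rate = 25)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  # dialect with plain x/y headers
  d <- utils::read.csv(f); names(d) <- c("frame", "x", "y")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, f2, row.names = FALSE)
  expect_equal(read_trajectory_csv(f2, 25)$y, tr$y, tolerance = 1e-12)
})
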