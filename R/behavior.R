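#' Open-field trajectory container
#'
#' @param x,y positions in cm (after pixel-to-cm calibration).
#' @param frame_rate camera frame rate (Hz).
#' @param arena `c(width, height)` in cm.
#' @param center_frac side fraction of the central zone (default 0.5:
#'   the central 50% rectangle).
#' @export
trajectory <- function(x, y, frame_rate, arena = c(50, 50),
                       center_frac = 0.5) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  stop_if_not(frame_rate > 0, "frame_rate must be positive")
  stop_if_not(all(x >= -1e-9 & x <= arena[1] + 1e-9 &
                    y >= -1e-9 & y <= arena[2] + 1e-9),
              "positions must lie inside the arena")
  structure(list(x = x, y = y, frame_rate = frame_rate, arena = arena,
                 center_frac = center_frac), class = "trajectory")
}

#' Simulate a piecewise-constant-speed open-field trajectory
#'
#' The animal moves at each segment's speed with a slowly drifting
#' heading, reflected at the arena walls so the path stays inside.
#'
#' @param profile data.frame with columns `duration_s`, `speed_cm_s`.
#' @param frame_rate frames per second (default 25).
#' @param arena `c(width, height)` cm.
#' @param seed integer seed.
#' @param turn_sd per-frame heading change SD in radians.
#' @return a [trajectory()], with the programmed per-frame speed in
#'   attribute `truth_speed`.
#' @export
gen_trajectory <- function(profile, frame_rate = 25, arena = c(50, 50),
                           seed = 1L, turn_sd = 0.15) {
  stop_if_not(is.data.frame(profile) &&
                all(c("duration_s", "speed_cm_s") %in% names(profile)),
              "profile needs columns duration_s and speed_cm_s")
  stop_if_not(all(profile$speed_cm_s >= 0), "speeds must be >= 0")
  n_per <- round(profile$duration_s * frame_rate)
  speeds <- rep(profile$speed_cm_s, n_per)
  n <- length(speeds)
  with_seed(seed, {
    heading <- cumsum(stats::rnorm(n, 0, turn_sd))
    step <- speeds / frame_rate
    x <- arena[1] / 2 + cumsum(c(0, (step * cos(heading))[-n]))
    y <- arena[2] / 2 + cumsum(c(0, (step * sin(heading))[-n]))
    # reflect at walls (triangle-wave fold keeps path length intact)
    fold <- function(v, w) {
      v <- v %% (2 * w)
      ifelse(v > w, 2 * w - v, v)
    }
    tr <- trajectory(fold(x, arena[1]), fold(y, arena[2]), frame_rate, arena)
    attr(tr, "truth_speed") <- speeds
    tr
  })
}

#' Sliding-window instantaneous velocity
#'
#' Speed at frame i is the path length over the trailing window of
#' `window_frames` frames (sum of inter-frame displacements across
#' frames i-3 .. i for the default 4-frame window) divided by the
#' window duration.  The first `window_frames - 1` values are `NA`.
#'
#' @param traj a [trajectory()].
#' @param window_frames sliding-window length in frames (default 4).
#' @return numeric vector of speeds (cm/s), one per frame.
#' @export
instant_velocity <- function(traj, window_frames = 4L) {
  n <- length(traj$x)
  stop_if_not(n >= window_frames,
              "trajectory shorter than the %d-frame window", window_frames)
  d <- c(0, sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  cd <- cumsum(d)
  k <- window_frames - 1L
  v <- rep(NA_real_, n)
  idx <- (k + 1L):n
  v[idx] <- (cd[idx] - cd[idx - k]) / (k / traj$frame_rate)
  v
}

#' Detect running episodes above a speed threshold
#'
#' Episodes are maximal runs of frames whose instantaneous velocity is
#' strictly greater than the threshold (default 5 cm/s).  The summary
#' reports total distance, running time, and the average speed defined
#' as the distance covered during running time divided by the time
#' spent running (`NA` when the animal never runs).
#'
#' @param traj a [trajectory()].
#' @param speed per-frame speeds (default recomputed with the 4-frame
#'   window).
#' @param threshold cm/s (strict inequality).
#' @return list with `episodes` (data.frame start/end frame, duration
#'   s) and `summary` (distance_cm, running_time_s, running_distance_cm,
#'   avg_running_speed_cm_s, mean_velocity_cm_s).
#' @export
detect_episodes <- function(traj, speed = instant_velocity(traj),
                            threshold = 5) {
  fr <- traj$frame_rate
  run <- !is.na(speed) & speed > threshold
  r <- rle(run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep <- data.frame(start_frame = starts[r$values],
                   end_frame = ends[r$values])
  ep$duration_s <- (ep$end_frame - ep$start_frame + 1L) / fr
  d <- c(0, sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  run_dist <- sum(d[run])
  run_time <- sum(run) / fr
  list(episodes = ep,
       summary = data.frame(
         distance_cm = sum(d),
         running_time_s = run_time,
         running_distance_cm = run_dist,
         avg_running_speed_cm_s = if (run_time > 0) run_dist / run_time
                                  else NA_real_,
         mean_velocity_cm_s = mean(speed, na.rm = TRUE),
         n_episodes = nrow(ep)))
}

#' Time spent in the central zone
#'
#' Frames whose position lies in the closed central rectangle (side =
#' `center_frac` of each arena dimension, centred) count as inside;
#' boundary frames are inside.
#'
#' @param traj a [trajectory()].
#' @return seconds in the centre zone.
#' @export
center_time <- function(traj) {
  w <- traj$arena[1]; h <- traj$arena[2]; f <- traj$center_frac
  lo_x <- w * (1 - f) / 2; hi_x <- w - lo_x
  lo_y <- h * (1 - f) / 2; hi_y <- h - lo_y
  inside <- traj$x >= lo_x & traj$x <= hi_x &
    traj$y >= lo_y & traj$y <= hi_y
  sum(inside) / traj$frame_rate
}

#' Write / read a trajectory CSV (`frame,x_cm,y_cm`)
#'
#' The reader also accepts tracking-export dialects with columns named
#' `x`/`y` or `x_cm`/`y_cm` (header sniffing).
#'
#' @param traj a [trajectory()]; @param path file path.
#' @param frame_rate,arena metadata needed on read.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(frame = seq_along(traj$x),
                              x_cm = traj$x, y_cm = traj$y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, frame_rate, arena = c(50, 50)) {
  d <- utils::read.csv(path)
  nx <- intersect(c("x_cm", "x"), names(d))[1]
  ny <- intersect(c("y_cm", "y"), names(d))[1]
  stop_if_not(!is.na(nx) && !is.na(ny),
              "trajectory CSV needs x/x_cm and y/y_cm columns")
  trajectory(d[[nx]], d[[ny]], frame_rate, arena)
}
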