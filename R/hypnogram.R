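#' Default per-epoch vigilance-state transition matrices
#'
#' Per-4-s-epoch Markov transition probabilities over
#' WAKE/NREM/REM/TREM, one matrix for the light phase and one for the
#' dark phase of a 12:12 light/dark cycle.  The defaults were chosen so
#' the chain's stationary architecture resembles a deeply sleeping
#' laboratory mouse: about 535 min of sleep in the light phase and
#' 270 min in the dark phase (about two thirds of total sleep in the
#' light phase, and a sleep-majority day, which the median-EMG
#' baseline of the rule-based scorer assumes), with roughly 85 min of
#' light-phase REM sleep.  TREM is reachable only from NREM and
#' transitions only to REM or WAKE, so transition-to-REM epochs are
#' brief and always border NREM.
#'
#' @return A list with elements `light` and `dark`, each a 4x4
#'   row-stochastic matrix with dimnames [VIGILANCE_STATES].
#' @export
default_transition_matrices <- function() {
  mk <- function(v) {
    m <- matrix(v, 4, 4, byrow = TRUE,
                dimnames = list(VIGILANCE_STATES, VIGILANCE_STATES))
    m
  }
  list(
    light = mk(c(
      .820, .180, .000, .000,
      .040, .925, .005, .030,
      .160, .000, .840, .000,
      .300, .000, .700, .000)),
    dark = mk(c(
      .938, .062, .000, .000,
      .085, .885, .002, .028,
      .180, .000, .820, .000,
      .400, .000, .600, .000))
  )
}

#' Hypnogram generator parameters
#'
#' @param days number of recorded days (each day = 21600 4-s epochs).
#' @param transition_light,transition_dark 4x4 row-stochastic per-epoch
#'   transition matrices over [VIGILANCE_STATES] (defaults from
#'   [default_transition_matrices()]).
#' @param lights_on_zt,lights_off_zt zeitgeber hours of lights-on/off
#'   (fixed 12:12 cycle: 0 and 12).
#' @param seed integer seed making the generated hypnogram reproducible.
#' @return An object of class `hypnogram_params`.
#' @export
hypnogram_params <- function(days = 1L,
                             transition_light = default_transition_matrices()$light,
                             transition_dark = default_transition_matrices()$dark,
                             lights_on_zt = 0, lights_off_zt = 12,
                             seed = 1L) {
  stop_if_not(is_count(days) && days >= 1, "days must be a positive integer")
  stop_if_not(identical(c(lights_on_zt, lights_off_zt), c(0, 12)),
              "only the regular 12:12 cycle (lights on ZT0, off ZT12) is supported")
  check_transition_matrix(transition_light, "transition_light")
  check_transition_matrix(transition_dark, "transition_dark")
  structure(list(days = as.integer(days),
                 transition_light = transition_light,
                 transition_dark = transition_dark,
                 lights_on_zt = 0, lights_off_zt = 12,
                 seed = as_seed(seed)),
            class = "hypnogram_params")
}

check_transition_matrix <- function(P, name) {
  stop_if_not(is.matrix(P) && all(dim(P) == c(4L, 4L)),
              "%s must be a 4x4 matrix over WAKE/NREM/REM/TREM", name)
  stop_if_not(all(P >= 0) && all(abs(rowSums(P) - 1) < 1e-8),
              "%s rows must be probabilities summing to 1", name)
  # TREM structural constraints: reachable only from NREM, leaves only
  # to REM or WAKE
  stop_if_not(all(P[c(1, 3, 4), 4] == 0),
              "%s: TREM may only be entered from NREM", name)
  stop_if_not(all(P[4, c(2, 4)] == 0),
              "%s: TREM may only transition to REM or WAKE", name)
  invisible(P)
}

#' Simulate a vigilance-state hypnogram
#'
#' Draws a per-epoch Markov chain over WAKE/NREM/REM/TREM, switching
#' between the light- and dark-phase transition matrices at ZT12/ZT0.
#' The chain starts in WAKE at ZT0 (lights on).
#'
#' @param params a [hypnogram_params()] object.
#' @return A `hypnogram`: data.frame with columns `epoch_index`
#'   (1-based), `state` (factor over [VIGILANCE_STATES]), `zt_phase`
#'   (`"light"`/`"dark"`), `day_index` (1-based).
#' @export
gen_hypnogram <- function(params) {
  stop_if_not(inherits(params, "hypnogram_params"),
              "params must come from hypnogram_params()")
  n <- params$days * 21600L
  epochs_per_hour <- 900L
  zt_hour <- (((seq_len(n) - 1L) %/% epochs_per_hour) %% 24L)
  phase <- ifelse(zt_hour < 12L, "light", "dark")
  day <- ((seq_len(n) - 1L) %/% 21600L) + 1L

  states <- integer(n)
  with_seed(params$seed, {
    u <- stats::runif(n)
    cumL <- t(apply(params$transition_light, 1, cumsum))
    cumD <- t(apply(params$transition_dark, 1, cumsum))
    cur <- 1L  # WAKE at lights-on
    for (i in seq_len(n)) {
      cm <- if (phase[i] == "light") cumL else cumD
      cur <- findInterval(u[i], cm[cur, ], left.open = TRUE) + 1L
      states[i] <- cur
    }
  })
  structure(data.frame(
    epoch_index = seq_len(n),
    state = factor(VIGILANCE_STATES[states], levels = VIGILANCE_STATES),
    zt_phase = phase,
    day_index = day,
    zt_h = (seq_len(n) - 1L) * EPOCH_S / 3600,
    stringsAsFactors = FALSE
  ), class = c("hypnogram", "data.frame"))
}

#' Assemble a hypnogram from a state sequence
#'
#' Utility for building hypnograms directly (e.g. designed test cases):
#' phase and day labels are derived from epoch position assuming the
#' recording starts at ZT0 under the 12:12 cycle.
#'
#' @param states character/factor vector over [VIGILANCE_STATES].
#' @param start_zt zeitgeber hour of the first epoch (default 0).
#' @return A `hypnogram` data.frame.
#' @export
as_hypnogram <- function(states, start_zt = 0) {
  states <- as.character(states)
  stop_if_not(all(states %in% VIGILANCE_STATES),
              "states must be WAKE/NREM/REM/TREM")
  n <- length(states)
  epoch_zt_h <- start_zt + (seq_len(n) - 1L) * EPOCH_S / 3600
  zt_hour <- epoch_zt_h %% 24
  structure(data.frame(
    epoch_index = seq_len(n),
    state = factor(states, levels = VIGILANCE_STATES),
    zt_phase = ifelse(zt_hour < 12, "light", "dark"),
    day_index = as.integer(epoch_zt_h %/% 24) + 1L,
    zt_h = epoch_zt_h,
    stringsAsFactors = FALSE
  ), class = c("hypnogram", "data.frame"))
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the per-epoch transition matrix associated with
#' eigenvalue 1, normalized to sum to 1.
#'
#' @param P row-stochastic matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stats::setNames(v / sum(v), rownames(P))
}

#' Write / read hypnogram CSV
#'
#' Columns: `epoch_index,state,zt_phase` (day and phase are re-derived
#' from the epoch index on read, assuming a ZT0 start).
#'
#' @param hyp a `hypnogram`.
#' @param path file path.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  utils::write.csv(hyp[, c("epoch_index", "state", "zt_phase")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("epoch_index", "state") %in% names(d)),
              "hypnogram CSV needs epoch_index and state columns")
  as_hypnogram(d$state)
}

#' Subset a hypnogram keeping phase/day/ZT labels
#'
#' Used to run the spectral pipeline on a phase-balanced subset of
#' epochs: phase, day, and zeitgeber-time labels travel with the
#' epochs, while `epoch_index` is re-numbered to match the generated
#' signal.
#'
#' @param hyp a `hypnogram`; @param idx epoch indices to keep.
#' @export
subset_hypnogram <- function(hyp, idx) {
  out <- hyp[idx, , drop = FALSE]
  out$epoch_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("hypnogram", "data.frame"))
}
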