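#' @keywords internal
"_PACKAGE"

#' Vigilance-state labels
#'
#' The four states used throughout: wakefulness, NREM sleep, REM sleep, and
#' transition-to-REM (TREM) epochs showing mixed slow-wave and theta
#' activity.  TREM counts toward REM sleep durations but is excluded from
#' state-specific spectra.
#'
#' @export
VIGILANCE_STATES <- c("WAKE", "NREM", "REM", "TREM")

# seconds per scoring epoch; fixed by the analysis design
EPOCH_S <- 4L

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Restrict a seed to the 32-bit range R accepts
#' @noRd
as_seed <- function(seed) {
  stop_if_not(length(seed) == 1L && is.numeric(seed) && !is.na(seed),
              "seed must be a single number")
  as.integer(abs(seed) %% .Machine$integer.max)
}

# Run an expression under a local RNG state seeded deterministically, so
# generators are pure functions of their seed and never disturb the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as_seed(seed))
  expr
}
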