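# The synthetic noisy input: a linear birth/autocatalysis/death process for
# the signalling molecule S with a mean-independent super-Poissonian Fano
# factor, stepped through a staircase of plateau means.

#' Calibrate the super-Poissonian input mechanism
#'
#' S is produced basally (0 -> S at rate `a`), autocatalytically
#' (S -> 2S at rate `b*S`, the positive-feedback production term that makes
#' the copy-number distribution super-Poissonian), and decays first-order
#' (S -> 0 at rate `d*S`).  For `b < d` the stationary mean is `a/(d-b)`
#' and the stationary Fano factor `d/(d-b)` -- independent of `a`, hence
#' identical at every plateau of the staircase.  The mechanism is
#' normalised to relaxation rate `d - b = 1`, so `a` equals the plateau
#' mean and `d` the target Fano factor.
#'
#' @param target_fano stationary variance/mean ratio, must exceed 1
#'   (strictly super-Poissonian mechanism); the Poissonian limit is
#'   approached as `target_fano -> 1` (`b -> 0`).
#' @param mean stationary copy-number mean (counts).
#' @return An object of class `ffl_input` with fields `a`, `b`, `d`,
#'   `mean`, `fano`.
#' @examples
#' inp <- calibrate_input(1.83, mean = 6)
#' c(inp$a, inp$b, inp$d)        # 6, 0.83, 1.83
#' inp$d / (inp$d - inp$b)       # 1.83
#' @export
calibrate_input <- function(target_fano = 1.83, mean = 1) {
  if (!is.numeric(target_fano) || target_fano <= 1)
    stop("target_fano must be > 1 (super-Poissonian mechanism)")
  if (!is.numeric(mean) || mean <= 0) stop("mean must be positive")
  structure(list(a = mean, b = target_fano - 1, d = target_fano,
                 mean = mean, fano = target_fano),
            class = "ffl_input")
}

#' @export
print.ffl_input <- function(x, ...) {
  cat("<ffl_input> mean=", x$mean, " fano=", x$fano,
      "  (a=", x$a, ", b=", x$b, ", d=", x$d, ")\n", sep = "")
  invisible(x)
}

#' Staircase input protocol
#'
#' Piecewise-constant schedule for the input's plateau mean: a baseline
#' plateau, five increasing plateaus, then the mirrored descent back to
#' baseline.  Every plateau lasts `duration` time units, long relative to
#' the input relaxation time (1 time unit) and the fastest layer
#' relaxation, so end-of-plateau statistics are stationary.
#'
#' @param levels five strictly increasing plateau means.
#' @param duration plateau length (time units).
#' @param baseline mean of the first and last plateau.
#' @return An object of class `ffl_protocol`: `segments` is a data frame
#'   with columns `level`, `t0`, `t1`, `phase` (`"base"`, `"up"`,
#'   `"down"`).
#' @examples
#' staircase()$segments$level   # 1 2 3 4 5 6 5 4 3 2 1
#' @export
staircase <- function(levels = c(2, 3, 4, 5, 6), duration = 20, baseline = 1) {
  if (length(levels) != 5L) stop("exactly five plateau levels are required")
  if (any(diff(levels) <= 0)) stop("plateau levels must be strictly increasing")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  if (baseline >= levels[1]) stop("baseline must lie below the first level")
  seq_levels <- c(baseline, levels, rev(c(baseline, levels[-5])))
  phase <- c("base", rep("up", 5), rep("down", 5))
  n <- length(seq_levels)
  segments <- data.frame(
    level = seq_levels,
    t0 = (seq_len(n) - 1) * duration,
    t1 = seq_len(n) * duration,
    phase = phase,
    stringsAsFactors = FALSE)
  structure(list(levels = levels, baseline = baseline, duration = duration,
                 segments = segments),
            class = "ffl_protocol")
}

#' Constant-input protocol
#'
#' Single plateau at a fixed mean, used for stationary analyses and
#' simulation at one input level.
#'
#' @param level plateau mean.
#' @param duration plateau length.
#' @return An `ffl_protocol` with one segment.
#' @export
constant_protocol <- function(level, duration = 50) {
  structure(list(levels = level, baseline = level, duration = duration,
                 segments = data.frame(level = level, t0 = 0, t1 = duration,
                                       phase = "base",
                                       stringsAsFactors = FALSE)),
            class = "ffl_protocol")
}

#' @export
print.ffl_protocol <- function(x, ...) {
  cat("<ffl_protocol> plateaus:",
      paste(x$segments$level, collapse = " "),
      " duration=", x$duration, "\n", sep = "")
  invisible(x)
}

#' Input mechanisms at reduced, default and increased noise
#'
#' Returns the input mechanism family used for the input-noise robustness
#' analysis: the autocatalytic and decay rates are re-tuned so the
#' stationary Fano factor takes the requested scale while every plateau
#' mean is unchanged (the mean is set by `a/(d-b)` alone).
#'
#' @param scale one of `"reduced"`, `"default"`, `"increased"`.
#' @param mean stationary mean of the returned mechanism.
#' @return An `ffl_input`.
#' @examples
#' set_input_noise("reduced", mean = 6)$fano    # 1.2
#' set_input_noise("default", mean = 6)$fano    # 1.83
#' @export
set_input_noise <- function(scale = c("default", "reduced", "increased"),
                            mean = 1) {
  scale <- match.arg(scale)
  fano <- c(reduced = 1.2, default = 1.83, increased = 3.0)[[scale]]
  calibrate_input(fano, mean = mean)
}
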