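#' Convert milliseconds to a whole number of samples
#'
#' Deterministic floor conversion used everywhere a duration in ms has to be
#' expressed in samples: `floor(ms * fs / 1000)`.
#'
#' @param ms duration in milliseconds.
#' @param fs sampling rate in Hz.
#' @return integer number of samples.
#' @export
ms_to_samples <- function(ms, fs) {
  stopifnot(is.numeric(ms), is.numeric(fs), fs > 0)
  as.integer(floor(ms * fs / 1000))
}

#' Convert a current array to picoamperes
#'
#' Internal unit convention is pA throughout. Accepted input units are
#' `"pA"`, `"nA"` and `"A"`.
#'
#' @param x numeric vector or matrix of currents.
#' @param units character unit label of `x`.
#' @return `x` rescaled to pA.
#' @export
to_pA <- function(x, units = c("pA", "nA", "A")) {
  units <- match.arg(units)
  x * switch(units, pA = 1, nA = 1e3, A = 1e12)
}

# Structured logging. Levels: 0 silent, 1 info, 2 debug; controlled by
# options(photodemix.verbose = <level>).
pd_log <- function(level, ...) {
  verbose <- getOption("photodemix.verbose", 0L)
  if (verbose >= level) message(sprintf(...))
}

# Stop with a consistent error class so callers/tests can match on it.
pd_stop <- function(fmt, ..., class = "photodemix_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
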