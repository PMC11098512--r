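#' Decay constraint specification
#'
#' Describes the exponential-decay constraint `q[i] <= gamma * q[i-1]`
#' applied to a temporal waveform from `start` onwards. `gamma = 1` gives a
#' plain monotone-decrease constraint; `gamma < 1` forces at least geometric
#' decay. `gamma` is defined per sample at the 20 kHz reference rate; use
#' [gamma_at_rate()] when operating at other sampling rates so the implied
#' time constant is preserved.
#'
#' @param gamma decay factor in (0, 1].
#' @param start 1-based index of the first constrained *pair*: the constraint
#'   binds `q[i] <= gamma * q[i-1]` for all `i > start`, i.e. samples before
#'   `start` are unconstrained. `start = 1` constrains the whole vector.
#' @return object of class `decay_constraint`.
#' @export
decay_constraint <- function(gamma = 0.999, start = 1L) {
  if (!(is.numeric(gamma) && length(gamma) == 1L && gamma > 0 && gamma <= 1))
    pd_stop("gamma must lie in (0, 1]")
  start <- as.integer(start)
  if (start < 1L) pd_stop("start must be >= 1")
  structure(list(gamma = gamma, start = start), class = "decay_constraint")
}

#' Rescale a per-sample decay factor to another sampling rate
#'
#' Keeps the implied exponential time constant fixed when resampling:
#' `gamma' = gamma^(20000 / fs)`.
#'
#' @param gamma decay factor defined at 20 kHz.
#' @param fs target sampling rate in Hz.
#' @return rescaled decay factor.
#' @export
gamma_at_rate <- function(gamma, fs) gamma^(20000 / fs)

#' Project a vector onto the set of gamma-decreasing vectors
#'
#' Euclidean projection of `x` onto `{q : q[i] <= gamma * q[i-1]}` for
#' indices after `constraint$start`; entries before `start` are returned
#' unchanged. For `gamma = 1` this is classic decreasing isotonic regression
#' (pool adjacent violators); for `gamma < 1` the generalized pooling
#' recursion used for autoregressive deconvolution of calcium traces. The
#' projection is exact, idempotent and non-expansive.
#'
#' @param x numeric vector.
#' @param constraint a [decay_constraint()].
#' @return projected vector, same length as `x`.
#' @examples
#' project_gamma_decreasing(c(1, 3, 2), decay_constraint(1))  # 2 2 2
#' @export
project_gamma_decreasing <- function(x, constraint = decay_constraint()) {
  stopifnot(inherits(constraint, "decay_constraint"))
  if (any(!is.finite(x))) pd_stop("non-finite input to projection")
  n <- length(x)
  s <- constraint$start
  if (s >= n) return(x)
  out <- x
  out[s:n] <- pava_gamma_decreasing_cpp(x[s:n], constraint$gamma)
  out
}
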