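# Continuous-time Markov chain machinery shared by the simulator and the
# multi-state model: generator construction/validation and transition
# probabilities via the matrix exponential.

#' Build a birth-death transition-intensity matrix
#'
#' Constructs the generator matrix of a continuous-time Markov chain on the
#' ordered GOSe states 3..8 (indices 1..6) in which only transitions between
#' adjacent categories are allowed. This is the default structure both for the
#' synthetic-cohort truth and for the fitted multi-state model: panel data with
#' 1-4 observations per patient cannot identify a dense intensity matrix, and
#' the adjacent-state structure is the standard choice for an ordinal scale.
#'
#' @param up numeric vector of length `n - 1`; upward intensities (per day)
#'   from states `1..n-1` to the next-better state.
#' @param down numeric vector of length `n - 1`; downward intensities from
#'   states `2..n` to the next-worse state.
#' @param n number of states (default 6, GOSe 3..8).
#' @return An `n x n` generator matrix with rows summing to zero.
#' @examples
#' Q <- generator_matrix(up = rep(0.01, 5), down = rep(0.002, 5))
#' rowSums(Q)
#' @export
generator_matrix <- function(up, down, n = N_STATES) {
  stopifnot(length(up) == n - 1, length(down) == n - 1)
  if (any(up < 0) || any(down < 0))
    stop("transition intensities must be non-negative", call. = FALSE)
  Q <- matrix(0, n, n)
  Q[cbind(1:(n - 1), 2:n)] <- up
  Q[cbind(2:n, 1:(n - 1))] <- down
  diag(Q) <- -rowSums(Q)
  Q
}

#' Validate a transition-intensity matrix
#'
#' Checks that off-diagonal entries are non-negative and each row sums to zero
#' (within `1e-10`); on failure the error names the offending row.
#'
#' @param Q square numeric matrix of transition intensities.
#' @return `Q`, invisibly.
#' @export
validate_generator <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("generator must be a square matrix", call. = FALSE)
  off <- Q
  diag(off) <- 0
  bad <- which(apply(off, 1, function(r) any(r < 0)))
  if (length(bad))
    stop(sprintf("generator row %d has a negative off-diagonal intensity", bad[1]),
         call. = FALSE)
  rs <- rowSums(Q)
  bad <- which(abs(rs) > 1e-10)
  if (length(bad))
    stop(sprintf("generator row %d does not sum to zero (sum = %.3g)", bad[1], rs[bad[1]]),
         call. = FALSE)
  invisible(Q)
}

#' Transition probability matrix of a continuous-time Markov chain
#'
#' Computes `expm(Q * dt)`, the matrix of state-transition probabilities over
#' an interval of `dt` days. Entries are clamped at zero against round-off.
#'
#' @param Q generator matrix (validated).
#' @param dt non-negative interval length in days.
#' @return Stochastic matrix with rows summing to 1.
#' @examples
#' Q <- generator_matrix(rep(0.01, 5), rep(0.002, 5))
#' P <- transition_matrix(Q, 180)
#' rowSums(P)
#' @export
transition_matrix <- function(Q, dt) {
  validate_generator(Q)
  stopifnot(is.numeric(dt), length(dt) == 1, dt >= 0)
  P <- cpp_ctmc_expm(Q, dt)
  dimnames(P) <- dimnames(Q)
  P
}
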