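# Internal assertions and seed handling.

stop_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) rlang::abort(sprintf(msg, ...))
  invisible(NULL)
}

is_binary01 <- function(y) {
  is.numeric(y) && !anyNA(y) && all(y %in% c(0, 1))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed from a single master
#' seed through this deterministic multiplicative hash, so that module-level
#' results are reproducible in isolation and the whole pipeline is a pure
#' function of one integer. The returned value is always a valid 32-bit R
#' integer seed.
#'
#' @param seed Master seed (single integer).
#' @param stream Stream index (non-negative integer); distinct streams give
#'   unrelated sub-seeds.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(42, 0)
#' split_seed(42, 1)
split_seed <- function(seed, stream = 0L) {
  stop_if(length(seed) != 1L || is.na(seed), "`seed` must be a single integer.")
  stop_if(length(stream) != 1L || is.na(stream) || stream < 0,
          "`stream` must be a single non-negative integer.")
  # Knuth multiplicative hash mod the Mersenne prime 2^31 - 1; doubles hold
  # the intermediate product exactly (< 2^53).
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) * 48271 + as.numeric(stream) * 16807 + 1
  as.integer(s %% m)
}

# Sample standard deviation with an informative error on degenerate input.
sd_strict <- function(x, what = "scores") {
  s <- stats::sd(x)
  stop_if(!is.finite(s) || s == 0,
          "standard deviation of %s is zero or undefined; cannot standardize.",
          what)
  s
}

as_matrix_named <- function(x, what = "matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  stop_if(!is.matrix(x) || !is.numeric(x), "`%s` must be a numeric matrix or data frame.", what)
  if (is.null(colnames(x))) colnames(x) <- paste0(what, seq_len(ncol(x)))
  x
}
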