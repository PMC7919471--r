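#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' All stochastic generators in the package draw their randomness from
#' sub-streams keyed by `(seed, tag)`, so that e.g. the lesion texture of a
#' patient is shared across scans while the acquisition noise is not.
#'
#' @param seed integer master seed.
#' @param ... character/numeric tags identifying the sub-stream.
#' @return a positive integer < 2^31 usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  tag <- paste(c(format(as.integer(seed)), vapply(list(...), format, "")),
               collapse = "/")
  h <- digest::digest2int(tag, seed = 0L)
  # map to [1, 2^31 - 2]; digest2int may be negative
  as.integer(abs(as.double(h)) %% (.Machine$integer.max - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gdr <- function(class, msg, ...) {
  stop(structure(class = c(class, "gdr_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Moment helpers used by the first-order feature family
#' @noRd
.skewness <- function(x) {
  n <- length(x); m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

.kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}
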