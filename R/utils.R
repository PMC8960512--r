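#' @keywords internal
#' @noRd
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child seed from a master seed, stream index kept below 2^31.
#' @keywords internal
#' @noRd
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

#' @keywords internal
#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)
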