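# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so that re-running a single stage reproduces exactly the draws
#' it saw inside the full pipeline. The substream seed is a deterministic
#' 31-bit hash of the master seed and the stream name.
#'
#' @param seed master integer seed.
#' @param name character stream name (e.g. "genotypes", "cv").
#' @return integer seed below 2^31, suitable for [set.seed()].
#' @export
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% m
  as.integer(h)
}

# consistent, quiet-able progress/filter logging
bcLog <- function(fmt, ...) {
  if (isTRUE(getOption("bcrisk.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(paste0("[bcrisk] ", fmt), ...))
}

# stop() with a consistent prefix and no call
bcStop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# validate a fraction-valued threshold
checkFraction <- function(x, name, lo = 0, hi = 1,
                          loOpen = TRUE, hiOpen = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (loOpen) x > lo else x >= lo) && (if (hiOpen) x < hi else x <= hi)
  if (!ok) bcStop("%s must be a fraction in %s%g, %g%s, got %s",
                  name, if (loOpen) "(" else "[", lo, hi,
                  if (hiOpen) ")" else "]", format(x))
  invisible(x)
}
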