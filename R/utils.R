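# Internal helpers: seed substreams and small utilities.

#' Derive an independent substream seed
#'
#' One user-facing seed is expanded into per-cohort, per-stage substreams so
#' that adding a generation stage never perturbs draws made by earlier stages.
#' The derivation is a simple multiplicative hash kept below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param seed base integer seed
#' @param stream stage index (small non-negative integer)
#' @return an integer seed
#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 48271 + stream * 16807 + 12345) %% 2147483647)
}

#' Statistical mode with ties broken to the smallest value
#' @param x numeric vector (NAs removed)
#' @return modal value
#' @keywords internal
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("cannot compute a mode of an all-missing vector")
  tab <- table(x)
  vals <- as.numeric(names(tab))
  # ties break to the smallest value; names(tab) sorts ascending already
  vals[which.max(tab)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
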