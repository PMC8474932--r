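#' Nearest-rank empirical quantile
#'
#' Quantile by the nearest-rank (ceiling) definition: the smallest value `v`
#' in `x` such that at least `p * length(x)` of the values are `<= v`.
#' Used for all empirical null thresholds so results are reproducible without
#' interpolation ambiguity.
#'
#' @param x numeric vector, non-empty.
#' @param p probability in (0, 1].
#' @return a single value of `x`.
#' @keywords internal
nearest_rank_quantile <- function(x, p) {
  stopifnot(length(x) > 0, is.numeric(x), p > 0, p <= 1)
  xs <- sort(x)
  xs[max(1L, ceiling(p * length(xs)))]
}

#' MD5 checksum of an arbitrary R object
#'
#' Serializes the object (version 3, platform-independent) to a temporary file
#' and hashes it. Used for pipeline run manifests.
#'
#' @param object any R object.
#' @return hex string.
#' @keywords internal
object_checksum <- function(object) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(object, con, version = 3)
  close(con)
  unname(tools::md5sum(tf))
}

# internal: stop with a consistent message prefix
abort <- function(...) stop(..., call. = FALSE)
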