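#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Largest-remainder apportionment
#'
#' Split an integer total `n` into class counts proportional to `props`,
#' using largest-remainder (Hamilton) rounding. Ties in the fractional parts
#' are broken in favour of earlier classes.
#'
#' @param n Integer total to apportion.
#' @param props Nonnegative numeric vector of proportions (normalized
#'   internally to sum to 1).
#' @return Integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, props) {
  stopifnot(is.numeric(props), all(props >= 0), sum(props) > 0, n >= 0)
  p <- props / sum(props)
  raw <- n * p
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- raw - counts
    take <- order(-frac, seq_along(frac))[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

# Normalize a proportion/percentage vector to sum to 1.  Accepts raw
# percentages (sum near 100) as well as proportions (sum near 1); errors if
# the vector is further than 5% from a valid composition.
normalize_props <- function(p, what = "proportions") {
  stopifnot(is.numeric(p), all(p >= 0), sum(p) > 0)
  s <- sum(p)
  if (abs(s - 100) < abs(s - 1)) p <- p / 100
  s <- sum(p)
  if (abs(s - 1) > 0.05) {
    stop(sprintf("%s sum to %.4f; expected a composition summing to 1 (or 100%%)",
                 what, s), call. = FALSE)
  }
  p / s
}

# Atomic file write: write via a tempfile in the same directory, then rename.
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

# Deterministic per-replicate seed derived from a scenario seed, kept within
# 32-bit integer range so set.seed() accepts it.
replicate_seed <- function(seed, rep) {
  as.integer((as.double(seed) * 7919 + as.double(rep) * 104729) %% 2147483629)
}
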