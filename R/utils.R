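#' Segment grid for a recording
#'
#' Start times (in seconds) of the 2-s analysis segments covering a
#' recording at 50% overlap, i.e. a 1-s hop.  A recording of `duration_s`
#' seconds holds `duration_s - 1` complete 2-s segments, starting at
#' 0, 1, ..., `duration_s - 2`.
#'
#' @param duration_s Recording length in seconds (integer-valued, >= 2).
#' @return Integer vector of segment start times in seconds.
#' @export
#' @examples
#' length(segment_grid(3600)) # 3599
segment_grid <- function(duration_s) {
  duration_s <- as.integer(duration_s)
  if (length(duration_s) != 1L || is.na(duration_s) || duration_s < 2L) {
    abort("`duration_s` must be a single integer >= 2.")
  }
  0:(duration_s - 2L)
}

# length of elementwise intersection of [a_lo, a_hi) with [b_lo, b_hi)
overlap_length <- function(a_lo, a_hi, b_lo, b_hi) {
  pmax(0, pmin(a_hi, b_hi) - pmax(a_lo, b_lo))
}

# total overlap of a single interval [lo, hi) with a set of intervals,
# computed on the union of the set (intervals may touch or overlap)
overlap_with_set <- function(lo, hi, set_lo, set_hi) {
  if (length(set_lo) == 0L) return(0)
  u <- merge_interval_set(set_lo, set_hi, gap = 0)
  sum(overlap_length(lo, hi, u$lo, u$hi))
}

# merge sorted-or-unsorted intervals whose gap is < `gap` (gap = 0 merges
# only touching/overlapping intervals); returns list(lo, hi)
merge_interval_set <- function(lo, hi, gap = 0) {
  if (length(lo) == 0L) return(list(lo = numeric(), hi = numeric()))
  o <- order(lo, hi)
  lo <- lo[o]
  hi <- hi[o]
  out_lo <- lo[1L]
  out_hi <- hi[1L]
  k <- 1L
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] - out_hi[k] < gap || lo[i] <= out_hi[k]) {
      out_hi[k] <- max(out_hi[k], hi[i])
    } else {
      k <- k + 1L
      out_lo[k] <- lo[i]
      out_hi[k] <- hi[i]
    }
  }
  list(lo = out_lo, hi = out_hi)
}

# rolling sum over windows of `width` consecutive values, hop 1;
# returns vector of length length(x) - width + 1
roll_sum <- function(x, width = 10L) {
  n <- length(x)
  if (n < width) return(numeric(0))
  cs <- cumsum(as.numeric(x))
  cs[width:n] - c(0, cs)[1:(n - width + 1L)]
}

# chunked squared Euclidean nearest-neighbour distance from each row of X
# to the rows of R (both already projected); avoids an n x r allocation
min_dist_sq <- function(X, R, chunk = 4096L) {
  X <- as.matrix(X)
  R <- as.matrix(R)
  if (nrow(R) == 0L) abort("reference set is empty")
  # min_j |x - r_j|^2 = |x|^2 - 2 max_j (x . r_j - |r_j|^2 / 2); the
  # shifted inner products come from one BLAS call on an augmented matrix
  Rt <- rbind(t(R), -rowSums(R * R) / 2)
  n <- nrow(X)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    Xc <- cbind(X[i0:i1, , drop = FALSE], 1)
    out[i0:i1] <- rowSums(Xc * Xc) - 1 - 2 * matrixStats::rowMaxs(Xc %*% Rt)
  }
  pmax(out, 0)
}

check_fraction <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a single number in [0, %s).",
                  name, if (allow_one) "1]" else "1"))
  }
  invisible(x)
}
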