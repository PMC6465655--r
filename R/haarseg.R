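#' Haar-wavelet segmentation of a Z-value profile
#'
#' Segments an ordered vector of region Z-values into piecewise-constant
#' segments using the HaarSeg scheme: the profile is convolved with Haar
#' step wavelets at dyadic scales 2^0 .. 2^(max_scale-1); local maxima of
#' the absolute convolution are breakpoint candidates; candidates are kept
#' by a Benjamini-Hochberg FDR test at level `fdr_q` against a robust noise
#' estimate (MAD of the unit-lag differences, scaled by sqrt(2)); and
#' breakpoints found at finer scales take precedence, coarser-scale
#' candidates being added only when no established breakpoint lies within
#' half the wavelet support. Accepted breakpoints are finally refined to the
#' least-squares split position within their half-support window. The result
#' is a deterministic, ordered, gap-free partition of the input.
#'
#' @param z Numeric vector of region Z-values (finite, length >= 1).
#' @param max_scale Number of dyadic scales (default 5: supports up to 16+16
#'   regions per wavelet arm).
#' @param fdr_q FDR level for breakpoint acceptance (default 0.001).
#' @return data.frame(start_index, end_index, n_regions, mean_z, median_z)
#'   with 1-based closed indices partitioning `1..length(z)`.
#' @export
haarseg_segment <- function(z, max_scale = 5, fdr_q = 0.001) {
  if (!all(is.finite(z))) stop("z contains non-finite values")
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must lie in (0, 1)")
  n <- length(z)
  breakpoints <- integer(0)
  bp_scale <- integer(0)
  if (n >= 2) {
    sigma <- stats::mad(diff(z)) / sqrt(2)
    cs <- c(0, cumsum(z))
    for (s in seq_len(max_scale)) {
      h <- 2^(s - 1)
      if (2 * h > n) break
      i <- (h + 1):(n - h + 1)          # candidate segment starts
      y <- (cs[i + h] - 2 * cs[i] + cs[i - h]) / sqrt(2 * h)
      a <- abs(y)
      left <- c(-Inf, a[-length(a)])
      right <- c(a[-1], -Inf)
      peak <- which(a >= left & a > right)
      if (!length(peak)) next
      keep <- if (sigma > 0) {
        p <- 2 * stats::pnorm(-a[peak] / sigma)
        bh_keep(p, fdr_q)
      } else a[peak] > 1e-10 * max(a, 1)
      cand <- i[peak[keep]]
      for (b in cand[order(-a[peak[keep]])]) {
        if (!length(breakpoints) || min(abs(breakpoints - b)) > h) {
          breakpoints <- c(breakpoints, b)
          bp_scale <- c(bp_scale, h)
        }
      }
    }
  }
  o <- order(breakpoints)
  b <- refine_breakpoints(z, breakpoints[o], bp_scale[o])
  start <- c(1L, b)
  end <- c(b - 1L, n)
  data.frame(start_index = start, end_index = end,
             n_regions = end - start + 1L,
             mean_z = vapply(seq_along(start),
                             function(k) mean(z[start[k]:end[k]]), numeric(1)),
             median_z = vapply(seq_along(start),
                               function(k) stats::median(z[start[k]:end[k]]),
                               numeric(1)))
}

# Local refinement of breakpoint positions: a breakpoint accepted at wavelet
# half-support h is only localized to within about h regions, so each one is
# moved, within its half-support window (bounded by its neighbours), to the
# split minimizing the squared error of the two flanking segments.
refine_breakpoints <- function(z, b, h) {
  if (!length(b)) return(b)
  n <- length(z)
  bounds <- c(1L, b, n + 1L)
  for (j in seq_along(b)) {
    lo <- bounds[j]; hi <- bounds[j + 2] - 1L      # flanking segment extent
    cand <- max(lo + 1L, b[j] - h[j] + 1L):min(hi, b[j] + h[j] - 1L)
    if (length(cand) <= 1L) next
    sse <- vapply(cand, function(c) {
      l <- z[lo:(c - 1L)]; r <- z[c:hi]
      sum((l - mean(l))^2) + sum((r - mean(r))^2)
    }, numeric(1))
    best <- cand[which.min(sse)]
    b[j] <- best
    bounds[j + 1] <- best
  }
  b
}

# Benjamini-Hochberg acceptance mask at level q.
bh_keep <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= q * seq_len(m) / m
  if (!any(ok)) return(rep(FALSE, m))
  thr <- p[o][max(which(ok))]
  p <= thr
}

# Piecewise-constant reconstruction of a segmentation (used by tests and
# reported diagnostics).
haarseg_reconstruct <- function(z, segments) {
  out <- numeric(length(z))
  for (k in seq_len(nrow(segments)))
    out[segments$start_index[k]:segments$end_index[k]] <- segments$mean_z[k]
  out
}
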