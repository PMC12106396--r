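#' Lower convex-hull baseline correction
#'
#' Estimates the diffuse background of a diffractogram as the lower
#' convex hull of the (q, intensity) points inside `q_range`, linearly
#' interpolated between hull vertices, and subtracts it. The hull
#' touches the signal at its vertices (corrected intensity exactly 0
#' there), lies at or below the signal everywhere, and always includes
#' the first and last bin of the range. The range is user-adjustable so
#' that peaks are not truncated by a hull vertex landing on a peak
#' flank; re-running with a new range is cheap and recorded in the
#' profile provenance.
#'
#' @param profile a [qprofile].
#' @param q_range numeric `c(q_lo, q_hi)` in 1/Angstrom; default
#'   `c(0.5, 2.5)` spans the cellulose (1-10)/(110) and (200)
#'   reflections and the water peak.
#' @return A list of class `baseline_result` with elements `profile`
#'   (the corrected [qprofile] restricted to the range), `baseline`,
#'   `corrected`, `hull_vertices` (indices into the restricted profile)
#'   and `q_range`.
#' @export
convex_hull_baseline <- function(profile, q_range = c(0.5, 2.5)) {
  stopifnot(inherits(profile, "qprofile"), length(q_range) == 2L,
            q_range[1L] < q_range[2L])
  keep <- profile$q >= q_range[1L] & profile$q <= q_range[2L]
  if (sum(keep) < 3L) {
    stop("fewer than 3 profile bins inside q_range", call. = FALSE)
  }
  sub <- profile[keep, ]
  h <- lower_hull_indices(sub$q, sub$intensity)
  baseline <- stats::approx(sub$q[h], sub$intensity[h], xout = sub$q,
                            method = "linear")$y
  corrected <- sub$intensity - baseline
  corrected[h] <- 0            # exact at vertices
  corrected <- pmax(corrected, 0)
  out <- qprofile(sub$q, corrected, sub$n_pixels,
                  provenance = attr(profile, "provenance"))
  out <- add_provenance(out, "convex-hull baseline on q in [%g, %g]",
                        q_range[1L], q_range[2L])
  structure(list(profile = out, q = sub$q, signal = sub$intensity,
                 baseline = baseline, corrected = corrected,
                 hull_vertices = h, q_range = q_range),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("Convex-hull baseline on q in [%g, %g]: %d bins, %d hull vertices\n",
              x$q_range[1L], x$q_range[2L], length(x$q), length(x$hull_vertices)))
  invisible(x)
}

# Andrew's monotone chain, lower hull only. x strictly increasing.
# Collinear interior points are not vertices (minimal vertex set).
lower_hull_indices <- function(x, y) {
  n <- length(x)
  h <- integer(n); m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      j <- h[m]; k <- h[m - 1L]
      cr <- (x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k])
      if (cr <= 0) m <- m - 1L else break
    }
    m <- m + 1L
    h[m] <- i
  }
  h[seq_len(m)]
}

#' Locate candidate peak centers from the second derivative
#'
#' Computes the second derivative of intensity with respect to q by
#' central differences on the uniform q grid and reports the deflection
#' points: local minima of `d2I/dq2` (maximal negative curvature, the
#' signature of a peak apex) whose prominence in `-d2I/dq2` is at least
#' `min_prominence`. These positions seed the pseudo-Voigt
#' deconvolution.
#'
#' @param profile a smoothed [qprofile] with at least 5 bins on a
#'   uniform q grid (isolated single-bin gaps are tolerated).
#' @param min_prominence prominence threshold in curvature units;
#'   default 3x the median absolute second derivative.
#' @return A data frame of class `deflection_set` with columns
#'   `q` (ascending) and `curvature` (the second derivative there).
#' @export
detect_deflections <- function(profile, min_prominence = NULL) {
  stopifnot(inherits(profile, "qprofile"))
  n <- nrow(profile)
  if (n < 5L) stop("need at least 5 bins to detect deflections", call. = FALSE)
  dq <- diff(profile$q)
  dq0 <- stats::median(dq)
  if (any(dq > 2 * dq0 * (1 + 1e-6))) {
    stop("q grid is non-uniform beyond a one-bin gap tolerance", call. = FALSE)
  }
  y <- profile$intensity
  d2 <- c(NA, (y[-c(1L, 2L)] - 2 * y[-c(1L, n)] + y[-c(n - 1L, n)]) / dq0^2, NA)
  v <- -d2[2:(n - 1L)]
  if (is.null(min_prominence)) {
    min_prominence <- 3 * stats::median(abs(d2), na.rm = TRUE)
  }
  peaks <- which(diff(sign(diff(c(-Inf, v, -Inf)))) == -2L)
  peaks <- peaks[v[peaks] > 0]
  if (length(peaks)) {
    prom <- vapply(peaks, function(i) peak_prominence(v, i), numeric(1))
    peaks <- peaks[prom >= min_prominence]
  }
  idx <- peaks + 1L   # offset for the dropped first bin
  structure(data.frame(q = profile$q[idx], curvature = d2[idx]),
            class = c("deflection_set", "data.frame"))
}

# Topographic prominence of peak i in vector v: height above the higher
# of the two key saddles (minima between the peak and the nearest
# higher terrain on each side; the global min of a side if none higher).
peak_prominence <- function(v, i) {
  left <- v[seq_len(i - 1L)]
  right <- v[seq.int(i + 1L, length(v))]
  if (i == 1L) left <- numeric(0)
  if (i == length(v)) right <- numeric(0)
  key <- function(side) {   # side ordered walking outward from the peak
    if (!length(side)) return(-Inf)
    higher <- which(side > v[i])
    if (length(higher)) min(side[seq_len(min(higher))]) else min(side)
  }
  key_left <- key(rev(left))
  key_right <- key(right)
  v[i] - max(key_left, key_right, -Inf)
}
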