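#' 1D azimuthally integrated scattering profile
#'
#' A `qprofile` is a data frame with columns `q` (momentum transfer,
#' 1/Angstrom, strictly increasing, stored to 3 decimal places on disk),
#' `intensity` (mean counts per bin) and `n_pixels` (contributing pixels
#' per bin; bins with no pixels are dropped, never zero-filled). The
#' `provenance` attribute carries free-text processing metadata.
#'
#' @param q numeric, strictly increasing.
#' @param intensity numeric, same length as `q`.
#' @param n_pixels integer pixel counts per bin (default 1).
#' @param provenance free-text metadata lines.
#' @return A data frame of class `qprofile`.
#' @export
qprofile <- function(q, intensity, n_pixels = rep(1L, length(q)),
                     provenance = character()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity) || length(q) != length(n_pixels)) {
    stop("q, intensity and n_pixels must have equal length", call. = FALSE)
  }
  if (length(q) && any(diff(q) <= 0)) {
    stop("q must be strictly increasing with no duplicates", call. = FALSE)
  }
  structure(
    data.frame(q = q, intensity = intensity, n_pixels = as.integer(n_pixels)),
    provenance = as.character(provenance),
    class = c("qprofile", "data.frame"))
}

#' @export
print.qprofile <- function(x, ...) {
  cat(sprintf("q-profile: %d bins, q in [%.3f, %.3f] 1/A\n",
              nrow(x), min(x$q), max(x$q)))
  prov <- attr(x, "provenance")
  if (length(prov)) cat(paste0("  ", prov, collapse = "\n"), "\n")
  invisible(x)
}

# carry provenance through subsetting
#' @export
`[.qprofile` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("q", "intensity") %in% names(out))) {
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("qprofile", "data.frame")
  }
  out
}

add_provenance <- function(profile, ...) {
  attr(profile, "provenance") <- c(attr(profile, "provenance"),
                                   sprintf(...))
  profile
}

#' Read / write q-profiles as CSV
#'
#' The on-disk format is a plain CSV with header columns `q`, `intensity`
#' and optionally `n_pixels`; `q` is written to 3 decimal places (the
#' binning resolution), intensity at full double precision. Reading
#' validates that `q` is strictly ascending.
#'
#' @param path CSV file path.
#' @param profile a [qprofile] to write.
#' @return `read_qprofile` returns a [qprofile]; `write_qprofile`
#'   returns `path` invisibly.
#' @export
read_qprofile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE)
  if (!all(c("q", "intensity") %in% names(df))) {
    stop("profile CSV must have columns `q` and `intensity`: ", path,
         call. = FALSE)
  }
  if (nrow(df) > 1L && any(diff(df$q) <= 0)) {
    stop("profile CSV has non-ascending or duplicate q: ", path, call. = FALSE)
  }
  n_pixels <- if ("n_pixels" %in% names(df)) df$n_pixels else rep(1L, nrow(df))
  qprofile(df$q, df$intensity, n_pixels,
           provenance = sprintf("read from %s", basename(path)))
}

#' @rdname read_qprofile
#' @export
write_qprofile <- function(profile, path) {
  stopifnot(inherits(profile, "qprofile"))
  lines <- c("q,intensity,n_pixels",
             sprintf("%.3f,%.17g,%d", profile$q, profile$intensity,
                     profile$n_pixels))
  writeLines(lines, path)
  invisible(path)
}
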