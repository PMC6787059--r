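#' Binned, normalised genome coverage
#'
#' Mean per-base depth over non-overlapping bins, normalised to the total
#' coverage (the sum of bin means), so the values sum to 1.
#'
#' @param hits aligned intervals: a fragment table or any data.frame with
#'   `start`, `end` and optionally `abundance` (default 1 per row).
#' @param contig_len contig length in nt.
#' @param bin bin width (default 1000); must not exceed `contig_len`.
#' @return a list of class `"coverage_track"` with `bin_size`, `bin_start`
#'   (0-based), `values` (normalised per-bin mean depth), and NULL
#'   `smoothed`/`ci_low`/`ci_high` slots filled by [smooth_coverage()].
#' @export
binned_coverage <- function(hits, contig_len, bin = 1000L) {
  if (bin > contig_len) stop("bin width ", bin, " exceeds contig length")
  nbin <- ceiling(contig_len / bin)
  depth_sum <- numeric(nbin)
  ab <- if ("abundance" %in% names(hits)) hits$abundance else
    rep(1L, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- min(hits$end[i], contig_len)
    b1 <- s %/% bin + 1L; b2 <- (e - 1L) %/% bin + 1L
    for (b in b1:b2) {
      lo <- (b - 1L) * bin; hi <- min(b * bin, contig_len)
      depth_sum[b] <- depth_sum[b] + ab[i] * (min(e, hi) - max(s, lo))
    }
  }
  bin_len <- pmin(seq_len(nbin) * bin, contig_len) -
    (seq_len(nbin) - 1L) * bin
  means <- depth_sum / bin_len
  tot <- sum(means)
  structure(list(bin_size = bin, bin_start = (seq_len(nbin) - 1L) * bin,
                 values = if (tot > 0) means / tot else means,
                 smoothed = NULL, ci_low = NULL, ci_high = NULL),
            class = "coverage_track")
}

#' Local-regression smoothing of a coverage track
#'
#' Tricube-weighted local linear (degree 1) regression of the normalised
#' bin values against bin midpoints, with a pointwise confidence band from
#' the normal approximation on the fit's standard errors.
#'
#' @param track a [binned_coverage()] track with at least 10 bins.
#' @param span loess span as a fraction of bins (default 0.05); the span
#'   window must cover at least 3 points.
#' @param ci confidence level for the band (default 0.99).
#' @return the track with `smoothed`, `ci_low`, `ci_high` filled in.
#' @export
smooth_coverage <- function(track, span = 0.05, ci = 0.99) {
  n <- length(track$values)
  if (n < 10L) stop("need >= 10 bins to smooth, got ", n)
  if (span * n < 3) stop("span window covers fewer than 3 points")
  x <- track$bin_start + track$bin_size / 2
  fit <- stats::loess(track$values ~ x, span = span, degree = 1L,
                      family = "gaussian", surface = "direct")
  pr <- stats::predict(fit, se = TRUE)
  z <- stats::qnorm(1 - (1 - ci) / 2)
  track$smoothed <- as.numeric(pr$fit)
  track$ci_low <- as.numeric(pr$fit - z * pr$se.fit)
  track$ci_high <- as.numeric(pr$fit + z * pr$se.fit)
  track
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d bins of %d nt%s\n", length(x$values),
              x$bin_size, if (is.null(x$smoothed)) "" else ", smoothed"))
  invisible(x)
}

#' Export a coverage track as bedGraph
#'
#' @param track a [binned_coverage()] track.
#' @param contig contig name.
#' @param path output path.
#' @param what `"values"` or `"smoothed"`.
#' @export
write_bedgraph <- function(track, contig, path, what = "values") {
  v <- track[[what]]
  if (is.null(v)) stop("track has no '", what, "' values")
  df <- data.frame(contig, track$bin_start,
                   pmin(track$bin_start + track$bin_size,
                        max(track$bin_start) + track$bin_size), v)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
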