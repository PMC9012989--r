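#' Temperature frequency curve
#'
#' Histogram of a temperature field: the distribution frequency of each
#' temperature value, on a fixed bin grid. The curve is the object the
#' bimodal background filter smooths and scans for peaks.
#'
#' @param field a [temperature_field()].
#' @param bin_width histogram bin width in degC; default 0.1 degC, one order
#'   above the 0.01 degC raw precision, which stabilizes peak detection.
#' @return An object of class `temperature_curve`: list with `bin_centers`
#'   (degC, strictly increasing) and `frequencies` (counts summing to the
#'   number of pixels).
#' @export
temperature_histogram <- function(field, bin_width = 0.1) {
  stopifnot(inherits(field, "temperature_field"))
  histogram_vector(as.vector(field$values), bin_width)
}

histogram_vector <- function(v, bin_width) {
  if (!is.finite(bin_width) || bin_width <= 0)
    ta_error("bin_width must be positive", "parameter_error")
  if (!length(v)) ta_error("no pixels to histogram", "validation_error")
  lo <- floor(min(v) / bin_width) * bin_width
  idx <- floor((v - lo) / bin_width + 1e-9) + 1L
  nbins <- max(idx)
  structure(list(bin_centers = lo + (seq_len(nbins) - 0.5) * bin_width,
                 frequencies = tabulate(idx, nbins),
                 bin_width = bin_width),
            class = "temperature_curve")
}

#' @export
print.temperature_curve <- function(x, ...) {
  cat(sprintf("<temperature_curve> %d bins of %.3g degC, %d pixels\n",
              length(x$bin_centers), x$bin_width, sum(x$frequencies)))
  invisible(x)
}

# half-sample symmetric reflection of out-of-range indices into 1..n
reflect_index <- function(i, n) {
  repeat {
    below <- i < 1L; above <- i > n
    if (!any(below) && !any(above)) return(i)
    i[below] <- 1L - i[below]
    i[above] <- 2L * n + 1L - i[above]
  }
}

#' Gaussian smoothing of a temperature curve
#'
#' Convolution with a discrete Gaussian kernel (sigma = size / 5, so the
#' default size-5 operator has unit sigma), normalized to sum 1, under a
#' reflect boundary. Reflection plus a symmetric normalized kernel conserves
#' the total count mass.
#'
#' @param curve a [temperature_histogram()] result.
#' @param size odd kernel size >= 3; default 5.
#' @return A `temperature_curve` on the same bin centers.
#' @export
gaussian_smooth <- function(curve, size = 5L) {
  stopifnot(inherits(curve, "temperature_curve"))
  size <- as.integer(size)
  if (is.na(size) || size < 3L || size %% 2L == 0L)
    ta_error("kernel size must be an odd integer >= 3", "parameter_error")
  h <- size %/% 2L
  k <- stats::dnorm(seq(-h, h), sd = size / 5)
  k <- k / sum(k)
  f <- curve$frequencies
  n <- length(f)
  out <- numeric(n)
  for (j in seq(-h, h))
    out <- out + k[j + h + 1L] * f[reflect_index(seq_len(n) + j, n)]
  structure(list(bin_centers = curve$bin_centers, frequencies = out,
                 bin_width = curve$bin_width),
            class = "temperature_curve")
}

# prominence of the local maximum at bin p: height above the higher of the
# two valley floors that separate it from taller terrain; a curve end is an
# open side and contributes no floor
peak_prominence <- function(f, p) {
  n <- length(f)
  left <- if (p > 1L) {
    higher <- which(f[seq_len(p - 1L)] > f[p])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(f[lo:p])
  } else -Inf
  right <- if (p < n) {
    higher <- which(f[(p + 1L):n] > f[p])
    hi <- if (length(higher)) p + min(higher) - 1L else n
    min(f[p:hi])
  } else -Inf
  base <- max(left, right)
  if (!is.finite(base)) f[p] else f[p] - base
}

#' Locate the first two peaks of a (smoothed) temperature curve
#'
#' Scans the curve for local maxima (plateaus count once, at their center
#' bin) whose prominence is at least `min_prominence_frac` of the curve
#' maximum, and returns the two lowest-temperature qualifying peaks in
#' ascending temperature order. In a thermography scene at ~25 degC ambient
#' these are the background mode and the lowest body mode.
#'
#' @param curve a smoothed [temperature_histogram()] curve.
#' @param min_prominence_frac prominence floor as a fraction of the maximum
#'   frequency; default 0.05. Filters noise wiggles.
#' @return An object of class `peak_pair`: `t1 < t2` (degC) and their
#'   prominences.
#' @export
find_first_two_peaks <- function(curve, min_prominence_frac = 0.05) {
  stopifnot(inherits(curve, "temperature_curve"))
  f <- curve$frequencies
  r <- rle(f)
  nr <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- vapply(seq_len(nr), function(j) {
    leftv <- if (j > 1L) r$values[j - 1L] else -Inf
    rightv <- if (j < nr) r$values[j + 1L] else -Inf
    r$values[j] > leftv && r$values[j] > rightv
  }, logical(1))
  cand <- which(is_max & r$values > 0)
  pos <- (starts[cand] + ends[cand]) %/% 2L
  prom <- vapply(pos, function(p) peak_prominence(f, p), numeric(1))
  keep <- prom >= min_prominence_frac * max(f)
  pos <- pos[keep]; prom <- prom[keep]
  if (length(pos) < 2L)
    ta_error("fewer than two qualifying peaks: no separable background mode",
             "unimodal_field_error")
  ord <- order(curve$bin_centers[pos])[1:2]
  structure(list(t1 = curve$bin_centers[pos[ord[1]]],
                 t2 = curve$bin_centers[pos[ord[2]]],
                 prominence = prom[ord]),
            class = "peak_pair")
}

#' Background threshold from a peak pair
#'
#' The default `"midpoint"` mode takes the temperature halfway between the
#' two peaks. The alternative `"segment-median"` mode takes the median of
#' the pixel temperatures strictly between the two peak temperatures (and
#' needs the field); both readings of "the median between the two peaks"
#' are supported.
#'
#' @param peaks a [find_first_two_peaks()] result.
#' @param mode `"midpoint"` (default) or `"segment-median"`.
#' @param field the [temperature_field()]; required for `"segment-median"`.
#' @return Threshold temperature in degC, strictly between the two peaks.
#' @export
bimodal_threshold <- function(peaks, mode = c("midpoint", "segment-median"),
                              field = NULL) {
  stopifnot(inherits(peaks, "peak_pair"))
  mode <- match.arg(mode)
  if (mode == "midpoint") return((peaks$t1 + peaks$t2) / 2)
  if (is.null(field))
    ta_error("segment-median mode needs the temperature field", "parameter_error")
  seg <- field$values[field$values > peaks$t1 & field$values < peaks$t2]
  if (!length(seg)) return((peaks$t1 + peaks$t2) / 2)
  stats::median(seg)
}

#' Bimodal background filtering
#'
#' The full filter: histogram the field, Gaussian-smooth the curve
#' (operator size 5), locate the first two peaks, threshold at the median
#' between them, and set every pixel below the threshold to exactly 0 degC.
#' Pixels at or above the threshold are untouched, so the multiset of
#' retained temperatures is preserved and the operation is idempotent.
#'
#' Exact 0 degC is the pipeline's reserved background code and no physical
#' scene temperature, so a field that already contains zeros is treated as
#' background-classified and returned unchanged — the retained skin surface
#' is itself multimodal (regional temperature structure), and thresholding
#' it again would cut into the body. This is what makes the filter
#' idempotent. A zero-free field whose curve is unimodal raises an error:
#' the scene has no separable background.
#'
#' @inheritParams temperature_histogram
#' @inheritParams gaussian_smooth
#' @inheritParams find_first_two_peaks
#' @param threshold_mode see [bimodal_threshold()].
#' @return The filtered [temperature_field()], with attributes `threshold`
#'   (degC) and `peaks` (the [find_first_two_peaks()] result).
#' @examples
#' ph <- generate_phantom(seed = 1)
#' filt <- filter_background(ph$field)
#' attr(filt, "threshold")
#' @export
filter_background <- function(field, bin_width = 0.1, smooth_size = 5L,
                              min_prominence_frac = 0.05,
                              threshold_mode = c("midpoint", "segment-median")) {
  stopifnot(inherits(field, "temperature_field"))
  threshold_mode <- match.arg(threshold_mode)
  v <- as.vector(field$values)
  if (any(v == 0)) {             # already background-classified: no-op
    res <- temperature_field(field$values)
    nz <- v[v != 0]
    attr(res, "threshold") <- if (length(nz)) min(nz) else 0
    attr(res, "peaks") <- NULL
    return(res)
  }
  curve <- gaussian_smooth(histogram_vector(v, bin_width), smooth_size)
  peaks <- find_first_two_peaks(curve, min_prominence_frac)
  thr <- bimodal_threshold(peaks, threshold_mode, field = field)
  out <- field$values
  out[out < thr] <- 0
  res <- temperature_field(out)
  attr(res, "threshold") <- thr
  attr(res, "peaks") <- peaks
  res
}
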