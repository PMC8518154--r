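# 3'-Seq peak calling: convolve read-end coverage with the second derivative
# of a Gaussian and take negative local minima of the convolved signal as
# peak centers.  The kernel
#     g''(k) = (k^2/sigma^4 - 1/sigma^2) * exp(-k^2 / (2 sigma^2))
# is negative at the origin, so coverage peaks appear as minima.

#' Peak caller configuration
#'
#' @param sigma Gaussian bandwidth in nt.  The convolution kernel is the
#'   second derivative of a Gaussian with this bandwidth, truncated at
#'   `kernel_halfwidth`.
#' @param kernel_halfwidth truncation half-width in nt (default `4 * sigma`).
#' @param min_mean_reads minimum mean read support per library; peaks with
#'   fewer than this average are discarded (strictly fewer: a peak at exactly
#'   the threshold is kept).
#' @param n_libraries number of pooled libraries the coverage came from.
#' @return A `peak_config` list.
#' @export
peak_config <- function(sigma = 15, kernel_halfwidth = NULL,
                        min_mean_reads = 5, n_libraries = 1L) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (min_mean_reads < 0) stop("min_mean_reads must be >= 0", call. = FALSE)
  structure(list(sigma = sigma,
                 kernel_halfwidth = as.integer(kernel_halfwidth %||%
                                                 ceiling(4 * sigma)),
                 min_mean_reads = min_mean_reads,
                 n_libraries = as.integer(n_libraries)),
            class = "peak_config")
}

# The truncated second-derivative-of-Gaussian kernel, k = -hw..hw.
ricker_kernel <- function(sigma, halfwidth) {
  k <- seq.int(-halfwidth, halfwidth)
  (k^2 / sigma^4 - 1 / sigma^2) * exp(-k^2 / (2 * sigma^2))
}

#' Convolve a coverage track with the second derivative of a Gaussian
#'
#' @param track A `coverage_track` (see [compute_end_coverage()]).
#' @param config A [peak_config()].
#' @return Numeric vector the same length as `track$counts`
#'   (`out[x] = sum_k track[x - k] * g''(k)`, zero-padded at the edges).
#' @export
ricker_convolve <- function(track, config = peak_config()) {
  x <- as.numeric(track$counts)
  if (length(x) == 0L) return(numeric(0))
  hw <- config$kernel_halfwidth
  kern <- ricker_kernel(config$sigma, hw)
  padded <- c(numeric(hw), x, numeric(hw))
  # kernel is symmetric in k, so filtering equals the convolution above
  out <- stats::filter(padded, kern, method = "convolution", sides = 2)
  as.numeric(out[(hw + 1L):(hw + length(x))])
}

#' Call PAS peaks from 3'-Seq read-end coverage
#'
#' Peak centers are the local minima of the convolved signal that are
#' negative and carry nonzero raw coverage.  Each center claims the read
#' ends within `kernel_halfwidth` of it (nearest center wins ties); peaks
#' whose mean per-library support falls below `min_mean_reads` are
#' discarded.  Windows extend 100 nt transcript-upstream of the center.
#'
#' @param track A `coverage_track` of read-end counts (pooled libraries).
#' @param config A [peak_config()].
#' @return data.frame of peaks: chrom, strand, center (bp), start, end
#'   (100-nt window in the site convention), read_count (claimed ends) and
#'   mean_support (read_count / n_libraries).
#' @export
call_peaks <- function(track, config = peak_config()) {
  empty <- data.frame(chrom = character(), strand = character(),
                      center = integer(), start = integer(), end = integer(),
                      read_count = integer(), mean_support = numeric(),
                      stringsAsFactors = FALSE)
  n <- length(track$counts)
  if (n == 0L || sum(track$counts) == 0L) return(empty)
  s <- ricker_convolve(track, config)
  hw <- config$kernel_halfwidth
  cum <- cumsum(as.numeric(track$counts))
  near_cov <- function(i) {   # any read end within +/- hw of position i
    lo <- max(i - hw, 1L); hi <- min(i + hw, n)
    (cum[hi] - if (lo > 1L) cum[lo - 1L] else 0) > 0
  }
  # local minima: strictly below the nearest differing value on each side;
  # a plateau of equal minima is represented by its first index
  is_min <- vapply(seq_len(n), function(i) {
    if (s[i] >= 0) return(FALSE)
    if (!near_cov(i)) return(FALSE)
    j <- i
    while (j > 1L && s[j - 1L] == s[i]) j <- j - 1L
    k <- i
    while (k < n && s[k + 1L] == s[i]) k <- k + 1L
    left_ok <- j == 1L || s[j - 1L] > s[i]
    right_ok <- k == n || s[k + 1L] > s[i]
    left_ok && right_ok && i == j  # plateau represented by first index
  }, FALSE)
  centers <- which(is_min)
  if (length(centers) == 0L) return(empty)
  # claim read ends by nearest center within the kernel half-width
  pos <- which(track$counts > 0L)
  support <- integer(length(centers))
  for (p in pos) {
    d <- abs(centers - p)
    b <- which.min(d)
    if (d[b] <= hw) support[b] <- support[b] + track$counts[p]
  }
  keep <- support / config$n_libraries >= config$min_mean_reads
  centers <- centers[keep]; support <- support[keep]
  if (length(centers) == 0L) return(empty)
  center_pos <- track$offset + centers - 1L
  if (identical(track$strand, "-")) {
    start <- center_pos; end <- center_pos + 100L
  } else {
    start <- center_pos - 100L; end <- center_pos
  }
  data.frame(chrom = track$chrom, strand = track$strand,
             center = as.integer(center_pos),
             start = as.integer(pmax(start, 0L)), end = as.integer(end),
             read_count = as.integer(support),
             mean_support = support / config$n_libraries,
             stringsAsFactors = FALSE)
}

#' Convert called peaks to candidate PAS sites
#'
#' Attaches the fields [assign_and_filter()] and [quantify_pau()] expect so
#' 3'-Seq peaks flow through the same usage quantification as long-read
#' sites.
#'
#' @param peaks data.frame from [call_peaks()] (possibly several tracks'
#'   worth, row-bound).
#' @return data.frame in the candidate-site layout of [build_pas_windows()].
#' @export
peaks_as_sites <- function(peaks) {
  out <- data.frame(chrom = peaks$chrom, strand = peaks$strand,
                    start = peaks$start, end = peaks$end,
                    read_count = peaks$read_count,
                    cleavage_pos = peaks$center,
                    stringsAsFactors = FALSE)
  out$event_idx <- rep(list(integer(0)), nrow(out))
  out
}
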