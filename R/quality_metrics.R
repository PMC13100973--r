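#' Spatial signal-to-noise ratio
#'
#' Mean signal intensity of (already-masked) brain voxels divided by the
#' standard deviation of that signal. Scale-invariant; undefined for a
#' constant image.
#'
#' @param intensities Numeric vector of voxel intensities (length >= 2).
#' @return SNR value.
#' @export
spatial_snr <- function(intensities) {
  intensities <- intensities[!is.na(intensities)]
  if (length(intensities) < 2) stop("need at least 2 intensities", call. = FALSE)
  s <- stats::sd(intensities)
  if (s == 0) stop("undefined SNR: zero standard deviation", call. = FALSE)
  mean(intensities) / s
}

#' Segmented temporal signal-to-noise ratio
#'
#' Splits a time series into consecutive non-overlapping segments of
#' `segment_length` points (anchored at the first time point), computes each
#' complete segment's mean/SD ratio, and averages the ratios. The trailing
#' remainder shorter than a segment is discarded; zero-SD segments are
#' skipped with a warning. Sensitive to mean shifts (tSNR is not
#' shift-invariant) and to slow signal drift, which is what makes it a
#' useful data-quality covariate.
#'
#' @param series Numeric time series of length `T >= segment_length`.
#' @param segment_length Points per segment (default 20, i.e. 20 TRs).
#' @return List: `tsnr` (mean of segment ratios), `n_segments`
#'   (`floor(T / segment_length)`), `n_discarded` trailing points.
#' @export
temporal_snr <- function(series, segment_length = 20L) {
  segment_length <- check_count(segment_length, "segment_length", min = 2L)
  n <- length(series)
  if (n < segment_length) {
    stop(sprintf("series length %d is shorter than one segment (%d)", n,
                 segment_length), call. = FALSE)
  }
  k <- n %/% segment_length
  ratios <- vapply(seq_len(k), function(i) {
    seg <- series[((i - 1) * segment_length + 1):(i * segment_length)]
    s <- stats::sd(seg)
    if (s == 0) NA_real_ else mean(seg) / s
  }, 0)
  if (anyNA(ratios)) {
    warning(sprintf("%d zero-variance segment(s) skipped", sum(is.na(ratios))))
  }
  list(tsnr = mean(ratios, na.rm = TRUE), n_segments = k,
       n_discarded = n - k * segment_length)
}

#' Per-group correlation of frailty with quality metrics
#'
#' Pearson correlation (with p value) between frailty and each quality
#' metric, within each group — the sensitivity check that image quality is
#' not driving frailty-brain associations.
#'
#' @param quality Data frame of quality metrics (numeric columns).
#' @param frailty Numeric frailty index, aligned to `quality` rows.
#' @param group Group labels (optional; `NULL` = one pooled analysis).
#' @return Data frame `group`, `metric`, `r`, `p`, `n`.
#' @export
quality_frailty_association <- function(quality, frailty, group = NULL) {
  quality <- as.data.frame(quality)
  if (is.null(group)) group <- rep("all", length(frailty))
  out <- list()
  for (g in unique(as.character(group))) {
    sel <- group == g
    for (metric in names(quality)) {
      x <- quality[[metric]][sel]; y <- frailty[sel]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) stop("need at least 3 paired observations", call. = FALSE)
      ht <- stats::cor.test(x[ok], y[ok])
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = metric, r = unname(ht$estimate),
        p = ht$p.value, n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
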