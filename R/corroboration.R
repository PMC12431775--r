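#' Corroboration statistics between CUT&Tag peaks and bound motif sites
#'
#' For one TF: the number of consensus peaks, the number of bound sites (a
#' site bound in at least one group counts once), the percentage of peaks
#' overlapping at least one bound site, and the percentage of bound sites
#' overlapping at least one peak. Overlap requires >= 1 shared base.
#'
#' @param peaks Peak interval data.frame for the TF.
#' @param bound_sites Interval data.frame of the TF's bound sites (distinct
#'   sites; `name` = site_id).
#' @return data.frame: n_peaks, n_bound_sites, pct_peaks_with_site,
#'   pct_sites_in_peak.
#' @export
corroboration_stats <- function(peaks, bound_sites) {
  n_pk <- nrow(peaks)
  n_st <- nrow(bound_sites)
  if (n_pk == 0L || n_st == 0L) {
    warning("zero peaks or zero bound sites: percentages reported as 0")
    return(data.frame(n_peaks = n_pk, n_bound_sites = n_st,
                      pct_peaks_with_site = 0, pct_sites_in_peak = 0))
  }
  ov <- overlap_pairs(peaks, bound_sites, min_bp = 1L)
  data.frame(n_peaks = n_pk, n_bound_sites = n_st,
             pct_peaks_with_site = 100 * length(unique(ov$query)) / n_pk,
             pct_sites_in_peak = 100 * length(unique(ov$subject)) / n_st)
}

#' Bound-site positions along normalized peak lengths
#'
#' For every (peak, contained site) pair the site midpoint is mapped to the
#' peak's \[0, 1\] axis: `(midpoint - peak_start) / peak_width`, clipped to
#' \[0, 1\]. A site inside two overlapping peaks contributes one position per
#' containing peak. Zero-width peaks are skipped with a warning.
#'
#' @param peaks Peak interval data.frame.
#' @param bound_sites Bound-site interval data.frame.
#' @param n_bins Histogram bin count (>= 2; default 20).
#' @return List: `positions` (numeric vector), `breaks`, `counts`.
#' @export
footprint_positions_in_peaks <- function(peaks, bound_sites, n_bins = 20) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  zero_w <- peaks$end - peaks$start <= 0
  if (any(zero_w)) {
    warning(sum(zero_w), " zero-width peak(s) skipped")
    peaks <- peaks[!zero_w, , drop = FALSE]
  }
  ov <- overlap_pairs(peaks, bound_sites, min_bp = 1L)
  mid <- (bound_sites$start[ov$subject] + bound_sites$end[ov$subject]) / 2
  pos <- (mid - peaks$start[ov$query]) / (peaks$end[ov$query] - peaks$start[ov$query])
  pos <- pmin(1, pmax(0, pos))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- if (length(pos)) {
    as.integer(table(cut(pos, breaks, include.lowest = TRUE)))
  } else integer(n_bins)
  list(positions = pos, breaks = breaks, counts = counts)
}
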