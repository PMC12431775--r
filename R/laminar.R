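#' Circle through three points (ventricular-surface fit)
#'
#' The ventricular surface is marked manually with three points; the
#' circumcircle through them defines the apical reference. Collinear points
#' raise an error.
#'
#' @param p1,p2,p3 Numeric length-2 vectors (x, y) in pixels, pairwise
#'   distinct.
#' @return List with `centre` (x, y) and `radius`.
#' @export
fit_vs_circle <- function(p1, p2, p3) {
  pts <- rbind(p1, p2, p3)
  if (any(duplicated(pts))) stop("points must be pairwise distinct")
  # perpendicular-bisector linear system: 2 (p_i - p_1) . c = |p_i|^2 - |p_1|^2
  A <- 2 * rbind(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
  b <- c(sum(pts[2, ]^2) - sum(pts[1, ]^2), sum(pts[3, ]^2) - sum(pts[1, ]^2))
  if (abs(det(A)) < 1e-12 * max(1, max(abs(A)))^2) {
    stop("points are collinear: no unique circle")
  }
  centre <- solve(A, b)
  list(centre = as.numeric(centre),
       radius = sqrt(sum((pts[1, ] - centre)^2)))
}

#' Laminar profile: per-cell distance from the ventricular surface and
#' background-filtered signals
#'
#' The average cell diameter is the mean over ROIs of the equivalent-circle
#' diameter `2 * sqrt(area / pi)`. A cell's distance is its centroid's
#' Euclidean distance to the circle centre minus the radius, divided by the
#' average diameter (cells apical to the surface get negative distances and
#' are flagged). Per channel and per image, signals at or below the
#' `background_quantile` quantile are set to zero (zeroed, not dropped, so
#' cell counts match across channels).
#'
#' @param rois ROI data.frame: roi_id, x, y, area, image, replicate, and
#'   channel columns (prefix `ch`).
#' @param circle Circle from [fit_vs_circle()] (or a named list per image).
#' @param background_quantile Background threshold quantile (default 0.25).
#' @return `rois` with columns `distance` (average-diameter units),
#'   `inside_vs` flag, and filtered channel columns, ordered by distance.
#' @export
quantify_profile <- function(rois, circle, background_quantile = 0.25) {
  if (nrow(rois) < 2) stop("need at least 2 cells")
  if (any(rois$area <= 0) || all(rois$area == 0)) stop("degenerate ROI areas")
  avg_d <- mean(2 * sqrt(rois$area / pi))
  get_circle <- function(img) if (!is.null(circle$centre)) circle else circle[[img]]
  eu <- vapply(seq_len(nrow(rois)), function(i) {
    cc <- get_circle(rois$image[i])
    sqrt((rois$x[i] - cc$centre[1])^2 + (rois$y[i] - cc$centre[2])^2) - cc$radius
  }, numeric(1))
  rois$distance <- eu / avg_d
  rois$inside_vs <- rois$distance < 0
  ch_cols <- grep("^ch", names(rois), value = TRUE)
  for (img in unique(rois$image)) {
    sel <- rois$image == img
    for (ch in ch_cols) {
      thr <- stats::quantile(rois[[ch]][sel], background_quantile, names = FALSE)
      v <- rois[[ch]][sel]
      v[v <= thr] <- 0
      rois[[ch]][sel] <- v
    }
  }
  rois[order(rois$distance), , drop = FALSE]
}

#' Centred sliding mean, shrinking at the boundaries
#'
#' Window `w` covers positions `i - floor((w-1)/2)` to `i + floor(w/2)`,
#' truncated at the series boundaries. `w = 1` is the identity.
#'
#' @param x Numeric vector (signal ordered by distance).
#' @param window Positive integer window size (default 12).
#' @return Numeric vector of the same length.
#' @export
sliding_mean <- function(x, window = 12) {
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  lo <- pmax(1, seq_len(n) - floor((window - 1) / 2))
  hi <- pmin(n, seq_len(n) + floor(window / 2))
  cs <- cumsum(c(0, x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth every channel of a laminar profile
#'
#' @param profile Output of [quantify_profile()] (ordered by distance).
#' @param window Sliding-mean window (default 12).
#' @return data.frame: distance plus one smoothed column per channel.
#' @export
smooth_profile <- function(profile, window = 12) {
  ch_cols <- grep("^ch", names(profile), value = TRUE)
  out <- data.frame(distance = profile$distance)
  for (ch in ch_cols) out[[ch]] <- sliding_mean(profile[[ch]], window)
  out
}

#' Normalize channels across biological replicates
#'
#' Divides each channel within each replicate by that replicate's mean of
#' the (background-filtered) signal, making per-replicate channel means
#' exactly 1 so replicates can be aggregated.
#'
#' @param profile Output of [quantify_profile()].
#' @return `profile` with normalized channel columns.
#' @export
normalize_replicates <- function(profile) {
  ch_cols <- grep("^ch", names(profile), value = TRUE)
  for (rep_id in unique(profile$replicate)) {
    sel <- profile$replicate == rep_id
    for (ch in ch_cols) {
      m <- mean(profile[[ch]][sel])
      if (m > 0) profile[[ch]][sel] <- profile[[ch]][sel] / m
    }
  }
  profile
}
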