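#' Construct a 16-bit fluorescence scan
#'
#' @param pixels Integer-valued matrix with intensities in `[0, 65535]`.
#' @param pixel_size Physical pixel size (m), optional.
#' @param label One of `"pre"`, `"post"`, `"calibration"`.
#' @return A list of class `uw_scan`.
#' @export
uw_scan <- function(pixels, pixel_size = NA_real_,
                    label = c("pre", "post", "calibration")) {
  label <- match.arg(label)
  .check_u16(pixels)
  structure(list(pixels = pixels, pixel_size = pixel_size, label = label),
            class = "uw_scan")
}

.check_u16 <- function(px) {
  if (!is.matrix(px) || !is.numeric(px) || any(px != round(px)) ||
      any(px < 0) || any(px > 65535))
    uw_stop("scan must be an integer-valued matrix with intensities in [0, 65535]",
            "uw_format_error")
  invisible(TRUE)
}

#' Threshold a scan to remove background
#'
#' Pixels with intensity strictly below `cutoff` are set to zero; pixels at
#' or above it are unchanged. The default cutoff 3600 is the background
#' threshold used for all fluorescent quantification. Idempotent.
#'
#' @param scan A `uw_scan` (or bare matrix).
#' @param cutoff Intensity threshold. Default 3600.
#' @return The thresholded `uw_scan`.
#' @export
threshold_scan <- function(scan, cutoff = 3600) {
  if (is.matrix(scan)) scan <- uw_scan(scan)
  .check_u16(scan$pixels)
  scan$pixels[scan$pixels < cutoff] <- 0
  scan
}

#' Total intensity of a scan
#' @param scan A `uw_scan`.
#' @return Sum of pixel intensities.
#' @export
total_intensity <- function(scan) sum(as.numeric(scan$pixels))

#' Beads-per-count calibration
#'
#' From a calibration image of a known number of manually counted beads:
#' threshold, then divide the bead count by the total remaining intensity
#' to get the number of beads per fluorescent count.
#'
#' @param scan Calibration `uw_scan`.
#' @param manual_bead_count Manually counted beads (> 0).
#' @param cutoff Background threshold. Default 3600.
#' @return Beads per intensity count (numeric scalar).
#' @export
beads_per_count <- function(scan, manual_bead_count, cutoff = 3600) {
  uw_check(manual_bead_count > 0, "manual_bead_count must be > 0")
  tot <- total_intensity(threshold_scan(scan, cutoff))
  if (tot <= 0)
    uw_stop("calibration scan has no signal above threshold", "uw_calibration_error")
  manual_bead_count / tot
}

#' ROI mask set
#'
#' @param masks Named list of logical matrices, all the same shape; names
#'   map to branch ids.
#' @return A list of class `uw_roiset`.
#' @export
uw_roiset <- function(masks) {
  uw_check(is.list(masks) && length(masks) > 0 && !is.null(names(masks)) &&
             all(nzchar(names(masks))),
           "masks must be a named list", "uw_format_error")
  shp <- dim(masks[[1]])
  for (m in masks) {
    uw_check(is.matrix(m) && is.logical(m) && identical(dim(m), shp),
             "all ROI masks must be logical matrices of identical shape",
             "uw_format_error")
  }
  structure(masks, class = "uw_roiset")
}

#' Targeting efficiency from pre/post fluorescence scans
#'
#' Both scans are thresholded, then the efficiency is the intensity inside
#' the target ROI after targeting divided by the total intensity before
#' targeting. A per-branch breakdown over all ROIs is returned as well;
#' over a full partition of the signal the per-branch values sum to
#' (post total)/(pre total). Noise can push the raw value slightly above 1;
#' it is reported unclamped.
#'
#' @param pre,post `uw_scan` objects of identical shape.
#' @param rois A [uw_roiset()] whose masks match the scan shape.
#' @param target Name of the target ROI.
#' @param cutoff Background threshold applied to both scans. Default 3600.
#' @return A list of class `uw_efficiency`: `efficiency` (target fraction),
#'   `per_branch` (named vector), `pre_total`, `post_total`.
#' @export
targeting_efficiency_from_scans <- function(pre, post, rois, target,
                                            cutoff = 3600) {
  uw_check(identical(dim(pre$pixels), dim(post$pixels)),
           "pre and post scans must have the same shape", "uw_format_error")
  uw_check(target %in% names(rois), "target ROI not found", "uw_domain_error")
  uw_check(identical(dim(rois[[1]]), dim(pre$pixels)),
           "ROI masks must match the scan shape", "uw_format_error")
  pre_thr <- threshold_scan(pre, cutoff)
  post_thr <- threshold_scan(post, cutoff)
  pre_total <- total_intensity(pre_thr)
  if (pre_total <= 0)
    uw_stop("pre-scan has no signal above threshold: efficiency undefined",
            "uw_calibration_error")
  per_branch <- vapply(unclass(rois), function(m)
    sum(as.numeric(post_thr$pixels[m])) / pre_total, numeric(1))
  structure(list(efficiency = per_branch[[target]], per_branch = per_branch,
                 pre_total = pre_total,
                 post_total = total_intensity(post_thr)),
            class = "uw_efficiency")
}
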