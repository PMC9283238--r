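#' Gray-level calibration for quantitative backscatter imaging
#'
#' Backscatter gray levels are standardised against carbon and aluminium
#' reference materials: image brightness/contrast are adjusted until carbon
#' reads gray 25 +/- 1 and aluminium 225 +/- 1. Calcium content is then an
#' affine function of gray level. The default anchors place 0 wt\% Ca at the
#' carbon gray and 39.86 wt\% Ca (the calcium mass fraction of pure
#' hydroxyapatite, the conventional upper anchor) at the aluminium gray;
#' both anchors are overridable for instrument-specific calibrations.
#'
#' @param gray_carbon,gray_aluminum target gray levels of the standards.
#' @param ca_carbon,ca_aluminum calcium wt\% assigned to the two anchors.
#' @param tolerance acceptance tolerance on measured standard gray levels.
#' @return a \code{gray_calibration} object with fields \code{slope} and
#'   \code{intercept} of the gray -> wt\% Ca map.
#' @export
gray_calibration <- function(gray_carbon = 25, gray_aluminum = 225,
                             ca_carbon = 0, ca_aluminum = 39.86,
                             tolerance = 1) {
  if (gray_aluminum <= gray_carbon) {
    stop("aluminium gray level must exceed the carbon gray level",
         call. = FALSE)
  }
  stopifnot(tolerance >= 0, ca_aluminum > ca_carbon)
  slope <- (ca_aluminum - ca_carbon) / (gray_aluminum - gray_carbon)
  structure(
    list(gray_carbon = gray_carbon, gray_aluminum = gray_aluminum,
         ca_carbon = ca_carbon, ca_aluminum = ca_aluminum,
         tolerance = tolerance,
         slope = slope, intercept = ca_carbon - slope * gray_carbon),
    class = "gray_calibration"
  )
}

#' Check measured standard gray levels against the calibration targets
#'
#' An imaging session is accepted when both standards fall within the
#' tolerance of their targets (by default carbon 25 +/- 1 and aluminium
#' 225 +/- 1).
#'
#' @param measured_carbon,measured_aluminum measured gray levels in
#'   [0, 255].
#' @param cal a \code{gray_calibration}.
#' @return list with \code{accepted} (logical), per-standard deviations
#'   \code{dev_carbon} / \code{dev_aluminum}, and a human-readable
#'   \code{reason} when rejected.
#' @export
check_standards <- function(measured_carbon, measured_aluminum,
                            cal = gray_calibration()) {
  stopifnot(inherits(cal, "gray_calibration"))
  if (measured_carbon < 0 || measured_carbon > 255 ||
      measured_aluminum < 0 || measured_aluminum > 255) {
    stop("gray levels must lie in [0, 255]", call. = FALSE)
  }
  dc <- measured_carbon - cal$gray_carbon
  da <- measured_aluminum - cal$gray_aluminum
  ok_c <- abs(dc) <= cal$tolerance
  ok_a <- abs(da) <= cal$tolerance
  reason <- NULL
  if (!ok_c) reason <- c(reason, sprintf("carbon off target by %+.2f", dc))
  if (!ok_a) reason <- c(reason, sprintf("aluminium off target by %+.2f", da))
  list(accepted = ok_c && ok_a, dev_carbon = dc, dev_aluminum = da,
       reason = if (is.null(reason)) "within tolerance"
                else paste(reason, collapse = "; "))
}

#' Map gray levels to calcium weight percent
#'
#' @param g gray level(s) in [0, 255].
#' @param cal a \code{gray_calibration}.
#' @return calcium content in wt\% (affine, strictly increasing in g).
#' @export
gray_to_calcium <- function(g, cal = gray_calibration()) {
  stopifnot(inherits(cal, "gray_calibration"))
  if (any(g < 0 | g > 255)) {
    stop("gray levels must lie in [0, 255]", call. = FALSE)
  }
  cal$intercept + cal$slope * g
}

#' Construct a backscatter-electron image
#'
#' @param pixels matrix of 8-bit gray levels (integers 0-255).
#' @param roi_mask logical matrix of the same shape marking region-of-
#'   interest pixels (e.g. the newly formed bone delimited by fluorochrome
#'   labels); defaults to the whole image.
#' @param meta named metadata list (sample, group).
#' @return a \code{bse_image} object.
#' @export
bse_image <- function(pixels, roi_mask = NULL, meta = list()) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0 | pixels > 255)) {
    stop("pixels must be 8-bit gray levels in [0, 255]", call. = FALSE)
  }
  if (is.null(roi_mask)) {
    roi_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  roi_mask <- as.matrix(roi_mask)
  if (!all(dim(roi_mask) == dim(pixels))) {
    stop("roi_mask must have the same shape as pixels", call. = FALSE)
  }
  structure(list(pixels = pixels, roi_mask = roi_mask != 0, meta = meta),
            class = "bse_image")
}

#' Read a backscatter image (and optional ROI mask) from PNG or TIFF
#'
#' 8-bit grayscale images only; for multi-channel files the first channel is
#' used. Mask files mark ROI membership with any nonzero pixel.
#'
#' @param path image file (.png or .tif/.tiff).
#' @param mask_path optional same-shape mask image.
#' @param meta metadata list.
#' @return a \code{bse_image}.
#' @export
read_bse_image <- function(path, mask_path = NULL, meta = list()) {
  read_gray <- function(p) {
    ext <- tolower(tools::file_ext(p))
    a <- switch(ext,
      png = png::readPNG(p),
      tif = , tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          stop("the 'tiff' package is required to read TIFF images",
               call. = FALSE)
        }
        tiff::readTIFF(p)
      },
      stop("unsupported image format '", ext, "' (use png or tiff)",
           call. = FALSE))
    if (length(dim(a)) == 3L) a <- a[, , 1]
    round(a * 255)
  }
  px <- read_gray(path)
  mask <- if (!is.null(mask_path)) read_gray(mask_path) > 0 else NULL
  bse_image(px, mask, meta = meta)
}

#' Write a gray matrix as an 8-bit PNG
#'
#' @param pixels gray-level matrix (0-255).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bse_image <- function(pixels, path) {
  png::writePNG(as.matrix(pixels) / 255, path)
  invisible(path)
}

#' Bone mineral density distribution metrics
#'
#' Builds the calcium-content histogram of the ROI pixels (one bin per
#' 8-bit gray step, mapped through the calibration, so the native detector
#' resolution is preserved) and summarises it by:
#' \describe{
#'   \item{ca_mean}{frequency-weighted mean calcium content, wt\%}
#'   \item{ca_peak}{bin centre of the histogram mode (most frequent calcium
#'     content), wt\%}
#'   \item{ca_width}{full width at half maximum by linear interpolation
#'     between the bins crossing half of the modal frequency, wt\%}
#' }
#' A single-gray-level ROI is degenerate: the width is reported as one bin
#' width and \code{degenerate} is set.
#'
#' @param img a \code{bse_image}; the ROI must contain >= 1000 pixels.
#' @param cal a \code{gray_calibration}.
#' @return an object of class \code{bmdd_metrics}: list with the normalised
#'   \code{histogram} (data.frame of \code{ca}, \code{frequency}),
#'   \code{ca_mean}, \code{ca_peak}, \code{ca_width}, \code{n_pixels},
#'   \code{degenerate}.
#' @export
compute_bmdd <- function(img, cal = gray_calibration()) {
  stopifnot(inherits(img, "bse_image"), inherits(cal, "gray_calibration"))
  g <- img$pixels[img$roi_mask]
  if (length(g) < 1000L) {
    stop("ROI must contain at least 1000 pixels", call. = FALSE)
  }
  counts <- tabulate(as.integer(round(g)) + 1L, nbins = 256L)
  freq <- counts / sum(counts)
  ca <- gray_to_calcium(0:255, cal)
  bin_w <- cal$slope                      # wt% per gray step

  ca_mean <- sum(freq * ca)
  mode_bin <- which.max(freq)
  ca_peak <- ca[mode_bin]
  degenerate <- sum(counts > 0) == 1L

  if (degenerate) {
    ca_width <- bin_w
  } else {
    half <- freq[mode_bin] / 2
    # left crossing: last bin below half-max before the mode
    left <- {
      below <- which(freq[seq_len(mode_bin)] < half)
      if (length(below) == 0L) ca[1] else {
        i <- max(below)
        ca[i] + bin_w * (half - freq[i]) / (freq[i + 1L] - freq[i])
      }
    }
    right <- {
      above_idx <- seq(mode_bin, 256L)
      below <- which(freq[above_idx] < half)
      if (length(below) == 0L) ca[256] else {
        j <- above_idx[min(below)]       # first bin below half-max after mode
        ca[j - 1L] + bin_w * (freq[j - 1L] - half) / (freq[j - 1L] - freq[j])
      }
    }
    ca_width <- right - left
  }

  structure(
    list(histogram = data.frame(ca = ca, frequency = freq),
         ca_mean = ca_mean, ca_peak = ca_peak, ca_width = ca_width,
         n_pixels = length(g), degenerate = degenerate),
    class = "bmdd_metrics"
  )
}

#' @export
print.bmdd_metrics <- function(x, ...) {
  cat(sprintf(
    "<bmdd_metrics> CaMean %.2f | CaPeak %.2f | CaWidth %.2f wt%% (%d px%s)\n",
    x$ca_mean, x$ca_peak, x$ca_width, x$n_pixels,
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
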