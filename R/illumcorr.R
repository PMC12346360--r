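# Retrospective multi-image illumination correction and gradient-based
# background estimation. The illumination correction function (ICF) is the
# smoothed pixelwise mean of many mostly-empty micrographs; images are
# corrected by dividing by the ICF and rescaling with its spatial mean.
# Background pixels are then selected by the Silver Mountain Operator (SMO):
# the norm of a moving average of unit gradient vectors, which is small in
# spatially uncorrelated background and large along structured signal.

#' Estimate the illumination correction function from a set of images
#'
#' Computes the pixelwise mean of the images, then refines it with a
#' Gaussian blur followed by a median filter, preserving only the large
#' gradients that represent vignetting. The result is clipped at a small
#' positive floor.
#'
#' @param images list of intensity matrices with identical dimensions.
#' @param gaussian_sigma Gaussian blur sigma in pixels.
#' @param median_size median filter window (odd, pixels).
#' @param floor minimum admissible ICF value.
#' @return object of class \code{illumination_field}: list with \code{icf}
#'   (matrix) and \code{mean_value} (its spatial mean).
#' @export
estimate_icf <- function(images, gaussian_sigma = 13, median_size = 15,
                         floor = 1e-3) {
  if (!is.list(images) || length(images) < 2)
    stop("need at least 2 images to estimate the ICF")
  d <- dim(images[[1]])
  if (!all(vapply(images, function(x) identical(dim(x), d), logical(1))))
    stop("images have mismatched shapes")
  avg <- Reduce(`+`, images) / length(images)
  sm <- from_ebi(EBImage::gblur(as_ebi(avg), sigma = gaussian_sigma))
  # medianFilter operates on [0,1] data with 16-bit quantization
  mx <- max(sm)
  if (mx <= 0) stop("ICF is non-positive everywhere")
  rad <- max(1L, as.integer((median_size - 1) / 2))
  sm <- from_ebi(EBImage::medianFilter(as_ebi(sm / mx), size = rad)) * mx
  icf <- pmax(sm, floor)
  if (any(icf <= 0)) stop("non-positive ICF pixel after flooring")
  structure(list(icf = icf, mean_value = mean(icf)),
            class = "illumination_field")
}

#' Correct an image with an illumination field
#'
#' Divides by the ICF and multiplies by the ICF's spatial mean, keeping the
#' corrected image on the original intensity scale. The output is
#' real-valued; quantization happens downstream at storage boundaries.
#'
#' @param image intensity matrix.
#' @param field an \code{\link{estimate_icf}} result.
#' @param scale_by \code{"icf_mean"} (default) multiplies by the ICF's
#'   spatial mean, keeping intensities comparable across images;
#'   \code{"image_mean"} multiplies by each image's own mean instead.
#' @return corrected matrix.
#' @export
apply_icf <- function(image, field, scale_by = c("icf_mean", "image_mean")) {
  stopifnot(inherits(field, "illumination_field"))
  scale_by <- match.arg(scale_by)
  if (!identical(dim(image), dim(field$icf)))
    stop("image and ICF shapes differ")
  sc <- if (scale_by == "icf_mean") field$mean_value else mean(image)
  image / field$icf * sc
}

#' Silver Mountain Operator map
#'
#' Per pixel, the intensity gradient (central differences inside, one-sided
#' at the borders) is normalized to unit length (zero gradients contribute
#' zero vectors), the vectors are averaged over a square window, and the
#' output is the Euclidean norm of the average. Values lie in [0, 1]:
#' near 1 where gradients are locally parallel (edges, ramps), near 0 in
#' uncorrelated background.
#'
#' @param image intensity matrix.
#' @param window odd averaging window size (>= 3).
#' @param smooth_sigma optional Gaussian pre-smoothing sigma (NULL = none).
#' @return matrix in [0, 1].
#' @export
smo_map <- function(image, window = 7, smooth_sigma = NULL) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  x <- image
  if (!is.null(smooth_sigma) && smooth_sigma > 0)
    x <- from_ebi(EBImage::gblur(as_ebi(x), sigma = smooth_sigma))
  h <- nrow(x); w <- ncol(x)
  gy <- x; gx <- x
  gy[2:(h - 1), ] <- (x[3:h, ] - x[1:(h - 2), ]) / 2
  gy[1, ] <- x[2, ] - x[1, ]; gy[h, ] <- x[h, ] - x[h - 1, ]
  gx[, 2:(w - 1)] <- (x[, 3:w] - x[, 1:(w - 2)]) / 2
  gx[, 1] <- x[, 2] - x[, 1]; gx[, w] <- x[, w] - x[, w - 1]
  nrm <- sqrt(gy^2 + gx^2)
  uy <- ifelse(nrm > 0, gy / nrm, 0)
  ux <- ifelse(nrm > 0, gx / nrm, 0)
  box <- matrix(1 / window^2, window, window)
  ay <- from_ebi(EBImage::filter2(as_ebi(uy), box))
  ax <- from_ebi(EBImage::filter2(as_ebi(ux), box))
  clamp(sqrt(ay^2 + ax^2), 0, 1)
}

#' Estimate and subtract the fluorescence background
#'
#' Computes the SMO map of an illumination-corrected image, excludes
#' saturated (>= \code{sat_threshold}) and empty-slide (<=
#' \code{empty_threshold}) pixels, selects as background the non-excluded
#' pixels whose SMO value falls below the given percentile of non-excluded
#' SMO values, and subtracts the median intensity of the selected pixels
#' from the whole image.
#'
#' @param image illumination-corrected intensity matrix (0--255 scale).
#' @param window SMO averaging window.
#' @param percentile SMO percentile defining background membership.
#' @param sat_threshold,empty_threshold exclusion limits in intensity units.
#' @return list with \code{centered} (real-valued matrix, background median
#'   at zero), \code{stored} (rescaled 0--255 8-bit version) and
#'   \code{model} (class \code{background_model}: \code{smo_grid},
#'   \code{selected_pixels} logical matrix, \code{bg_median},
#'   \code{exclusion_mask}).
#' @export
subtract_background <- function(image, window = 7, percentile = 5,
                                sat_threshold = 255, empty_threshold = 5) {
  excl <- image >= sat_threshold | image <= empty_threshold
  if (all(excl)) stop("all pixels excluded (saturated or empty)")
  smo <- smo_map(image, window = window)
  thr <- quantile(smo[!excl], percentile / 100)
  sel <- !excl & smo <= thr
  if (!any(sel)) stop("background selection is empty")
  bg_median <- median(image[sel])
  centered <- image - bg_median
  model <- structure(list(smo_grid = smo, selected_pixels = sel,
                          bg_median = bg_median, exclusion_mask = excl),
                     class = "background_model")
  list(centered = centered, stored = rescale8(centered), model = model)
}
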