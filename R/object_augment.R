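# Object-level augmentation: polygonal contour approximation of object
# masks, zero-mean perturbation of the keypoints along local normals,
# soft copy-paste blending of objects into background scenes, and full
# composite synthesis with trimap ignore rings.

#' Polygonal approximation of a mask boundary
#'
#' Samples keypoints along the traced boundary at approximately equal
#' arc-length spacing. With zero perturbation the polygon rasterizes back
#' to essentially the original mask.
#'
#' @param mask logical matrix, one 8-connected component.
#' @param gap target arc-length spacing between keypoints, pixels.
#' @return n x 2 matrix of (row, col) keypoints (closed implicitly).
#' @export
approximate_polygon <- function(mask, gap = 5) {
  if (!any(mask)) stop("mask is empty")
  lab <- label_components8(matrix(as.integer(mask), nrow(mask)))
  if (max(lab) != 1) stop("mask must be a single connected component")
  bd <- trace_boundary(mask)
  seg <- sqrt(rowSums((bd - bd[c(2:nrow(bd), 1), ])^2))
  arc <- c(0, cumsum(head(seg, -1)))
  total <- arc[length(arc)] + seg[length(seg)]
  n_kp <- max(4L, round(total / gap))
  targets <- seq(0, total, length.out = n_kp + 1)[seq_len(n_kp)]
  idx <- vapply(targets, function(t) which.min(abs(arc - t)), integer(1))
  kp <- bd[unique(idx), , drop = FALSE]
  # boundary pixel centers sit half a pixel inside the digital outline;
  # push keypoints outward by 0.5 px along the local normal so the
  # rasterized polygon conserves the mask area in the zero-noise limit
  n <- nrow(kp)
  if (n >= 4) {
    prev <- kp[c(n, seq_len(n - 1)), , drop = FALSE]
    nxt <- kp[c(2:n, 1), , drop = FALSE]
    chord <- nxt - prev
    len <- sqrt(rowSums(chord^2)); len[len == 0] <- 1
    nrm <- cbind(-chord[, 2], chord[, 1]) / len
    probe <- round(kp + nrm)
    probe[, 1] <- clamp(probe[, 1], 1, nrow(mask))
    probe[, 2] <- clamp(probe[, 2], 1, ncol(mask))
    inward <- mask[probe]          # normal points into the mask: flip
    nrm[inward, ] <- -nrm[inward, , drop = FALSE]
    kp <- kp + 0.5 * nrm
  }
  kp
}

polygon_is_simple <- function(kp) {
  n <- nrow(kp)
  nx <- kp[c(2:n, 1), , drop = FALSE]
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1 & !(i == 1 & j == n)), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  p1 <- kp[i, , drop = FALSE]; p2 <- nx[i, , drop = FALSE]
  p3 <- kp[j, , drop = FALSE]; p4 <- nx[j, , drop = FALSE]
  d1 <- (p4[, 2] - p3[, 2]) * (p1[, 1] - p3[, 1]) -
    (p4[, 1] - p3[, 1]) * (p1[, 2] - p3[, 2])
  d2 <- (p4[, 2] - p3[, 2]) * (p2[, 1] - p3[, 1]) -
    (p4[, 1] - p3[, 1]) * (p2[, 2] - p3[, 2])
  d3 <- (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]) -
    (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2])
  d4 <- (p2[, 2] - p1[, 2]) * (p4[, 1] - p1[, 1]) -
    (p2[, 1] - p1[, 1]) * (p4[, 2] - p1[, 2])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Perturb contour keypoints along local normals
#'
#' Each keypoint is displaced by a zero-mean Gaussian amount along the unit
#' normal of the chord joining its two neighbors, with standard deviation
#' \code{noise_scale * gap}. Displacements are therefore perpendicular to
#' the local tangent, which preserves coherent outlines. If the perturbed
#' polygon self-intersects, it is redrawn (bounded retries).
#'
#' @param keypoints n x 2 matrix from \code{\link{approximate_polygon}}.
#' @param gap the keypoint spacing used for the approximation.
#' @param noise_scale displacement magnitude as a multiple of \code{gap}.
#' @param max_tries retries on self-intersection.
#' @return perturbed keypoint matrix (attribute \code{displacement} holds
#'   the signed normal offsets).
#' @export
perturb_contour <- function(keypoints, gap = 5, noise_scale = 0.4,
                            max_tries = 25L) {
  n <- nrow(keypoints)
  if (n < 4) stop("need at least 4 keypoints")
  if (noise_scale == 0) {
    out <- keypoints
    attr(out, "displacement") <- numeric(n)
    return(out)
  }
  prev <- keypoints[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- keypoints[c(2:n, 1), , drop = FALSE]
  chord <- nxt - prev
  len <- sqrt(rowSums(chord^2))
  len[len == 0] <- 1
  normal <- cbind(-chord[, 2], chord[, 1]) / len
  sigma <- noise_scale * gap
  for (t in seq_len(max_tries)) {
    eps <- rnorm(n, 0, sigma)
    out <- keypoints + normal * eps
    if (polygon_is_simple(out)) {
      attr(out, "displacement") <- eps
      attr(out, "normal") <- normal
      return(out)
    }
  }
  stop("perturbed contour self-intersects after ", max_tries, " retries")
}

#' Rasterize a closed polygon to a mask
#'
#' @param keypoints n x 2 (row, col) vertices.
#' @param height,width output size.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(keypoints, height, width) {
  polygon_fill(keypoints, as.integer(height), as.integer(width)) > 0
}

#' Soft copy-paste of one object into a scene
#'
#' The perturbed mask is eroded and dilated \code{iterations} times with a
#' 3x3 cross. Core pixels (eroded mask) are pasted verbatim from the object
#' crop; the ring between erosion and dilation is blended as
#' \code{w * object + (1 - w) * scene} with \code{w} decreasing with signed
#' distance outward from the mask boundary; outside the dilated mask the
#' scene is untouched. The ring is marked as ignore (trimap); the soft
#' weights are never used as training targets.
#'
#' @param scene background matrix (0--255).
#' @param object_crop object crop matrix (0--255).
#' @param mask logical mask in crop coordinates (e.g. rasterized perturbed
#'   contour).
#' @param position (row, col) of the crop's top-left corner in the scene.
#' @param iterations erosion/dilation iterations.
#' @return list \code{image}, \code{fg_mask} (supervised foreground: mask
#'   minus the ignore ring), \code{ignore_mask}, \code{full_mask} (the
#'   pasted perturbed mask), \code{core_mask}, all scene-sized.
#' @export
soft_cp_paste <- function(scene, object_crop, mask, position,
                          iterations = 5) {
  ch <- nrow(object_crop); cw <- ncol(object_crop)
  if (ch > nrow(scene) || cw > ncol(scene))
    stop("object crop larger than the scene")
  r0 <- position[1]; c0 <- position[2]
  if (r0 < 1 || c0 < 1 || r0 + ch - 1 > nrow(scene) ||
      c0 + cw - 1 > ncol(scene))
    stop("object does not fit in the scene at this position")
  cross <- EBImage::makeBrush(3, "diamond")
  m_ebi <- as_ebi(mask * 1)
  er <- m_ebi; di <- m_ebi
  for (i in seq_len(iterations)) {
    er <- EBImage::erode(er, cross)
    di <- EBImage::dilate(di, cross)
  }
  core <- from_ebi(er) > 0
  dil <- from_ebi(di) > 0
  ring <- dil & !core
  # signed distance from the mask boundary: positive inside the mask
  d_in <- from_ebi(EBImage::distmap(as_ebi(mask * 1)))
  d_out <- from_ebi(EBImage::distmap(as_ebi((!mask) * 1)))
  sd <- d_in - d_out
  wgt <- clamp((sd + iterations) / (2 * iterations), 0, 1)
  rows <- r0:(r0 + ch - 1); cols <- c0:(c0 + cw - 1)
  sub <- scene[rows, cols]
  blended <- wgt * object_crop + (1 - wgt) * sub
  blended[core] <- object_crop[core]
  out <- scene
  patch <- sub
  patch[dil] <- blended[dil]     # outside dilated mask: scene verbatim
  patch[core] <- object_crop[core]
  out[rows, cols] <- patch
  place <- function(m) {
    full <- matrix(FALSE, nrow(scene), ncol(scene))
    full[rows, cols] <- m
    full
  }
  full_mask <- place(mask)
  ring_full <- place(ring)
  list(image = out, fg_mask = full_mask & !ring_full,
       ignore_mask = ring_full, full_mask = full_mask,
       core_mask = place(core))
}

#' Compose a synthetic training scene from the banks
#'
#' Draws a background scene, crops it to the composite size, inserts
#' \code{n_objects} (default drawn uniformly from 0--5) objects after
#' optional right-angle rotation/flip and contour perturbation, using soft
#' copy-paste. Placements avoid core overlap; when a placement cannot be
#' found after bounded retries, fewer objects are placed and recorded.
#'
#' @param banks bank list (\code{objects}, \code{backgrounds}).
#' @param size composite side, pixels (the segmenter input tile).
#' @param n_objects number of objects, or NULL to draw from 0..5.
#' @param gap,noise_scale contour perturbation parameters.
#' @param iterations soft-CP erosion/dilation iterations.
#' @param max_tries placement retries per object.
#' @return object of class \code{composite_sample}: \code{image},
#'   \code{fg_mask}, \code{ignore_mask}, \code{placements}.
#' @export
compose_scene <- function(banks, size = 108, n_objects = NULL, gap = 5,
                          noise_scale = 0.4, iterations = 5,
                          max_tries = 20L) {
  if (length(banks$backgrounds) == 0) stop("background bank is empty")
  if (is.null(n_objects)) n_objects <- sample(0:5, 1)
  if (n_objects > 0 && length(banks$objects) == 0)
    stop("object bank is empty but objects were requested")
  bg <- banks$backgrounds[[sample.int(length(banks$backgrounds), 1)]]
  bh <- nrow(bg$image); bw <- ncol(bg$image)
  if (bh < size || bw < size)
    stop("background scene smaller than the composite size")
  r0 <- sample.int(bh - size + 1, 1); c0 <- sample.int(bw - size + 1, 1)
  img <- bg$image[r0:(r0 + size - 1), c0:(c0 + size - 1)]
  fg <- matrix(FALSE, size, size)
  ignore <- matrix(FALSE, size, size)
  cores <- matrix(FALSE, size, size)
  placements <- list()
  for (k in seq_len(n_objects)) {
    oi <- sample.int(length(banks$objects), 1)
    ob <- banks$objects[[oi]]
    crop <- ob$crop; mask <- ob$mask
    rot <- sample(0:3, 1)
    if (rot > 0) for (i in seq_len(rot)) {
      crop <- t(crop[nrow(crop):1, , drop = FALSE])
      mask <- t(mask[nrow(mask):1, , drop = FALSE])
    }
    if (runif(1) < 0.5) {
      crop <- crop[nrow(crop):1, , drop = FALSE]
      mask <- mask[nrow(mask):1, , drop = FALSE]
    }
    if (nrow(crop) > size - 2 || ncol(crop) > size - 2) next
    kp <- tryCatch(approximate_polygon(mask, gap), error = function(e) NULL)
    pm <- mask
    if (!is.null(kp) && nrow(kp) >= 4) {
      kp2 <- tryCatch(perturb_contour(kp, gap, noise_scale),
                      error = function(e) kp)
      pm2 <- rasterize_polygon(kp2, nrow(mask), ncol(mask))
      if (sum(pm2) >= 0.25 * sum(mask)) pm <- pm2
    }
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      pr <- sample.int(size - nrow(crop) + 1, 1)
      pc <- sample.int(size - ncol(crop) + 1, 1)
      cand <- matrix(FALSE, size, size)
      cand[pr:(pr + nrow(crop) - 1), pc:(pc + ncol(crop) - 1)] <- pm
      if (any(cand & cores)) next
      pasted <- soft_cp_paste(img, crop, pm, c(pr, pc),
                              iterations = iterations)
      img <- pasted$image
      fg <- (fg & !pasted$ignore_mask) | pasted$fg_mask
      ignore <- (ignore | pasted$ignore_mask) & !pasted$fg_mask
      cores <- cores | pasted$full_mask
      placements[[length(placements) + 1]] <-
        list(object = oi, position = c(pr, pc), rot = rot)
      placed <- TRUE
      break
    }
  }
  structure(list(image = img, fg_mask = fg, ignore_mask = ignore,
                 placements = placements),
            class = "composite_sample")
}
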