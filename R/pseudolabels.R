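# Conversion of CAMs into training material: high-confidence CAM regions
# become an object bank (cut-out deposits with local context), and a second,
# looser threshold defines a buffer that is removed and inpainted to build
# plaque-free background scenes.

#' Extract object instances from a CAM
#'
#' Each 8-connected component of \code{upsampled > t_fg} (above a minimum
#' area) becomes one instance, cropped with a context margin clipped at the
#' patch borders.
#'
#' @param cam an \code{\link{extract_cam}} result (or list with
#'   \code{upsampled}).
#' @param image intensity matrix (0--255) aligned with the CAM.
#' @param t_fg foreground CAM threshold.
#' @param context_margin context padding around the component, pixels.
#' @param min_area smallest component kept, pixels.
#' @param source optional provenance list (subject, patch id).
#' @return list of instances: \code{crop} (matrix, 0--255, 8-bit levels),
#'   \code{mask} (logical, crop coordinates), \code{contour}
#'   (n x 2 matrix of boundary points), \code{bbox}, \code{source}.
#' @export
extract_objects <- function(cam, image, t_fg = 0.5, context_margin = 16,
                            min_area = 20, source = NULL) {
  up <- cam$upsampled
  if (!identical(dim(up), dim(image)))
    stop("CAM and image shapes differ")
  lab <- label_components8(matrix(as.integer(up > t_fg), nrow(up)))
  n <- max(lab)
  out <- list()
  for (k in seq_len(n)) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    r0 <- max(1, min(px[, 1]) - context_margin)
    r1 <- min(nrow(image), max(px[, 1]) + context_margin)
    c0 <- max(1, min(px[, 2]) - context_margin)
    c1 <- min(ncol(image), max(px[, 2]) + context_margin)
    mask <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
    mask[cbind(px[, 1] - r0 + 1, px[, 2] - c0 + 1)] <- TRUE
    contour <- trace_boundary(mask)
    out[[length(out) + 1]] <-
      list(crop = quantize8(image[r0:r1, c0:c1]), mask = mask,
           contour = contour, bbox = c(r0, c0, r1, c1),
           source = c(source, list(component = k)))
  }
  out
}

#' Margin contrast of an object instance
#'
#' Relative intensity drop from the object's interior to a thin ring just
#' outside its mask: near 1 when the surroundings are dark, near 0 (or
#' negative) when the bright structure continues beyond the mask.
#' Parenchymal deposits have a diffuse halo, so their CAM-derived masks
#' show a clear positive margin contrast; vascular segments continue as
#' bright tubes beyond the mask and score low. Used to screen harvested
#' pseudo-objects, mirroring the morphology-based exclusion of vascular
#' amyloid that is standard in ThioS quantification.
#'
#' @param object an instance from \code{\link{extract_objects}}.
#' @param ring_radius ring width outside the mask, pixels.
#' @return scalar (NA when the ring is empty).
#' @export
margin_contrast <- function(object, ring_radius = 3) {
  dil <- from_ebi(EBImage::dilate(as_ebi(object$mask * 1),
                                  EBImage::makeBrush(2 * ring_radius + 1,
                                                     "disc"))) > 0
  ring <- dil & !object$mask
  if (sum(ring) < 5) return(NA_real_)
  inside <- mean(object$crop[object$mask])
  (inside - mean(object$crop[ring])) / max(inside, 1)
}

# ordered boundary of the largest contour of a single-component mask,
# (row, col) coordinates
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(as_ebi(mask * 1))
  if (length(oc) == 0) stop("empty mask has no boundary")
  best <- which.max(vapply(oc, nrow, numeric(1)))
  xy <- oc[[best]]            # EBImage returns (x, y) 0-based
  cbind(row = xy[, 2] + 1, col = xy[, 1] + 1)
}

#' Build a plaque-free background scene from a CAM
#'
#' Dilates \code{upsampled > t_bg} by a disc, removes those pixels and fills
#' the holes by offset-based inpainting: for each hole, candidate shifts are
#' scored by how well the shifted image matches the known pixels around the
#' hole, and the best-matching offset copies surrounding texture into it
#' (with an outward ring-fill fallback for holes no single offset can
#' cover). Pixels outside the removal mask are bit-identical to the input.
#'
#' @param image intensity matrix (0--255, 8-bit levels).
#' @param cam activation map aligned with \code{image}; may be NULL for an
#'   originally-negative scene (empty removal mask).
#' @param t_bg background CAM threshold.
#' @param dilation_radius disc radius for the buffer zone, pixels.
#' @param n_offsets candidate offsets per hole.
#' @param source provenance list.
#' @return object of class \code{background_scene}: \code{image},
#'   \code{removal_mask}, \code{origin}, \code{source}.
#' @export
make_background <- function(image, cam = NULL, t_bg = 0.2,
                            dilation_radius = 6, n_offsets = 40,
                            source = NULL) {
  if (is.null(cam)) {
    return(structure(list(image = quantize8(image),
                          removal_mask = matrix(FALSE, nrow(image), ncol(image)),
                          origin = "originally-negative", source = source),
                     class = "background_scene"))
  }
  up <- cam$upsampled
  if (!identical(dim(up), dim(image))) stop("CAM and image shapes differ")
  removal <- up > t_bg
  if (any(removal)) {
    brush <- EBImage::makeBrush(2 * dilation_radius + 1, "disc")
    removal <- from_ebi(EBImage::dilate(as_ebi(removal * 1), brush)) > 0
  }
  if (all(removal)) stop("removal mask covers the whole image; nothing to inpaint from")
  out <- inpaint_offsets(quantize8(image), removal, n_offsets = n_offsets)
  structure(list(image = out, removal_mask = removal, origin = "inpainted",
                 source = source),
            class = "background_scene")
}

# offset-based texture fill of holes (shift-map family): per connected hole,
# try shifts that map the hole into known territory and keep the best match
# on the surrounding ring; fall back to iterative ring fill.
inpaint_offsets <- function(image, holes, n_offsets = 40) {
  if (!any(holes)) return(image)
  h <- nrow(image); w <- ncol(image)
  known <- !holes
  out <- image
  lab <- label_components8(matrix(as.integer(holes), h))
  ring_brush <- EBImage::makeBrush(7, "disc")
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    px <- which(comp, arr.ind = TRUE)
    ring <- from_ebi(EBImage::dilate(as_ebi(comp * 1), ring_brush)) > 0 &
      known
    rpx <- which(ring, arr.ind = TRUE)
    span <- max(diff(range(px[, 1])), diff(range(px[, 2]))) + 1
    best <- NULL; best_score <- Inf
    for (t in seq_len(n_offsets)) {
      dy <- sample(c(-1, 1), 1) * sample.int(max(2 * span, 10), 1)
      dx <- sample(c(-1, 1), 1) * sample.int(max(2 * span, 10), 1)
      src <- cbind(px[, 1] + dy, px[, 2] + dx)
      ok <- src[, 1] >= 1 & src[, 1] <= h & src[, 2] >= 1 & src[, 2] <= w
      if (!all(ok)) next
      if (!all(known[src])) next
      rsrc <- cbind(rpx[, 1] + dy, rpx[, 2] + dx)
      rok <- rsrc[, 1] >= 1 & rsrc[, 1] <= h & rsrc[, 2] >= 1 &
        rsrc[, 2] <= w
      if (sum(rok) < 4) next
      rs <- rsrc[rok, , drop = FALSE]
      use <- known[rs]
      if (sum(use) < 4) next
      score <- mean((image[rpx[rok, , drop = FALSE]][use] -
                       image[rs][use])^2)
      if (score < best_score) { best_score <- score; best <- c(dy, dx) }
    }
    if (!is.null(best)) {
      src <- cbind(px[, 1] + best[1], px[, 2] + best[2])
      out[px] <- image[src]
    } else {
      out <- ring_fill(out, comp)
    }
  }
  out
}

# iterative onion-peel fill: repeatedly assign hole-border pixels the mean
# of their known neighbors
ring_fill <- function(image, comp) {
  known <- !comp
  val <- image
  val[comp] <- 0
  kern <- matrix(1, 3, 3)
  while (any(!known)) {
    cnt <- from_ebi(EBImage::filter2(as_ebi(known * 1), kern,
                                     boundary = 0))
    sm <- from_ebi(EBImage::filter2(as_ebi(val * known), kern,
                                    boundary = 0))
    border <- !known & cnt > 0
    if (!any(border)) break
    val[border] <- sm[border] / cnt[border]
    known[border] <- TRUE
  }
  val[comp] <- round(val[comp])
  image[comp] <- val[comp]
  image
}

#' Save or load object/background banks
#'
#' Banks are directories: \code{objects/<id>/} holds \code{crop.tif}
#' (8-bit), \code{mask.png} (0/255) and \code{meta.json} (contour and
#' provenance); \code{backgrounds/<id>/} holds \code{image.tif},
#' \code{removal.png} and \code{meta.json}. Round trips are bit-exact.
#'
#' @param bank list with elements \code{objects} and \code{backgrounds}.
#' @param dir bank directory.
#' @return \code{load_bank} returns the bank list.
#' @export
save_bank <- function(bank, dir) {
  ids <- function(entries) vapply(entries, function(e)
    if (!is.null(e$id)) e$id else NA_character_, character(1))
  obj_ids <- names(bank$objects)
  if (is.null(obj_ids)) obj_ids <- sprintf("obj%05d", seq_along(bank$objects))
  if (anyDuplicated(obj_ids)) stop("duplicate object ids in bank")
  bg_ids <- names(bank$backgrounds)
  if (is.null(bg_ids)) bg_ids <- sprintf("bg%05d", seq_along(bank$backgrounds))
  if (anyDuplicated(bg_ids)) stop("duplicate background ids in bank")
  for (i in seq_along(bank$objects)) {
    d <- file.path(dir, "objects", obj_ids[i])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    ob <- bank$objects[[i]]
    write_gray(ob$crop, file.path(d, "crop.tif"))
    write_gray(ob$mask * 255, file.path(d, "mask.png"))
    jsonlite::write_json(list(contour = unclass(ob$contour),
                              bbox = ob$bbox, source = ob$source),
                         file.path(d, "meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  for (i in seq_along(bank$backgrounds)) {
    d <- file.path(dir, "backgrounds", bg_ids[i])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    bg <- bank$backgrounds[[i]]
    write_gray(bg$image, file.path(d, "image.tif"))
    write_gray(bg$removal_mask * 255, file.path(d, "removal.png"))
    jsonlite::write_json(list(origin = bg$origin, source = bg$source),
                         file.path(d, "meta.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname save_bank
#' @export
load_bank <- function(dir) {
  read_meta <- function(p) {
    meta <- tryCatch(jsonlite::read_json(p, simplifyVector = TRUE),
                     error = function(e)
                       stop("corrupted bank metadata at ", p))
    meta
  }
  obj_dirs <- sort(list.dirs(file.path(dir, "objects"), recursive = FALSE))
  objects <- setNames(lapply(obj_dirs, function(d) {
    meta <- read_meta(file.path(d, "meta.json"))
    contour <- matrix(unlist(meta$contour), ncol = 2,
                      dimnames = list(NULL, c("row", "col")))
    list(crop = read_gray(file.path(d, "crop.tif")),
         mask = read_gray(file.path(d, "mask.png")) > 0,
         contour = contour, bbox = meta$bbox, source = meta$source)
  }), basename(obj_dirs))
  bg_dirs <- sort(list.dirs(file.path(dir, "backgrounds"), recursive = FALSE))
  backgrounds <- setNames(lapply(bg_dirs, function(d) {
    meta <- read_meta(file.path(d, "meta.json"))
    structure(list(image = read_gray(file.path(d, "image.tif")),
                   removal_mask = read_gray(file.path(d, "removal.png")) > 0,
                   origin = meta$origin, source = meta$source),
              class = "background_scene")
  }), basename(bg_dirs))
  list(objects = objects, backgrounds = backgrounds)
}

#' Build object and background banks from patches and their CAMs
#'
#' Positive patches contribute objects (and inpainted backgrounds); negative
#' patches enter the background bank unchanged.
#'
#' @param patches labeled patch list (from \code{\link{derive_patches}}).
#' @param cams list of activation maps parallel to \code{patches} (only
#'   needed for positive patches).
#' @param labels 0/1 labels parallel to \code{patches}.
#' @param subjects subject ids parallel to \code{patches}.
#' @param t_fg,t_bg CAM thresholds.
#' @param dilation_radius buffer dilation radius, pixels.
#' @param context_margin object crop margin, pixels.
#' @param min_area minimum object component area, pixels.
#' @param min_margin_contrast drop harvested objects whose
#'   \code{\link{margin_contrast}} falls below this value (bright structure
#'   continuing beyond the mask indicates a vascular segment, not a
#'   deposit); NULL disables the screen.
#' @return bank list (\code{objects}, \code{backgrounds}).
#' @export
build_banks <- function(patches, cams, labels, subjects, t_fg = 0.5,
                        t_bg = 0.2, dilation_radius = 6, context_margin = 16,
                        min_area = 20, min_margin_contrast = 0.3) {
  objects <- list(); backgrounds <- list()
  for (i in seq_along(patches)) {
    img <- patches[[i]]$image
    src <- list(subject = subjects[i], patch = i)
    if (labels[i] == 1) {
      obs <- extract_objects(cams[[i]], img, t_fg = t_fg,
                             context_margin = context_margin,
                             min_area = min_area, source = src)
      if (!is.null(min_margin_contrast)) {
        mc <- vapply(obs, margin_contrast, numeric(1))
        obs <- obs[!is.na(mc) & mc >= min_margin_contrast]
      }
      objects <- c(objects, obs)
      # patches whose CAM buffer swallows (nearly) the whole patch cannot
      # yield a usable background scene and are skipped
      bg <- tryCatch(make_background(img, cams[[i]], t_bg = t_bg,
                                     dilation_radius = dilation_radius,
                                     source = src),
                     error = function(e) NULL)
      if (!is.null(bg) && mean(bg$removal_mask) < 0.6)
        backgrounds <- c(backgrounds, list(bg))
    } else {
      backgrounds <- c(backgrounds, list(make_background(img, NULL,
                                                         source = src)))
    }
  }
  list(objects = objects, backgrounds = backgrounds)
}
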