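# Synthetic ThioS-like micrograph generator. Scenes contain bright compact
# plaque cores with radially decaying halos (ground-truth positive), bright
# curvilinear vessels (ground-truth negative), a multiplicative vignette,
# additive background fluorescence and Gaussian noise. All sampling is
# seeded, so identical specs reproduce identical scenes bit for bit.

#' Specify a synthetic micrograph scene
#'
#' Intensities are on the 8-bit 0--255 scale. Plaques are rendered as an
#' elliptical core of constant intensity plus a halo decaying as
#' \eqn{A_h \exp(-d^2 / 2\sigma^2)} beyond the core edge, with
#' \eqn{\sigma = \mathrm{halo\_scale} \times r}. The ground-truth plaque
#' boundary is the set of pixels whose plaque contribution exceeds a fixed
#' fraction (\code{gt_fraction}, default 10\%) of the core intensity, which
#' gives a rule-defined mask suitable for Dice scoring. Vessels are smooth
#' random tubes of constant width, rendered as bright as plaques but always
#' ground-truth negative.
#'
#' @param height,width scene size in pixels.
#' @param n_plaques number of plaques to place without overlap.
#' @param core_radius_range plaque core radius range (pixels); radii are
#'   sampled log-uniformly within it.
#' @param halo_scale halo width as a multiple of the core radius.
#' @param core_intensity_range,halo_intensity_range,background_level,noise_sd
#'   intensities in 8-bit units.
#' @param elongation_range core axis ratio range (>= 1).
#' @param n_vessels number of vessels.
#' @param vessel_width_range vessel width range (pixels).
#' @param vignette_strength fractional intensity falloff at the corners,
#'   in [0, 1).
#' @param microns_per_pixel physical scale.
#' @param gt_fraction fraction of core intensity defining the ground-truth
#'   plaque boundary.
#' @param seed integer seed.
#' @return object of class \code{scene_spec}.
#' @export
scene_spec <- function(height = 512, width = 512, n_plaques = 8,
                       core_radius_range = c(8, 16), halo_scale = 0.4,
                       core_intensity_range = c(150, 230),
                       halo_intensity_range = c(90, 150),
                       background_level = 40, noise_sd = 4,
                       elongation_range = c(1, 1.4),
                       n_vessels = 2, vessel_width_range = c(5, 9),
                       vignette_strength = 0.25, microns_per_pixel = 0.9,
                       gt_fraction = 0.1, seed = 1L) {
  spec <- list(height = height, width = width, n_plaques = n_plaques,
               core_radius_range = core_radius_range, halo_scale = halo_scale,
               core_intensity_range = core_intensity_range,
               halo_intensity_range = halo_intensity_range,
               background_level = background_level, noise_sd = noise_sd,
               elongation_range = elongation_range,
               n_vessels = n_vessels, vessel_width_range = vessel_width_range,
               vignette_strength = vignette_strength,
               microns_per_pixel = microns_per_pixel,
               gt_fraction = gt_fraction, seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  rng_ok <- function(r, lo = 0, hi = 255)
    length(r) == 2 && r[1] <= r[2] && r[1] >= lo && r[2] <= hi
  if (spec$height < 32 || spec$width < 32) stop("scene too small")
  if (spec$n_plaques < 0) stop("n_plaques must be >= 0")
  if (!rng_ok(spec$core_radius_range, 1, Inf)) stop("bad core_radius_range")
  if (!rng_ok(spec$core_intensity_range)) stop("bad core_intensity_range")
  if (!rng_ok(spec$halo_intensity_range)) stop("bad halo_intensity_range")
  if (spec$background_level < 0 || spec$background_level > 255)
    stop("background_level outside [0,255]")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$vignette_strength < 0 || spec$vignette_strength >= 1)
    stop("vignette_strength must lie in [0,1)")
  if (spec$elongation_range[1] < 1) stop("elongation must be >= 1")
  invisible(spec)
}

vignette_field <- function(h, w, strength) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
  1 - strength * d2 / max(d2)
}

# profile of one plaque on a local window; returns list(field, gt)
render_plaque <- function(h, w, cy, cx, r, elong, theta, core_int, halo_int,
                          halo_scale, gt_fraction) {
  sigma <- halo_scale * r
  ext <- ceiling(r * elong + sigma * sqrt(2 * max(0, log(max(
    halo_int / (gt_fraction * core_int), 1.5)))) + 2)
  rows <- max(1, floor(cy - ext)):min(h, ceiling(cy + ext))
  cols <- max(1, floor(cx - ext)):min(w, ceiling(cx + ext))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  de <- sqrt((u / elong)^2 + v^2)   # elliptical radius; core edge at de = r
  fld <- ifelse(de <= r, core_int,
                halo_int * exp(-(de - r)^2 / (2 * sigma^2)))
  gt <- fld >= gt_fraction * core_int
  list(rows = rows, cols = cols, field = fld, gt = gt)
}

# a smooth random tube; returns list(field, mask)
render_vessel <- function(h, w, width) {
  # random smooth path from one border to another via spline through a few
  # jittered control points
  nk <- 5
  side <- sample(1:4, 1)
  p0 <- switch(side, c(1, runif(1, 1, w)), c(h, runif(1, 1, w)),
               c(runif(1, 1, h), 1), c(runif(1, 1, h), w))
  p1 <- c(runif(1, 1, h), runif(1, 1, w))
  # opposite-ish endpoint
  p1 <- switch(side, c(h, runif(1, 1, w)), c(1, runif(1, 1, w)),
               c(runif(1, 1, h), w), c(runif(1, 1, h), 1))
  t0 <- seq(0, 1, length.out = nk)
  ry <- p0[1] + (p1[1] - p0[1]) * t0 + c(0, rnorm(nk - 2, 0, h / 10), 0)
  rx <- p0[2] + (p1[2] - p0[2]) * t0 + c(0, rnorm(nk - 2, 0, w / 10), 0)
  tt <- seq(0, 1, length.out = max(h, w) * 4)
  py <- spline(t0, ry, xout = tt)$y
  px <- spline(t0, rx, xout = tt)$y
  keep <- py >= 1 & py <= h & px >= 1 & px <= w
  raster <- matrix(0, h, w)
  raster[cbind(round(py[keep]), round(px[keep]))] <- 1
  if (sum(raster) == 0) return(NULL)
  dmap <- from_ebi(EBImage::distmap(as_ebi(1 - raster)))
  half <- width / 2
  mask <- dmap <= half
  fall <- exp(-pmax(dmap - half, 0)^2 / (2 * 1.5^2))
  list(field = fall, mask = mask)
}

#' Generate one synthetic micrograph with ground truth
#'
#' Plaques are placed so their ground-truth footprints do not overlap each
#' other or any vessel; placement retries are bounded and failure raises an
#' error naming the constraint. The composed intensity is
#' (background + plaques + vessels) x vignette + noise, clipped to [0, 255]
#' and quantized to 8-bit levels.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param max_tries placement retries per plaque.
#' @return list with elements \code{image} (matrix, 0--255),
#'   \code{gt} (list \code{parenchymal_mask}, \code{instance_labels},
#'   \code{vessel_mask}) and \code{spec}.
#' @export
generate_scene <- function(spec, max_tries = 60L) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    field <- matrix(0, h, w)
    vessel_mask <- matrix(FALSE, h, w)
    if (spec$n_vessels > 0) {
      for (i in seq_len(spec$n_vessels)) {
        vw <- runif(1, spec$vessel_width_range[1], spec$vessel_width_range[2])
        vint <- runif(1, spec$core_intensity_range[1],
                      spec$core_intensity_range[2])
        ves <- render_vessel(h, w, vw)
        if (is.null(ves)) next
        field <- pmax(field, vint * ves$field)
        vessel_mask <- vessel_mask | ves$mask
      }
    }
    parmask <- matrix(FALSE, h, w)
    inst <- matrix(0L, h, w)
    # forbid placement near vessels and prior plaques
    occupied <- vessel_mask
    if (spec$n_plaques > 0) {
      for (k in seq_len(spec$n_plaques)) {
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          lr <- log(spec$core_radius_range)
          r <- exp(runif(1, lr[1], lr[2]))
          elong <- runif(1, spec$elongation_range[1], spec$elongation_range[2])
          theta <- runif(1, 0, pi)
          core_int <- runif(1, spec$core_intensity_range[1],
                            spec$core_intensity_range[2])
          halo_int <- runif(1, spec$halo_intensity_range[1],
                            spec$halo_intensity_range[2])
          margin <- r * elong * 2 + 2
          if (2 * margin >= min(h, w)) next
          cy <- runif(1, margin, h - margin)
          cx <- runif(1, margin, w - margin)
          pl <- render_plaque(h, w, cy, cx, r, elong, theta, core_int,
                              halo_int, spec$halo_scale, spec$gt_fraction)
          sub_occ <- occupied[pl$rows, pl$cols]
          if (any(sub_occ & pl$gt)) next
          field[pl$rows, pl$cols] <- pmax(field[pl$rows, pl$cols], pl$field)
          parmask[pl$rows, pl$cols] <- parmask[pl$rows, pl$cols] | pl$gt
          sub_inst <- inst[pl$rows, pl$cols]
          sub_inst[pl$gt] <- k
          inst[pl$rows, pl$cols] <- sub_inst
          # keep a small buffer between ground-truth footprints
          occ <- matrix(FALSE, h, w)
          occ[pl$rows, pl$cols] <- pl$gt
          occ <- from_ebi(EBImage::dilate(as_ebi(occ * 1),
                                          EBImage::makeBrush(5, "disc"))) > 0
          occupied <- occupied | occ
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place plaque ", k, " of ", spec$n_plaques,
               " without overlap after ", max_tries, " tries")
      }
    }
    img <- spec$background_level + field
    img <- img * vignette_field(h, w, spec$vignette_strength)
    if (spec$noise_sd > 0) img <- img + rnorm(h * w, 0, spec$noise_sd)
    img <- quantize8(img)
    # vessels never count as parenchymal ground truth
    parmask[vessel_mask] <- FALSE
    inst[vessel_mask] <- 0L
    list(image = img,
         gt = list(parenchymal_mask = parmask,
                   instance_labels = inst,
                   vessel_mask = vessel_mask),
         spec = spec)
  })
}

#' Specify a synthetic cohort of subjects
#'
#' @param subjects data.frame with columns \code{subject_id}, \code{region}
#'   (\code{"parietal"} or \code{"temporal"}) and \code{dementia}
#'   (\code{"yes"}/\code{"no"}).
#' @param scenes_per_subject scenes generated per subject.
#' @param group_effects list with named numeric vectors \code{size_log10}
#'   and \code{elongation}; names are \code{"region.dementia"} keys (e.g.
#'   \code{"parietal.yes"}). \code{size_log10} shifts the mean of the
#'   log10 core radius, \code{elongation} adds to the core axis ratio.
#' @param base a \code{\link{scene_spec}} used as template.
#' @param subject_intensity_sd per-subject multiplicative brightness
#'   variation (sd of a unit-mean factor).
#' @param seed integer seed.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(subjects, scenes_per_subject = 4,
                        group_effects = list(size_log10 = numeric(),
                                             elongation = numeric()),
                        base = scene_spec(), subject_intensity_sd = 0.04,
                        seed = 1L) {
  if (nrow(subjects) == 0) stop("subject list is empty")
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids")
  if (!all(subjects$region %in% c("parietal", "temporal")))
    stop("region must be parietal or temporal")
  if (!all(subjects$dementia %in% c("yes", "no")))
    stop("dementia must be yes or no")
  structure(list(subjects = subjects,
                 scenes_per_subject = scenes_per_subject,
                 group_effects = group_effects, base = base,
                 subject_intensity_sd = subject_intensity_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

group_key <- function(region, dementia) paste(region, dementia, sep = ".")

effect_of <- function(effects, key) {
  if (is.null(effects) || length(effects) == 0) return(0)
  if (key %in% names(effects)) effects[[key]] else 0
}

#' Generate a cohort of synthetic scenes with subject structure
#'
#' Group effects act on the sampled plaque parameters of each subject's
#' scenes: the \code{size_log10} effect multiplies the core radius range by
#' \code{10^shift} (an exact shift of the mean log10 radius), and the
#' \code{elongation} effect adds to the axis-ratio range. A per-subject
#' brightness factor emulates staining variability.
#'
#' @param cohort a \code{\link{cohort_spec}}.
#' @return list of entries \code{list(image, gt, meta)}; \code{meta} carries
#'   \code{subject_id}, \code{region}, \code{dementia}, \code{scene},
#'   \code{microns_per_pixel}.
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  out <- list()
  idx <- 0L
  for (s in seq_len(nrow(cohort$subjects))) {
    sub <- cohort$subjects[s, ]
    key <- group_key(sub$region, sub$dementia)
    size_shift <- effect_of(cohort$group_effects$size_log10, key)
    elong_shift <- effect_of(cohort$group_effects$elongation, key)
    bright <- with_seed(cohort$seed * 1000L + s,
                        max(0.7, rnorm(1, 1, cohort$subject_intensity_sd)))
    for (sc in seq_len(cohort$scenes_per_subject)) {
      spec <- cohort$base
      spec$core_radius_range <- spec$core_radius_range * 10^size_shift
      spec$elongation_range <- spec$elongation_range + elong_shift
      spec$core_intensity_range <-
        clamp(spec$core_intensity_range * bright, 0, 255)
      spec$halo_intensity_range <-
        clamp(spec$halo_intensity_range * bright, 0, 255)
      spec$seed <- as.integer((cohort$seed * 7919L + s * 101L + sc) %% .Machine$integer.max)
      idx <- idx + 1L
      sc_out <- generate_scene(spec)
      out[[idx]] <- list(image = sc_out$image, gt = sc_out$gt,
                         meta = list(subject_id = sub$subject_id,
                                     region = sub$region,
                                     dementia = sub$dementia,
                                     scene = sc,
                                     microns_per_pixel = spec$microns_per_pixel))
    }
  }
  out
}

#' Derive labeled patches from a scene
#'
#' Cuts \code{patch_size} square patches on a grid (non-overlapping when the
#' image size allows; the last row/column is shifted inward so patches can
#' overlap rather than fall off the edge) plus optionally \code{n_random}
#' random positions. A patch is labeled 1 iff the parenchymal ground-truth
#' area inside it reaches \code{min_positive_area}; vessels alone never make
#' a patch positive.
#'
#' @param image intensity matrix (0--255).
#' @param gt ground-truth list from \code{\link{generate_scene}}.
#' @param patch_size patch side in pixels.
#' @param min_positive_area minimum parenchymal pixel count for label 1.
#' @param n_random extra random patch positions.
#' @param meta optional metadata list copied to each patch.
#' @return list of patches \code{list(image, label, row, col, meta)}.
#' @export
derive_patches <- function(image, gt, patch_size = 128, min_positive_area = 50,
                           n_random = 0, meta = NULL) {
  h <- nrow(image); w <- ncol(image)
  if (patch_size > h || patch_size > w)
    stop("patch_size exceeds image dimensions")
  starts <- function(n) {
    s <- seq(1, n - patch_size + 1, by = patch_size)
    if (tail(s, 1) != n - patch_size + 1) s <- c(s, n - patch_size + 1)
    s
  }
  pos <- expand.grid(row = starts(h), col = starts(w))
  if (n_random > 0) {
    pos <- rbind(pos, data.frame(
      row = sample.int(h - patch_size + 1, n_random, replace = TRUE),
      col = sample.int(w - patch_size + 1, n_random, replace = TRUE)))
  }
  lapply(seq_len(nrow(pos)), function(i) {
    r <- pos$row[i]; c <- pos$col[i]
    rows <- r:(r + patch_size - 1); cols <- c:(c + patch_size - 1)
    area <- sum(gt$parenchymal_mask[rows, cols])
    list(image = image[rows, cols],
         label = as.integer(area >= min_positive_area),
         row = r, col = c, meta = meta)
  })
}
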