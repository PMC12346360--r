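# Per-deposit morphometry: dual-percentile subregions, chain-code and
# convex-hull geometry, box-counting fractal dimension and lacunarity, and
# intensity descriptors -- 19 parameters per deposit in four groups
# (size, structural complexity, global geometry, intensity).

#' Delineate compact and diffuse subregions of a deposit
#'
#' Thresholds are the 80th and 50th percentiles (linear interpolation,
#' inclusive) of the intensities inside the predicted mask: pixels at or
#' above the 80th percentile form the compact core, pixels at or above the
#' 50th percentile form the deposit proper, so
#' compact \code{⊆} deposit \code{⊆} predicted mask.
#'
#' @param image intensity matrix.
#' @param predicted_mask logical matrix (non-empty).
#' @param pct_compact,pct_deposit percentile thresholds.
#' @return list \code{deposit_mask}, \code{compact_mask},
#'   \code{thr_deposit}, \code{thr_compact}.
#' @export
binarize_subregions <- function(image, predicted_mask, pct_compact = 80,
                                pct_deposit = 50) {
  if (!any(predicted_mask)) stop("predicted mask is empty")
  if (pct_compact <= pct_deposit)
    stop("pct_compact must exceed pct_deposit")
  vals <- image[predicted_mask]
  thr_c <- quantile(vals, pct_compact / 100, names = FALSE)
  thr_d <- quantile(vals, pct_deposit / 100, names = FALSE)
  list(deposit_mask = predicted_mask & image >= thr_d,
       compact_mask = predicted_mask & image >= thr_c,
       thr_deposit = thr_d, thr_compact = thr_c)
}

# chain-code perimeter with corner-corrected weights (0.948 per straight
# step, 1.340 per diagonal step), which removes the systematic
# overestimation of smooth outlines by raw sqrt(2)-weighted chains
chain_perimeter <- function(mask) {
  if (sum(mask) == 1) return(4)
  bd <- trace_boundary(mask)
  if (nrow(bd) < 2) return(4)
  seg <- sqrt(rowSums((bd - bd[c(2:nrow(bd), 1), , drop = FALSE])^2))
  sum(ifelse(seg > 1.2, 1.340, 0.948))
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

polygon_perimeter <- function(v) {
  n <- nrow(v)
  sum(sqrt(rowSums((v - v[c(2:n, 1), , drop = FALSE])^2)))
}

polygon_centroid <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(v))
  c(sum((v[, 1] + v[j, 1]) * cr), sum((v[, 2] + v[j, 2]) * cr)) / (6 * a)
}

# second central moments of the polygon interior (continuous), returned as
# a 2x2 covariance-like matrix
polygon_moments <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  ctr <- polygon_centroid(v)
  x <- v[, 1] - ctr[1]; y <- v[, 2] - ctr[2]
  xj <- x[j]; yj <- y[j]
  cr <- x * yj - xj * y
  a <- sum(cr) / 2
  ixx <- sum(cr * (x^2 + x * xj + xj^2)) / 12
  iyy <- sum(cr * (y^2 + y * yj + yj^2)) / 12
  ixy <- sum(cr * (x * yj + 2 * x * y + 2 * xj * yj + xj * y)) / 24
  s <- sign(a)
  matrix(c(ixx, ixy, ixy, iyy) * s / abs(a), 2, 2)
}

# Welzl's minimum enclosing circle on a point set
min_enclosing_circle <- function(pts) {
  circ2 <- function(p, q) {
    c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
  }
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(cc, p) sqrt(sum((p - cc[1:2])^2)) <= cc[3] + 1e-9
  n <- nrow(pts)
  if (n == 1) return(c(pts[1, ], 0))
  ord <- sample.int(n)
  cc <- circ2(pts[ord[1], ], pts[ord[2], ])
  for (i in seq_len(n)) {
    pi_ <- pts[ord[i], ]
    if (inside(cc, pi_)) next
    cc <- c(pi_, 0)
    for (j in seq_len(i - 1)) {
      pj <- pts[ord[j], ]
      if (inside(cc, pj)) next
      cc <- circ2(pi_, pj)
      for (k in seq_len(j - 1)) {
        pk <- pts[ord[k], ]
        if (inside(cc, pk)) next
        c3 <- circ3(pi_, pj, pk)
        if (!is.null(c3)) cc <- c3
      }
    }
  }
  cc
}

#' Size and convex-hull measurements of a deposit mask
#'
#' Area is the pixel count scaled by the squared pixel pitch; the perimeter
#' is the corner-corrected chain length of the 8-connected boundary. Hull
#' metrics (area, perimeter, smallest enclosing circle, maximum span, mean
#' centroid-to-vertex radius) are computed on the convex hull of the pixel
#' centers. A single-pixel mask falls back to degenerate values
#' (hull area = pixel area, span = pixel pitch).
#'
#' @param deposit_mask logical matrix.
#' @param microns_per_pixel pixel pitch.
#' @return list of measurements (micron units) plus \code{hull} (vertex
#'   matrix, pixel units) for reuse.
#' @export
measure_size_and_hull <- function(deposit_mask, microns_per_pixel = 1) {
  if (!any(deposit_mask)) stop("mask is empty")
  mpp <- microns_per_pixel
  area_px <- sum(deposit_mask)
  per_px <- chain_perimeter(deposit_mask)
  px <- which(deposit_mask, arr.ind = TRUE)
  if (area_px < 3 || nrow(unique(px)) < 3) {
    return(list(deposit_area = area_px * mpp^2, perimeter = per_px * mpp,
                hull_area = area_px * mpp^2, hull_perimeter = per_px * mpp,
                bounding_circle_diameter = mpp, max_span = mpp,
                mean_radius = mpp / 2, hull = px, degenerate = TRUE))
  }
  hidx <- grDevices::chull(px[, 2], px[, 1])
  hull <- px[hidx, , drop = FALSE]
  if (nrow(hull) < 3) {
    span <- max(dist(px)) * mpp
    return(list(deposit_area = area_px * mpp^2, perimeter = per_px * mpp,
                hull_area = area_px * mpp^2, hull_perimeter = per_px * mpp,
                bounding_circle_diameter = span, max_span = span,
                mean_radius = span / 2, hull = hull, degenerate = TRUE))
  }
  # pixels are unit squares: measure the hull of the pixel *extents* by
  # Minkowski-dilating the center hull by half a pixel; this keeps
  # solidity of convex digitized shapes at 1 instead of slightly above
  ha_raw <- polygon_area(hull)
  hp_raw <- polygon_perimeter(hull)
  ha <- ha_raw + 0.5 * hp_raw + pi / 4
  hp <- hp_raw + pi
  mec <- min_enclosing_circle(hull[, c(1, 2), drop = FALSE])
  span <- max(dist(hull)) + 1
  ctr <- polygon_centroid(hull)
  radii <- sqrt((hull[, 1] - ctr[1])^2 + (hull[, 2] - ctr[2])^2) + 0.5
  list(deposit_area = area_px * mpp^2, perimeter = per_px * mpp,
       hull_area = ha * mpp^2, hull_perimeter = hp * mpp,
       bounding_circle_diameter = (2 * mec[3] + 1) * mpp,
       max_span = span * mpp,
       mean_radius = mean(radii) * mpp, hull = hull,
       hull_centroid = ctr, hull_radii = radii * mpp, degenerate = FALSE)
}

#' Shape and global geometry descriptors
#'
#' Circularity \eqn{4\pi A / P^2}, roughness (perimeter / hull perimeter),
#' solidity (area / hull area), hull circularity
#' \eqn{4\pi A_h / P_h^2}, span ratio (major/minor principal axis of the
#' hull) and max/min centroid-to-vertex radius ratio.
#'
#' @param size result of \code{\link{measure_size_and_hull}}.
#' @return named list of the six dimensionless descriptors (NA on
#'   degenerate hulls).
#' @export
measure_shape <- function(size) {
  if (isTRUE(size$degenerate) || size$perimeter <= 0 ||
      size$hull_perimeter <= 0 || size$hull_area <= 0) {
    return(list(roughness = NA_real_, circularity = NA_real_,
                solidity = NA_real_, span_ratio = NA_real_,
                max_min_radius = NA_real_, hull_circularity = NA_real_))
  }
  mom <- polygon_moments(size$hull)
  evec <- eigen(mom, symmetric = TRUE)$vectors
  # principal-axis extents of the hull vertices, plus the unit pixel width
  proj1 <- size$hull %*% evec[, 1]
  proj2 <- size$hull %*% evec[, 2]
  ext <- sort(c(diff(range(proj1)), diff(range(proj2))) + 1,
              decreasing = TRUE)
  span_ratio <- if (ext[2] > 0) ext[1] / ext[2] else NA_real_
  radii <- size$hull_radii
  list(roughness = size$perimeter / size$hull_perimeter,
       circularity = 4 * pi * size$deposit_area / size$perimeter^2,
       solidity = size$deposit_area / size$hull_area,
       span_ratio = span_ratio,
       max_min_radius = if (min(radii) > 0) max(radii) / min(radii)
       else NA_real_,
       hull_circularity = 4 * pi * size$hull_area / size$hull_perimeter^2)
}

#' Box-counting fractal dimension and lacunarity
#'
#' The mask (cropped to its bounding box) is scanned with grids of box
#' sizes in a power series (powers of 2 from \code{min_box} up to
#' \code{max_frac} of the larger bounding-box side). Grid placement is
#' cyclic: each placement shifts the grid by a random offset with
#' wrap-around at the bounding box, so every foreground pixel falls in
#' exactly one box at every size and compact shapes are not biased by
#' partial edge boxes. The fractal dimension is the negative slope of the
#' log-log regression of occupied-box counts on box size; lacunarity is the
#' squared coefficient of variation of per-box foreground masses (occupied
#' boxes only), averaged over sizes. Both are averaged over
#' \code{n_grid} placements.
#'
#' @param mask logical matrix.
#' @param n_grid number of randomized grid placements.
#' @param min_box smallest box size.
#' @param max_frac largest box size as a fraction of the bounding box.
#' @param seed RNG seed for the placements.
#' @return list \code{fractal_dimension}, \code{lacunarity},
#'   \code{box_sizes}.
#' @export
box_count <- function(mask, n_grid = 12, min_box = 2, max_frac = 0.45,
                      seed = 1L) {
  if (!any(mask)) stop("mask is empty")
  px <- which(mask, arr.ind = TRUE)
  px[, 1] <- px[, 1] - min(px[, 1])
  px[, 2] <- px[, 2] - min(px[, 2])
  L1 <- max(px[, 1]) + 1L
  L2 <- max(px[, 2]) + 1L
  smax <- floor(max_frac * max(L1, L2))
  sizes <- min_box * 2^(0:30)
  sizes <- sizes[sizes <= smax]
  if (length(sizes) < 2)
    stop("fewer than 2 usable box sizes; mask too small")
  with_seed(seed, {
    fds <- numeric(n_grid)
    lacs <- numeric(n_grid)
    for (g in seq_len(n_grid)) {
      ns <- numeric(length(sizes))
      lc <- numeric(length(sizes))
      for (si in seq_along(sizes)) {
        s <- sizes[si]
        o1 <- sample.int(s, 1) - 1L
        o2 <- sample.int(s, 1) - 1L
        b1 <- ((px[, 1] + o1) %% L1) %/% s
        b2 <- ((px[, 2] + o2) %% L2) %/% s
        k2 <- max(b2) + 1L
        masses <- tabulate(b1 * k2 + b2 + 1L,
                           nbins = (max(b1) + 1L) * k2)
        masses <- masses[masses > 0]
        ns[si] <- length(masses)
        mu <- mean(masses)
        lc[si] <- if (mu > 0) mean((masses - mu)^2) / mu^2 else 0
      }
      fds[g] <- -unname(coef(stats::lm(log(ns) ~ log(sizes)))[2])
      lacs[g] <- mean(lc)
    }
    list(fractal_dimension = mean(fds), lacunarity = mean(lacs),
         box_sizes = sizes)
  })
}

#' Intensity descriptors
#'
#' @param image intensity matrix.
#' @param deposit_mask logical matrix.
#' @return list \code{mean_gray} and \code{integrated_density}
#'   (deposit pixel count x mean gray, i.e. the in-mask intensity sum).
#' @export
measure_intensity <- function(image, deposit_mask) {
  if (!any(deposit_mask)) stop("mask is empty")
  mg <- mean(image[deposit_mask])
  list(mean_gray = mg, integrated_density = sum(deposit_mask) * mg)
}

#' Measure all 19 morphometric parameters for each deposit instance
#'
#' For each labeled instance the deposit/compact subregions are delineated
#' from the in-mask intensity percentiles, and the size, complexity,
#' geometry and intensity parameters are measured on the deposit mask.
#' Size parameters and integrated density are log10-transformed; when a
#' parameter column contains zeros, 1 is added uniformly to that column
#' before the log.
#'
#' @param image intensity matrix (0--255).
#' @param instances integer instance label matrix (e.g. from
#'   \code{\link{postprocess}}).
#' @param microns_per_pixel pixel pitch.
#' @param labels list with \code{subject}, \code{region}, \code{dementia}.
#' @param n_grid box-counting grid placements.
#' @param seed seed for box-counting grids.
#' @return data.frame, one row per deposit: raw columns, log10 columns
#'   (\code{log_} prefix) and group labels.
#' @export
assemble_records <- function(image, instances, microns_per_pixel = 1,
                             labels = list(subject = NA, region = NA,
                                           dementia = NA),
                             n_grid = 12, seed = 1L) {
  ids <- sort(unique(instances[instances > 0]))
  rows <- lapply(ids, function(k) {
    pred <- instances == k
    sub <- binarize_subregions(image, pred)
    dm <- sub$deposit_mask
    if (!any(dm)) dm <- pred
    sz <- measure_size_and_hull(dm, microns_per_pixel)
    sh <- measure_shape(sz)
    fdl <- tryCatch(box_count(dm, n_grid = n_grid, seed = seed + k),
                    error = function(e)
                      list(fractal_dimension = NA_real_,
                           lacunarity = NA_real_))
    it <- measure_intensity(image, dm)
    compact_area <- sum(sub$compact_mask) * microns_per_pixel^2
    deposit_area <- sz$deposit_area
    data.frame(instance = k,
               deposit_area = deposit_area,
               compact_area = compact_area,
               perimeter = sz$perimeter,
               hull_area = sz$hull_area,
               hull_perimeter = sz$hull_perimeter,
               bounding_circle_diameter = sz$bounding_circle_diameter,
               max_span = sz$max_span,
               mean_radius = sz$mean_radius,
               fractal_dimension = fdl$fractal_dimension,
               lacunarity = fdl$lacunarity,
               roughness = sh$roughness,
               circularity = sh$circularity,
               solidity = sh$solidity,
               span_ratio = sh$span_ratio,
               max_min_radius = sh$max_min_radius,
               hull_circularity = sh$hull_circularity,
               mean_gray = it$mean_gray,
               integrated_density = it$integrated_density,
               diffuseness = (deposit_area - compact_area) /
                 deposit_area,
               raw_predicted_area = sum(pred) * microns_per_pixel^2,
               subject = labels$subject, region = labels$region,
               dementia = labels$dementia,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  if (is.null(rec)) return(rec)
  log_cols <- c("deposit_area", "compact_area", "perimeter", "hull_area",
                "hull_perimeter", "bounding_circle_diameter", "max_span",
                "mean_radius", "integrated_density")
  for (cl in log_cols) {
    v <- rec[[cl]]
    off <- if (any(v == 0, na.rm = TRUE)) 1 else 0
    rec[[paste0("log_", cl)]] <- log10(v + off)
  }
  rec
}

#' The 19 analysis columns of a record table
#'
#' Size parameters and integrated density enter on the log10 scale; the
#' complexity, geometry and remaining intensity parameters enter raw.
#' @return character vector of column names.
#' @export
morpho_parameters <- function() {
  c("log_deposit_area", "log_compact_area", "log_perimeter",
    "log_hull_area", "log_hull_perimeter", "log_bounding_circle_diameter",
    "log_max_span", "log_mean_radius",
    "fractal_dimension", "lacunarity", "roughness", "circularity",
    "solidity", "span_ratio", "max_min_radius", "hull_circularity",
    "mean_gray", "log_integrated_density", "diffuseness")
}
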