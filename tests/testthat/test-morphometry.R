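test_that("subregion thresholds follow a sort-and-threshold oracle", {
  # constant deposit: both masks equal the predicted mask
  img <- matrix(100, 20, 20)
  pred <- matrix(FALSE, 20, 20); pred[5:15, 5:15] <- TRUE
  sub <- binarize_subregions(img, pred)
  expect_identical(sub$deposit_mask, pred)
  expect_identical(sub$compact_mask, pred)

  # two-level deposit: 100 px at 200, 100 px at 50
  img2 <- matrix(0, 20, 20)
  pred2 <- matrix(FALSE, 20, 20)
  pred2[1:10, 1:20] <- TRUE
  img2[1:5, 1:20] <- 200
  img2[6:10, 1:20] <- 50
  sub2 <- binarize_subregions(img2, pred2)
  vals <- sort(img2[pred2])
  thr80 <- quantile(vals, 0.8, names = FALSE)
  thr50 <- quantile(vals, 0.5, names = FALSE)
  expect_identical(sub2$compact_mask, pred2 & img2 >= thr80)
  expect_identical(sub2$deposit_mask, pred2 & img2 >= thr50)
  expect_true(all(sub2$compact_mask[sub2$compact_mask] %in% TRUE))
  # nesting
  expect_true(all(sub2$deposit_mask[sub2$compact_mask]))
  expect_true(all(pred2[sub2$deposit_mask]))
  # diffuseness bounded
  diff_idx <- (sum(sub2$deposit_mask) - sum(sub2$compact_mask)) /
    sum(sub2$deposit_mask)
  expect_gte(diff_idx, 0); expect_lte(diff_idx, 1)
  expect_error(binarize_subregions(img2, matrix(FALSE, 20, 20)), "empty")
})

test_that("size and hull metrics match geometry oracles on primitives", {
  # axis-aligned filled square, 100 x 100 at 1 um/px
  sq <- matrix(FALSE, 110, 110); sq[6:105, 6:105] <- TRUE
  sz <- measure_size_and_hull(sq, 1)
  expect_equal(sz$deposit_area, 1e4)
  expect_lt(abs(sz$hull_area - 1e4) / 1e4, 0.01)
  expect_lt(abs(sz$max_span - 100 * sqrt(2)) / (100 * sqrt(2)), 0.01)

  # disc radius 50
  dm <- disc_mask(50)
  szd <- measure_size_and_hull(dm, 1)
  expect_lt(abs(szd$bounding_circle_diameter - 100) / 100, 0.02)
  shd <- measure_shape(szd)
  expect_gte(shd$solidity, 0.98)
  expect_gt(shd$circularity, 0.95); expect_lt(shd$circularity, 1.05)
  expect_gt(shd$roughness, 0.98); expect_lt(shd$roughness, 1.05)
  expect_gt(shd$hull_circularity, 0.95); expect_lt(shd$hull_circularity, 1.05)
  expect_lte(shd$span_ratio, 1.05)
  expect_gte(shd$span_ratio, 1)

  # max span equals the brute-force O(n^2) oracle over boundary pixels
  # (plus the unit pixel extent shared by both endpoints)
  set.seed(3)
  for (i in 1:5) {
    m <- disc_mask(sample(10:20, 1))
    m[1:3, ] <- FALSE                    # truncate: still convex-ish
    sz2 <- measure_size_and_hull(m, 1)
    bd <- which(m, arr.ind = TRUE)
    expect_equal(sz2$max_span, max(dist(bd)) + 1, tolerance = 1e-9)
  }

  # 100 x 10 rectangle span ratio
  rect <- matrix(FALSE, 120, 30); rect[11:110, 11:20] <- TRUE
  shr <- measure_shape(measure_size_and_hull(rect, 1))
  expect_lt(abs(shr$span_ratio - 10) / 10, 0.10)

  # single-pixel degeneracy
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  szs <- measure_size_and_hull(single, 2)
  expect_equal(szs$deposit_area, 4)      # 1 px at 2 um/px
  expect_equal(szs$max_span, 2)
  expect_true(is.na(measure_shape(szs)$circularity))
})

test_that("scale covariance and rotation robustness hold", {
  m <- disc_mask(18)
  a <- measure_size_and_hull(m, 1)
  b <- measure_size_and_hull(m, 2)
  expect_equal(b$deposit_area, 4 * a$deposit_area)
  expect_equal(b$perimeter, 2 * a$perimeter)
  expect_equal(b$max_span, 2 * a$max_span)
  sa <- measure_shape(a); sb <- measure_shape(b)
  expect_equal(unlist(sa), unlist(sb), tolerance = 1e-9)

  rect <- matrix(FALSE, 60, 60); rect[21:40, 11:50] <- TRUE
  r90 <- t(rect)
  s1 <- measure_shape(measure_size_and_hull(rect, 1))
  s2 <- measure_shape(measure_size_and_hull(r90, 1))
  expect_equal(unlist(s1), unlist(s2), tolerance = 1e-9)
})

test_that("box counting recovers known dimensions", {
  sq <- matrix(TRUE, 256, 256)
  bc <- box_count(sq, seed = 4)
  expect_lt(abs(bc$fractal_dimension - 2), 0.05)

  ln <- matrix(FALSE, 3, 256); ln[2, ] <- TRUE
  bl <- box_count(ln, seed = 4)
  expect_lt(abs(bl$fractal_dimension - 1), 0.05)

  carpet <- sierpinski_carpet(6)      # 729 x 729
  bs <- box_count(carpet, seed = 4)
  expect_lt(abs(bs$fractal_dimension - log(8) / log(3)), 0.05)
  expect_gt(bs$lacunarity, 0)         # gappy pattern, heterogeneous masses

  # translation invariance
  sq2 <- matrix(FALSE, 300, 300); sq2[23:278, 31:286] <- TRUE
  bt <- box_count(sq2, seed = 4)
  expect_lt(abs(bt$fractal_dimension - bc$fractal_dimension), 0.03)

  expect_error(box_count(matrix(FALSE, 5, 5)), "empty")
  tiny <- matrix(FALSE, 6, 6); tiny[3:4, 3:4] <- TRUE
  expect_error(box_count(tiny), "box sizes")
})

test_that("intensity measures satisfy their identities", {
  img <- matrix(100, 30, 30)
  m <- matrix(FALSE, 30, 30); m[1:20, 1:10] <- TRUE
  it <- measure_intensity(img, m)
  expect_equal(it$mean_gray, 100)
  expect_equal(it$integrated_density, 20000)
  # identity: area x mean = sum
  set.seed(5)
  img2 <- matrix(runif(900, 0, 255), 30)
  it2 <- measure_intensity(img2, m)
  expect_equal(it2$integrated_density, sum(img2[m]), tolerance = 1e-9)
  it3 <- measure_intensity(2 * img2, m)
  expect_equal(it3$integrated_density, 2 * it2$integrated_density)
})

test_that("assembled records hold the 19 parameters and their invariants", {
  sp <- scene_spec(height = 384, width = 384, n_plaques = 10, n_vessels = 0,
                   core_radius_range = c(7, 13), noise_sd = 3, seed = 33)
  records <- NULL
  for (s in 1:6) {
    sp$seed <- 33 + s
    sc <- generate_scene(sp)
    rec <- assemble_records(sc$image, sc$gt$instance_labels,
                            microns_per_pixel = 0.9,
                            labels = list(subject = paste0("S", s),
                                          region = "parietal",
                                          dementia = "no"),
                            n_grid = 4, seed = 7)
    expect_equal(nrow(rec), max(sc$gt$instance_labels))
    records <- rbind(records, rec)
  }
  expect_true(all(morpho_parameters() %in% names(records)))
  expect_length(morpho_parameters(), 19)
  ok <- complete.cases(records[, morpho_parameters()])
  expect_gt(mean(ok), 0.9)
  r <- records[ok, ]
  expect_true(all(r$diffuseness >= 0 & r$diffuseness <= 1))
  expect_true(all(r$solidity > 0 & r$solidity <= 1.02))
  expect_true(all(r$circularity > 0 & r$circularity < 1.15))
  expect_true(all(r$span_ratio >= 1))
  expect_true(all(r$max_min_radius >= 1))
  expect_true(all(r$compact_area <= r$deposit_area))
  # log transform with +1 offset when zeros occur
  expect_equal(r$log_deposit_area,
               log10(r$deposit_area + as.integer(any(records$deposit_area == 0))),
               tolerance = 1e-12)
})

test_that("a zero compact area logs to zero after the +1 offset", {
  rec <- data.frame(instance = 1, deposit_area = 100, compact_area = 0,
                    perimeter = 40, hull_area = 100, hull_perimeter = 40,
                    bounding_circle_diameter = 12, max_span = 12,
                    mean_radius = 5, integrated_density = 1e4)
  log_cols <- c("deposit_area", "compact_area", "perimeter", "hull_area",
                "hull_perimeter", "bounding_circle_diameter", "max_span",
                "mean_radius", "integrated_density")
  for (cl in log_cols) {
    v <- rec[[cl]]
    off <- if (any(v == 0)) 1 else 0
    rec[[paste0("log_", cl)]] <- log10(v + off)
  }
  expect_equal(rec$log_compact_area, 0)
  expect_equal(rec$log_deposit_area, 2)
})
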