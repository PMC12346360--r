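fake_cam <- function(up) structure(list(raw = up, upsampled = up),
                                   class = "activation_map")

test_that("object extraction finds exactly the supra-threshold components", {
  img <- matrix(50, 96, 96)
  up <- matrix(0, 96, 96)
  expect_length(extract_objects(fake_cam(up), img), 0)

  up[10:24, 10:24] <- 0.9
  up[60:80, 55:75] <- 0.8
  obs <- extract_objects(fake_cam(up), img, t_fg = 0.5, context_margin = 4,
                         min_area = 20)
  expect_length(obs, 2)
  expect_equal(max(flood_fill_components(up > 0.5)), 2)
  # masks reproduce the component pixels
  expect_equal(sum(obs[[1]]$mask), 15 * 15)
  # context margin respected
  expect_equal(dim(obs[[1]]$crop), c(15 + 8, 15 + 8))

  # blob touching the border: crop clipped, mask preserved
  up2 <- matrix(0, 96, 96)
  up2[1:12, 1:12] <- 1
  obs2 <- extract_objects(fake_cam(up2), img, context_margin = 10,
                          min_area = 20)
  expect_length(obs2, 1)
  expect_equal(sum(obs2[[1]]$mask), 144)
  expect_equal(dim(obs2[[1]]$crop), c(22, 22))

  # tiny components are dropped
  up3 <- matrix(0, 96, 96); up3[4:5, 4:5] <- 1
  expect_length(extract_objects(fake_cam(up3), img, min_area = 20), 0)
})

test_that("background synthesis inpaints only the removal mask", {
  set.seed(4)
  img <- quantize8(matrix(40 + rnorm(96 * 96, 0, 5), 96))
  # zero CAM: untouched
  bg0 <- make_background(img, fake_cam(matrix(0, 96, 96)))
  expect_identical(bg0$image, img)
  expect_false(any(bg0$removal_mask))

  # planted bright blob; CAM supra-threshold exactly on the blob
  blob <- disc_mask(9, pad = 0)
  img2 <- img
  img2[40 + seq_len(nrow(blob)) - 10, 40 + seq_len(ncol(blob)) - 10][blob] <- 220
  up <- matrix(0, 96, 96)
  up[40 + seq_len(nrow(blob)) - 10, 40 + seq_len(ncol(blob)) - 10][blob] <- 0.9
  bg <- make_background(img2, fake_cam(up), t_bg = 0.2, dilation_radius = 4)
  # outside the removal mask: bit-identical
  expect_identical(bg$image[!bg$removal_mask], img2[!bg$removal_mask])
  # inpainted interior statistically matches the surrounding annulus
  ann <- thioseg:::from_ebi(EBImage::dilate(
    thioseg:::as_ebi(bg$removal_mask * 1), EBImage::makeBrush(15, "disc"))) > 0
  ann <- ann & !bg$removal_mask
  expect_lt(abs(mean(bg$image[bg$removal_mask]) - mean(img2[ann])) /
              mean(img2[ann]), 0.10)

  expect_error(make_background(img2, fake_cam(matrix(1, 96, 96))),
               "whole image")
})

test_that("foreground components are nested inside the dilated removal zone", {
  set.seed(11)
  for (i in 1:10) {
    up <- matrix(0, 64, 64)
    n <- sample(1:3, 1)
    for (k in seq_len(n)) {
      r <- sample(8:40, 1); c <- sample(8:40, 1)
      up[r:(r + sample(4:10, 1)), c:(c + sample(4:10, 1))] <-
        runif(1, 0.45, 1)
    }
    fg <- up > 0.5
    removal <- up > 0.2
    removal <- thioseg:::from_ebi(EBImage::dilate(
      thioseg:::as_ebi(removal * 1), EBImage::makeBrush(13, "disc"))) > 0
    expect_true(all(removal[fg]))
  }
})

test_that("banks round-trip bit-exactly through disk and reject duplicates", {
  dir <- withr::local_tempdir()
  empty <- list(objects = list(), backgrounds = list())
  save_bank(empty, file.path(dir, "empty"))
  back <- load_bank(file.path(dir, "empty"))
  expect_length(back$objects, 0)
  expect_length(back$backgrounds, 0)

  set.seed(9)
  img <- quantize8(matrix(runif(96 * 96, 0, 255), 96))
  up <- matrix(0, 96, 96)
  up[20:40, 20:45] <- 0.9; up[60:75, 50:70] <- 0.7
  objs <- extract_objects(fake_cam(up), img, context_margin = 5,
                          source = list(subject = "S1", patch = 3))
  bgs <- list(make_background(img, NULL, source = list(subject = "S2",
                                                       patch = 4)))
  bank <- list(objects = objs, backgrounds = bgs)
  save_bank(bank, file.path(dir, "b1"))
  back <- load_bank(file.path(dir, "b1"))
  expect_length(back$objects, 2)
  for (i in 1:2) {
    expect_identical(back$objects[[i]]$crop * 1, objs[[i]]$crop * 1)
    expect_identical(back$objects[[i]]$mask, objs[[i]]$mask)
    expect_equal(unname(back$objects[[i]]$contour),
                 unname(objs[[i]]$contour))
    expect_equal(back$objects[[i]]$source$subject, "S1")
  }
  expect_identical(back$backgrounds[[1]]$image * 1, img * 1)
  expect_equal(back$backgrounds[[1]]$origin, "originally-negative")

  dup <- list(objects = setNames(objs, c("a", "a")), backgrounds = list())
  expect_error(save_bank(dup, file.path(dir, "b2")), "duplicate")

  # corrupted metadata errors, naming the entry
  writeLines("{not json", file.path(dir, "b1", "objects",
                                    "obj00001", "meta.json"))
  expect_error(load_bank(file.path(dir, "b1")), "corrupted")
})

test_that("only positive patches contribute objects to the bank", {
  set.seed(3)
  patches <- lapply(1:4, function(i)
    list(image = quantize8(matrix(runif(64 * 64, 0, 255), 64))))
  up <- matrix(0, 64, 64); up[20:40, 20:40] <- 0.9
  cams <- list(fake_cam(up), fake_cam(up), NULL, NULL)
  labels <- c(1, 1, 0, 0)
  banks <- build_banks(patches, cams, labels, subjects = c("A", "A", "B", "B"),
                       dilation_radius = 4)
  src <- vapply(banks$objects, function(o) o$source$subject, character(1))
  expect_true(all(src == "A"))
  origins <- vapply(banks$backgrounds, function(b) b$origin, character(1))
  expect_setequal(unique(origins), c("inpainted", "originally-negative"))
})

test_that("margin contrast separates halo-fringed deposits from tubes", {
  set.seed(41)
  # deposit-like: bright core, dim ring outside the mask
  core <- disc_mask(8, pad = 8)
  crop <- matrix(30 + rnorm(length(core), 0, 3), nrow(core))
  crop[core] <- 200
  dep <- list(crop = quantize8(crop), mask = core)
  expect_gt(margin_contrast(dep), 0.5)
  # vessel-like: a CAM component inside a wide bright band that continues
  # beyond the mask in every direction
  tube <- matrix(FALSE, 25, 25); tube[8:18, ] <- TRUE
  crop2 <- matrix(30 + rnorm(625, 0, 3), 25)
  crop2[tube] <- 200
  mask2 <- matrix(FALSE, 25, 25); mask2[11:15, 8:18] <- TRUE
  ves <- list(crop = quantize8(crop2), mask = mask2)
  expect_lt(margin_contrast(ves), 0.3)
  # the bank screen drops the tube and keeps the deposit
  cam_dep <- matrix(0, nrow(core), ncol(core)); cam_dep[core] <- 0.9
  patches <- list(list(image = dep$crop), list(image = ves$crop))
  cams <- list(structure(list(upsampled = cam_dep), class = "activation_map"),
               structure(list(upsampled = mask2 * 0.9),
                         class = "activation_map"))
  banks <- build_banks(patches, cams, labels = c(1, 1),
                       subjects = c("A", "A"), dilation_radius = 3,
                       min_margin_contrast = 0.3)
  expect_length(banks$objects, 1)
  banks_all <- build_banks(patches, cams, labels = c(1, 1),
                           subjects = c("A", "A"), dilation_radius = 3,
                           min_margin_contrast = NULL)
  expect_length(banks_all$objects, 2)
})
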