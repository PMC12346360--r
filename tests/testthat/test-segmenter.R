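test_that("valid-convolution size arithmetic matches the oracle", {
  # independent arithmetic oracle
  size_oracle <- function(n, depth) {
    for (i in seq_len(depth)) { n <- n - 4; if (n %% 2) return(NA); n <- n / 2 }
    n <- n - 4
    for (i in seq_len(depth)) n <- 2 * n - 4
    n
  }
  expect_equal(seg_size_schedule(572, 4)$output_tile, 388)
  expect_equal(size_oracle(572, 4), 388)
  expect_equal(seg_size_schedule(188, 3)$output_tile, size_oracle(188, 3))
  expect_equal(seg_size_schedule(108, 2)$output_tile, size_oracle(108, 2))
  expect_error(seg_size_schedule(100, 4), "admissible")
})

test_that("the unified focal loss matches a term-by-term oracle", {
  # printed example batch
  p1 <- matrix(c(0.9, 0.8, 0.1, 0.2), 2)
  g1 <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(unified_focal_loss(p1, g1),
               ufl_oracle(p1, g1), tolerance = 1e-6)

  set.seed(14)
  for (i in 1:100) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    p <- matrix(runif(h * w, 0.01, 0.99), h)
    g <- matrix(rbinom(h * w, 1, 0.4), h)
    ign <- if (i %% 2) matrix(runif(h * w) < 0.2, h) else NULL
    if (!is.null(ign) && all(ign)) ign[1, 1] <- FALSE
    lam <- runif(1); del <- runif(1); gam <- runif(1, 0, 2)
    expect_equal(unified_focal_loss(p, g, ign, lam, del, gam),
                 ufl_oracle(p, g, ign, lam, del, gam), tolerance = 1e-6)
  }
})

test_that("loss endpoints, perfect-prediction limit and monotonicity hold", {
  set.seed(15)
  p <- matrix(runif(16, 0.05, 0.95), 4)
  g <- matrix(rbinom(16, 1, 0.5), 4)
  l1 <- unified_focal_loss(p, g, lambda = 1)
  l0 <- unified_focal_loss(p, g, lambda = 0)
  lmid <- unified_focal_loss(p, g, lambda = 0.3)
  expect_equal(lmid, 0.3 * l1 + 0.7 * l0, tolerance = 1e-12)

  eps <- 1e-7
  perfect <- ifelse(g == 1, 1 - eps, eps)
  expect_lt(unified_focal_loss(perfect, g), 1e-3)

  # raising p1 on a true-foreground pixel never increases the loss
  for (i in which(g == 1)) {
    for (step in c(0.01, 0.1)) {
      p2 <- p
      p2[i] <- min(p2[i] + step, 0.999)
      expect_lte(unified_focal_loss(p2, g), unified_focal_loss(p, g) + 1e-12)
    }
  }
  expect_error(unified_focal_loss(p, g, ignore = matrix(TRUE, 4, 4)),
               "non-ignored")
})

tiny_seg_spec <- segmenter_spec(input_tile = 36, depth = 1,
                                base_channels = 4)

test_that("the forward pass maps input tiles to sigmoid probability grids", {
  m <- build_segmenter(tiny_seg_spec, seed = 2)
  x <- array(runif(36 * 36 * 2), dim = c(36, 36, 1, 2))
  fw <- thioseg:::segmenter_forward(m$params, x, tiny_seg_spec)
  expect_equal(dim(fw$p), c(tiny_seg_spec$output_tile,
                            tiny_seg_spec$output_tile, 1, 2))
  expect_true(all(fw$p > 0 & fw$p < 1))
  # deterministic given weights
  fw2 <- thioseg:::segmenter_forward(m$params, x, tiny_seg_spec)
  expect_identical(fw$p, fw2$p)
})

test_that("training on composites reduces the loss and keeps the final snapshot", {
  banks <- tiny_banks(n_obj = 6, n_bg = 6, bg_size = 60, seed = 5)
  cfg <- list(epochs = 20, batch_size = 4, batches_per_epoch = 4,
              lr = 4e-3, seed = 3)
  spec <- segmenter_spec(input_tile = 44, depth = 1, base_channels = 4)
  fit <- train_segmenter(banks, spec, config = cfg)
  expect_s3_class(fit, "thioseg_segmenter")
  expect_lt(tail(fit$loss_history, 1), 0.5 * fit$loss_history[1])
  expect_length(fit$dev_loss_history, cfg$epochs)
  # snapshot rule: retrains with the same seed reproduce the final weights
  fit2 <- train_segmenter(banks, spec, config = cfg)
  expect_identical(fit$params, fit2$params)

  # fold isolation: bank provenance outside the training subjects
  expect_error(train_segmenter(banks, spec, config = cfg,
                               train_subjects = "S1"),
               "leakage")
})

test_that("tiled inference covers each pixel exactly once and is consistent", {
  m <- build_segmenter(tiny_seg_spec, seed = 4)
  out_t <- tiny_seg_spec$output_tile

  # constant image -> constant probability grid
  const <- matrix(0, 50, 70)
  pr <- predict_full(m, const)
  expect_equal(dim(pr), c(50, 70))
  expect_lt(diff(range(pr)), 1e-12)

  # an image exactly one output tile large equals the single-tile pass
  set.seed(6)
  img <- quantize8(matrix(runif(out_t * out_t, 0, 255), out_t))
  pr1 <- predict_full(m, img)
  m0 <- tiny_seg_spec$margin / 2
  padded <- thioseg:::mirror_pad(img / 255, m0, m0, m0, m0)
  fw <- thioseg:::segmenter_forward(m$params,
                                    thioseg:::stack_batch(list(padded)),
                                    tiny_seg_spec)
  expect_equal(pr1, fw$p[, , 1, 1], tolerance = 1e-12)

  # coverage oracle: tile output regions partition the padded canvas
  h <- 45; w <- 61
  nth <- ceiling(h / out_t); ntw <- ceiling(w / out_t)
  cover <- matrix(0, nth * out_t, ntw * out_t)
  for (ti in seq_len(nth)) for (tj in seq_len(ntw)) {
    cover[(ti - 1) * out_t + seq_len(out_t),
          (tj - 1) * out_t + seq_len(out_t)] <-
      cover[(ti - 1) * out_t + seq_len(out_t),
            (tj - 1) * out_t + seq_len(out_t)] + 1
  }
  expect_true(all(cover == 1))
})

test_that("postprocessing applies threshold, hole fill, size and border rules", {
  prob <- matrix(0, 120, 120)
  # blob with a hole, area just under/over the minimum
  blob <- disc_mask(34, pad = 2)   # area ~3630
  prob[30 + seq_len(nrow(blob)) - 1, 30 + seq_len(ncol(blob)) - 1][blob] <- 0.9
  prob[60:63, 60:63] <- 0          # interior hole
  pm <- postprocess(prob, threshold = 0.5, min_size = 3500)
  expect_true(all(pm$binary[60:63, 60:63]))   # hole filled
  expect_equal(max(pm$instances), 1)

  # area 3499 is removed, 3500 kept
  p2 <- matrix(0, 120, 120)
  p2[2:71, 11:60] <- 1             # 70 x 50 = 3500
  pm2 <- postprocess(p2, min_size = 3500, drop_border = FALSE)
  expect_equal(sum(pm2$binary), 3500)
  p3 <- matrix(0, 120, 120)
  p3[2:71, 11:60] <- 1
  p3[2, 11] <- 0                   # 3499
  pm3 <- postprocess(p3, min_size = 3500)
  expect_equal(sum(pm3$binary), 0)

  # border-touching components are excluded from instances
  p4 <- matrix(0, 60, 60)
  p4[1:10, 20:30] <- 1
  p4[30:40, 20:30] <- 1
  pm4 <- postprocess(p4, min_size = 50)
  expect_equal(max(pm4$instances), 1)
  expect_false(any(pm4$instances[1, ] > 0))
  expect_error(postprocess(matrix(2, 4, 4)), "lie in")
})

test_that("segmentation metrics match printed-formula oracles", {
  m <- segmentation_metrics(50, 900, 10, 40)
  expect_equal(m$dice, 100 / 150, tolerance = 1e-12)
  expect_equal(m$jaccard, 0.5)
  expect_equal(m$recall, 50 / 90)
  expect_equal(m$fdr, 10 / 60)
  perfect <- segmentation_metrics(100, 900, 0, 0)
  expect_equal(perfect$dice, 1); expect_equal(perfect$jaccard, 1)
  expect_equal(perfect$pa, 1); expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fnr, 0)
  expect_error(segmentation_metrics(-1, 1, 1, 1), "negative")

  set.seed(23)
  for (i in 1:1000) {
    cnt <- rpois(4, 8)
    m <- segmentation_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    tp <- cnt[1]; tn <- cnt[2]; fp <- cnt[3]; fn <- cnt[4]
    if (2 * tp + fp + fn > 0) {
      expect_equal(m$dice, 2 * tp / (2 * tp + fp + fn))
      if (tp + fp + fn > 0) {
        expect_equal(m$jaccard, tp / (tp + fp + fn))
        # Dice-Jaccard identity
        expect_equal(m$dice, 2 * m$jaccard / (1 + m$jaccard),
                     tolerance = 1e-12)
      }
    }
    if (fp + tn > 0) expect_equal(m$fpr, fp / (fp + tn))
    if (fn + tn > 0) expect_equal(m$for_, fn / (fn + tn))
  }
})

test_that("vascular exclusion removes tube-borne components, keeps deposits", {
  set.seed(47)
  img <- quantize8(matrix(5 + rnorm(200 * 200, 0, 2), 200))
  # a deposit: bright blob with decaying halo
  d <- sqrt(outer((1:200 - 60)^2, (1:200 - 60)^2, "+"))
  img <- pmax(img, quantize8(200 * exp(-pmax(d - 10, 0)^2 / (2 * 6^2))))
  # a vessel: bright horizontal band crossing the image
  img[140:146, ] <- 200
  prob <- matrix(0, 200, 200)
  prob[d <= 14] <- 0.9                       # correct deposit prediction
  prob[140:146, 90:140] <- 0.9               # false blob on the vessel
  pm <- postprocess(prob, min_size = 100, drop_border = FALSE)
  expect_equal(max(pm$instances), 2)
  out <- exclude_vascular(pm, img, max_extension = 12)
  expect_equal(max(out$instances), 1)
  # the surviving component is the deposit
  expect_true(any(out$binary[d <= 10]))
  expect_false(any(out$binary[140:146, 90:140]))
})
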