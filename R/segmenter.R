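# Valid-convolution encoder-decoder segmenter. Two unpadded 3x3
# convolutions per level, 2x2 max pooling in the encoder, 2x2-stride-2
# transposed convolutions with cropped skip concatenation in the decoder,
# and a sigmoid 1x1 head. Trained with the asymmetric unified focal loss on
# soft copy-paste composites; applied to full micrographs by mirrored
# overlap tiling.

#' Valid-convolution size arithmetic
#'
#' @param input_tile input side in pixels.
#' @param depth number of pooling levels.
#' @return list \code{output_tile}, \code{margin}, \code{sizes} (per-level
#'   encoder sizes), or an error if the schedule does not produce integer
#'   even sizes at every pooling step.
#' @export
seg_size_schedule <- function(input_tile, depth) {
  r <- seg_sizes_try(input_tile, depth)
  if (is.null(r))
    stop("input tile ", input_tile, " is inadmissible at depth ", depth,
         "; admissible nearby sizes: ",
         paste(admissible_tiles(input_tile, depth), collapse = ", "))
  r
}

# NULL when the schedule does not yield positive integer, even sizes
seg_sizes_try <- function(input_tile, depth) {
  s <- input_tile
  sizes <- integer(0)
  for (i in seq_len(depth)) {
    s <- s - 4                      # two 3x3 valid convolutions
    if (s <= 0 || s %% 2 != 0) return(NULL)
    sizes <- c(sizes, s)
    s <- s / 2
  }
  s <- s - 4                        # bottleneck convolutions
  if (s <= 0) return(NULL)
  for (i in seq_len(depth)) {
    s <- 2 * s - 4                  # upconv then two valid convolutions
    if (s <= 0) return(NULL)
  }
  list(output_tile = s, margin = input_tile - s, sizes = sizes)
}

admissible_tiles <- function(around, depth, span = 60) {
  cand <- max(16, around - span):(around + span)
  cand[vapply(cand, function(n) !is.null(seg_sizes_try(n, depth)),
              logical(1))]
}

#' Specify the segmenter
#'
#' @param input_tile input tile side (full profile 572 -> output 388 at
#'   depth 4; desk profile 108 -> output 68 at depth 2).
#' @param depth pooling levels.
#' @param base_channels channels of the first encoder level.
#' @return object of class \code{segmenter_spec} with the derived
#'   \code{output_tile} and \code{margin}.
#' @export
segmenter_spec <- function(input_tile = 108, depth = 2, base_channels = 8) {
  sched <- seg_size_schedule(input_tile, depth)
  structure(list(input_tile = input_tile, depth = depth,
                 base_channels = base_channels,
                 output_tile = sched$output_tile, margin = sched$margin),
            class = "segmenter_spec")
}

#' Asymmetric unified focal loss
#'
#' \eqn{L = \lambda L_{maF} + (1-\lambda) L_{maFT}} where the modified
#' asymmetric focal term is
#' \eqn{-(\delta/N)\sum_{FG}\log p_t - ((1-\delta)/N)\sum_{BG}(1-p_t)^\gamma \log p_t}
#' (\eqn{p_t} = probability of the true class; no focal suppression on the
#' rare foreground class), and the focal Tversky term is
#' \eqn{(1-mTI_{BG}) + (1-mTI_{FG})^{1-\gamma}} with the modified Tversky
#' index weighting false negatives by \eqn{\delta} and false positives by
#' \eqn{1-\delta}. Ignored pixels are excluded from every sum and from N.
#'
#' @param p1 predicted foreground probabilities (vector or matrix).
#' @param g1 foreground ground-truth indicators.
#' @param ignore logical, pixels excluded from the loss (or NULL).
#' @param lambda,delta,gamma loss parameters.
#' @param eps numerical floor.
#' @param return_grad also return d(loss)/d(p1) (same shape as p1, zero on
#'   ignored pixels).
#' @return scalar loss, or list \code{(loss, grad)}.
#' @export
unified_focal_loss <- function(p1, g1, ignore = NULL, lambda = 0.5,
                               delta = 0.6, gamma = 0.5, eps = 1e-7,
                               return_grad = FALSE) {
  if (lambda < 0 || lambda > 1 || delta < 0 || delta > 1 || gamma < 0)
    stop("loss parameters out of range")
  keep <- if (is.null(ignore)) rep(TRUE, length(p1)) else !as.logical(ignore)
  p <- clamp(as.numeric(p1)[keep], eps, 1 - eps)
  g <- as.numeric(g1)[keep]
  N <- length(p)
  if (N == 0) stop("no non-ignored pixels in the batch")
  fg <- g == 1
  p0 <- 1 - p
  # modified asymmetric focal loss
  lmaf <- -(delta / N) * sum(log(p[fg])) -
    ((1 - delta) / N) * sum(p[!fg]^gamma * log(p0[!fg]))
  # modified Tversky indices (shared cross terms)
  A1 <- sum(p[fg]); A0 <- sum(p0[!fg])
  FNs <- sum(p0[fg])          # predicted BG on true FG
  FPs <- sum(p[!fg])          # predicted FG on true BG
  B <- delta * FNs + (1 - delta) * FPs
  mti1 <- A1 / (A1 + B)
  mti0 <- A0 / (A0 + B)
  if (!is.finite(mti1)) mti1 <- 0   # empty foreground with B = 0 cannot occur (B >= 0)
  lmaft <- (1 - mti0) + (1 - mti1)^(1 - gamma)
  loss <- lambda * lmaf + (1 - lambda) * lmaft
  if (!return_grad) return(loss)
  # gradient wrt p (foreground probability), kept pixels only
  gmaf <- numeric(N)
  gmaf[fg] <- -(delta / N) / p[fg]
  pb <- p[!fg]
  gmaf[!fg] <- -((1 - delta) / N) *
    (gamma * pb^(gamma - 1) * log(p0[!fg]) - pb^gamma / p0[!fg])
  dA1 <- as.numeric(fg)
  dA0 <- -as.numeric(!fg)
  dB <- delta * (-as.numeric(fg)) + (1 - delta) * as.numeric(!fg)
  den1 <- (A1 + B)^2
  den0 <- (A0 + B)^2
  dmti1 <- (dA1 * B - A1 * dB) / pmax(den1, eps)
  dmti0 <- (dA0 * B - A0 * dB) / pmax(den0, eps)
  gmaft <- -dmti0 - (1 - gamma) * pmax(1 - mti1, eps)^(-gamma) * dmti1
  gk <- lambda * gmaf + (1 - lambda) * gmaft
  grad <- array(0, dim = if (is.null(dim(p1))) length(p1) else dim(p1))
  grad[keep] <- gk
  list(loss = loss, grad = grad)
}

# ---- network ----------------------------------------------------------

segmenter_init <- function(spec) {
  p <- list()
  cin <- 1
  for (i in seq_len(spec$depth)) {
    ch <- spec$base_channels * 2^(i - 1)
    p[[paste0("e", i, "_w1")]] <- he_init(3, cin, ch)
    p[[paste0("e", i, "_b1")]] <- numeric(ch)
    p[[paste0("e", i, "_w2")]] <- he_init(3, ch, ch)
    p[[paste0("e", i, "_b2")]] <- numeric(ch)
    cin <- ch
  }
  chb <- spec$base_channels * 2^spec$depth
  p$bot_w1 <- he_init(3, cin, chb); p$bot_b1 <- numeric(chb)
  p$bot_w2 <- he_init(3, chb, chb); p$bot_b2 <- numeric(chb)
  cin <- chb
  for (i in rev(seq_len(spec$depth))) {
    ch <- spec$base_channels * 2^(i - 1)
    p[[paste0("d", i, "_wu")]] <- he_init(2, cin, ch)
    p[[paste0("d", i, "_bu")]] <- numeric(ch)
    p[[paste0("d", i, "_w1")]] <- he_init(3, 2 * ch, ch)
    p[[paste0("d", i, "_b1")]] <- numeric(ch)
    p[[paste0("d", i, "_w2")]] <- he_init(3, ch, ch)
    p[[paste0("d", i, "_b2")]] <- numeric(ch)
    cin <- ch
  }
  p$head_w <- he_init(1, cin, 1)
  p$head_b <- numeric(1)
  p
}

segmenter_forward <- function(params, x, spec) {
  cache <- list(x = x)
  a <- x
  for (i in seq_len(spec$depth)) {
    a1 <- relu_fwd(conv_fwd(a, params[[paste0("e", i, "_w1")]],
                            params[[paste0("e", i, "_b1")]], 0))
    a2 <- relu_fwd(conv_fwd(a1, params[[paste0("e", i, "_w2")]],
                            params[[paste0("e", i, "_b2")]], 0))
    cache[[paste0("enc", i)]] <- list(input = a, a1 = a1, a2 = a2)
    mp <- maxpool2_fwd(a2)
    cache[[paste0("pool", i)]] <- mp
    a <- mp$y
  }
  b1 <- relu_fwd(conv_fwd(a, params$bot_w1, params$bot_b1, 0))
  b2 <- relu_fwd(conv_fwd(b1, params$bot_w2, params$bot_b2, 0))
  cache$bot <- list(input = a, a1 = b1, a2 = b2)
  a <- b2
  for (i in rev(seq_len(spec$depth))) {
    up <- upconv2_fwd(a, params[[paste0("d", i, "_wu")]],
                      params[[paste0("d", i, "_bu")]])
    skip <- crop_center(cache[[paste0("enc", i)]]$a2, dim(up)[1], dim(up)[2])
    cat_in <- concat_c(skip, up)
    d1 <- relu_fwd(conv_fwd(cat_in, params[[paste0("d", i, "_w1")]],
                            params[[paste0("d", i, "_b1")]], 0))
    d2 <- relu_fwd(conv_fwd(d1, params[[paste0("d", i, "_w2")]],
                            params[[paste0("d", i, "_b2")]], 0))
    cache[[paste0("dec", i)]] <- list(up_in = a, up = up, cat = cat_in,
                                      a1 = d1, a2 = d2)
    a <- d2
  }
  z <- conv_fwd(a, params$head_w, params$head_b, 0)
  cache$head_in <- a
  cache$z <- z
  list(p = sigmoid(z), cache = cache)
}

# gz: gradient at the logit (same dims as z)
segmenter_backward <- function(params, spec, cache, gz) {
  grads <- lapply(params, function(p) p * 0)
  bw <- conv_bwd(cache$head_in, params$head_w, gz, 0)
  grads$head_w <- bw$gw; grads$head_b <- bw$gb
  ga <- bw$gx
  skip_grads <- list()
  for (i in seq_len(spec$depth)) {
    dc <- cache[[paste0("dec", i)]]
    g2 <- relu_bwd(ga, dc$a2)
    bw2 <- conv_bwd(dc$a1, params[[paste0("d", i, "_w2")]], g2, 0)
    grads[[paste0("d", i, "_w2")]] <- bw2$gw
    grads[[paste0("d", i, "_b2")]] <- bw2$gb
    g1 <- relu_bwd(bw2$gx, dc$a1)
    bw1 <- conv_bwd(dc$cat, params[[paste0("d", i, "_w1")]], g1, 0)
    grads[[paste0("d", i, "_w1")]] <- bw1$gw
    grads[[paste0("d", i, "_b1")]] <- bw1$gb
    ch <- spec$base_channels * 2^(i - 1)
    gskip <- bw1$gx[, , seq_len(ch), , drop = FALSE]
    gup <- bw1$gx[, , ch + seq_len(ch), , drop = FALSE]
    skip_grads[[i]] <- gskip
    bwu <- upconv2_bwd(dc$up_in, params[[paste0("d", i, "_wu")]], gup)
    grads[[paste0("d", i, "_wu")]] <- bwu$gw
    grads[[paste0("d", i, "_bu")]] <- bwu$gb
    ga <- bwu$gx
  }
  bc <- cache$bot
  g2 <- relu_bwd(ga, bc$a2)
  bw2 <- conv_bwd(bc$a1, params$bot_w2, g2, 0)
  grads$bot_w2 <- bw2$gw; grads$bot_b2 <- bw2$gb
  g1 <- relu_bwd(bw2$gx, bc$a1)
  bw1 <- conv_bwd(bc$input, params$bot_w1, g1, 0)
  grads$bot_w1 <- bw1$gw; grads$bot_b1 <- bw1$gb
  ga <- bw1$gx
  for (i in rev(seq_len(spec$depth))) {
    ec <- cache[[paste0("enc", i)]]
    mp <- cache[[paste0("pool", i)]]
    ga <- maxpool2_bwd(ga, mp$idx, dim(ec$a2))
    # add the cropped-skip gradient back into the encoder activation
    gs <- skip_grads[[i]]
    d <- dim(ec$a2); ds <- dim(gs)
    r0 <- (d[1] - ds[1]) %/% 2; c0 <- (d[2] - ds[2]) %/% 2
    ga[r0 + seq_len(ds[1]), c0 + seq_len(ds[2]), , ] <-
      ga[r0 + seq_len(ds[1]), c0 + seq_len(ds[2]), , , drop = FALSE] + gs
    g2 <- relu_bwd(ga, ec$a2)
    bw2 <- conv_bwd(ec$a1, params[[paste0("e", i, "_w2")]], g2, 0)
    grads[[paste0("e", i, "_w2")]] <- bw2$gw
    grads[[paste0("e", i, "_b2")]] <- bw2$gb
    g1 <- relu_bwd(bw2$gx, ec$a1)
    bw1 <- conv_bwd(ec$input, params[[paste0("e", i, "_w1")]], g1, 0)
    grads[[paste0("e", i, "_w1")]] <- bw1$gw
    grads[[paste0("e", i, "_b1")]] <- bw1$gb
    ga <- bw1$gx
  }
  grads
}

#' Build an untrained segmenter
#'
#' @param spec a \code{\link{segmenter_spec}}.
#' @param seed seed for weight initialization.
#' @return object of class \code{thioseg_segmenter}.
#' @export
build_segmenter <- function(spec, seed = 1L) {
  params <- with_seed(seed, segmenter_init(spec))
  structure(list(params = params, spec = spec, trained = FALSE),
            class = "thioseg_segmenter")
}

#' @export
print.thioseg_segmenter <- function(x, ...) {
  cat("valid-convolution segmenter: tile ", x$spec$input_tile, " -> ",
      x$spec$output_tile, " (depth ", x$spec$depth, ", base ",
      x$spec$base_channels, " channels), ",
      if (isTRUE(x$trained)) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Train the segmenter on streamed composites
#'
#' Composites are synthesized on the fly from the banks (soft copy-paste of
#' 0--5 objects into background crops). The loss is the asymmetric unified
#' focal loss evaluated on the central output window, with trimap ignore
#' pixels excluded. Optimization is Adam; the snapshot at the final epoch is
#' returned regardless of development loss (monitoring only).
#'
#' @param banks bank list; entries must carry \code{source$subject} for
#'   provenance checking.
#' @param spec a \code{\link{segmenter_spec}}.
#' @param loss_params list \code{lambda}, \code{delta}, \code{gamma}.
#' @param config list: \code{epochs}, \code{batch_size},
#'   \code{batches_per_epoch}, \code{lr}, \code{seed}, \code{dev_fraction}.
#' @param train_subjects if given, every bank entry must originate from one
#'   of these subjects (fold isolation); violations are an error.
#' @param verbose print epoch losses.
#' @return a trained \code{thioseg_segmenter} with a \code{loss_history}.
#' @export
train_segmenter <- function(banks, spec,
                            loss_params = list(lambda = 0.5, delta = 0.6,
                                               gamma = 0.5),
                            config = list(), train_subjects = NULL,
                            verbose = FALSE) {
  cfg <- utils::modifyList(list(epochs = 12, batch_size = 16,
                                batches_per_epoch = 6, lr = 1e-3,
                                beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                                seed = 1L, dev_fraction = 0.1),
                           config)
  if (!is.null(train_subjects)) {
    subs <- c(vapply(banks$objects, function(o)
      as.character(o$source$subject %||% NA), character(1)),
      vapply(banks$backgrounds, function(b)
        as.character(b$source$subject %||% NA), character(1)))
    bad <- subs[!is.na(subs) & !(subs %in% train_subjects)]
    if (length(bad))
      stop("fold leakage: bank entries from non-training subjects: ",
           paste(unique(bad), collapse = ", "))
  }
  model <- build_segmenter(spec, seed = cfg$seed)
  params <- model$params
  state <- opt_state(params)
  out_t <- spec$output_tile
  m0 <- spec$margin / 2
  history <- numeric(cfg$epochs)
  dev_history <- numeric(cfg$epochs)
  # fixed development composites, same augmentation pipeline, monitoring only
  dev_comps <- if (cfg$dev_fraction > 0)
    with_seed(cfg$seed + 99991L,
              lapply(seq_len(max(2L, round(cfg$dev_fraction *
                                             cfg$batch_size *
                                             cfg$batches_per_epoch))),
                     function(i) compose_scene(banks,
                                               size = spec$input_tile)))
  else NULL
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0; nb <- 0
      for (b in seq_len(cfg$batches_per_epoch)) {
        comps <- lapply(seq_len(cfg$batch_size), function(i)
          compose_scene(banks, size = spec$input_tile))
        x <- stack_batch(lapply(comps, function(cc) cc$image / 255))
        fw <- segmenter_forward(params, x, spec)
        p1 <- fw$p
        gdim <- dim(p1)
        g1 <- array(0, gdim); ign <- array(FALSE, gdim)
        for (i in seq_along(comps)) {
          rows <- m0 + seq_len(out_t); cols <- m0 + seq_len(out_t)
          g1[, , 1, i] <- comps[[i]]$fg_mask[rows, cols]
          ign[, , 1, i] <- comps[[i]]$ignore_mask[rows, cols]
        }
        lf <- unified_focal_loss(p1, g1, ignore = ign,
                                 lambda = loss_params$lambda,
                                 delta = loss_params$delta,
                                 gamma = loss_params$gamma,
                                 return_grad = TRUE)
        gz <- lf$grad * p1 * (1 - p1)
        dim(gz) <- gdim
        grads <- segmenter_backward(params, spec, fw$cache, gz)
        upd <- adam_step(params, grads, state, lr = cfg$lr,
                         beta1 = cfg$beta1, beta2 = cfg$beta2,
                         eps = cfg$eps)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + lf$loss; nb <- nb + 1
      }
      history[ep] <- ep_loss / nb
      if (!is.null(dev_comps)) {
        xd <- stack_batch(lapply(dev_comps, function(cc) cc$image / 255))
        fwd <- segmenter_forward(params, xd, spec)
        gd <- array(0, dim(fwd$p)); id <- array(FALSE, dim(fwd$p))
        for (i in seq_along(dev_comps)) {
          rows <- m0 + seq_len(out_t)
          gd[, , 1, i] <- dev_comps[[i]]$fg_mask[rows, rows]
          id[, , 1, i] <- dev_comps[[i]]$ignore_mask[rows, rows]
        }
        dev_history[ep] <- unified_focal_loss(fwd$p, gd, ignore = id,
                                              lambda = loss_params$lambda,
                                              delta = loss_params$delta,
                                              gamma = loss_params$gamma)
      }
      if (verbose) message("segmenter epoch ", ep, " loss ",
                           signif(history[ep], 4))
    }
  })
  # snapshot rule: the final-epoch weights are kept regardless of the
  # development loss, which is recorded for monitoring only
  structure(list(params = params, spec = spec, trained = TRUE,
                 loss_history = history, dev_loss_history = dev_history,
                 loss_params = loss_params),
            class = "thioseg_segmenter")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mirror_pad <- function(image, top, left, bottom, right) {
  h <- nrow(image); w <- ncol(image)
  refl <- function(idx, n) {
    # reflect indices without repeating the border pixel
    idx <- ((idx - 1) %% (2 * n - 2))
    ifelse(idx < n, idx + 1, 2 * n - idx - 1)
  }
  rows <- refl(seq(1 - top, h + bottom), h)
  cols <- refl(seq(1 - left, w + right), w)
  image[rows, cols, drop = FALSE]
}

#' Full-image prediction by mirrored overlap tiling
#'
#' The image is reflected at the borders by the network margin, padded at
#' the right/bottom to a whole number of output tiles, and processed in
#' tiles whose output regions partition the canvas; each image pixel is
#' predicted exactly once.
#'
#' @param model a trained \code{thioseg_segmenter}.
#' @param image intensity matrix (0--255), already preprocessed.
#' @return foreground probability matrix of the same size.
#' @export
predict_full <- function(model, image) {
  spec <- model$spec
  out_t <- spec$output_tile
  m0 <- spec$margin / 2
  h <- nrow(image); w <- ncol(image)
  nth <- ceiling(h / out_t); ntw <- ceiling(w / out_t)
  padded <- mirror_pad(image / 255, m0, m0,
                       m0 + nth * out_t - h, m0 + ntw * out_t - w)
  prob <- matrix(0, nth * out_t, ntw * out_t)
  for (ti in seq_len(nth))
    for (tj in seq_len(ntw)) {
      r0 <- (ti - 1) * out_t; c0 <- (tj - 1) * out_t
      tile <- padded[r0 + seq_len(spec$input_tile),
                     c0 + seq_len(spec$input_tile)]
      fw <- segmenter_forward(model$params, stack_batch(list(tile)), spec)
      prob[r0 + seq_len(out_t), c0 + seq_len(out_t)] <- fw$p[, , 1, 1]
    }
  prob[seq_len(h), seq_len(w), drop = FALSE]
}

#' @rdname predict_full
#' @param object a \code{thioseg_segmenter}.
#' @param ... unused.
#' @export
predict.thioseg_segmenter <- function(object, image, ...)
  predict_full(object, image)

#' Postprocess a probability map into deposits
#'
#' Thresholding, per-component hole filling, size exclusion
#' (components with area below \code{min_size} are removed) and border
#' exclusion: components touching the image boundary are removed from the
#' instance labeling (and from \code{binary} only if
#' \code{drop_border_in_binary}).
#'
#' @param prob probability matrix in [0, 1].
#' @param threshold binarization threshold.
#' @param min_size minimum component area in pixels (the full-resolution
#'   default 3500 px scales with the squared resolution factor in desk
#'   profiles).
#' @param drop_border drop border-touching components from instances.
#' @param drop_border_in_binary also drop them from the binary mask.
#' @return object of class \code{prediction_mask}: \code{prob},
#'   \code{binary}, \code{instances} (integer matrix).
#' @export
postprocess <- function(prob, threshold = 0.5, min_size = 249,
                        drop_border = TRUE, drop_border_in_binary = FALSE) {
  if (min(prob) < 0 || max(prob) > 1) stop("prob must lie in [0,1]")
  binary <- prob >= threshold
  lab <- label_components8(matrix(as.integer(binary), nrow(binary)))
  if (max(lab) > 0) {
    filled <- from_ebi(EBImage::fillHull(as_ebi(lab))) > 0
    binary <- filled
    lab <- label_components8(matrix(as.integer(binary), nrow(binary)))
  }
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(areas < min_size)
    if (length(small)) {
      binary[lab %in% small] <- FALSE
      lab[lab %in% small] <- 0L
    }
  }
  inst <- lab
  if (drop_border && max(inst) > 0) {
    border_ids <- unique(c(inst[1, ], inst[nrow(inst), ],
                           inst[, 1], inst[, ncol(inst)]))
    border_ids <- border_ids[border_ids > 0]
    if (length(border_ids)) {
      inst[inst %in% border_ids] <- 0L
      if (drop_border_in_binary) binary[lab %in% border_ids] <- FALSE
    }
  }
  # relabel instances consecutively
  if (max(inst) > 0) {
    ids <- sort(unique(inst[inst > 0]))
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    inst[inst > 0] <- remap[inst[inst > 0]]
  }
  structure(list(prob = prob, binary = binary, instances = inst),
            class = "prediction_mask")
}

#' Morphology-based exclusion of vascular structures
#'
#' ThioS stains vascular amyloid as brightly as parenchymal deposits, and
#' morphology-based exclusion is the standard way to separate the two. A
#' parenchymal deposit's halo decays into background, so the bright region
#' containing it barely exceeds the predicted component; a vascular segment
#' is part of a tube whose brightness continues far beyond any local blob.
#' For each predicted component, the image is thresholded at
#' \code{bright_frac} of the component's mean intensity within a local
#' window, and the connected bright region containing the component is
#' traced; components whose bright region extends more than
#' \code{max_extension} pixels beyond them are removed as vascular.
#'
#' @param pm a \code{\link{postprocess}} result.
#' @param image the intensity image the prediction was made on.
#' @param bright_frac threshold as a fraction of the component's mean
#'   in-component intensity.
#' @param max_extension maximum tolerated extension of the bright region
#'   beyond the component, pixels (scales with resolution).
#' @param margin local window padding around each component, pixels.
#' @return the filtered \code{prediction_mask}.
#' @export
exclude_vascular <- function(pm, image, bright_frac = 0.5,
                             max_extension = 12, margin = 50) {
  lab <- label_components8(matrix(as.integer(pm$binary), nrow(pm$binary)))
  drop <- integer(0)
  for (k in seq_len(max(lab))) {
    inst <- lab == k
    px <- which(inst, arr.ind = TRUE)
    r <- range(px[, 1]); cl <- range(px[, 2])
    rr <- max(1, r[1] - margin):min(nrow(image), r[2] + margin)
    cc <- max(1, cl[1] - margin):min(ncol(image), cl[2] + margin)
    win <- image[rr, cc]; iw <- inst[rr, cc]
    bright <- win >= bright_frac * mean(image[inst])
    blab <- label_components8(matrix(as.integer(bright), nrow(bright)))
    ids <- setdiff(unique(blab[iw]), 0L)
    if (!length(ids)) next
    bc <- blab %in% ids
    dout <- from_ebi(EBImage::distmap(as_ebi((!iw) * 1)))
    if (max(c(0, dout[bc & !iw])) > max_extension) drop <- c(drop, k)
  }
  if (length(drop)) {
    sel <- matrix(lab %in% drop, nrow(lab))
    pm$binary[sel] <- FALSE
    pm$instances[sel] <- 0L
    ids <- sort(unique(pm$instances[pm$instances > 0]))
    if (length(ids)) {
      remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
      pm$instances[pm$instances > 0] <- remap[pm$instances[pm$instances > 0]]
    }
  }
  pm
}

#' Pixel-level segmentation metrics
#'
#' The eleven standard ratios from segmentation confusion counts. Zero
#' denominators yield \code{NA}.
#'
#' @param tp,tn,fp,fn pixel confusion counts.
#' @return named list: dice, jaccard, recall, pa, specificity, precision,
#'   npv, fpr, fdr, fnr, for_.
#' @export
segmentation_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(dice = ratio(2 * tp, 2 * tp + fp + fn),
       jaccard = ratio(tp, tp + fp + fn),
       recall = ratio(tp, tp + fn),
       pa = ratio(tp + tn, tp + tn + fp + fn),
       specificity = ratio(tn, tn + fp),
       precision = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       fpr = ratio(fp, fp + tn),
       fdr = ratio(fp, fp + tp),
       fnr = ratio(fn, fn + tp),
       for_ = ratio(fn, fn + tn))
}

#' Confusion counts between predicted and reference masks
#' @param pred,ref logical matrices.
#' @return list tp, tn, fp, fn.
#' @export
mask_confusion <- function(pred, ref) {
  list(tp = sum(pred & ref), tn = sum(!pred & !ref),
       fp = sum(pred & !ref), fn = sum(!pred & ref))
}
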