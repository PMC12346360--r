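# Patch-level binary classifier: a compact fully convolutional network of
# fire modules (1x1 squeeze followed by parallel 1x1 and 3x3 expands, in
# the SqueezeNet style) with identity skip connections around alternate
# modules, a thresholded-average-pooling (TAP) head, and a sigmoid output.
# Class activation maps are formed from the final feature maps with the
# head's negative weights clamped to zero.

#' Specify the classifier architecture
#'
#' @param input_size input patch side in pixels (desk profile 128; the
#'   full-scale profile uses 572).
#' @param stem_channels channels of the initial 3x3 convolution.
#' @param fire_module_widths list of \code{c(squeeze, expand1x1, expand3x3)}
#'   channel counts, one per fire module.
#' @param bypass_after indices of fire modules wrapped by an identity skip
#'   connection (input and output widths must match there).
#' @param pool_after indices of fire modules followed by 2x2 max pooling.
#' @param final_map_channels number of final feature maps feeding TAP.
#' @param tap_threshold TAP activation threshold (activation units).
#' @return object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(input_size = 128, stem_channels = 8,
                            fire_module_widths = list(
                              c(4, 8, 8), c(4, 8, 8),
                              c(8, 16, 16), c(8, 16, 16),
                              c(12, 24, 24), c(12, 24, 24)),
                            bypass_after = c(2, 4, 6),
                            pool_after = c(2, 4),
                            final_map_channels = 16,
                            tap_threshold = 0) {
  spec <- list(input_size = input_size, stem_channels = stem_channels,
               fire_module_widths = fire_module_widths,
               bypass_after = bypass_after, pool_after = pool_after,
               final_map_channels = final_map_channels,
               tap_threshold = tap_threshold)
  n_pool <- 1 + length(pool_after)   # stem pool + fire pools
  spec$map_size <- input_size / 2^n_pool
  if (spec$map_size != round(spec$map_size))
    stop("input_size is not divisible by the pooling schedule")
  if (spec$map_size < 16)
    stop("final feature maps would be smaller than 16 x 16")
  if (!is.finite(tap_threshold)) stop("tap_threshold must be finite")
  widths <- vapply(fire_module_widths, function(wd) wd[2] + wd[3], numeric(1))
  ins <- c(stem_channels, head(widths, -1))
  for (b in bypass_after)
    if (ins[b] != widths[b])
      stop("bypass around fire module ", b,
           " needs matching input/output widths")
  class(spec) <- "classifier_spec"
  spec
}

#' Thresholded average pooling
#'
#' Mean of the activations strictly greater than the threshold; 0 when no
#' activation exceeds it. With \code{tau = -Inf} this is global average
#' pooling; with \code{tau} just below the maximum it approaches global max
#' pooling.
#'
#' @param feature_map numeric matrix (or array).
#' @param tau threshold.
#' @return scalar.
#' @export
tap_pool <- function(feature_map, tau) {
  v <- feature_map[feature_map > tau]
  if (length(v) == 0) 0 else mean(v)
}

#' Binary cross-entropy
#'
#' Mean over the batch of \eqn{-[y \log p + (1-y)\log(1-p)]}; supports soft
#' labels in [0, 1]. Probabilities are clipped away from 0 and 1.
#'
#' @param y labels in [0, 1].
#' @param p predicted probabilities.
#' @param eps clipping bound.
#' @return scalar loss.
#' @export
binary_cross_entropy <- function(y, p, eps = 1e-12) {
  if (length(y) != length(p)) stop("length mismatch between y and p")
  p <- clamp(p, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Mixup of two samples
#'
#' The coefficient is drawn from a symmetric Beta whose shape depends on
#' whether the two labels agree: \code{alpha_intra} (sharp, near 0.5) for
#' same-class pairs, \code{alpha_inter} (near 0/1) for cross-class pairs.
#'
#' @param x1,x2 input arrays of identical shape.
#' @param y1,y2 labels in [0, 1].
#' @param alpha_intra,alpha_inter Beta shapes.
#' @param lambda optional fixed coefficient (overrides sampling).
#' @return list \code{(x, y, lambda)}.
#' @export
mixup_pair <- function(x1, y1, x2, y2, alpha_intra = 8.0, alpha_inter = 0.2,
                       lambda = NULL) {
  if (!identical(dim(x1), dim(x2)) || length(x1) != length(x2))
    stop("mixup inputs have different shapes")
  if (is.null(lambda)) {
    a <- if (isTRUE(all.equal(y1, y2))) alpha_intra else alpha_inter
    lambda <- rbeta(1, a, a)
  }
  list(x = lambda * x1 + (1 - lambda) * x2,
       y = lambda * y1 + (1 - lambda) * y2, lambda = lambda)
}

# ---- network ----------------------------------------------------------

classifier_init <- function(spec) {
  p <- list(stem_w = he_init(3, 1, spec$stem_channels),
            stem_b = numeric(spec$stem_channels))
  cin <- spec$stem_channels
  for (i in seq_along(spec$fire_module_widths)) {
    wd <- spec$fire_module_widths[[i]]
    p[[paste0("f", i, "_sq_w")]] <- he_init(1, cin, wd[1])
    p[[paste0("f", i, "_sq_b")]] <- numeric(wd[1])
    p[[paste0("f", i, "_e1_w")]] <- he_init(1, wd[1], wd[2])
    p[[paste0("f", i, "_e1_b")]] <- numeric(wd[2])
    p[[paste0("f", i, "_e3_w")]] <- he_init(3, wd[1], wd[3])
    p[[paste0("f", i, "_e3_b")]] <- numeric(wd[3])
    cin <- wd[2] + wd[3]
  }
  p$final_w <- he_init(1, cin, spec$final_map_channels)
  p$final_b <- numeric(spec$final_map_channels)
  p$head_w <- rnorm(spec$final_map_channels, 0, 0.1)
  p$head_b <- 0
  p
}

classifier_forward <- function(params, x, spec) {
  cache <- list(x = x)
  a <- conv_fwd(x, params$stem_w, params$stem_b, pad = 1)
  a <- relu_fwd(a); cache$stem <- a
  mp <- maxpool2_fwd(a); a <- mp$y
  cache$stem_pool <- mp
  for (i in seq_along(spec$fire_module_widths)) {
    fin <- a
    sq <- relu_fwd(conv_fwd(a, params[[paste0("f", i, "_sq_w")]],
                            params[[paste0("f", i, "_sq_b")]], 0))
    e1 <- conv_fwd(sq, params[[paste0("f", i, "_e1_w")]],
                   params[[paste0("f", i, "_e1_b")]], 0)
    e3 <- conv_fwd(sq, params[[paste0("f", i, "_e3_w")]],
                   params[[paste0("f", i, "_e3_b")]], 1)
    out <- relu_fwd(concat_c(e1, e3))
    if (i %in% spec$bypass_after) out <- out + fin
    cache[[paste0("fire", i)]] <- list(input = fin, sq = sq, out = out)
    a <- out
    if (i %in% spec$pool_after) {
      mp <- maxpool2_fwd(a)
      cache[[paste0("pool", i)]] <- mp
      a <- mp$y
    }
  }
  fmap <- relu_fwd(conv_fwd(a, params$final_w, params$final_b, 0))
  cache$pre_final <- a
  cache$fmap <- fmap
  d <- dim(fmap)
  # TAP per channel and sample (vectorized: one column per map)
  tau <- spec$tap_threshold
  fm <- matrix(fmap, d[1] * d[2], d[3] * d[4])
  sel <- fm > tau
  cnt <- colSums(sel)
  feats <- matrix(ifelse(cnt > 0, colSums(fm * sel) / pmax(cnt, 1), 0),
                  d[3], d[4])
  cache$tap_sel <- sel
  cache$tap_cnt <- cnt
  z <- drop(crossprod(feats, params$head_w)) + params$head_b
  cache$feats <- feats
  list(p = sigmoid(z), z = z, cache = cache)
}

# gz: d(loss)/d(logit), one per sample
classifier_backward <- function(params, spec, fw, gz) {
  cache <- fw$cache
  grads <- lapply(params, function(p) p * 0)
  feats <- cache$feats
  grads$head_w <- drop(feats %*% gz)
  grads$head_b <- sum(gz)
  d <- dim(cache$fmap)
  gfeats <- outer(params$head_w, gz)       # K x N
  scale <- ifelse(cache$tap_cnt > 0,
                  as.vector(gfeats) / pmax(cache$tap_cnt, 1), 0)
  gfmap <- cache$tap_sel * rep(scale, each = d[1] * d[2])
  gfmap <- array(gfmap, dim = d)
  gfmap <- relu_bwd(gfmap, cache$fmap)
  bw <- conv_bwd(cache$pre_final, params$final_w, gfmap, 0)
  grads$final_w <- bw$gw; grads$final_b <- bw$gb
  ga <- bw$gx
  for (i in rev(seq_along(spec$fire_module_widths))) {
    if (i %in% spec$pool_after) {
      mp <- cache[[paste0("pool", i)]]
      ga <- maxpool2_bwd(ga, mp$idx, dim(cache[[paste0("fire", i)]]$out))
    }
    fc <- cache[[paste0("fire", i)]]
    gout <- ga
    gskip <- if (i %in% spec$bypass_after) gout else 0
    # fc$out includes the bypass; recover the pre-bypass relu output
    pre <- fc$out - if (i %in% spec$bypass_after) fc$input else 0
    gact <- relu_bwd(gout, pre)
    wd <- spec$fire_module_widths[[i]]
    ge1 <- gact[, , seq_len(wd[2]), , drop = FALSE]
    ge3 <- gact[, , wd[2] + seq_len(wd[3]), , drop = FALSE]
    bw1 <- conv_bwd(fc$sq, params[[paste0("f", i, "_e1_w")]], ge1, 0)
    bw3 <- conv_bwd(fc$sq, params[[paste0("f", i, "_e3_w")]], ge3, 1)
    grads[[paste0("f", i, "_e1_w")]] <- bw1$gw
    grads[[paste0("f", i, "_e1_b")]] <- bw1$gb
    grads[[paste0("f", i, "_e3_w")]] <- bw3$gw
    grads[[paste0("f", i, "_e3_b")]] <- bw3$gb
    gsq <- relu_bwd(bw1$gx + bw3$gx, fc$sq)
    bws <- conv_bwd(fc$input, params[[paste0("f", i, "_sq_w")]], gsq, 0)
    grads[[paste0("f", i, "_sq_w")]] <- bws$gw
    grads[[paste0("f", i, "_sq_b")]] <- bws$gb
    ga <- bws$gx + gskip
  }
  ga <- maxpool2_bwd(ga, cache$stem_pool$idx, dim(cache$stem))
  ga <- relu_bwd(ga, cache$stem)
  bw <- conv_bwd(cache$x, params$stem_w, ga, 1)
  grads$stem_w <- bw$gw; grads$stem_b <- bw$gb
  grads
}

# random 90-degree rotations and flips, cheap and exact
augment_patch <- function(m) {
  k <- sample(0:3, 1)
  if (k > 0) for (i in seq_len(k)) m <- t(m[nrow(m):1, ])
  if (runif(1) < 0.5) m <- m[nrow(m):1, ]
  m
}

#' Train the patch classifier with patient-wise folds
#'
#' Patches are scaled to [0, 1], resized to the spec input size if needed,
#' geometrically augmented (right-angle rotations and flips) and mixed up
#' within each batch. Optimization is RMSprop on binary cross-entropy; 10\%
#' of the training patches are held out as a development set and the
#' checkpoint with the lowest development loss is retained.
#'
#' @param patches list of intensity matrices (0--255).
#' @param labels integer 0/1 labels.
#' @param subjects subject id per patch (character).
#' @param fold_plan a \code{\link{make_fold_plan}} result.
#' @param spec a \code{\link{classifier_spec}}.
#' @param config list: \code{epochs}, \code{batch_size}, \code{lr},
#'   \code{mixup_alpha_intra}, \code{mixup_alpha_inter}, \code{augment},
#'   \code{seed}.
#' @param folds which fold ids to train (default all).
#' @param verbose print per-epoch losses.
#' @return list of per-fold objects of class \code{thioseg_classifier}, each
#'   with \code{params}, \code{spec}, \code{dev_loss}, \code{fold},
#'   \code{test_subject}.
#' @export
train_classifier <- function(patches, labels, subjects, fold_plan, spec,
                             config = list(), folds = NULL, verbose = FALSE) {
  cfg <- utils::modifyList(list(epochs = 30, batch_size = 16, lr = 5e-4,
                                lr_decay = TRUE,
                                mixup_alpha_intra = 8.0,
                                mixup_alpha_inter = 0.2,
                                augment = TRUE, mixup = TRUE, seed = 1L),
                           config)
  check_fold_plan(fold_plan, unique(subjects))
  if (is.null(folds)) folds <- seq_along(fold_plan$folds)
  lapply(folds, function(f) {
    test_subject <- fold_plan$folds[[f]]
    train_idx <- which(!(subjects %in% test_subject))
    if (any(subjects[train_idx] %in% test_subject))
      stop("fold leakage: subject present in both train and test partitions")
    with_seed(cfg$seed + f, {
      dev_n <- max(1L, round(fold_plan$dev_fraction * length(train_idx)))
      dev_idx <- sample(train_idx, dev_n)
      tr_idx <- setdiff(train_idx, dev_idx)
      params <- classifier_init(spec)
      state <- opt_state(params)
      prep <- function(m) {
        m <- m / 255
        if (nrow(m) != spec$input_size)
          m <- bilinear_resize(m, spec$input_size, spec$input_size)
        m
      }
      dev_x <- stack_batch(lapply(patches[dev_idx], prep))
      dev_y <- labels[dev_idx]
      best <- list(loss = Inf, params = params)
      history <- numeric(cfg$epochs)
      for (ep in seq_len(cfg$epochs)) {
        # step decay stabilizes the late phase of RMSprop on small batches
        lr_ep <- if (isTRUE(cfg$lr_decay))
          cfg$lr * 0.5^((ep > 0.6 * cfg$epochs) + (ep > 0.85 * cfg$epochs))
        else cfg$lr
        ord <- sample(tr_idx)
        for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
          bi <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
          if (length(bi) < 2) next
          xs <- lapply(patches[bi], prep)
          if (cfg$augment) xs <- lapply(xs, augment_patch)
          ys <- as.numeric(labels[bi])
          if (cfg$mixup) {
            perm <- sample(length(bi))
            for (j in seq_along(bi)) {
              mx <- mixup_pair(xs[[j]], ys[j], xs[[perm[j]]], ys[perm[j]],
                               cfg$mixup_alpha_intra, cfg$mixup_alpha_inter)
              xs[[j]] <- mx$x; ys[j] <- mx$y
            }
          }
          x <- stack_batch(xs)
          fw <- classifier_forward(params, x, spec)
          gz <- (fw$p - ys) / length(ys)
          grads <- classifier_backward(params, spec, fw, gz)
          upd <- rmsprop_step(params, grads, state, lr = lr_ep)
          params <- upd$params; state <- upd$state
        }
        fwd <- classifier_forward(params, dev_x, spec)
        dl <- binary_cross_entropy(dev_y, fwd$p)
        history[ep] <- dl
        if (dl < best$loss) best <- list(loss = dl, params = params)
        if (verbose) message("fold ", f, " epoch ", ep,
                             " dev loss ", signif(dl, 4))
      }
      structure(list(params = best$params, spec = spec,
                     dev_loss = history, best_dev_loss = best$loss,
                     fold = f, test_subject = test_subject),
                class = "thioseg_classifier")
    })
  })
}

#' @export
print.thioseg_classifier <- function(x, ...) {
  cat("TAP classifier (fold ", x$fold, ", test subject ",
      x$test_subject, ")\n", sep = "")
  cat("  input ", x$spec$input_size, " px, ",
      length(x$spec$fire_module_widths), " fire modules, best dev loss ",
      signif(x$best_dev_loss, 4), "\n", sep = "")
  invisible(x)
}

#' Predict patch probabilities
#'
#' @param object a \code{thioseg_classifier}.
#' @param patches list of intensity matrices (0--255).
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.thioseg_classifier <- function(object, patches, ...) {
  spec <- object$spec
  prep <- function(m) {
    m <- m / 255
    if (nrow(m) != spec$input_size)
      m <- bilinear_resize(m, spec$input_size, spec$input_size)
    m
  }
  out <- numeric(length(patches))
  for (b0 in seq(1, length(patches), by = 16)) {
    bi <- b0:min(b0 + 15, length(patches))
    x <- stack_batch(lapply(patches[bi], prep))
    out[bi] <- classifier_forward(object$params, x, spec)$p
  }
  out
}

#' Extract a class activation map
#'
#' The raw map is \eqn{\sum_k \max(w_k, 0) F_k} over the final feature maps
#' with the head weights clamped at zero, so it is non-negative. It is
#' bilinearly upsampled to the input resolution and divided by its maximum
#' (a zero map stays zero).
#'
#' @param model a \code{thioseg_classifier}.
#' @param patch intensity matrix (0--255).
#' @return object of class \code{activation_map}: list \code{raw},
#'   \code{upsampled}, \code{prob}.
#' @export
extract_cam <- function(model, patch) {
  spec <- model$spec
  m <- patch / 255
  if (nrow(m) != spec$input_size)
    m <- bilinear_resize(m, spec$input_size, spec$input_size)
  fw <- classifier_forward(model$params, stack_batch(list(m)), spec)
  w <- pmax(model$params$head_w, 0)
  d <- dim(fw$cache$fmap)
  raw <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) raw <- raw + w[k] * fw$cache$fmap[, , k, 1]
  up <- bilinear_resize(raw, nrow(patch), ncol(patch))
  up <- pmax(up, 0)
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(list(raw = raw, upsampled = up, prob = fw$p),
            class = "activation_map")
}

#' Patch-level classification metrics
#'
#' Accuracy (proportion of correctly classified patches), precision, recall
#' and F1 from confusion counts. Ratios with zero denominators are reported
#' as \code{NA}, never as 0.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return named list of the four metrics.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  if (tp + tn + fp + fn == 0) stop("all counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = ratio(tp + tn, tp + tn + fp + fn),
       precision = ratio(tp, tp + fp),
       recall = ratio(tp, tp + fn),
       f1 = ratio(2 * tp, 2 * tp + fp + fn))
}
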