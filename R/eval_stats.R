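# Patient-wise group k-fold evaluation of the whole chain, PCA of the
# morphometric records, and ANOVA + Tukey group comparison of component
# scores.

#' Build a patient-wise fold plan
#'
#' One fold per subject: the fold's subject is the test case and every
#' other subject is available for training. Within each training run a
#' fraction of the training data is held out as a development set.
#'
#' @param subject_ids character vector of unique subject ids (>= 2).
#' @param dev_fraction development-set fraction within training folds.
#' @return object of class \code{fold_plan}.
#' @export
make_fold_plan <- function(subject_ids, dev_fraction = 0.10) {
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) < 2) stop("need at least 2 subjects")
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  structure(list(folds = as.list(subject_ids),
                 n_folds = length(subject_ids),
                 dev_fraction = dev_fraction),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("patient-wise fold plan:", x$n_folds, "folds (one test subject each),",
      "dev fraction", x$dev_fraction, "\n")
  invisible(x)
}

# every subject tested exactly once; any extra subject in the data that the
# plan never tests is an error
check_fold_plan <- function(plan, subjects) {
  stopifnot(inherits(plan, "fold_plan"))
  tested <- unlist(plan$folds)
  if (anyDuplicated(tested))
    stop("fold plan tests a subject more than once")
  missing <- setdiff(subjects, tested)
  if (length(missing))
    stop("subjects never tested by the fold plan: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Principal component analysis of morphometric records
#'
#' Columns are z-scored and the correlation structure decomposed; the
#' components are ordered by decreasing explained variance and the sign of
#' each loading column is fixed by making its largest-magnitude entry
#' positive.
#'
#' @param records data.frame of deposit records
#'   (\code{\link{assemble_records}}) or a plain numeric data.frame.
#' @param parameters columns to use (default the 19 analysis parameters).
#' @return object of class \code{morpho_pca}: \code{loadings},
#'   \code{explained_variance_ratio}, \code{scores}, \code{center},
#'   \code{scale}.
#' @export
run_pca <- function(records, parameters = NULL) {
  if (is.null(parameters))
    parameters <- intersect(morpho_parameters(), names(records))
  x <- as.matrix(records[, parameters, drop = FALSE])
  if (nrow(x) < 2) stop("need at least 2 records")
  if (anyNA(x)) stop("missing values in parameters: ",
                     paste(parameters[colSums(is.na(x)) > 0],
                           collapse = ", "))
  vars <- apply(x, 2, var)
  if (any(vars == 0))
    stop("zero-variance column(s): ",
         paste(parameters[vars == 0], collapse = ", "))
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = rot, explained_variance_ratio = evr,
                 scores = scores, center = pc$center, scale = pc$scale),
            class = "morpho_pca")
}

#' @export
print.morpho_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat("morphometric PCA:", ncol(x$loadings), "components;",
      "top-3 explained variance",
      paste(sprintf("%.1f%%", 100 * evr[seq_len(min(3, length(evr)))]),
            collapse = ", "),
      sprintf("(cumulative %.1f%%)\n",
              100 * sum(evr[seq_len(min(3, length(evr)))])))
  invisible(x)
}

#' Compare principal-component scores across groups
#'
#' One-way ANOVA over the region x dementia groups followed by Tukey's HSD
#' (Tukey-Kramer for unequal group sizes).
#'
#' @param scores numeric vector (one PC score per deposit).
#' @param groups factor or character of group membership.
#' @return object of class \code{group_comparison}: \code{F}, \code{p},
#'   \code{df}, \code{tukey} (data.frame with difference, confidence
#'   bounds and adjusted p per pair).
#' @export
compare_groups <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  cnt <- table(groups)
  if (any(cnt < 2)) stop("group(s) with fewer than 2 observations: ",
                         paste(names(cnt)[cnt < 2], collapse = ", "))
  d <- data.frame(score = as.numeric(scores), group = groups)
  fit <- aov(score ~ group, data = d)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
                 df = sm[["Df"]], tukey = tukey,
                 groups = levels(groups)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA over %d groups: F = %.3f, p = %.3g\n",
              length(x$groups), x$F, x$p))
  sig <- x$tukey[x$tukey$p_adj < 0.05, , drop = FALSE]
  cat("Tukey HSD:", nrow(sig), "of", nrow(x$tukey),
      "pairs significant at 0.05\n")
  invisible(x)
}

#' Desk-scale pipeline configuration
#'
#' Bundles the reduced-resolution profile used for CPU-scale runs:
#' 512 px scenes, 128 px patches, a 108 -> 68 px segmenter tile, and the
#' postprocessing minimum size scaled from the full-resolution default
#' (3500 px at 1920 px width) by the squared resolution factor.
#'
#' @param seed base seed.
#' @return config list consumed by \code{\link{evaluate_pipeline}}.
#' @export
desk_profile <- function(seed = 1L) {
  list(patch_size = 128, min_positive_area = 50,
       classifier_spec = classifier_spec(input_size = 128),
       classifier_config = list(epochs = 48, batch_size = 16, lr = 1.5e-3,
                                seed = seed),
       max_train_patches = 256,
       segmenter_spec = segmenter_spec(input_tile = 108, depth = 2,
                                       base_channels = 8),
       segmenter_config = list(epochs = 24, batch_size = 16,
                               batches_per_epoch = 7, lr = 1e-3,
                               seed = seed),
       loss_params = list(lambda = 0.5, delta = 0.6, gamma = 0.5),
       t_fg = 0.5, t_bg = 0.2, dilation_radius = 6, context_margin = 12,
       min_object_area = 20,
       post_threshold = 0.5, post_min_size = round(3500 * (512 / 1920)^2),
       vascular_exclusion = TRUE, vascular_max_extension = 12,
       icf_sigma = 13, icf_median = 15,
       use_preprocess = TRUE, seed = seed)
}

preprocess_images <- function(images, cfg) {
  field <- estimate_icf(images$train, gaussian_sigma = cfg$icf_sigma,
                        median_size = cfg$icf_median)
  corr <- function(img) {
    out <- subtract_background(apply_icf(img, field))
    clamp(out$centered, 0, 255)
  }
  list(train = lapply(images$train, corr),
       test = lapply(images$test, corr), field = field)
}

#' Run the full weakly supervised chain with patient-wise folds
#'
#' For each requested fold: illumination-correct and background-center all
#' scenes with a training-fold ICF, derive labeled patches, train the TAP
#' classifier, extract CAMs of positive training patches, build object and
#' background banks, train the segmenter on soft copy-paste composites, and
#' evaluate tiled predictions on the held-out subject's scenes against
#' ground truth. Fold isolation is machine-checked at the classifier, bank
#' and segmenter stages.
#'
#' @param dataset cohort list from \code{\link{generate_cohort}}.
#' @param fold_plan a \code{\link{make_fold_plan}} over the cohort's
#'   subjects.
#' @param config a \code{\link{desk_profile}}-style list.
#' @param folds fold indices to run (default all).
#' @param verbose progress messages.
#' @return object of class \code{pipeline_report}: per-fold rows of the 4
#'   classification and 11 segmentation metrics plus the vessel
#'   false-positive rate, and their means.
#' @export
evaluate_pipeline <- function(dataset, fold_plan, config = desk_profile(),
                              folds = NULL, verbose = FALSE) {
  subjects_all <- vapply(dataset, function(d) as.character(d$meta$subject_id),
                         character(1))
  check_fold_plan(fold_plan, unique(subjects_all))
  if (is.null(folds)) folds <- seq_len(fold_plan$n_folds)
  fold_rows <- list()
  for (f in folds) {
    test_subject <- fold_plan$folds[[f]]
    is_test <- subjects_all %in% test_subject
    if (all(is_test) || !any(is_test))
      stop("fold ", f, " has an empty train or test partition")
    train_scenes <- dataset[!is_test]
    test_scenes <- dataset[is_test]
    if (verbose) message("fold ", f, ": test subject ", test_subject)

    imgs <- list(train = lapply(train_scenes, `[[`, "image"),
                 test = lapply(test_scenes, `[[`, "image"))
    if (isTRUE(config$use_preprocess)) {
      imgs <- preprocess_images(imgs, config)
    }

    patch_of <- function(scenes, corrected) {
      out <- list()
      for (i in seq_along(scenes)) {
        ps <- derive_patches(corrected[[i]], scenes[[i]]$gt,
                             patch_size = config$patch_size,
                             min_positive_area = config$min_positive_area,
                             meta = scenes[[i]]$meta)
        out <- c(out, ps)
      }
      out
    }
    tr_patches <- patch_of(train_scenes, imgs$train)
    te_patches <- patch_of(test_scenes, imgs$test)
    tr_labels <- vapply(tr_patches, `[[`, integer(1), "label")
    tr_subj <- vapply(tr_patches, function(p)
      as.character(p$meta$subject_id), character(1))
    if (any(tr_subj %in% test_subject))
      stop("fold leakage: test-subject patches in the training set")

    # balanced subsample for the classifier
    keep <- with_seed(config$seed + 17 * f, {
      pos <- which(tr_labels == 1); neg <- which(tr_labels == 0)
      n_half <- min(length(pos), length(neg),
                    ceiling(config$max_train_patches / 2))
      c(sample(pos, n_half), sample(neg, n_half))
    })
    cls <- train_classifier(lapply(tr_patches[keep], `[[`, "image"),
                            tr_labels[keep], tr_subj[keep], fold_plan,
                            config$classifier_spec,
                            config$classifier_config, folds = f)[[1]]

    te_labels <- vapply(te_patches, `[[`, integer(1), "label")
    te_prob <- predict(cls, lapply(te_patches, `[[`, "image"))
    te_pred <- as.integer(te_prob >= 0.5)
    cm <- classification_metrics(tp = sum(te_pred == 1 & te_labels == 1),
                                 tn = sum(te_pred == 0 & te_labels == 0),
                                 fp = sum(te_pred == 1 & te_labels == 0),
                                 fn = sum(te_pred == 0 & te_labels == 1))

    # banks from training patches only
    pos_idx <- which(tr_labels == 1)
    cams <- vector("list", length(tr_patches))
    for (i in pos_idx) cams[[i]] <- extract_cam(cls, tr_patches[[i]]$image)
    banks <- with_seed(config$seed + 53L * f,
                       build_banks(tr_patches, cams, tr_labels, tr_subj,
                                   t_fg = config$t_fg, t_bg = config$t_bg,
                                   dilation_radius = config$dilation_radius,
                                   context_margin = config$context_margin,
                                   min_area = config$min_object_area))
    if (verbose) message("  banks: ", length(banks$objects), " objects, ",
                         length(banks$backgrounds), " backgrounds")
    if (length(banks$objects) == 0)
      stop("object bank is empty; CAMs yielded no components in fold ", f)

    seg_cfg <- config$segmenter_config
    seg_cfg$seed <- config$seed + 31L * f
    seg <- train_segmenter(banks, config$segmenter_spec,
                           loss_params = config$loss_params,
                           config = seg_cfg,
                           train_subjects = setdiff(unique(subjects_all),
                                                    test_subject))

    conf <- list(tp = 0, tn = 0, fp = 0, fn = 0)
    vessel_fp <- 0; vessel_px <- 0
    for (i in seq_along(test_scenes)) {
      prob <- predict_full(seg, imgs$test[[i]])
      pm <- postprocess(prob, threshold = config$post_threshold,
                        min_size = config$post_min_size)
      if (isTRUE(config$vascular_exclusion))
        pm <- exclude_vascular(pm, imgs$test[[i]],
                               max_extension = config$vascular_max_extension)
      gt <- test_scenes[[i]]$gt
      cc <- mask_confusion(pm$binary, gt$parenchymal_mask)
      conf <- Map(`+`, conf, cc)
      vessel_fp <- vessel_fp + sum(pm$binary & gt$vessel_mask)
      vessel_px <- vessel_px + sum(gt$vessel_mask)
    }
    sm <- do.call(segmentation_metrics, conf)
    row <- c(list(fold = f), setNames(cm, paste0("cls_", names(cm))), sm,
             list(vessel_fp_rate = if (vessel_px > 0) vessel_fp / vessel_px
                  else NA_real_))
    fold_rows[[length(fold_rows) + 1]] <- row
    if (verbose) message(sprintf("  dice %.3f, vessel FP rate %.4f",
                                 sm$dice, vessel_fp / max(vessel_px, 1)))
  }
  tab <- as.data.frame(do.call(rbind, lapply(fold_rows, function(r)
    vapply(r, as.numeric, numeric(1)))))
  means <- colMeans(tab[, -1, drop = FALSE], na.rm = TRUE)
  structure(list(per_fold = tab, mean = means), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("weakly supervised pipeline report over", nrow(x$per_fold),
      "fold(s)\n")
  cat(sprintf("  mean patch accuracy %.3f, dice %.3f, jaccard %.3f, vessel FP rate %.4f\n",
              x$mean[["cls_accuracy"]], x$mean[["dice"]], x$mean[["jaccard"]],
              x$mean[["vessel_fp_rate"]]))
  invisible(x)
}
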