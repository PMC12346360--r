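test_that("empty scene is the vignetted constant background", {
  sp <- scene_spec(height = 64, width = 64, n_plaques = 0, n_vessels = 0,
                   noise_sd = 0, background_level = 40,
                   vignette_strength = 0.3, seed = 3)
  sc <- generate_scene(sp)
  expect_equal(sum(sc$gt$parenchymal_mask), 0)
  expect_equal(sum(sc$gt$vessel_mask), 0)
  v <- thioseg:::vignette_field(64, 64, 0.3)
  expect_equal(sc$image, quantize8(40 * v))
})

test_that("identical spec and seed reproduce the scene bit for bit", {
  sp <- scene_spec(height = 160, width = 160, n_plaques = 3, n_vessels = 1,
                   seed = 11)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$gt, b$gt)
})

test_that("instance labels agree with an independent flood-fill oracle", {
  sp <- scene_spec(height = 256, width = 256, n_plaques = 5, n_vessels = 0,
                   seed = 21)
  sc <- generate_scene(sp)
  labs <- sort(unique(as.vector(sc$gt$instance_labels)))
  expect_equal(labs, 0:5)
  oracle <- flood_fill_components(sc$gt$parenchymal_mask)
  expect_equal(max(oracle), 5)
  # each instance is exactly one oracle component
  for (k in 1:5) {
    comp <- oracle[sc$gt$instance_labels == k]
    expect_length(unique(comp), 1)
  }
  # mask/instance consistency
  expect_true(all((sc$gt$instance_labels > 0) == sc$gt$parenchymal_mask))
  expect_false(any(sc$gt$vessel_mask & sc$gt$parenchymal_mask))
})

test_that("ground truth and instances stay consistent over many scenes", {
  for (s in 1:20) {
    sp <- scene_spec(height = 128, width = 128, n_plaques = sample(0:3, 1),
                     n_vessels = sample(0:2, 1),
                     core_radius_range = c(6, 10), seed = 100 + s)
    sc <- generate_scene(sp)
    expect_true(all((sc$gt$instance_labels > 0) == sc$gt$parenchymal_mask))
    expect_false(any(sc$gt$vessel_mask & sc$gt$parenchymal_mask))
    oracle <- flood_fill_components(sc$gt$parenchymal_mask)
    expect_equal(max(oracle), max(sc$gt$instance_labels))
  }
})

test_that("impossible placement errors out naming the constraint", {
  sp <- scene_spec(height = 96, width = 96, n_plaques = 40,
                   core_radius_range = c(12, 14), seed = 5)
  expect_error(generate_scene(sp), "without overlap")
})

test_that("cohort structure maps scenes to subjects", {
  subjects <- data.frame(subject_id = paste0("P", 1:7),
                         region = rep(c("parietal", "temporal"), length.out = 7),
                         dementia = rep(c("yes", "no"), length.out = 7))
  ch <- cohort_spec(subjects, scenes_per_subject = 4,
                    base = scene_spec(height = 96, width = 96, n_plaques = 2,
                                      n_vessels = 0,
                                      core_radius_range = c(5, 8)),
                    seed = 2)
  ds <- generate_cohort(ch)
  expect_length(ds, 28)
  subj <- vapply(ds, function(d) d$meta$subject_id, character(1))
  expect_equal(as.vector(table(subj)), rep(4, 7))
  expect_error(cohort_spec(subjects[0, ]), "empty")
  expect_error(cohort_spec(rbind(subjects, subjects[1, ])), "duplicate")
})

test_that("group effects are absent under zero shifts and recovered when planted", {
  mk_cohort <- function(effects, seed) {
    subjects <- data.frame(subject_id = paste0("Q", 1:8),
                           region = "parietal",
                           dementia = rep(c("yes", "no"), each = 4))
    cohort_spec(subjects, scenes_per_subject = 6,
                base = scene_spec(height = 256, width = 256, n_plaques = 12,
                                  n_vessels = 0, core_radius_range = c(5, 9),
                                  noise_sd = 2),
                group_effects = effects, subject_intensity_sd = 0,
                seed = seed)
  }
  radii_by_group <- function(ds) {
    out <- list(yes = c(), no = c())
    for (d in ds) {
      areas <- table(d$gt$instance_labels[d$gt$instance_labels > 0])
      out[[d$meta$dementia]] <- c(out[[d$meta$dementia]],
                                  log10(as.numeric(areas)))
    }
    out
  }
  null_ds <- generate_cohort(mk_cohort(list(size_log10 = numeric()), 7))
  g0 <- radii_by_group(null_ds)
  expect_gte(length(g0$yes), 250)
  expect_gt(t.test(g0$yes, g0$no)$p.value, 0.01)

  eff_ds <- generate_cohort(mk_cohort(
    list(size_log10 = c(parietal.yes = 0.15)), 7))
  g1 <- radii_by_group(eff_ds)
  # a +0.15 shift of mean log10 radius doubles in log10 area units
  shift <- mean(g1$yes) - mean(g1$no)
  expect_lt(abs(shift - 0.30), 0.06)
})

test_that("patch labels follow the parenchymal area rule and ignore vessels", {
  sp <- scene_spec(height = 128, width = 128, n_plaques = 0, n_vessels = 0,
                   noise_sd = 0, seed = 1)
  sc <- generate_scene(sp)
  ps <- derive_patches(sc$image, sc$gt, patch_size = 64,
                       min_positive_area = 50)
  expect_true(all(vapply(ps, `[[`, integer(1), "label") == 0L))

  # a vessel-only scene never yields positive patches
  spv <- scene_spec(height = 128, width = 128, n_plaques = 0, n_vessels = 2,
                    seed = 8)
  scv <- generate_scene(spv)
  expect_gt(sum(scv$gt$vessel_mask), 0)
  psv <- derive_patches(scv$image, scv$gt, patch_size = 64,
                        min_positive_area = 50)
  expect_true(all(vapply(psv, `[[`, integer(1), "label") == 0L))
  # oracle: label equals mask-intersection area rule
  for (p in psv)
    expect_identical(p$label,
                     as.integer(sum(scv$gt$parenchymal_mask[
                       p$row:(p$row + 63), p$col:(p$col + 63)]) >= 50))

  # a patch centered on a large plaque is positive
  spp <- scene_spec(height = 128, width = 128, n_plaques = 1, n_vessels = 0,
                    core_radius_range = c(14, 16), seed = 10)
  scp <- generate_scene(spp)
  expect_gt(sum(scp$gt$parenchymal_mask), 2000)
  psp <- derive_patches(scp$image, scp$gt, patch_size = 128,
                        min_positive_area = 100)
  expect_equal(psp[[1]]$label, 1L)
  expect_error(derive_patches(scp$image, scp$gt, patch_size = 200, 50),
               "exceeds")
})
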