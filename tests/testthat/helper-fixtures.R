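# In-code fixtures shared across test files.

disc_mask <- function(r, pad = 6) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")) <= r
}

sierpinski_carpet <- function(levels = 6) {
  n <- 3^levels
  i <- 0:(n - 1)
  dig <- sapply(seq_len(levels) - 1, function(k) (i %/% 3^k) %% 3)
  bad <- matrix(FALSE, n, n)
  for (k in seq_len(levels))
    bad <- bad | outer(dig[, k] == 1, dig[, k] == 1, "&")
  !bad
}

# a tiny synthetic bank: bright blob objects and textured backgrounds,
# enough to exercise composition and segmenter training
tiny_banks <- function(n_obj = 6, n_bg = 6, bg_size = 72, seed = 1) {
  set.seed(seed)
  objects <- lapply(seq_len(n_obj), function(i) {
    r <- sample(5:8, 1)
    m <- disc_mask(r, pad = 4)
    crop <- matrix(30 + rnorm(length(m), 0, 4), nrow(m))
    crop[m] <- 170 + rnorm(sum(m), 0, 10)
    list(crop = quantize8(crop), mask = m,
         contour = thioseg:::trace_boundary(m),
         bbox = c(1, 1, nrow(m), ncol(m)),
         source = list(subject = paste0("S", 1 + i %% 2), patch = i,
                       component = 1))
  })
  backgrounds <- lapply(seq_len(n_bg), function(i) {
    img <- quantize8(matrix(30 + rnorm(bg_size^2, 0, 4), bg_size))
    structure(list(image = img,
                   removal_mask = matrix(FALSE, bg_size, bg_size),
                   origin = "originally-negative",
                   source = list(subject = paste0("S", 1 + i %% 2),
                                 patch = 100 + i)),
              class = "background_scene")
  })
  list(objects = objects, backgrounds = backgrounds)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
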