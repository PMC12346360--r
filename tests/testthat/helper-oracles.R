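# Independent oracles, deliberately implemented with plain loops and base R
# so they share no code path with the package internals they check.

# BFS flood fill, 8-connectivity (indexed queue; pixels packed as r + h*c)
flood_fill_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  queue <- integer(h * w)
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0) next
    nxt <- nxt + 1L
    lab[r0, c0] <- nxt
    queue[1] <- r0 + h * (c0 - 1L)
    head_i <- 1L; tail_i <- 1L
    while (head_i <= tail_i) {
      p <- queue[head_i]; head_i <- head_i + 1L
      pr <- ((p - 1L) %% h) + 1L
      pc <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- pr + dr; c <- pc + dc
        if (r < 1 || r > h || c < 1 || c > w) next
        if (mask[r, c] && lab[r, c] == 0) {
          lab[r, c] <- nxt
          tail_i <- tail_i + 1L
          queue[tail_i] <- r + h * (c - 1L)
        }
      }
    }
  }
  lab
}

# term-by-term summation of the asymmetric unified focal loss
ufl_oracle <- function(p1, g1, ignore = NULL, lambda = 0.5, delta = 0.6,
                       gamma = 0.5, eps = 1e-7) {
  p1 <- as.numeric(p1); g1 <- as.numeric(g1)
  keep <- if (is.null(ignore)) rep(TRUE, length(p1)) else !as.logical(ignore)
  s_maf <- 0; N <- 0
  a1 <- 0; a0 <- 0; fns <- 0; fps <- 0
  for (i in seq_along(p1)) {
    if (!keep[i]) next
    N <- N + 1
    p <- min(max(p1[i], eps), 1 - eps)
    if (g1[i] == 1) {
      s_maf <- s_maf + delta * (-log(p))
      a1 <- a1 + p
      fns <- fns + (1 - p)
    } else {
      s_maf <- s_maf + (1 - delta) * (1 - (1 - p))^gamma * (-log(1 - p))
      a0 <- a0 + (1 - p)
      fps <- fps + p
    }
  }
  b <- delta * fns + (1 - delta) * fps
  mti1 <- a1 / (a1 + b)
  mti0 <- a0 / (a0 + b)
  lambda * (s_maf / N) +
    (1 - lambda) * ((1 - mti0) + (1 - mti1)^(1 - gamma))
}

tap_oracle <- function(m, tau) {
  v <- c()
  for (x in m) if (x > tau) v <- c(v, x)
  if (length(v) == 0) 0 else sum(v) / length(v)
}

# one-way ANOVA from first principles
anova_oracle <- function(scores, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  gm <- sapply(gl, function(g) mean(scores[groups == g]))
  n <- sapply(gl, function(g) sum(groups == g))
  grand <- mean(scores)
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(sapply(gl, function(g) {
    v <- scores[groups == g]; sum((v - mean(v))^2)
  }))
  dfb <- length(gl) - 1
  dfw <- length(scores) - length(gl)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE),
       mse = ssw / dfw, n = n, means = gm, dfw = dfw)
}

# Tukey-Kramer adjusted p for one pair, from the studentized range
tukey_oracle_p <- function(scores, groups, g1, g2) {
  a <- anova_oracle(scores, groups)
  k <- length(unique(groups))
  se <- sqrt(a$mse / 2 * (1 / a$n[[g1]] + 1 / a$n[[g2]]))
  q <- abs(a$means[[g1]] - a$means[[g2]]) / se
  ptukey(q, k, a$dfw, lower.tail = FALSE)
}

hausdorff_points <- function(a, b) {
  d <- as.matrix(dist(rbind(a, b)))
  ab <- d[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b)), drop = FALSE]
  max(max(apply(ab, 1, min)), max(apply(ab, 2, min)))
}
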