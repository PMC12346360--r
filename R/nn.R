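# Shared building blocks for the two small convolutional networks: weight
# initialization, activations and first-order optimizers. Tensors are R
# arrays with dim (height, width, channels, batch); the convolution and
# pooling kernels live in src/nn_ops.cpp.

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(g, y) {           # y is the forward output
  g[y <= 0] <- 0
  g
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# parameter containers are flat named lists of arrays; optimizer state
# mirrors their structure
opt_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

rmsprop_step <- function(params, grads, state, lr = 5e-4, rho = 0.9,
                         eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state$v[[nm]]) + eps)
  }
  list(params = params, state = state)
}

# stack a list of HxW matrices into a (H, W, 1, N) array
stack_batch <- function(mats) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), dim = c(h, w, 1, length(mats)))
}

conv_fwd <- function(x, w, b, pad = 0) conv2d_fwd(x, w, b, as.integer(pad))
conv_bwd <- function(x, w, gy, pad = 0) conv2d_bwd(x, w, gy, as.integer(pad))

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

crop_center <- function(x, target_h, target_w) {
  d <- dim(x)
  r0 <- (d[1] - target_h) %/% 2
  c0 <- (d[2] - target_w) %/% 2
  x[r0 + seq_len(target_h), c0 + seq_len(target_w), , , drop = FALSE]
}
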