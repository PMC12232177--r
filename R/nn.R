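# Minimal multilayer-perceptron machinery (dense layers, ReLU or shifted
# softplus, Adam optimizer). The CV networks are small enough that plain
# BLAS-backed matrix code is the right tool; layers store weights as
# (input x output) matrices so a batch forward pass is X %*% W + b.

nn_init <- function(widths, act = c("relu", "ssp")) {
  act <- match.arg(act)
  L <- length(widths) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    nin <- widths[l]
    nout <- widths[l + 1L]
    # He-style scaling; sensible for both activations at these depths
    W[[l]] <- matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
    b[[l]] <- numeric(nout)
  }
  structure(list(W = W, b = b, act = act, widths = widths), class = "opescv_mlp")
}

nn_act <- function(x, act) {
  if (act == "relu") return(pmax(x, 0))
  # shifted softplus log(1 + e^x) - log 2, stable for large |x|
  pmax(x, 0) + log1p(exp(-abs(x))) - log(2)
}

nn_dact <- function(x, act) {
  if (act == "relu") return((x > 0) * 1)
  1 / (1 + exp(-x))
}

# forward pass; returns list of post-activations H (H[[1]] = input) and
# pre-activations Z per layer; the final layer is linear
nn_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  Z <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(H[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    H[[l + 1L]] <- if (l == L) Z[[l]] else nn_act(Z[[l]], net$act)
  }
  list(H = H, Z = Z)
}

# backward pass from d(loss)/d(output); returns parameter gradients and
# optionally the gradient w.r.t. the input batch
nn_backward <- function(net, cache, Gout, input_grad = FALSE) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- Gout
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * nn_dact(cache$Z[[l - 1L]], net$act)
    } else if (input_grad) {
      delta <- delta %*% t(net$W[[1L]])
    }
  }
  list(gW = gW, gb = gb, gX = if (input_grad) delta else NULL)
}

adam_init <- function(net) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero(net$W), vW = zero(net$W), mb = zero(net$b), vb = zero(net$b),
       t = 0L)
}

adam_step <- function(net, state, grads, lr, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    g <- grads$gW[[l]] + 2 * l2 * net$W[[l]]
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * g
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * g^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    g <- grads$gb[[l]]
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * g
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * g^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}
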