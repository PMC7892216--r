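# Dense feed-forward machinery for the seven-subnet hierarchical network.
# Everything here is plain matrix algebra on small layers; subnets are lists
# of (W, b, act) layers and the graph wiring is hard-coded in hnn_forward /
# hnn_backward below.

.SELU_LAMBDA <- 1.0507009873554805
.SELU_ALPHA <- 1.6732632423543772

act_fun <- function(name, z) {
  switch(name,
    linear = z,
    relu = pmax(z, 0),
    elu = ifelse(z > 0, z, expm1(z)),
    selu = .SELU_LAMBDA * ifelse(z > 0, z, .SELU_ALPHA * expm1(z)),
    softplus = {
      # numerically stable log(1 + exp(z))
      out <- pmax(z, 0) + log1p(exp(-abs(z)))
      out
    },
    stop_input("unknown activation '", name, "'")
  )
}

# derivative of the activation, given both pre-activation z and output a
act_grad <- function(name, z, a) {
  switch(name,
    linear = array(1, dim = dim(z)),
    relu = (z > 0) + 0,
    elu = ifelse(z > 0, 1, a + 1),
    selu = ifelse(z > 0, .SELU_LAMBDA, a + .SELU_LAMBDA * .SELU_ALPHA),
    softplus = 1 / (1 + exp(-z)),
    stop_input("unknown activation '", name, "'")
  )
}

hnn_activations <- function() c("selu", "elu", "relu", "softplus", "linear")

# Allocate a subnet: list of layers, each list(W, b, act). Weights are drawn
# uniform on init_range from the current RNG stream; biases start at zero.
subnet_init <- function(sizes, acts, init_range = c(-0.05, 0.05)) {
  nl <- length(sizes) - 1L
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    fi <- sizes[l]; fo <- sizes[l + 1L]
    layers[[l]] <- list(
      W = matrix(stats::runif(fi * fo, init_range[1L], init_range[2L]), fi, fo),
      b = numeric(fo),
      act = acts[l]
    )
  }
  layers
}

# Forward pass through one subnet. Returns list(out, cache) where cache holds
# the layer inputs and pre-activations needed by the backward pass.
subnet_forward <- function(layers, X) {
  nl <- length(layers)
  Ains <- vector("list", nl)
  Zs <- vector("list", nl)
  A <- X
  n <- nrow(X)
  for (l in seq_len(nl)) {
    ly <- layers[[l]]
    Ains[[l]] <- A
    Z <- A %*% ly$W
    Z <- Z + rep(ly$b, each = n)
    Zs[[l]] <- Z
    A <- act_fun(ly$act, Z)
  }
  list(out = A, Ain = Ains, Z = Zs)
}

# Backward pass through one subnet given the gradient of the loss w.r.t. its
# output. Returns list(gW, gb, dX).
subnet_backward <- function(layers, cache, dOut) {
  nl <- length(layers)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  dA <- dOut
  for (l in rev(seq_len(nl))) {
    ly <- layers[[l]]
    Z <- cache$Z[[l]]
    Aout <- if (l == nl) NULL else cache$Ain[[l + 1L]]
    if (is.null(Aout)) Aout <- act_fun(ly$act, Z)  # only hit when nl layer output not cached
    dZ <- dA * act_grad(ly$act, Z, Aout)
    gW[[l]] <- crossprod(cache$Ain[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, ly$W)
  }
  list(gW = gW, gb = gb, dX = dA)
}

# Full-graph forward. X is an n x 10 matrix in canonical feature order
# (r_nod | r_ipv r_bpv | g_ipv g_bpv | b_ipv b_bpv | r_it g_it b_it).
# Wiring: O1..O5 consume the five input groups, O6 = f(O2, O3, O4),
# O7 = f(O1, O5, O6); the O7 output is the dose estimate H.
hnn_forward <- function(subnets, X, cache = FALSE) {
  f1 <- subnet_forward(subnets$O1, X[, 1L, drop = FALSE])
  f2 <- subnet_forward(subnets$O2, X[, 2:3, drop = FALSE])
  f3 <- subnet_forward(subnets$O3, X[, 4:5, drop = FALSE])
  f4 <- subnet_forward(subnets$O4, X[, 6:7, drop = FALSE])
  f5 <- subnet_forward(subnets$O5, X[, 8:10, drop = FALSE])
  x6 <- cbind(f2$out, f3$out, f4$out)
  f6 <- subnet_forward(subnets$O6, x6)
  x7 <- cbind(f1$out, f5$out, f6$out)
  f7 <- subnet_forward(subnets$O7, x7)
  if (!cache) return(drop(f7$out))
  list(out = drop(f7$out),
       caches = list(O1 = f1, O2 = f2, O3 = f3, O4 = f4, O5 = f5, O6 = f6, O7 = f7))
}

# Full-graph backward. dH is the gradient of the loss w.r.t. the O7 output
# (length n). Returns per-subnet weight/bias gradients in the same shape as
# the subnets themselves.
hnn_backward <- function(subnets, fw, dH) {
  dH <- matrix(dH, ncol = 1L)
  b7 <- subnet_backward(subnets$O7, fw$caches$O7, dH)
  d1 <- b7$dX[, 1L, drop = FALSE]
  d5 <- b7$dX[, 2L, drop = FALSE]
  d6 <- b7$dX[, 3L, drop = FALSE]
  b6 <- subnet_backward(subnets$O6, fw$caches$O6, d6)
  b2 <- subnet_backward(subnets$O2, fw$caches$O2, b6$dX[, 1L, drop = FALSE])
  b3 <- subnet_backward(subnets$O3, fw$caches$O3, b6$dX[, 2L, drop = FALSE])
  b4 <- subnet_backward(subnets$O4, fw$caches$O4, b6$dX[, 3L, drop = FALSE])
  b1 <- subnet_backward(subnets$O1, fw$caches$O1, d1)
  b5 <- subnet_backward(subnets$O5, fw$caches$O5, d5)
  list(O1 = b1, O2 = b2, O3 = b3, O4 = b4, O5 = b5, O6 = b6, O7 = b7)
}

adam_init <- function(subnets) {
  lapply(subnets, function(layers) lapply(layers, function(ly) {
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  }))
}

# One Adam update over every parameter; returns list(subnets, state).
adam_step <- function(subnets, grads, state, t,
                      lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  lr_t <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (sn in names(subnets)) {
    layers <- subnets[[sn]]
    for (l in seq_along(layers)) {
      st <- state[[sn]][[l]]
      gW <- grads[[sn]]$gW[[l]]
      gb <- grads[[sn]]$gb[[l]]
      st$mW <- beta1 * st$mW + (1 - beta1) * gW
      st$vW <- beta2 * st$vW + (1 - beta2) * gW * gW
      st$mb <- beta1 * st$mb + (1 - beta1) * gb
      st$vb <- beta2 * st$vb + (1 - beta2) * gb * gb
      layers[[l]]$W <- layers[[l]]$W - lr_t * st$mW / (sqrt(st$vW) + eps)
      layers[[l]]$b <- layers[[l]]$b - lr_t * st$mb / (sqrt(st$vb) + eps)
      state[[sn]][[l]] <- st
    }
    subnets[[sn]] <- layers
  }
  list(subnets = subnets, state = state)
}
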