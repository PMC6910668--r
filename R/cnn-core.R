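# Internal CNN engine.
#
# Activations are (channels x H*W*batch) matrices with spatial index
# s = h + H*(w-1) + H*W*(b-1). The 3x3 same-padded convolutions, the
# 2x2/stride-2 max pooling, and the fused batchnorm+ReLU run in compiled
# code (src/conv_ops.cpp); the linear head and softmax stay in R.
# Convolution weights are (C_out x 9*C_in) matrices whose columns are
# ordered c + C_in*(dy + 3*dx).

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# forward pass through the three conv blocks and the linear head; with
# keep = TRUE every intermediate needed for backprop is retained.
ssann_forward <- function(model, X, B, training = FALSE, keep = FALSE) {
  cfg <- model$config
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  A <- X
  caches <- if (keep) vector("list", 3L) else NULL
  for (l in 1:3) {
    p <- model$params[[paste0("conv", l)]]
    if (keep) {
      Pt <- cpp_im2col3x3(A, H, W, B)
      conv <- cpp_conv_patches(Pt, p$W, p$b)
    } else {
      Pt <- NULL
      conv <- cpp_conv3x3_fwd(A, p$W, p$b, H, W, B)
    }
    if (training) {
      st <- cpp_row_stats(conv)
      mu <- as.numeric(st$mean); v <- as.numeric(st$var)
      model$state[[l]]$mean <- (1 - BN_MOMENTUM) * model$state[[l]]$mean +
        BN_MOMENTUM * mu
      model$state[[l]]$var <- (1 - BN_MOMENTUM) * model$state[[l]]$var +
        BN_MOMENTUM * v
    } else {
      mu <- model$state[[l]]$mean; v <- model$state[[l]]$var
    }
    inv <- 1 / sqrt(v + BN_EPS)
    R <- cpp_bnrelu_fwd(conv, p$gamma, p$beta, mu, inv)
    pl <- cpp_maxpool_fwd(R, H, W, B)
    if (keep) {
      caches[[l]] <- list(Pt = Pt, conv = conv, relu_out = R,
                          C_in = nrow(A), mu = mu, inv = inv,
                          amax = pl$amax, R_cols = ncol(R), H = H, W = W)
    }
    A <- pl$out
    H <- H %/% 2L; W <- W %/% 2L
  }
  flat <- matrix(A, nrow = nrow(A) * H * W, ncol = B)
  logits <- model$params$fc$W %*% flat + model$params$fc$b
  list(logits = logits, flat = flat, caches = caches, model = model,
       out_shape = c(nrow(A), H, W))
}

ssann_backward <- function(model, fw, y, B) {
  probs <- softmax_cols(fw$logits)
  loss <- -mean(log(pmax(probs[cbind(y, seq_len(B))], 1e-12)))
  dlogits <- probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B
  grads <- list(fc = list(W = tcrossprod(dlogits, fw$flat),
                          b = rowSums(dlogits)))
  dflat <- crossprod(model$params$fc$W, dlogits)
  dA <- matrix(dflat, nrow = fw$out_shape[1])
  for (l in 3:1) {
    ca <- fw$caches[[l]]
    p <- model$params[[paste0("conv", l)]]
    dR <- cpp_maxpool_bwd(dA, ca$amax, nrow(dA), ca$R_cols)
    bnb <- cpp_bnrelu_bwd(dR, ca$conv, ca$relu_out, p$gamma, ca$mu, ca$inv)
    wg <- cpp_conv3x3_wgrad(ca$Pt, bnb$dA)
    grads[[paste0("conv", l)]] <- list(W = wg$dW, b = as.numeric(wg$db),
                                       gamma = as.numeric(bnb$dgamma),
                                       beta = as.numeric(bnb$dbeta))
    if (l > 1) {
      # data gradient of a same-padded conv = conv of dOut with the
      # spatially flipped, channel-transposed kernel
      dA <- cpp_conv3x3_fwd(bnb$dA, flip_kernel(p$W, ca$C_in),
                            numeric(ca$C_in), ca$H, ca$W, B)
    }
  }
  list(loss = loss, grads = grads)
}

flip_kernel <- function(W, C_in) {
  C_out <- nrow(W)
  Wb <- matrix(0, C_in, 9L * C_out)
  for (dy in 0:2) for (dx in 0:2) {
    k <- dy + 3L * dx
    kf <- (2L - dy) + 3L * (2L - dx)
    Wb[, C_out * kf + seq_len(C_out)] <-
      t(W[, C_in * k + seq_len(C_in), drop = FALSE])
  }
  Wb
}
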