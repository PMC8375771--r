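# Internal numerical engine for the eight-stage surrogate classifier.
#
# Batches of images are D x n matrices (one column per image). Internally
# activations use a channel-fastest flattening (index = c + C*((h-1) +
# H*(w-1))) so that the im2col product of a 3x3 same-convolution can be
# reshaped between stages without transposition and the inner loops run in
# BLAS. User-facing image arrays are (H, W, C); `net_forward` converts on
# entry and `net_backward` converts the input gradient back.

CONV_K <- 3L

# --- geometry (channel-fastest layout) ------------------------------------

# Patch-gather indices and sparse scatter matrix for a 3x3 same conv.
conv_geom <- function(H, W, C) {
  k <- CONV_K
  Hp <- H + 2L
  Wp <- W + 2L
  # interior of the zero-padded canvas, channel-fastest
  cc <- rep(seq_len(C), times = H * W)
  hh <- rep(rep(seq_len(H), each = C), times = W)
  ww <- rep(seq_len(W), each = C * H)
  inner <- cc + C * (hh) + C * Hp * (ww)           # hp = h+1, wp = w+1
  # patch-element offsets, ordered dh fastest, then dw, then channel
  dh <- rep(0:(k - 1L), times = k * C)
  dw <- rep(rep(0:(k - 1L), each = k), times = C)
  ch <- rep(seq_len(C), each = k * k)
  off <- ch + C * dh + C * Hp * dw
  # output positions, ordered h fastest then w (channel handled by rows)
  ph <- rep(seq_len(H), times = W)
  pw <- rep(seq_len(W), each = H)
  pos <- C * (ph - 1L) + C * Hp * (pw - 1L)
  M <- outer(off, pos, `+`)                        # (k*k*C) x (H*W)
  Mvec <- as.vector(M)
  scatter <- Matrix::sparseMatrix(
    i = Mvec, j = seq_along(Mvec), x = 1,
    dims = c(Hp * Wp * C, length(Mvec))
  )
  list(H = H, W = W, C = C, Hp = Hp, Wp = Wp,
       kkC = k * k * C, n_pos = H * W, d_pad = Hp * Wp * C,
       inner = inner, Mvec = Mvec, scatter = scatter)
}

# 2x2 stride-2 max-pool indices, channel-fastest layout; H, W even.
pool_geom <- function(H, W, C) {
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  base_c <- rep(seq_len(C), times = H2 * W2)
  base_i <- rep(rep(seq_len(H2), each = C), times = W2)
  base_j <- rep(seq_len(W2), each = C * H2)
  idx <- function(a, b) {
    base_c + C * (2L * base_i - 2L + a) + C * H * (2L * base_j - 2L + b)
  }
  list(H2 = H2, W2 = W2, C = C, d_in = H * W * C,
       I = list(idx(0L, 0L), idx(1L, 0L), idx(0L, 1L), idx(1L, 1L)))
}

# Permutation taking an (H, W, C)-flattened image to channel-fastest order.
chw_perm <- function(H, W, C) {
  cc <- rep(seq_len(C), times = H * W)
  hh <- rep(rep(seq_len(H), each = C), times = W)
  ww <- rep(seq_len(W), each = C * H)
  hh + H * (ww - 1L) + H * W * (cc - 1L)
}

# --- single layers --------------------------------------------------------

conv_forward <- function(Wm, b, g, X, keep_cols = FALSE) {
  n <- ncol(X)
  Xpad <- matrix(0, g$d_pad, n)
  Xpad[g$inner, ] <- X
  cols <- Xpad[g$Mvec, , drop = FALSE]
  dim(cols) <- c(g$kkC, g$n_pos * n)
  Y <- Wm %*% cols + b                             # outC x (n_pos*n)
  dim(Y) <- c(nrow(Wm) * g$n_pos, n)
  list(out = Y, cols = if (keep_cols) cols else NULL)
}

conv_backward <- function(Wm, g, cols, dOut, n) {
  outC <- nrow(Wm)
  dY <- dOut
  dim(dY) <- c(outC, g$n_pos * n)
  dW <- dY %*% t(cols)
  db <- rowSums(dY)
  dcols <- crossprod(Wm, dY)                       # kkC x (n_pos*n)
  dim(dcols) <- c(g$kkC * g$n_pos, n)
  dXpad <- as.matrix(g$scatter %*% dcols)
  list(dX = dXpad[g$inner, , drop = FALSE], dW = dW, db = db)
}

pool_forward <- function(pg, X) {
  a <- X[pg$I[[1L]], , drop = FALSE]
  b <- X[pg$I[[2L]], , drop = FALSE]
  cc <- X[pg$I[[3L]], , drop = FALSE]
  d <- X[pg$I[[4L]], , drop = FALSE]
  out <- pmax(a, b, cc, d)
  which4 <- 1L + (b == out) + 2L * ((cc == out) & (b != out)) +
    3L * ((d == out) & (cc != out) & (b != out))
  # ties resolved deterministically: first window element attaining the max
  which4[a == out] <- 1L
  list(out = out, which4 = which4)
}

pool_backward <- function(pg, which4, dOut, n) {
  d_out <- length(pg$I[[1L]])
  sel <- matrix(pg$I[[1L]], d_out, n)
  for (j in 2:4) {
    m <- which4 == j
    sel[m] <- rep(pg$I[[j]], times = n)[m]
  }
  lin <- sel + rep((seq_len(n) - 1L) * pg$d_in, each = d_out)
  dX <- matrix(0, pg$d_in, n)
  # flatten: a two-column index matrix would be taken as coordinate pairs
  dX[as.vector(lin)] <- as.vector(dOut)
  dX
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max), `-`)
  E <- exp(Z)
  sweep(E, 2L, colSums(E), `/`)
}

# --- full network ---------------------------------------------------------

# Architecture: stages 1-5 convolutional (ReLU; max-pool after 1, 2, 5),
# stages 6-7 fully connected with ReLU, stage 8 fully connected + softmax.
surrogate_architecture <- function(input_shape, n_classes,
                                   conv_widths = c(8L, 16L, 16L, 16L, 32L),
                                   fc_widths = c(128L, 64L)) {
  H <- input_shape[1L]; W <- input_shape[2L]; C <- input_shape[3L]
  pool_at <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  stages <- vector("list", 8L)
  for (s in 1:5) {
    inC <- if (s == 1L) C else conv_widths[s - 1L]
    g <- conv_geom(H, W, inC)
    pg <- NULL
    Ho <- H; Wo <- W
    if (pool_at[s]) {
      if (H %% 2L || W %% 2L) {
        stop("spatial size must be even before each pooling stage; got ",
             H, "x", W, " at stage ", s, call. = FALSE)
      }
      pg <- pool_geom(H, W, conv_widths[s])
      Ho <- H %/% 2L; Wo <- W %/% 2L
    }
    stages[[s]] <- list(
      name = paste0("L", s),
      kind = if (pool_at[s]) "conv+relu+pool" else "conv+relu",
      in_shape = c(H, W, inC), out_shape = c(Ho, Wo, conv_widths[s]),
      width = conv_widths[s], geom = g, pool = pg,
      n_units = Ho * Wo * conv_widths[s], fan_in = 9L * inC
    )
    H <- Ho; W <- Wo
  }
  d_conv <- stages[[5L]]$n_units
  dims_fc <- c(d_conv, fc_widths, n_classes)
  for (s in 6:8) {
    j <- s - 5L
    stages[[s]] <- list(
      name = paste0("L", s),
      kind = if (s == 8L) "softmax-output" else "fully-connected+relu",
      in_dim = dims_fc[j], width = dims_fc[j + 1L],
      n_units = dims_fc[j + 1L], fan_in = dims_fc[j]
    )
  }
  stages
}

init_params <- function(stages, seed) {
  set.seed(seed)
  lapply(stages, function(st) {
    list(W = matrix(stats::rnorm(st$width * st$fan_in, sd = sqrt(2 / st$fan_in)),
                    st$width, st$fan_in),
         b = numeric(st$width))
  })
}

# Forward pass on a raw-pixel batch X (D x n, (H,W,C) flattening, [0, 255]).
net_forward <- function(net, X, want_stages = FALSE, want_cache = FALSE) {
  stages <- net$stages
  params <- net$params
  A <- X[net$chw, , drop = FALSE] / 255 - 0.5
  acts <- if (want_stages) vector("list", 8L) else NULL
  cache <- if (want_cache) vector("list", 8L) else NULL
  n <- ncol(X)
  for (s in 1:5) {
    st <- stages[[s]]
    cf <- conv_forward(params[[s]]$W, params[[s]]$b, st$geom, A,
                       keep_cols = want_cache)
    R <- cf$out * (cf$out > 0)
    if (!is.null(st$pool)) {
      pf <- pool_forward(st$pool, R)
      out <- pf$out
      if (want_cache) cache[[s]] <- list(cols = cf$cols, relu = R,
                                         which4 = pf$which4)
    } else {
      out <- R
      if (want_cache) cache[[s]] <- list(cols = cf$cols, relu = R,
                                         which4 = NULL)
    }
    if (want_stages) acts[[s]] <- out
    A <- out
  }
  for (s in 6:7) {
    if (want_cache) cache[[s]] <- list(X_in = A)
    Z <- params[[s]]$W %*% A + params[[s]]$b
    A <- Z * (Z > 0)
    if (want_cache) cache[[s]]$relu <- A
    if (want_stages) acts[[s]] <- A
  }
  if (want_cache) cache[[8L]] <- list(X_in = A)
  logits <- params[[8L]]$W %*% A + params[[8L]]$b
  P <- softmax_cols(logits)
  if (want_stages) acts[[8L]] <- P
  list(probs = P, acts = acts, cache = cache, n = n)
}

# Backprop from a gradient seeded at the logits.
net_backward <- function(net, fwd, dLogits, want_input_grad = FALSE,
                         want_param_grads = TRUE) {
  stages <- net$stages
  params <- net$params
  cache <- fwd$cache
  n <- fwd$n
  grads <- if (want_param_grads) vector("list", 8L) else NULL
  dA <- dLogits
  for (s in 8:6) {
    if (want_param_grads) {
      grads[[s]] <- list(W = dA %*% t(cache[[s]]$X_in), b = rowSums(dA))
    }
    dA <- crossprod(params[[s]]$W, dA)
    if (s > 6L) dA <- dA * (cache[[s - 1L]]$relu > 0)
  }
  for (s in 5:1) {
    st <- stages[[s]]
    if (!is.null(st$pool)) {
      dA <- pool_backward(st$pool, cache[[s]]$which4, dA, n)
    }
    dA <- dA * (cache[[s]]$relu > 0)
    cb <- conv_backward(params[[s]]$W, st$geom, cache[[s]]$cols, dA, n)
    if (want_param_grads) grads[[s]] <- list(W = cb$dW, b = cb$db)
    if (s > 1L || want_input_grad) dA <- cb$dX
  }
  input_grad <- NULL
  if (want_input_grad) {
    input_grad <- matrix(0, nrow(dA), n)
    input_grad[net$chw, ] <- dA / 255
  }
  list(grads = grads, input_grad = input_grad)
}

# Gradient of the target-class softmax probability (or log-probability)
# with respect to raw pixels, one target class per image column.
net_input_gradient <- function(net, X, class_ids, on = c("prob", "logprob")) {
  on <- match.arg(on)
  fwd <- net_forward(net, X, want_cache = TRUE)
  P <- fwd$probs
  n <- ncol(X)
  sel <- cbind(class_ids, seq_len(n))
  onehot <- matrix(0, nrow(P), n)
  onehot[sel] <- 1
  dLogits <- if (on == "prob") {
    sweep(onehot - P, 2L, P[sel], `*`)
  } else {
    onehot - P
  }
  bk <- net_backward(net, fwd, dLogits, want_input_grad = TRUE,
                     want_param_grads = FALSE)
  list(grad = bk$input_grad, probs = P)
}

adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0
  ))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (s in seq_along(params)) {
    g <- grads[[s]]
    st <- state[[s]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    params[[s]]$W <- params[[s]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    params[[s]]$b <- params[[s]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[s]] <- st
  }
  list(params = params, state = state)
}
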