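# Low-level neural building blocks for the Siamese encoder: 1D "same"
# convolution via im2col + BLAS matrix multiply, ReLU, ceil-mode max
# pooling with stride 2, a dense layer, and the Adam optimizer. Activation
# matrices are laid out [B*L, C] with the time index fastest within each
# batch element.

# Expand x [B*L, C] to [B*L, k*C] so convolution becomes one matrix
# multiply. Column blocks are ordered by tap offset -h..h (h = (k-1)/2);
# out-of-range taps are zero (zero padding).
im2col1d <- function(x, B, L, C, k) {
  h <- (k - 1L) %/% 2L
  lvec <- rep.int(seq_len(L), B)
  M <- matrix(0, B * L, k * C)
  for (j in seq_len(k)) {
    o <- j - 1L - h
    cols <- ((j - 1L) * C + 1L):(j * C)
    if (o == 0L) {
      M[, cols] <- x
    } else {
      valid <- which(lvec + o >= 1L & lvec + o <= L)
      M[valid, cols] <- x[valid + o, , drop = FALSE]
    }
  }
  M
}

# Adjoint of im2col1d: scatter tap-block gradients back to input rows.
col2im1d <- function(dM, B, L, C, k) {
  h <- (k - 1L) %/% 2L
  lvec <- rep.int(seq_len(L), B)
  dx <- matrix(0, B * L, C)
  for (j in seq_len(k)) {
    o <- j - 1L - h
    cols <- ((j - 1L) * C + 1L):(j * C)
    if (o == 0L) {
      dx <- dx + dM[, cols, drop = FALSE]
    } else {
      valid <- which(lvec + o >= 1L & lvec + o <= L)
      dx[valid + o, ] <- dx[valid + o, , drop = FALSE] + dM[valid, cols, drop = FALSE]
    }
  }
  dx
}

# Max pool, width 2, stride 2, ceil mode: an odd final element forms its
# own window, so L -> ceiling(L / 2) and odd lengths survive the stack.
pool2_forward <- function(a, B, L) {
  Lp <- (L + 1L) %/% 2L
  p <- rep.int(seq_len(Lp), B)
  b <- rep(seq_len(B), each = Lp)
  r1 <- (b - 1L) * L + 2L * p - 1L
  has2 <- 2L * p <= L
  y <- a[r1, , drop = FALSE]
  if (any(has2)) {
    y2 <- a[r1[has2] + 1L, , drop = FALSE]
    sub <- y[has2, , drop = FALSE]
    hit <- y2 > sub
    sub[hit] <- y2[hit]
    y[has2, ] <- sub
  }
  list(y = y, r1 = r1, has2 = has2, Lp = Lp)
}

# Route pooled gradients to the argmax of each window (ties -> earlier tap).
pool2_backward <- function(dy, pool, a, B, L) {
  C <- ncol(dy)
  da <- matrix(0, B * L, C)
  r1 <- pool$r1
  has2 <- pool$has2
  take1 <- matrix(TRUE, nrow(dy), C)
  if (any(has2)) {
    y1 <- a[r1[has2], , drop = FALSE]
    y2 <- a[r1[has2] + 1L, , drop = FALSE]
    take1[has2, ] <- y1 >= y2
  }
  da[r1, ] <- dy * take1
  if (any(has2)) {
    da[r1[has2] + 1L, ] <- (dy * !take1)[has2, , drop = FALSE]
  }
  da
}

# Length after the pooling stack, and hence the flattened dimension.
pooled_lengths <- function(L, n_blocks) {
  lens <- integer(n_blocks + 1L)
  lens[1] <- L
  for (i in seq_len(n_blocks)) lens[i + 1L] <- (lens[i] + 1L) %/% 2L
  lens
}

# Encoder forward pass over a batch of B segments stacked as x [B*L, 2].
# Returns the [B, embed_dim] embeddings; with cache = TRUE also every
# intermediate needed for backpropagation.
encoder_forward <- function(params, config, x, B, cache = FALSE) {
  k <- config$kernel_size
  L <- nrow(x) / B
  C <- ncol(x)
  caches <- if (cache) vector("list", length(config$conv_filters)) else NULL
  for (i in seq_along(config$conv_filters)) {
    M <- im2col1d(x, B, L, C, k)
    Z <- M %*% params[[paste0("cW", i)]]
    Z <- Z + rep(params[[paste0("cb", i)]], each = nrow(Z))
    A <- Z
    A[A < 0] <- 0
    pool <- pool2_forward(A, B, L)
    if (cache) caches[[i]] <- list(M = M, A = A, pool = pool, L = L, C = C)
    x <- pool$y
    L <- pool$Lp
    C <- ncol(x)
  }
  # flatten [B*Lf, C] -> [B, Lf*C], time-major within each element
  flat <- matrix(as.vector(t(x)), nrow = B, byrow = TRUE)
  E <- flat %*% params$dW
  E <- E + rep(params$db, each = B)
  if (!cache) return(E)
  list(E = E, flat = flat, Lf = L, Cf = C, caches = caches)
}

# Backward pass: dE [B, embed_dim] -> gradients for every encoder
# parameter (named like the parameter list).
encoder_backward <- function(params, config, fwd, dE, B) {
  grads <- list()
  grads$dW <- crossprod(fwd$flat, dE)
  grads$db <- colSums(dE)
  dflat <- tcrossprod(dE, params$dW)
  dx <- matrix(as.vector(t(dflat)), ncol = fwd$Cf, byrow = TRUE)
  k <- config$kernel_size
  for (i in rev(seq_along(config$conv_filters))) {
    cc <- fwd$caches[[i]]
    dA <- pool2_backward(dx, cc$pool, cc$A, B, cc$L)
    dZ <- dA * (cc$A > 0)
    grads[[paste0("cW", i)]] <- crossprod(cc$M, dZ)
    grads[[paste0("cb", i)]] <- colSums(dZ)
    dM <- tcrossprod(dZ, params[[paste0("cW", i)]])
    dx <- col2im1d(dM, B, cc$L, cc$C, k)
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
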