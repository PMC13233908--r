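# Minimal 1-D convolutional network, implemented directly on BLAS matrix
# products (im2col), with binary cross-entropy loss and Adam. Small enough
# to train on a CPU in minutes; deterministic given a seed and a
# single-threaded BLAS.
#
# Layout: activations are matrices with rows indexed by (position, batch)
# — position fastest — and one column per channel; convolutions use "same"
# zero padding and are realized as a single (L*B) x (K*Cin) gather followed
# by one matrix product. Each conv block is conv -> ReLU -> max-pool(2);
# the head is global average pooling -> dense -> sigmoid.

.cnn_cache <- new.env(parent = emptyenv())

# cached row-gather indices mapping padded rows -> im2col rows for offset k
conv_gather_idx <- function(L, B, K) {
  key <- paste(L, B, K, sep = "_")
  idx <- .cnn_cache[[key]]
  if (is.null(idx)) {
    Lp <- L + K - 1L
    idx <- lapply(seq_len(K), function(k)
      as.vector(outer(k:(k + L - 1L), (0:(B - 1L)) * Lp, "+")))
    .cnn_cache[[key]] <- idx
  }
  idx
}

pool_idx <- function(L, B) {
  key <- paste("p", L, B, sep = "_")
  idx <- .cnn_cache[[key]]
  if (is.null(idx)) {
    L2 <- L %/% 2L
    base <- rep((0:(B - 1L)) * L, each = L2)
    idx <- list(odd = base + rep(seq(1L, 2L * L2, by = 2L), B),
                even = base + rep(seq(2L, 2L * L2, by = 2L), B), L2 = L2)
    .cnn_cache[[key]] <- idx
  }
  idx
}

conv_forward <- function(a, L, B, W, b, K) {
  cin <- ncol(a)
  Lp <- L + K - 1L
  pl <- (K - 1L) %/% 2L
  apad <- matrix(0, Lp * B, cin)
  data_rows <- as.vector(outer((pl + 1L):(pl + L), (0:(B - 1L)) * Lp, "+"))
  apad[data_rows, ] <- a
  gi <- conv_gather_idx(L, B, K)
  xcol <- do.call(cbind, lapply(gi, function(ix) apad[ix, , drop = FALSE]))
  y <- xcol %*% W
  y <- y + rep(b, each = nrow(y))
  list(out = y, xcol = xcol, data_rows = data_rows, Lp = Lp, cin = cin)
}

conv_backward <- function(cache, dY, W, L, B, K) {
  dW <- crossprod(cache$xcol, dY)
  db <- colSums(dY)
  dxcol <- tcrossprod(dY, W)
  cin <- cache$cin
  dapad <- matrix(0, cache$Lp * B, cin)
  gi <- conv_gather_idx(L, B, K)
  for (k in seq_len(K)) {
    blk <- dxcol[, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    dapad[gi[[k]], ] <- dapad[gi[[k]], , drop = FALSE] + blk
  }
  list(dX = dapad[cache$data_rows, , drop = FALSE], dW = dW, db = db)
}

pool2_forward <- function(a, L, B) {
  pi_ <- pool_idx(L, B)
  odd <- a[pi_$odd, , drop = FALSE]
  even <- a[pi_$even, , drop = FALSE]
  take_odd <- odd >= even
  list(out = pmax(odd, even), take_odd = take_odd, L = L, L2 = pi_$L2)
}

pool2_backward <- function(cache, dY, B) {
  pi_ <- pool_idx(cache$L, B)
  dX <- matrix(0, cache$L * B, ncol(dY))
  dX[pi_$odd, ] <- dY * cache$take_odd
  dX[pi_$even, ] <- dY * !cache$take_odd
  dX
}

init_cnn_params <- function(config) {
  K <- config$kernel
  cin <- 1L
  conv <- list()
  for (ch in config$channels) {
    conv[[length(conv) + 1L]] <- list(
      W = matrix(stats::rnorm(K * cin * ch, sd = sqrt(2 / (K * cin))), K * cin, ch),
      b = numeric(ch))
    cin <- ch
  }
  list(conv = conv,
       dense = list(W = matrix(stats::rnorm(cin, sd = sqrt(2 / cin)), cin, 1),
                    b = 0))
}

# forward pass over a batch matrix x (B x window_len); returns logits and
# (optionally) caches for backprop
cnn_forward <- function(params, x, config, keep_cache = FALSE) {
  B <- nrow(x)
  L <- ncol(x)
  a <- matrix(t(x), ncol = 1L)         # rows (position, batch), 1 channel
  caches <- list()
  for (li in seq_along(params$conv)) {
    cf <- conv_forward(a, L, B, params$conv[[li]]$W, params$conv[[li]]$b,
                       config$kernel)
    relu_mask <- cf$out > 0
    a1 <- cf$out * relu_mask
    pf <- pool2_forward(a1, L, B)
    if (keep_cache) caches[[li]] <- list(conv = cf, relu = relu_mask,
                                         pool = pf, L = L)
    a <- pf$out
    L <- pf$L2
  }
  gap <- rowsum(a, rep(seq_len(B), each = L), reorder = FALSE) / L  # B x C
  z <- as.numeric(gap %*% params$dense$W + params$dense$b)
  list(logits = z, gap = gap, L_final = L, B = B, caches = caches)
}

cnn_backward <- function(params, fw, dz, config) {
  B <- fw$B
  grads <- list(conv = vector("list", length(params$conv)), dense = NULL)
  grads$dense <- list(W = crossprod(fw$gap, matrix(dz)), b = sum(dz))
  dgap <- tcrossprod(matrix(dz), params$dense$W)      # B x C
  L <- fw$L_final
  da <- dgap[rep(seq_len(B), each = L), , drop = FALSE] / L
  for (li in rev(seq_along(params$conv))) {
    cache <- fw$caches[[li]]
    da <- pool2_backward(cache$pool, da, B)
    da <- da * cache$relu
    cb <- conv_backward(cache$conv, da, params$conv[[li]]$W, cache$L, B,
                        config$kernel)
    grads$conv[[li]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dX
  }
  grads
}

# flatten/apply Adam over the nested parameter list
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  upd <- function(p, g, s) {
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t); vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  for (li in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      r <- upd(params$conv[[li]][[nm]], grads$conv[[li]][[nm]],
               state$conv[[li]][[nm]])
      params$conv[[li]][[nm]] <- r$p
      state$conv[[li]][[nm]] <- r$s
    }
  }
  for (nm in c("W", "b")) {
    r <- upd(params$dense[[nm]], grads$dense[[nm]], state$dense[[nm]])
    params$dense[[nm]] <- r$p
    state$dense[[nm]] <- r$s
  }
  list(params = params, state = state)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable binary cross-entropy from logits
bce_from_logits <- function(z, y) mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))

# per-window robust standardization: location by median, scale by MAD
standardize_windows <- function(w, eps = 1e-3) {
  med <- apply(w, 1, stats::median)
  sc <- apply(abs(w - med), 1, stats::median) * 1.4826 + eps
  (w - med) / sc
}
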