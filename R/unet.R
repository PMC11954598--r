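#' U-Net architecture specification
#'
#' A resolution-relative U-Net for noise prediction: four feature-map
#' resolutions (full size down to 1/8), two convolutional residual blocks
#' per level, single-head spatial self-attention at the level whose
#' resolution is 1/4 of the input, and a sinusoidal time embedding
#' injected into every residual block. Input and output share the same
#' spatial shape (1 channel in, 1 channel out). Because the architecture
#' is defined relative to the input resolution it runs identically at
#' 256 px and at 32-64 px desk scales.
#'
#' @param base_width base channel count; level widths are
#'   `base_width * c(1, 2, 2, 4)`.
#' @param emb_dim dimension of the time embedding.
#' @return An object of class `unet_spec` with fields `channels`
#'   (length 4), `attn_level` (fixed at 3, the 1/4-resolution level),
#'   `emb_dim`, `base_width`.
#' @export
unet_spec <- function(base_width = 8L, emb_dim = 32L) {
  base_width <- as.integer(base_width)
  stopifnot(base_width >= 1L)
  structure(
    list(base_width = base_width,
         channels = base_width * c(1L, 2L, 2L, 4L),
         levels = 4L,
         attn_level = 3L,  # resolution = input / 4
         emb_dim = as.integer(emb_dim)),
    class = "unet_spec"
  )
}

rb_init <- function(cin, cout, emb_dim) {
  p <- list(conv1 = conv3_init(cin, cout),
            conv2 = conv3_init(cout, cout, gain = 0.1),
            temb = lin_init(emb_dim, cout))
  if (cin != cout) p$short <- conv1_init(cin, cout)
  p
}

rb_f <- function(x, temb, p) {
  h1 <- silu_f(x)
  c1 <- conv3_f(h1, p$conv1)
  tp <- lin_f(temb, p$temb)
  dc1 <- dim(c1$y)
  y1 <- c1$y + rep(tp$y, each = dc1[1] * dc1[2])
  h2 <- silu_f(y1)
  c2 <- conv3_f(h2, p$conv2)
  if (!is.null(p$short)) {
    sh <- conv1_f(x, p$short)
    y <- c2$y + sh$y
    cache <- list(x = x, c1 = c1$cache, tp = tp$cache, y1 = y1, c2 = c2$cache, sh = sh$cache)
  } else {
    y <- c2$y + x
    cache <- list(x = x, c1 = c1$cache, tp = tp$cache, y1 = y1, c2 = c2$cache, sh = NULL)
  }
  list(y = y, cache = cache)
}

rb_b <- function(dy, p, cache) {
  g <- list()
  b2 <- conv3_b(dy, p$conv2, cache$c2)
  g$conv2 <- list(W = b2$dW, b = b2$db)
  dy1 <- silu_b(b2$dx, cache$y1)
  dtemb_vec <- apply(dy1, 3, sum)
  bt <- lin_b(dtemb_vec, p$temb, cache$tp)
  g$temb <- list(W = bt$dW, b = bt$db)
  b1 <- conv3_b(dy1, p$conv1, cache$c1)
  g$conv1 <- list(W = b1$dW, b = b1$db)
  dx <- silu_b(b1$dx, cache$x)
  if (!is.null(p$short)) {
    bs <- conv1_b(dy, p$short, cache$sh)
    g$short <- list(W = bs$dW, b = bs$db)
    dx <- dx + bs$dx
  } else {
    dx <- dx + dy
  }
  list(dx = dx, grads = g, dtemb = bt$dx)
}

#' Initialize U-Net parameters
#'
#' The final output convolution is zero-initialized (the network starts
#' by predicting zero noise), a standard stabilizer for diffusion
#' training.
#'
#' @param spec a [unet_spec()].
#' @param seed integer RNG seed.
#' @return nested named list of parameter arrays.
#' @export
unet_init <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  ch <- spec$channels; E <- spec$emb_dim
  p <- list()
  p$temb_mlp <- lin_init(E, E)
  p$conv_in <- conv3_init(1L, ch[1])
  for (l in 1:4) {
    cin <- if (l == 1L) ch[1] else ch[l - 1L]
    p[[paste0("enc", l, "_rb1")]] <- rb_init(cin, ch[l], E)
    p[[paste0("enc", l, "_rb2")]] <- rb_init(ch[l], ch[l], E)
    if (l == spec$attn_level) {
      p[[paste0("enc", l, "_attn1")]] <- attn_init(ch[l])
      p[[paste0("enc", l, "_attn2")]] <- attn_init(ch[l])
    }
  }
  for (l in 3:1) {
    p[[paste0("dec", l, "_rb1")]] <- rb_init(ch[l + 1L] + ch[l], ch[l], E)
    p[[paste0("dec", l, "_rb2")]] <- rb_init(ch[l], ch[l], E)
    if (l == spec$attn_level) {
      p[[paste0("dec", l, "_attn1")]] <- attn_init(ch[l])
      p[[paste0("dec", l, "_attn2")]] <- attn_init(ch[l])
    }
  }
  p$conv_out <- list(W = matrix(0, 9 * ch[1], 1L), b = rep(0, 1L))
  p
}

#' U-Net forward pass
#'
#' @param x input image, `(H, W)` matrix or `(H, W, 1)` array; `H` and
#'   `W` must be divisible by 8.
#' @param t integer diffusion step (time conditioning).
#' @param params parameters from [unet_init()].
#' @param spec the matching [unet_spec()].
#' @param want_cache keep intermediate activations for backprop.
#' @return list with `y` (same spatial shape as `x`, the predicted
#'   noise) and `cache`.
#' @export
unet_forward <- function(x, t, params, spec, want_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
    stop("unet_forward: spatial dimensions must be divisible by 8")
  }
  C <- list()
  te0 <- time_embedding(t, spec$emb_dim)
  tl <- lin_f(te0, params$temb_mlp)
  temb <- silu_f(tl$y)
  C$temb <- list(pre = tl$y, cache = tl$cache)
  ci <- conv3_f(x, params$conv_in)
  C$conv_in <- ci$cache
  h <- ci$y
  skips <- list()
  dims <- list()
  for (l in 1:4) {
    r1 <- rb_f(h, temb, params[[paste0("enc", l, "_rb1")]])
    C[[paste0("enc", l, "_rb1")]] <- r1$cache; h <- r1$y
    if (l == spec$attn_level) {
      a1 <- attn_f(h, params[[paste0("enc", l, "_attn1")]])
      C[[paste0("enc", l, "_attn1")]] <- a1$cache; h <- a1$y
    }
    r2 <- rb_f(h, temb, params[[paste0("enc", l, "_rb2")]])
    C[[paste0("enc", l, "_rb2")]] <- r2$cache; h <- r2$y
    if (l == spec$attn_level) {
      a2 <- attn_f(h, params[[paste0("enc", l, "_attn2")]])
      C[[paste0("enc", l, "_attn2")]] <- a2$cache; h <- a2$y
    }
    if (l < 4L) {
      skips[[l]] <- h
      dims[[l]] <- dim(h)
      h <- pool2_f(h)
    }
  }
  for (l in 3:1) {
    h <- up2_f(h)
    nskip <- dim(skips[[l]])[3]
    h <- array(c(h, skips[[l]]), c(dim(h)[1], dim(h)[2], dim(h)[3] + nskip))
    r1 <- rb_f(h, temb, params[[paste0("dec", l, "_rb1")]])
    C[[paste0("dec", l, "_rb1")]] <- r1$cache; h <- r1$y
    if (l == spec$attn_level) {
      a1 <- attn_f(h, params[[paste0("dec", l, "_attn1")]])
      C[[paste0("dec", l, "_attn1")]] <- a1$cache; h <- a1$y
    }
    r2 <- rb_f(h, temb, params[[paste0("dec", l, "_rb2")]])
    C[[paste0("dec", l, "_rb2")]] <- r2$cache; h <- r2$y
    if (l == spec$attn_level) {
      a2 <- attn_f(h, params[[paste0("dec", l, "_attn2")]])
      C[[paste0("dec", l, "_attn2")]] <- a2$cache; h <- a2$y
    }
  }
  co <- conv3_f(h, params$conv_out)
  C$conv_out <- co$cache
  C$dims <- dims
  y <- matrix(co$y, d[1], d[2])
  list(y = y, cache = if (want_cache) C else NULL)
}

#' U-Net backward pass
#'
#' @param dy gradient of the loss with respect to the network output,
#'   `(H, W)` matrix.
#' @param params,spec as in [unet_forward()].
#' @param cache the cache returned by `unet_forward(..., want_cache = TRUE)`.
#' @return nested list of parameter gradients, same structure as
#'   `params`.
#' @export
unet_backward <- function(dy, params, spec, cache) {
  G <- list()
  dtemb_acc <- rep(0, spec$emb_dim)
  dyy <- array(dy, c(dim(dy), 1L))
  bo <- conv3_b(dyy, params$conv_out, cache$conv_out)
  G$conv_out <- list(W = bo$dW, b = bo$db)
  dh <- bo$dx
  ch <- spec$channels
  dskips <- list()
  for (l in 1:3) {
    if (l == spec$attn_level) {
      ba <- attn_b(dh, params[[paste0("dec", l, "_attn2")]], cache[[paste0("dec", l, "_attn2")]])
      G[[paste0("dec", l, "_attn2")]] <- ba[c("dWq", "dWk", "dWv", "dWo")]
      names(G[[paste0("dec", l, "_attn2")]]) <- c("Wq", "Wk", "Wv", "Wo")
      dh <- ba$dx
    }
    br <- rb_b(dh, params[[paste0("dec", l, "_rb2")]], cache[[paste0("dec", l, "_rb2")]])
    G[[paste0("dec", l, "_rb2")]] <- br$grads; dtemb_acc <- dtemb_acc + br$dtemb
    dh <- br$dx
    if (l == spec$attn_level) {
      ba <- attn_b(dh, params[[paste0("dec", l, "_attn1")]], cache[[paste0("dec", l, "_attn1")]])
      G[[paste0("dec", l, "_attn1")]] <- ba[c("dWq", "dWk", "dWv", "dWo")]
      names(G[[paste0("dec", l, "_attn1")]]) <- c("Wq", "Wk", "Wv", "Wo")
      dh <- ba$dx
    }
    br <- rb_b(dh, params[[paste0("dec", l, "_rb1")]], cache[[paste0("dec", l, "_rb1")]])
    G[[paste0("dec", l, "_rb1")]] <- br$grads; dtemb_acc <- dtemb_acc + br$dtemb
    dh <- br$dx
    # split concat: first channels came from the upsampled path
    cup <- ch[l + 1L]
    dup <- dh[, , seq_len(cup), drop = FALSE]
    dskips[[l]] <- dh[, , cup + seq_len(ch[l]), drop = FALSE]
    dh <- up2_b(dup)
  }
  for (l in 4:1) {
    if (l < 4L) {
      dh <- pool2_b(dh, cache$dims[[l]])
      dh <- dh + dskips[[l]]
    }
    if (l == spec$attn_level) {
      ba <- attn_b(dh, params[[paste0("enc", l, "_attn2")]], cache[[paste0("enc", l, "_attn2")]])
      G[[paste0("enc", l, "_attn2")]] <- ba[c("dWq", "dWk", "dWv", "dWo")]
      names(G[[paste0("enc", l, "_attn2")]]) <- c("Wq", "Wk", "Wv", "Wo")
      dh <- ba$dx
    }
    br <- rb_b(dh, params[[paste0("enc", l, "_rb2")]], cache[[paste0("enc", l, "_rb2")]])
    G[[paste0("enc", l, "_rb2")]] <- br$grads; dtemb_acc <- dtemb_acc + br$dtemb
    dh <- br$dx
    if (l == spec$attn_level) {
      ba <- attn_b(dh, params[[paste0("enc", l, "_attn1")]], cache[[paste0("enc", l, "_attn1")]])
      G[[paste0("enc", l, "_attn1")]] <- ba[c("dWq", "dWk", "dWv", "dWo")]
      names(G[[paste0("enc", l, "_attn1")]]) <- c("Wq", "Wk", "Wv", "Wo")
      dh <- ba$dx
    }
    br <- rb_b(dh, params[[paste0("enc", l, "_rb1")]], cache[[paste0("enc", l, "_rb1")]])
    G[[paste0("enc", l, "_rb1")]] <- br$grads; dtemb_acc <- dtemb_acc + br$dtemb
    dh <- br$dx
  }
  bi <- conv3_b(dh, params$conv_in, cache$conv_in)
  G$conv_in <- list(W = bi$dW, b = bi$db)
  # time-embedding MLP: temb = silu(lin(te0)) feeds every residual block
  dpre <- silu_b(dtemb_acc, cache$temb$pre)
  bt <- lin_b(dpre, params$temb_mlp, cache$temb$cache)
  G$temb_mlp <- list(W = bt$dW, b = bt$db)
  # return grads ordered like params
  G[names(params)]
}
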