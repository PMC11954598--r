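# Minimal neural-network primitives with hand-derived backpropagation.
# Feature maps are (H, W, C) arrays; convolutions are realized as im2col
# matrix products so all heavy lifting goes through BLAS.

sigmoid_ <- function(x) 1 / (1 + exp(-x))

silu_f <- function(x) x * sigmoid_(x)

silu_b <- function(dy, x) {
  s <- sigmoid_(x)
  dy * (s * (1 + x * (1 - s)))
}

# ---- 3x3 "same" convolution ------------------------------------------------

im2col3 <- function(x) {
  d <- dim(x)
  .im2col3_cpp(as.vector(x), d[1], d[2], d[3])
}

col2im3 <- function(dcol, H, W, C) {
  dx <- .col2im3_cpp(dcol, H, W, C)
  dim(dx) <- c(H, W, C)
  dx
}

conv3_init <- function(cin, cout, gain = 1) {
  fan_in <- 9 * cin
  list(W = matrix(stats::rnorm(9 * cin * cout, sd = gain / sqrt(fan_in)), 9 * cin, cout),
       b = rep(0, cout))
}

conv3_f <- function(x, p) {
  d <- dim(x)
  Xc <- im2col3(x)
  y <- Xc %*% p$W + rep(p$b, each = d[1] * d[2])
  dim(y) <- c(d[1], d[2], ncol(p$W))
  list(y = y, cache = list(Xc = Xc, d = d))
}

conv3_b <- function(dy, p, cache) {
  d <- cache$d
  dym <- dy
  dim(dym) <- c(d[1] * d[2], ncol(p$W))
  list(
    dx = col2im3(dym %*% t(p$W), d[1], d[2], d[3]),
    dW = crossprod(cache$Xc, dym),
    db = colSums(dym)
  )
}

# ---- 1x1 convolution -------------------------------------------------------

conv1_init <- function(cin, cout, gain = 1) {
  list(W = matrix(stats::rnorm(cin * cout, sd = gain / sqrt(cin)), cin, cout),
       b = rep(0, cout))
}

conv1_f <- function(x, p) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3])
  y <- xm %*% p$W + rep(p$b, each = d[1] * d[2])
  dim(y) <- c(d[1], d[2], ncol(p$W))
  list(y = y, cache = list(xm = xm, d = d))
}

conv1_b <- function(dy, p, cache) {
  d <- cache$d
  dym <- dy
  dim(dym) <- c(d[1] * d[2], ncol(p$W))
  dx <- dym %*% t(p$W)
  dim(dx) <- d
  list(dx = dx,
       dW = crossprod(cache$xm, dym),
       db = colSums(dym))
}

# ---- dense layer (vectors) -------------------------------------------------

lin_init <- function(nin, nout, gain = 1) {
  list(W = matrix(stats::rnorm(nin * nout, sd = gain / sqrt(nin)), nin, nout),
       b = rep(0, nout))
}

lin_f <- function(x, p) list(y = drop(x %*% p$W) + p$b, cache = x)

lin_b <- function(dy, p, cache) {
  list(dx = drop(p$W %*% dy), dW = outer(cache, dy), db = dy)
}

# ---- 2x2 average pool / nearest-neighbour upsample -------------------------

pool2_f <- function(x) {
  d <- dim(x)
  i <- seq(1L, d[1], by = 2L); j <- seq(1L, d[2], by = 2L)
  y <- (x[i, j, , drop = FALSE] + x[i + 1L, j, , drop = FALSE] +
        x[i, j + 1L, , drop = FALSE] + x[i + 1L, j + 1L, , drop = FALSE]) / 4
  y
}

pool2_b <- function(dy, dx_dim) {
  dx <- array(0, dx_dim)
  i <- seq(1L, dx_dim[1], by = 2L); j <- seq(1L, dx_dim[2], by = 2L)
  g <- dy / 4
  dx[i, j, ] <- g; dx[i + 1L, j, ] <- g
  dx[i, j + 1L, ] <- g; dx[i + 1L, j + 1L, ] <- g
  dx
}

up2_f <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  i <- seq(1L, 2L * d[1], by = 2L); j <- seq(1L, 2L * d[2], by = 2L)
  y[i, j, ] <- x; y[i + 1L, j, ] <- x
  y[i, j + 1L, ] <- x; y[i + 1L, j + 1L, ] <- x
  y
}

up2_b <- function(dy) {
  d <- dim(dy)
  i <- seq(1L, d[1], by = 2L); j <- seq(1L, d[2], by = 2L)
  dy[i, j, , drop = FALSE] + dy[i + 1L, j, , drop = FALSE] +
    dy[i, j + 1L, , drop = FALSE] + dy[i + 1L, j + 1L, , drop = FALSE]
}

# ---- single-head spatial self-attention ------------------------------------

attn_init <- function(c) {
  list(Wq = matrix(stats::rnorm(c * c, sd = 1 / sqrt(c)), c, c),
       Wk = matrix(stats::rnorm(c * c, sd = 1 / sqrt(c)), c, c),
       Wv = matrix(stats::rnorm(c * c, sd = 1 / sqrt(c)), c, c),
       Wo = matrix(0, c, c))  # zero-init output projection: block starts as identity
}

attn_f <- function(x, p) {
  d <- dim(x); C <- d[3]
  X <- x
  dim(X) <- c(d[1] * d[2], C)
  q <- X %*% p$Wq; k <- X %*% p$Wk; v <- X %*% p$Wv
  S <- q %*% t(k) / sqrt(C)
  S <- S - apply(S, 1, max)
  A <- exp(S); A <- A / rowSums(A)
  O <- A %*% v
  proj <- O %*% p$Wo
  dim(proj) <- d
  y <- x + proj
  list(y = y, cache = list(X = X, q = q, k = k, v = v, A = A, O = O, d = d))
}

attn_b <- function(dy, p, cache) {
  d <- cache$d; C <- d[3]
  dym <- dy
  dim(dym) <- c(d[1] * d[2], C)
  dWo <- crossprod(cache$O, dym)
  dO <- dym %*% t(p$Wo)
  dA <- dO %*% t(cache$v)
  dv <- crossprod(cache$A, dO)
  # softmax backward (row-wise)
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dq <- dS %*% cache$k / sqrt(C)
  dk <- crossprod(dS, cache$q) / sqrt(C)
  dX <- dq %*% t(p$Wq) + dk %*% t(p$Wk) + dv %*% t(p$Wv)
  dim(dX) <- d
  list(dx = dy + dX,
       dWq = crossprod(cache$X, dq), dWk = crossprod(cache$X, dk),
       dWv = crossprod(cache$X, dv), dWo = dWo)
}

# ---- sinusoidal time embedding --------------------------------------------

time_embedding <- function(t, dim) {
  half <- dim %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  c(sin(t * freq), cos(t * freq))
}

# ---- Adam optimizer over a nested parameter list ---------------------------

nn_zeros_like <- function(params) rapply(params, function(x) x * 0, how = "replace")

nn_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- nn_map2(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nn_map2(state$m, state$v, function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- nn_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
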