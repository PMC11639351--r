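# Differentiable building blocks with hand-derived backward passes.
# Every *_fwd returns list(y = ..., cache = ...); the matching *_bwd takes the
# cache and the upstream gradient and returns list(gx = ..., grads = <mirrors params>).

# ---- initialisers -----------------------------------------------------------

.init_linear <- function(cin, cout) {
  list(w = matrix(.trunc_normal(cin * cout), cin, cout), b = numeric(cout))
}

.init_conv <- function(cin, cout, kern, groups = 1L) {
  kern <- rep_len(kern, 3L)
  n <- cout * (cin %/% groups) * prod(kern)
  list(w = array(.trunc_normal(n), dim = c(cout, cin %/% groups, kern)),
       b = numeric(cout))
}

.init_convt <- function(cin, cout, s = 2L) {
  list(w = array(.trunc_normal(cin * cout * s^3), dim = c(cin, cout, s, s, s)),
       b = numeric(cout))
}

.init_ln <- function(c) list(g = rep(1, c), b = numeric(c))

# ---- linear -----------------------------------------------------------------

.linear_fwd <- function(x, p) {
  .tally_add("linear", 2 * nrow(x) * nrow(p$w) * ncol(p$w))
  y <- x %*% p$w
  y <- sweep(y, 2L, p$b, "+")
  list(y = y, cache = x)
}

.linear_bwd <- function(p, cache, gy) {
  list(gx = gy %*% t(p$w),
       grads = list(w = crossprod(cache, gy), b = colSums(gy)))
}

# ---- layer norm over the channel axis of tokens -----------------------------

.ln_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, p$g, "*"), 2L, p$b, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

.ln_bwd <- function(p, cache, gy) {
  xhat <- cache$xhat
  gg <- colSums(gy * xhat)
  gb <- colSums(gy)
  gxhat <- sweep(gy, 2L, p$g, "*")
  m1 <- rowMeans(gxhat)
  m2 <- rowMeans(gxhat * xhat)
  gx <- cache$inv * (gxhat - m1 - xhat * m2)
  list(gx = gx, grads = list(g = gg, b = gb))
}

# ---- GELU (exact, Phi-based) -------------------------------------------------

.gelu_fwd <- function(x) list(y = x * pnorm(x), cache = x)

.gelu_bwd <- function(cache, gy) gy * (pnorm(cache) + cache * dnorm(cache))

# ---- conv wrappers ----------------------------------------------------------

.conv_fwd <- function(x, p, stride = 1L, pad = 0L, groups = 1L, name = "conv") {
  kern <- dim(p$w)[3:5]
  stride <- rep_len(as.integer(stride), 3L)
  pad <- rep_len(as.integer(pad), 3L)
  xd <- dim(x)
  outsp <- (xd[-1L] + 2L * pad - kern) %/% stride + 1L
  .tally_add(name, 2 * (xd[1L] %/% groups) * dim(p$w)[1L] * prod(kern) * prod(outsp))
  y <- cpp_conv3d_fwd(x, dim(x), p$w, p$b, as.integer(kern), stride, pad, as.integer(groups))
  list(y = y, cache = list(x = x, stride = stride, pad = pad, groups = as.integer(groups)))
}

.conv_bwd <- function(p, cache, gy) {
  kern <- dim(p$w)[3:5]
  r <- cpp_conv3d_bwd(cache$x, dim(cache$x), p$w, gy, as.integer(kern),
                      cache$stride, cache$pad, cache$groups, dim(p$w)[1L])
  list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
}

.convt_fwd <- function(x, p, s = 2L, name = "convt") {
  xd <- dim(x)
  .tally_add(name, 2 * xd[1L] * dim(p$w)[2L] * s^3 * prod(xd[-1L] * s))
  y <- cpp_convt3d_fwd(x, dim(x), p$w, p$b, as.integer(s))
  list(y = y, cache = list(x = x, s = as.integer(s)))
}

.convt_bwd <- function(p, cache, gy) {
  r <- cpp_convt3d_bwd(cache$x, dim(cache$x), p$w, gy, cache$s, dim(p$w)[2L])
  list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
}

# ---- softmax ----------------------------------------------------------------

.softmax_rows <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# channel-axis softmax for (C, ...) arrays
.softmax_channels <- function(z) {
  d <- dim(z)
  zm <- matrix(z, nrow = d[1L])
  m <- apply(zm, 2L, max)
  e <- exp(sweep(zm, 2L, m, "-"))
  p <- sweep(e, 2L, colSums(e), "/")
  array(p, dim = d)
}
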