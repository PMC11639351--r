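# Numerical correctness of the differentiable building blocks: forward passes
# against naive oracles and hand-derived backward passes against central
# finite differences.

naive_conv3d <- function(x, w, b, stride, pad, groups) {
  C <- dim(x)[1]; sp <- dim(x)[-1]
  Cout <- dim(w)[1]; Cg <- dim(w)[2]; kern <- dim(w)[3:5]
  stride <- rep_len(stride, 3); pad <- rep_len(pad, 3)
  outsp <- (sp + 2 * pad - kern) %/% stride + 1
  Cog <- Cout / groups
  y <- array(0, c(Cout, outsp))
  for (co in 1:Cout) {
    g <- (co - 1) %/% Cog
    for (ox in 1:outsp[1]) for (oy in 1:outsp[2]) for (oz in 1:outsp[3]) {
      acc <- b[co]
      for (cl in 1:Cg) {
        ci <- g * Cg + cl
        for (i in 1:kern[1]) for (j in 1:kern[2]) for (k in 1:kern[3]) {
          ix <- (ox - 1) * stride[1] - pad[1] + i
          iy <- (oy - 1) * stride[2] - pad[2] + j
          iz <- (oz - 1) * stride[3] - pad[3] + k
          if (ix >= 1 && ix <= sp[1] && iy >= 1 && iy <= sp[2] && iz >= 1 && iz <= sp[3])
            acc <- acc + w[co, cl, i, j, k] * x[ci, ix, iy, iz]
        }
      }
      y[co, ox, oy, oz] <- acc
    }
  }
  y
}

test_that("3D convolution matches a naive loop oracle across layouts", {
  set.seed(1)
  x <- array(rnorm(4 * 6 * 6 * 6), c(4, 6, 6, 6))
  cases <- list(
    list(p = tctnet:::.init_conv(4L, 6L, 3L), stride = 1, pad = 1, groups = 1),
    list(p = tctnet:::.init_conv(4L, 5L, 7L), stride = 2, pad = 3, groups = 1),
    list(p = tctnet:::.init_conv(4L, 4L, c(7L, 1L, 1L), groups = 4L),
         stride = 1, pad = c(3, 0, 0), groups = 4),
    list(p = tctnet:::.init_conv(4L, 4L, 2L, groups = 4L), stride = 2, pad = 0, groups = 4))
  for (cs in cases) {
    got <- tctnet:::.conv_fwd(x, cs$p, stride = cs$stride, pad = cs$pad, groups = cs$groups)$y
    want <- naive_conv3d(x, cs$p$w, cs$p$b, cs$stride, cs$pad, cs$groups)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("convolution and transposed-convolution gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(3 * 6 * 6 * 6), c(3, 6, 6, 6))
  p <- tctnet:::.init_conv(3L, 4L, 3L)
  r0 <- tctnet:::.conv_fwd(x, p, stride = 2, pad = 1)
  R <- array(rnorm(length(r0$y)), dim(r0$y))

  lw <- function(wv) {
    p2 <- p; p2$w[] <- wv
    r <- tctnet:::.conv_fwd(x, p2, stride = 2, pad = 1)
    bk <- tctnet:::.conv_bwd(p2, r$cache, R)
    list(loss = sum(r$y * R), grad = as.vector(bk$grads$w))
  }
  lx <- function(xv) {
    x2 <- x; x2[] <- xv
    r <- tctnet:::.conv_fwd(x2, p, stride = 2, pad = 1)
    bk <- tctnet:::.conv_bwd(p, r$cache, R)
    list(loss = sum(r$y * R), grad = as.vector(bk$gx))
  }
  expect_lt(fd_relerr(lw, as.vector(p$w)), 1e-5)
  expect_lt(fd_relerr(lx, as.vector(x)), 1e-5)

  pt <- tctnet:::.init_convt(3L, 2L, 2L)
  rt <- tctnet:::.convt_fwd(x, pt, 2L)
  expect_identical(dim(rt$y), c(2L, 12L, 12L, 12L))
  Rt <- array(rnorm(length(rt$y)), dim(rt$y))
  lt <- function(wv) {
    p2 <- pt; p2$w[] <- wv
    r <- tctnet:::.convt_fwd(x, p2, 2L)
    bk <- tctnet:::.convt_bwd(p2, r$cache, Rt)
    list(loss = sum(r$y * Rt), grad = as.vector(bk$grads$w))
  }
  expect_lt(fd_relerr(lt, as.vector(pt$w)), 1e-5)
})

test_that("layer norm, GELU and linear gradients match finite differences", {
  set.seed(3)
  x <- matrix(rnorm(7 * 5), 7, 5)
  p <- tctnet:::.init_ln(5L)
  p$g <- runif(5, 0.5, 1.5); p$b <- rnorm(5)
  R <- matrix(rnorm(35), 7, 5)
  lln <- function(xv) {
    x2 <- x; x2[] <- xv
    r <- tctnet:::.ln_fwd(x2, p)
    bk <- tctnet:::.ln_bwd(p, r$cache, R)
    list(loss = sum(r$y * R), grad = as.vector(bk$gx))
  }
  expect_lt(fd_relerr(lln, as.vector(x)), 1e-4)

  lg <- function(xv) {
    x2 <- x; x2[] <- xv
    r <- tctnet:::.gelu_fwd(x2)
    list(loss = sum(r$y * R), grad = as.vector(tctnet:::.gelu_bwd(r$cache, R)))
  }
  expect_lt(fd_relerr(lg, as.vector(x)), 1e-5)

  pl <- tctnet:::.init_linear(5L, 4L)
  Rl <- matrix(rnorm(28), 7, 4)
  ll <- function(wv) {
    p2 <- pl; p2$w[] <- wv
    r <- tctnet:::.linear_fwd(x, p2)
    bk <- tctnet:::.linear_bwd(p2, r$cache, Rl)
    list(loss = sum(r$y * Rl), grad = as.vector(bk$grads$w))
  }
  expect_lt(fd_relerr(ll, as.vector(pl$w)), 1e-5)
})

test_that("channel softmax produces per-voxel simplex values", {
  set.seed(4)
  z <- array(rnorm(4 * 3 * 3 * 3, sd = 4), c(4, 3, 3, 3))
  p <- tctnet:::.softmax_channels(z)
  expect_true(all(p > 0))
  expect_lt(max(abs(apply(p, c(2, 3, 4), sum) - 1)), 1e-12)
})

test_that("whole-network gradient matches finite differences at sampled parameters", {
  set.seed(5)
  cfg <- tiny_config()
  m <- tctnet(cfg)
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  lbl <- array(sample(c(0L, 1L, 2L, 4L), 16^3, replace = TRUE), c(16, 16, 16))
  G <- oneHotLabels(lbl)

  fwd <- tctnet:::.model_fwd(m, x, keep_cache = TRUE)
  lg <- tctnet:::.dice_ce_grad(fwd$logits, G)
  grads <- tctnet:::.model_bwd(m, fwd$cache, lg$grad)

  flat_paths <- function(p, prefix = integer()) {
    if (is.numeric(p)) return(list(prefix))
    out <- list()
    for (k in seq_along(p)) out <- c(out, flat_paths(p[[k]], c(prefix, k)))
    out
  }
  get_at <- function(p, path) { for (k in path) p <- p[[k]]; p }
  set_at <- function(p, path, v) {
    if (length(path) == 1L) { p[[path[1]]] <- v; return(p) }
    p[[path[1]]] <- set_at(p[[path[1]]], path[-1], v)
    p
  }
  loss_of <- function(params) {
    m2 <- m; m2@params <- params
    f <- tctnet:::.model_fwd(m2, x)
    tctnet:::.dice_ce_grad(f$logits, G)$loss
  }
  paths <- flat_paths(m@params)
  eps <- 1e-5
  for (pi in sample(length(paths), 8L)) {
    path <- paths[[pi]]
    arr <- get_at(m@params, path)
    i <- sample(length(arr), 1L)
    a1 <- arr; a1[i] <- a1[i] + eps
    a2 <- arr; a2[i] <- a2[i] - eps
    gnum <- (loss_of(set_at(m@params, path, a1)) - loss_of(set_at(m@params, path, a2))) / (2 * eps)
    gan <- get_at(grads, path)[i]
    expect_lt(abs(gnum - gan) / max(1e-5, abs(gnum), abs(gan)), 1e-3)
  }
})
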