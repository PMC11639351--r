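# Convolution Transformer block: convolutional projection of K/V, multi-head
# self-attention, pre-norm residual layout. No positional encoding anywhere.

#' Scaled dot-product multi-head self-attention
#'
#' Splits the channel axis of `Q`, `K`, `V` into `heads` sub-spaces of width
#' `C/heads`, applies `Softmax(Q K' / sqrt(d_k)) V` per head, and concatenates
#' the head outputs. The learned output merge projection lives in the
#' surrounding transformer block, not here.
#'
#' @param Q,K,V token matrices (rows = tokens, columns = channels). `K` and `V`
#'   must have the same number of rows; all three share the channel width.
#' @param heads number of attention heads; must divide the channel width.
#' @return a token matrix with the shape of `Q`.
#' @export
multiHeadAttention <- function(Q, K, V, heads) {
  r <- .mhsa_fwd(Q, K, V, heads)
  r$y
}

.mhsa_fwd <- function(Q, K, V, n) {
  C <- ncol(Q)
  if (ncol(K) != C || ncol(V) != C)
    stop("channel width mismatch between Q (", C, ") and K/V (", ncol(K), ")", call. = FALSE)
  if (C %% n != 0L)
    stop("channel width ", C, " not divisible by ", n, " heads", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must have equal length", call. = FALSE)
  d <- C %/% n
  L <- nrow(Q); Lk <- nrow(K)
  .tally_add("attention", 2 * 2 * L * Lk * C)
  O <- matrix(0, L, C)
  A <- vector("list", n)
  for (h in seq_len(n)) {
    idx <- ((h - 1L) * d + 1L):(h * d)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(d)
    A[[h]] <- .softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  list(y = O, cache = list(Q = Q, K = K, V = V, A = A, n = n, d = d))
}

.mhsa_bwd <- function(cache, gO) {
  n <- cache$n; d <- cache$d
  gQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  gK <- matrix(0, nrow(cache$K), ncol(cache$K))
  gV <- gK
  for (h in seq_len(n)) {
    idx <- ((h - 1L) * d + 1L):(h * d)
    A <- cache$A[[h]]
    gOh <- gO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    gA <- tcrossprod(gOh, Vh)
    gV[, idx] <- crossprod(A, gOh)
    gS <- A * (gA - rowSums(gA * A))
    gQ[, idx] <- gS %*% cache$K[, idx, drop = FALSE] / sqrt(d)
    gK[, idx] <- crossprod(gS, cache$Q[, idx, drop = FALSE]) / sqrt(d)
  }
  list(gQ = gQ, gK = gK, gV = gV)
}

# ---- convolutional projection ----------------------------------------------
# Tokens are reshaped to their 3D grid; a depth-wise convolution of stride k
# (kernel k for k > 1, kernel 3/stride 1/pad 1 for k = 1, so a centred delta
# kernel is the identity) shrinks the K/V sequence by k^3; learned pointwise
# projections then produce Q, K, V.

.init_ct_block <- function(C, k, mlp_ratio = 4) {
  kv_kern <- if (k > 1L) k else 3L
  hidden <- as.integer(round(mlp_ratio * C))
  list(ln1 = .init_ln(C),
       kconv = .init_conv(C, C, kv_kern, groups = C),
       vconv = .init_conv(C, C, kv_kern, groups = C),
       wq = .init_linear(C, C), wk = .init_linear(C, C), wv = .init_linear(C, C),
       wo = .init_linear(C, C),
       ln2 = .init_ln(C),
       mlp1 = .init_linear(C, hidden), mlp2 = .init_linear(hidden, C))
}

.check_reduction <- function(spatial, k) {
  bad <- which(spatial %% k != 0L)
  if (length(bad))
    stop("reduction rate k = ", k, " does not divide spatial dim(s) ",
         paste(c("H", "W", "D")[bad], "=", spatial[bad], collapse = ", "), call. = FALSE)
}

.conv_projection_fwd <- function(tok, spatial, p, k) {
  .check_reduction(spatial, k)
  C <- ncol(tok)
  arr <- .to_array(tok, spatial)
  if (k > 1L) {
    kc <- .conv_fwd(arr, p$kconv, stride = k, pad = 0L, groups = C, name = "kv_dwconv")
    vc <- .conv_fwd(arr, p$vconv, stride = k, pad = 0L, groups = C, name = "kv_dwconv")
    spk <- spatial %/% k
  } else {
    kc <- .conv_fwd(arr, p$kconv, stride = 1L, pad = 1L, groups = C, name = "kv_dwconv")
    vc <- .conv_fwd(arr, p$vconv, stride = 1L, pad = 1L, groups = C, name = "kv_dwconv")
    spk <- spatial
  }
  q <- .linear_fwd(tok, p$wq)
  kk <- .linear_fwd(.to_tokens(kc$y), p$wk)
  vv <- .linear_fwd(.to_tokens(vc$y), p$wv)
  list(Q = q$y, K = kk$y, V = vv$y, spk = spk,
       cache = list(q = q$cache, kk = kk$cache, vv = vv$cache,
                    kc = kc$cache, vc = vc$cache, spk = spk))
}

.conv_projection_bwd <- function(p, cache, gQ, gK, gV) {
  qb <- .linear_bwd(p$wq, cache$q, gQ)
  kb <- .linear_bwd(p$wk, cache$kk, gK)
  vb <- .linear_bwd(p$wv, cache$vv, gV)
  kcb <- .conv_bwd(p$kconv, cache$kc, .to_array(kb$gx, cache$spk))
  vcb <- .conv_bwd(p$vconv, cache$vc, .to_array(vb$gx, cache$spk))
  gtok <- qb$gx + .to_tokens(kcb$gx) + .to_tokens(vcb$gx)
  list(gtok = gtok,
       grads = list(wq = qb$grads, wk = kb$grads, wv = vb$grads,
                    kconv = kcb$grads, vconv = vcb$grads))
}

# ---- full CT block ----------------------------------------------------------

.ct_fwd <- function(tok, spatial, p, heads, k) {
  ln1 <- .ln_fwd(tok, p$ln1)
  proj <- .conv_projection_fwd(ln1$y, spatial, p, k)
  at <- .mhsa_fwd(proj$Q, proj$K, proj$V, heads)
  o <- .linear_fwd(at$y, p$wo)
  x2 <- tok + o$y
  ln2 <- .ln_fwd(x2, p$ln2)
  z1 <- .linear_fwd(ln2$y, p$mlp1)
  g1 <- .gelu_fwd(z1$y)
  z2 <- .linear_fwd(g1$y, p$mlp2)
  y <- x2 + z2$y
  list(y = y,
       cache = list(ln1 = ln1$cache, proj = proj$cache, at = at$cache,
                    o = o$cache, ln2 = ln2$cache, z1 = z1$cache,
                    g1 = g1$cache, z2 = z2$cache))
}

.ct_bwd <- function(p, cache, gy) {
  lb2 <- .linear_bwd(p$mlp2, cache$z2, gy)
  gg1 <- .gelu_bwd(cache$g1, lb2$gx)
  lb1 <- .linear_bwd(p$mlp1, cache$z1, gg1)
  lnb2 <- .ln_bwd(p$ln2, cache$ln2, lb1$gx)
  gx2 <- gy + lnb2$gx
  ob <- .linear_bwd(p$wo, cache$o, gx2)
  mb <- .mhsa_bwd(cache$at, ob$gx)
  pb <- .conv_projection_bwd(p, cache$proj, mb$gQ, mb$gK, mb$gV)
  lnb1 <- .ln_bwd(p$ln1, cache$ln1, pb$gtok)
  gx <- gx2 + lnb1$gx
  grads <- c(list(ln1 = lnb1$grads, ln2 = lnb2$grads, wo = ob$grads,
                  mlp1 = lb1$grads, mlp2 = lb2$grads),
             pb$grads)
  list(gx = gx, grads = grads[names(p)])
}
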