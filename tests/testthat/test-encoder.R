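# Encoder: stem arithmetic, patch embedding ladder, convolutional projection,
# attention behaviour, and the transformer block contracts.

test_that("stem halves spatial dims with the 7x7x7 stride-2 kernel", {
  # full-scale crop: 128^3 input halves to 64^3 (1-channel narrow net keeps it cheap)
  p <- tctnet:::.with_seed(1L, list(conv = tctnet:::.init_conv(1L, 2L, 7L),
                                    ln = tctnet:::.init_ln(2L)))
  st <- tctnet:::.stem_fwd(p, array(0.1, c(1, 128, 128, 128)))
  expect_identical(st$spatial, c(64L, 64L, 64L))
  expect_identical(ncol(st$tokens), 2L)
  expect_identical(dim(p$conv$w)[3:5], c(7L, 7L, 7L))

  st2 <- tctnet:::.stem_fwd(p, array(0.1, c(1, 32, 32, 32)))
  expect_identical(st2$spatial, c(16L, 16L, 16L))
})

test_that("stem rejects odd spatial dims and non-finite input, naming the problem", {
  p <- list(conv = tctnet:::.init_conv(1L, 2L, 7L), ln = tctnet:::.init_ln(2L))
  expect_error(tctnet:::.stem_fwd(p, array(0, c(1, 7, 8, 8))), "X")
  bad <- array(0, c(1, 8, 8, 8)); bad[1, 1, 1, 1] <- NA
  expect_error(tctnet:::.stem_fwd(p, bad), "non-finite")
})

test_that("all-zero stem input with zero bias gives a spatially constant output", {
  p <- tctnet:::.with_seed(1L, list(conv = tctnet:::.init_conv(2L, 3L, 7L),
                                    ln = tctnet:::.init_ln(3L)))
  st <- tctnet:::.stem_fwd(p, array(0, c(2, 8, 8, 8)))
  # zero input, zero conv bias -> LN of a constant (zero-variance) row -> 0 -> GELU(0) = 0
  expect_lt(max(abs(st$tokens)), 1e-12)
  expect_lt(max(apply(st$tokens, 2, function(v) diff(range(v)))), 1e-12)
})

test_that("convolutional patch embedding halves dims and the encoder ladder hits scales 2,4,8,16", {
  cfg <- tiny_config()
  m <- tctnet(cfg)
  x <- array(rnorm(2 * 32^3), c(2, 32, 32, 32))
  pyr <- encoderForward(m, x)
  expect_length(pyr, 4L)
  expect_identical(vapply(pyr, attr, 0L, "stage_scale"), c(2L, 4L, 8L, 16L))
  expect_identical(lapply(pyr, function(f) unname(dim(f)[-1])),
                   list(c(16L, 16L, 16L), c(8L, 8L, 8L), c(4L, 4L, 4L), c(2L, 2L, 2L)))
  expect_identical(vapply(pyr, function(f) dim(f)[1L], 0L), cfg$stage_widths)
  # with reductions (8,4,2,1), scale x k = 16 at every stage, so the K/V grid
  # has the same per-axis size (input/16) throughout
  expect_true(all(cfg$stage_reductions * 2L^(1:4) == 16L))
  expect_error(encoderForward(m, array(0, c(2, 24, 32, 32))), "divisible by 16")
})

test_that("convolutional projection shrinks K/V by k^3 and keeps Q at full length", {
  set.seed(6)
  C <- 8L
  p <- tctnet:::.init_ct_block(C, 2L)
  tok <- matrix(rnorm(8^3 * C), 8^3, C)
  pr <- tctnet:::.conv_projection_fwd(tok, c(8L, 8L, 8L), p, 2L)
  expect_identical(nrow(pr$Q), 512L)
  expect_identical(nrow(pr$K), 64L)   # 8^3 / 2^3
  expect_identical(nrow(pr$V), 64L)

  p1 <- tctnet:::.init_ct_block(C, 1L)
  pr1 <- tctnet:::.conv_projection_fwd(tok, c(8L, 8L, 8L), p1, 1L)
  expect_identical(nrow(pr1$K), nrow(pr1$Q))

  expect_error(tctnet:::.conv_projection_fwd(tok, c(8L, 8L, 8L), p, 3L), "k = 3")
})

test_that("a centred delta kernel makes the k=1 depth-wise projection the identity", {
  set.seed(7)
  C <- 4L
  p <- tctnet:::.init_ct_block(C, 1L)
  p$kconv$w[] <- 0
  for (c in 1:C) p$kconv$w[c, 1, 2, 2, 2] <- 1  # centred delta per channel
  p$kconv$b[] <- 0
  p$wk$w <- diag(C); p$wk$b[] <- 0               # disable the pointwise projection
  tok <- matrix(rnorm(4^3 * C), 4^3, C)
  pr <- tctnet:::.conv_projection_fwd(tok, c(4L, 4L, 4L), p, 1L)
  expect_lt(max(abs(pr$K - tok)), 1e-12)
})

test_that("multi-head attention equals the dense-loop oracle and handles degenerate keys", {
  set.seed(8)
  Q <- matrix(rnorm(6 * 4), 6, 4)
  K <- matrix(rnorm(5 * 4), 5, 4)
  V <- matrix(rnorm(5 * 4), 5, 4)
  expect_lt(max(abs(multiHeadAttention(Q, K, V, 2L) - naive_attention(Q, K, V, 2L))), 1e-5)

  # a single key/value: softmax over one key is 1, so V broadcasts to every query
  K1 <- K[1, , drop = FALSE]; V1 <- V[1, , drop = FALSE]
  out <- multiHeadAttention(Q, K1, V1, 2L)
  expect_lt(max(abs(sweep(out, 2L, V1[1, ]))), 1e-12)

  # scaling Q and K by c -> 0 drives the output to the uniform average of V rows
  out0 <- multiHeadAttention(Q * 1e-8, K * 1e-8, V, 2L)
  expect_lt(max(abs(sweep(out0, 2L, colMeans(V)))), 1e-6)

  expect_error(multiHeadAttention(Q, K[, 1:2], V[, 1:2], 2L), "mismatch")
})

test_that("attention softmax rows sum to one", {
  set.seed(9)
  r <- tctnet:::.mhsa_fwd(matrix(rnorm(24), 6, 4), matrix(rnorm(20), 5, 4),
                          matrix(rnorm(20), 5, 4), 2L)
  for (A in r$cache$A) expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
})

test_that("transformer block preserves shape and is the identity at zero output projections", {
  set.seed(10)
  C <- 8L
  p <- tctnet:::.init_ct_block(C, 2L)
  tok <- matrix(rnorm(4^3 * C), 4^3, C)
  r <- tctnet:::.ct_fwd(tok, c(4L, 4L, 4L), p, heads = 2L, k = 2L)
  expect_identical(dim(r$y), dim(tok))

  p0 <- p
  p0$wo$w[] <- 0; p0$wo$b[] <- 0
  p0$mlp2$w[] <- 0; p0$mlp2$b[] <- 0
  r0 <- tctnet:::.ct_fwd(tok, c(4L, 4L, 4L), p0, heads = 2L, k = 2L)
  expect_lt(max(abs(r0$y - tok)), 1e-12)
})

test_that("without positional encoding the block is equivariant to token permutations (k = 1)", {
  set.seed(11)
  C <- 4L
  p <- tctnet:::.init_ct_block(C, 1L)
  # delta kernels make the k = 1 depth-wise convs permutation-transparent, so
  # the whole block sees tokens as an unordered set
  p$kconv$w[] <- 0; p$vconv$w[] <- 0
  for (c in 1:C) { p$kconv$w[c, 1, 2, 2, 2] <- 1; p$vconv$w[c, 1, 2, 2, 2] <- 1 }
  p$kconv$b[] <- 0; p$vconv$b[] <- 0
  tok <- matrix(rnorm(2 * 2 * 2 * C), 8, C)
  perm <- sample(8)
  y <- tctnet:::.ct_fwd(tok, c(2L, 2L, 2L), p, heads = 2L, k = 1L)$y
  yp <- tctnet:::.ct_fwd(tok[perm, ], c(2L, 2L, 2L), p, heads = 2L, k = 1L)$y
  expect_lt(max(abs(yp - y[perm, ])), 1e-10)
})

test_that("two encoder passes with identical weights and inputs are bit-identical", {
  m <- tctnet(tiny_config())
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  expect_identical(encoderForward(m, x), encoderForward(m, x))
})
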