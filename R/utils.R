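# Internal helpers: array/token conversion, RNG scoping, validation, flop tally.

# Feature maps live as (C, X, Y, Z) arrays, channel fastest; token matrices are
# L x C with L = X*Y*Z and voxel order identical to the array's spatial order.

.to_tokens <- function(arr) {
  d <- dim(arr)
  t(matrix(arr, nrow = d[1L]))
}

.to_array <- function(tok, spatial) {
  array(t(tok), dim = c(ncol(tok), spatial))
}

.check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

.spatial_dims <- function(arr) dim(arr)[-1L]

# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Truncated normal (+/- 2 sd) initialiser, the convention for transformer projections.
.trunc_normal <- function(n, sd = 0.02) {
  lo <- pnorm(-2); hi <- pnorm(2)
  qnorm(runif(n, lo, hi)) * sd
}

# ---- flop tally -------------------------------------------------------------
# When enabled, the layer wrappers record the flops of each executed operation
# (multiply-add = 2 flops) from the shapes seen at run time. This is the
# instrumented counter used to cross-check the analytic one in countFlops().

.tally <- new.env(parent = emptyenv())
.tally$on <- FALSE
.tally$entries <- list()

.tally_start <- function() {
  .tally$on <- TRUE
  .tally$entries <- list()
}

.tally_stop <- function() {
  .tally$on <- FALSE
  entries <- .tally$entries
  .tally$entries <- list()
  if (length(entries) == 0L) return(data.frame(name = character(), flops = numeric()))
  data.frame(name = vapply(entries, `[[`, "", "name"),
             flops = vapply(entries, `[[`, 0, "flops"),
             stringsAsFactors = FALSE)
}

.tally_add <- function(name, flops) {
  if (isTRUE(.tally$on)) .tally$entries[[length(.tally$entries) + 1L]] <- list(name = name, flops = flops)
  invisible(NULL)
}

# recursive map over nested parameter trees (named lists of numeric arrays)
.tree_map <- function(f, p) {
  if (is.numeric(p)) return(f(p))
  lapply(p, function(x) .tree_map(f, x))
}

.tree_map2 <- function(f, p, q) {
  if (is.numeric(p)) return(f(p, q))
  out <- vector("list", length(p))
  names(out) <- names(p)
  for (i in seq_along(p)) out[[i]] <- .tree_map2(f, p[[i]], q[[i]])
  out
}

.tree_reduce <- function(f, p, init = 0) {
  acc <- init
  rec <- function(x) {
    if (is.numeric(x)) acc <<- f(acc, x)
    else for (e in x) rec(e)
  }
  rec(p)
  acc
}

.n_params <- function(p) .tree_reduce(function(a, x) a + length(x), p)

# map f over n parallel trees of identical structure
.tree_mapn <- function(f, trees) {
  if (is.numeric(trees[[1L]])) return(do.call(f, trees))
  out <- vector("list", length(trees[[1L]]))
  names(out) <- names(trees[[1L]])
  for (i in seq_along(out))
    out[[i]] <- .tree_mapn(f, lapply(trees, `[[`, i))
  out
}

.grad_global_norm <- function(g) sqrt(.tree_reduce(function(a, x) a + sum(x * x), g))
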