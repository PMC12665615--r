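`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. seed = NULL uses the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Neighbor lookup: value of `a` at voxel (i + by) along `axis`, NA-padded at the
# boundary. Works for 3-D arrays and 4-D arrays shifted along a spatial axis.
shift_array <- function(a, axis, by) {
  d <- dim(a)
  out <- array(NA, d)
  storage.mode(out) <- storage.mode(a)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq(1 + by, n) else seq(1, n + by)
  dst <- if (by > 0) seq(1, n - by) else seq(1 - by, n)
  idx_all <- lapply(d, seq_len)
  is_ <- idx_all; is_[[axis]] <- src
  id_ <- idx_all; id_[[axis]] <- dst
  val <- do.call(`[`, c(list(a), is_, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), id_, list(val)))
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# Assign `values` into component `k` of a 4-D array at logical mask `m` (3-D).
set_component <- function(arr4, k, mask, values) {
  tmp <- arr4[, , , k]
  tmp[mask] <- values
  arr4[, , , k] <- tmp
  arr4
}

# Draw independent sub-seeds (< 2^31) from the current RNG stream.
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)
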