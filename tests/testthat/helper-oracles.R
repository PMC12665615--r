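# Independent oracles and small fixture builders used across the suite.

# Brute-force TFCE by its definition: per threshold, connected components via
# igraph on the 26 (or 6/18) neighborhood graph, then the explicit sum.
brute_tfce <- function(stat, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  d <- dim(stat)
  mx <- max(stat)
  if (is.null(dh)) dh <- if (mx > 0) mx / 100 else 1
  out <- array(0, d)
  nsteps <- floor(mx / dh + 1e-7)
  if (nsteps < 1 || mx <= 0) return(out)
  coords <- which(stat > 0, arr.ind = TRUE)
  vox <- which(stat > 0)
  for (t in seq_len(nsteps)) {
    h <- t * dh
    keep <- stat[vox] >= h - dh * 1e-6
    if (!any(keep)) next
    cc <- coords[keep, , drop = FALSE]
    vv <- vox[keep]
    k <- nrow(cc)
    edges <- NULL
    if (k > 1) {
      pairs <- t(combn(k, 2))
      dd <- abs(cc[pairs[, 1], , drop = FALSE] - cc[pairs[, 2], , drop = FALSE])
      cheb <- apply(dd, 1, max)
      manh <- rowSums(dd)
      adj <- switch(as.character(connectivity),
                    "6" = cheb == 1 & manh == 1,
                    "18" = cheb == 1 & manh <= 2,
                    "26" = cheb == 1)
      edges <- pairs[adj, , drop = FALSE]
    }
    g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_len(k), seq_len(k))),
                                     directed = FALSE)
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    out[vv] <- out[vv] + sizes^E * h^H * dh
  }
  out
}

# Benjamini-Hochberg step-up by the definition: q_(i) = min_{j >= i} p_(j) n / j.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Random unit director field on a small grid.
random_director_field <- function(shape = c(6, 6, 6), seed = 1) {
  set.seed(seed)
  a <- array(rnorm(prod(shape) * 3), c(shape, 3))
  nrm <- sqrt(a[, , , 1]^2 + a[, , , 2]^2 + a[, , , 3]^2)
  for (k in 1:3) a[, , , k] <- a[, , , k] / nrm
  director_field(a)
}

# Flip the director sign at a random subset of voxels.
flip_directors <- function(field, seed = 1) {
  set.seed(seed)
  s <- array(sample(c(-1, 1), prod(dim(field$mask)), replace = TRUE),
             dim(field$mask))
  a <- field$directors
  for (k in 1:3) a[, , , k] <- a[, , , k] * s
  director_field(a, field$mask, field$spacing)
}

# Interior selector: drop `border` voxels on every face.
interior_mask <- function(shape, border = 2) {
  m <- array(FALSE, shape)
  ix <- lapply(shape, function(n) (border + 1):(n - border))
  m[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
  m
}

# In-plane radius (in voxel units) from the grid center, as a 3-D array.
radius_array <- function(shape) {
  ctr <- (shape[1:2] - 1) / 2
  x <- (0:(shape[1] - 1)) - ctr[1]
  y <- (0:(shape[2] - 1)) - ctr[2]
  array(rep(sqrt(outer(x^2, y^2, `+`)), shape[3]), shape)
}

# Small two-ROI cohort spec used by several statistics tests.
quick_cohort_spec <- function(..., seed = 1) {
  cohort_spec(n_per_group = c(HC = 16, MSA = 16), metrics = "twist",
              output = "volumes", seed = seed, ...)
}
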