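# Independent reference implementations used as test oracles. These stay
# deliberately naive (reshape/transpose, exhaustive pairwise distances,
# central differences) and share no code with the package internals.

# Channel shuffle by reshape-transpose on the channel index.
oracle_shuffle_perm <- function(C, groups) {
  idx <- matrix(seq_len(C), nrow = C / groups, ncol = groups, byrow = FALSE)
  as.vector(t(idx))
}

# All surface voxels of a binary mask: any voxel with a 6-neighbour outside
# the mask (volume border counts as outside).
oracle_surface <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  keep <- vapply(seq_len(nrow(idx)), function(i) {
    v <- idx[i, ] + 1L
    !(pad[v[1] - 1, v[2], v[3]] && pad[v[1] + 1, v[2], v[3]] &&
        pad[v[1], v[2] - 1, v[3]] && pad[v[1], v[2] + 1, v[3]] &&
        pad[v[1], v[2], v[3] - 1] && pad[v[1], v[2], v[3] + 1])
  }, logical(1))
  idx[keep, , drop = FALSE]
}

# O(n*m) pairwise directed distances between surface point sets (mm).
oracle_directed <- function(a_idx, b_idx, spacing) {
  as <- sweep(a_idx, 2, spacing, "*")
  bs <- sweep(b_idx, 2, spacing, "*")
  vapply(seq_len(nrow(as)), function(i) {
    sqrt(min(colSums((t(bs) - as[i, ])^2)))
  }, numeric(1))
}

oracle_hd <- function(pred, truth, spacing = c(1, 1, 1), percentile = 100) {
  sp <- oracle_surface(pred)
  st <- oracle_surface(truth)
  d1 <- oracle_directed(sp, st, spacing)
  d2 <- oracle_directed(st, sp, spacing)
  if (percentile >= 100) return(max(max(d1), max(d2)))
  max(quantile(d1, percentile / 100, names = FALSE),
      quantile(d2, percentile / 100, names = FALSE))
}

random_mask <- function(extent = 8L, p = 0.3) {
  array(runif(extent^3) < p, dim = rep(extent, 3L))
}

# central-difference gradient of a scalar function of an array
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# a small network configuration for fast structural tests
tiny_config <- function(input_size = 16L)
  hmnet_config(input_size = input_size, branch_channels = c(8L, 16L, 32L, 64L))

rand_volume <- function(channels, extent, sd = 0.5)
  array(rnorm(channels * extent^3, sd = sd), dim = c(channels, rep(extent, 3L)))
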