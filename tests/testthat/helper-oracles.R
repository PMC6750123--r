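# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive per-voxel loops / direct formulas and share no
# code with the package internals.

oracle_ssd <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s
}

oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    na <- na + a[i]; nb <- nb + b[i]
  }
  2 * inter / (na + nb)
}

# joint-histogram MI in bits, equal-width bins over each vector's [min,max]
oracle_mi <- function(a, b, n_bins) {
  bin <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) return(rep(1L, length(v)))
    i <- floor((v - lo) / (hi - lo) * n_bins) + 1L
    pmin(i, n_bins)
  }
  ia <- bin(a); ib <- bin(b)
  joint <- matrix(0, n_bins, n_bins)
  for (t in seq_along(ia)) joint[ia[t], ib[t]] <- joint[ia[t], ib[t]] + 1
  p <- joint / length(ia)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in 1:n_bins) for (j in 1:n_bins)
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  mi
}

# direct 4x4 homogeneous matrix product, element by element
oracle_matmul <- function(a, b) {
  out <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    for (k in 1:4) out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

# random small volume / mask on a simple grid
rand_volume <- function(dim = c(8, 8, 8), v2w = diag(4)) {
  new_volume(array(runif(prod(dim), 10, 100), dim = dim), v2w)
}

rand_mask <- function(dim = c(8, 8, 8), p = 0.4, v2w = diag(4)) {
  new_mask(array(as.double(runif(prod(dim)) < p), dim = dim), v2w)
}

random_invertible_affine <- function(from = "a", to = "b") {
  p <- c(runif(3, -40, 40), runif(3, -20, 20),
         runif(3, 0.7, 1.3), runif(3, -0.2, 0.2))
  affine_transform(params = p, from_space = from, to_space = to)
}

# coarse phantom settings: same 192 mm world extent as the default grid but
# 4 mm voxels, so registrations run in about a second
coarse_spec <- function(...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L), voxel_size = c(4, 4, 4), ...)
}

# tiny mediator library of distinct-anatomy phantoms for workflow tests
tiny_library <- function(n = 3, seed = 11, spec = coarse_spec()) {
  cohort <- make_cohort(n, 1, seed = seed, spec = spec)
  cohort$library
}
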