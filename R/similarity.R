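#' Histogram matching of one volume to another
#'
#' Remaps `source` intensities through the monotone map that sends its
#' empirical quantiles to those of `reference` (piecewise-linear CDF matching
#' on `n_levels` quantile points). Used to normalize each mediator to the
#' registered subject image before SSD scoring; mutual information needs no
#' such normalization.
#'
#' @param source volume to remap.
#' @param reference volume supplying the target intensity distribution.
#' @param n_levels number of quantile points of the matching map.
#' @return `source` with remapped intensities (same grid).
#' @export
histogram_match <- function(source, reference, n_levels = 256L) {
  stopifnot(inherits(source, "medbridge_volume"),
            inherits(reference, "medbridge_volume"))
  if (n_levels < 2L) stop("n_levels must be at least 2")
  s <- as.numeric(source$data)
  r <- as.numeric(reference$data)
  if (max(s) == min(s)) stop("constant-valued source volume")
  if (max(r) == min(r)) stop("constant-valued reference volume")
  probs <- seq(0, 1, length.out = n_levels)
  qs <- quantile(s, probs, names = FALSE, type = 7)
  qr <- quantile(r, probs, names = FALSE, type = 7)
  # collapse duplicated source quantiles, keeping the map monotone
  keep <- !duplicated(qs)
  qs <- qs[keep]; qr <- qr[keep]
  out <- if (length(qs) == 1L) rep(qr, length(s))
         else approx(qs, qr, xout = s, rule = 2, ties = "ordered")$y
  new_volume(array(out, dim = source$shape), source$voxel_to_world)
}

#' Sum of squared differences
#'
#' `sum((x - y)^2)` over every voxel of the shared grid — no masking, so
#' out-of-field-of-view zeros after resampling penalize poor overlap.
#' Smaller is better; the mediator with the smallest SSD against the
#' registered subject is selected.
#'
#' @param x,y volumes on the same grid.
#' @return Non-negative scalar.
#' @export
ssd <- function(x, y) {
  stopifnot(inherits(x, "medbridge_volume"), inherits(y, "medbridge_volume"))
  if (!identical(x$shape, y$shape)) stop("volumes must share a grid")
  sum((as.numeric(x$data) - as.numeric(y$data))^2)
}

bin_indices <- function(v, n_bins) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(rep(1L, length(v)))
  i <- floor((v - lo) / (hi - lo) * n_bins) + 1L
  i[i > n_bins] <- n_bins
  as.integer(i)
}

#' Mutual information between two volumes
#'
#' MI in bits from the joint `n_bins` x `n_bins` equal-width intensity
#' histogram over all voxels of the shared grid (each image binned over its
#' own [min, max] range): `sum p(x,y) log2(p(x,y) / (p(x) p(y)))`, with
#' zero-count cells contributing 0. The mediator with the highest MI against
#' the registered subject is selected; note raw MI is unbounded above (it
#' equals the marginal entropy for identical images), so only its argmax is
#' meaningful for selection.
#'
#' @param x,y volumes on the same grid.
#' @param n_bins number of histogram bins per axis (>= 2).
#' @return Non-negative scalar, in bits.
#' @export
mutual_information <- function(x, y, n_bins = 64L) {
  stopifnot(inherits(x, "medbridge_volume"), inherits(y, "medbridge_volume"))
  if (!identical(x$shape, y$shape)) stop("volumes must share a grid")
  if (n_bins < 2L) stop("n_bins must be at least 2")
  ix <- bin_indices(as.numeric(x$data), n_bins)
  iy <- bin_indices(as.numeric(y$data), n_bins)
  joint <- tabulate(ix + (iy - 1L) * n_bins, nbins = n_bins * n_bins)
  n <- length(ix)
  pj <- joint / n
  pm <- matrix(pj, n_bins, n_bins)
  px <- rowSums(pm)
  py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log2(pm[nz] / outer(px, py)[nz]))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|X intersect Y| / (|X| + |Y|)` by voxel counting: 1 for complete
#' overlap, 0 for disjoint masks. Registration into the template space is
#' conventionally considered successful when the brain-mask Dice exceeds
#' 0.85.
#'
#' @param x,y `medbridge_mask`s on the same grid, not both empty.
#' @return Scalar in [0, 1].
#' @export
dice <- function(x, y) {
  stopifnot(inherits(x, "medbridge_mask"), inherits(y, "medbridge_mask"))
  if (!identical(x$shape, y$shape)) stop("masks must share a grid")
  nx <- sum(x$data)
  ny <- sum(y$data)
  if (nx + ny == 0) stop("both masks are empty")
  2 * sum(x$data * y$data) / (nx + ny)
}
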