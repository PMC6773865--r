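#' Undecimated a-trous B-spline wavelet decomposition
#'
#' Decomposes a 2-D image into detail planes and a smooth residual with
#' the cubic B-spline a-trous scheme: the separable kernel
#' `[1, 4, 6, 4, 1] / 16` is applied with hole spacing doubling at every
#' level, and detail plane j is the difference between successive
#' smoothings. The transform is exactly additive: the sum of all planes
#' plus the residual reconstructs the input to floating-point precision.
#' Borders are handled by mirror-symmetric extension.
#'
#' @param image numeric matrix of finite intensities.
#' @param n_levels number of detail planes (>= 1). Plane j has a
#'   characteristic support of about `2^j` pixels, so diffraction-limited
#'   spots of ~4 px scale concentrate in plane 2.
#' @return list with `planes` (list of `n_levels` matrices) and
#'   `residual` (matrix).
#' @export
a_trous_decompose <- function(image, n_levels = 2L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix")
  if (anyNA(image) || any(!is.finite(image)))
    stop("`image` must be finite-valued")
  if (n_levels < 1L) stop("`n_levels` must be >= 1")
  if (min(dim(image)) < 5L)
    stop("image smaller than the 5-pixel kernel support")
  planes <- vector("list", n_levels)
  smooth <- image
  for (j in seq_len(n_levels)) {
    nxt <- bspline_smooth(smooth, spacing = 2L^(j - 1L))
    planes[[j]] <- smooth - nxt
    smooth <- nxt
  }
  list(planes = planes, residual = smooth)
}

# Separable B3-spline smoothing with holes of `spacing` pixels,
# mirror-extended borders.
bspline_smooth <- function(image, spacing = 1L) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * spacing
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (k in seq_along(off))  # rows
    out <- out + w[k] * image[reflect_index(seq_len(nr) + off[k], nr), , drop = FALSE]
  res <- matrix(0, nr, nc)
  for (k in seq_along(off))  # columns
    res <- res + w[k] * out[, reflect_index(seq_len(nc) + off[k], nc), drop = FALSE]
  res
}

#' Segmentation parameters
#'
#' @param wavelet_scale characteristic object scale in pixels; must be a
#'   power of two >= 2. The detail plane kept is `log2(wavelet_scale)`
#'   (scale 4 keeps the second plane). Default 4.
#' @param k threshold multiplier: pixels whose wavelet coefficient
#'   exceeds `k` times the local noise SD are foreground. Default 8.
#' @param min_object_area minimum connected-component area in pixels
#'   (default 2).
#' @param tile_size side of the square tiles (pixels) over which the
#'   local noise SD is estimated (default 32).
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(wavelet_scale = 4, k = 8,
                                min_object_area = 2, tile_size = 32) {
  lev <- log2(wavelet_scale)
  if (wavelet_scale < 2 || lev != round(lev))
    stop("`wavelet_scale` must be a power of two >= 2")
  stop_if_not_scalar_num(k, "k", positive = TRUE)
  structure(list(wavelet_scale = wavelet_scale, k = k,
                 min_object_area = as.integer(min_object_area),
                 tile_size = as.integer(tile_size)),
            class = "segmentation_params")
}

# Robust local noise-SD map of a wavelet plane: MAD/0.6745 in
# `tile` x `tile` tiles, bilinearly interpolated between tile centers.
# Estimated on the plane that is thresholded, so the k-sigma rule is
# calibrated against the noise actually present at that scale; the MAD
# makes the estimate robust to the sparse bright spots themselves.
local_sd_map <- function(first_plane, tile = 32L) {
  nr <- nrow(first_plane); nc <- ncol(first_plane)
  if (nr <= tile && nc <= tile)
    return(matrix(stats::mad(first_plane), nr, nc))
  rb <- tile_breaks(nr, tile); cb <- tile_breaks(nc, tile)
  sdg <- matrix(0, length(rb$centers), length(cb$centers))
  for (i in seq_along(rb$centers)) for (j in seq_along(cb$centers))
    sdg[i, j] <- stats::mad(first_plane[rb$lo[i]:rb$hi[i], cb$lo[j]:cb$hi[j]])
  bilinear_expand(sdg, rb$centers, cb$centers, nr, nc)
}

tile_breaks <- function(n, tile) {
  k <- max(1L, floor(n / tile))
  edges <- round(seq(0L, n, length.out = k + 1L))
  lo <- edges[-length(edges)] + 1L; hi <- edges[-1L]
  list(lo = lo, hi = hi, centers = (lo + hi) / 2)
}

bilinear_expand <- function(grid, rc, cc, nr, nc) {
  interp1 <- function(centers, n) {
    # for each output coordinate, the two bracketing centers and weight
    x <- seq_len(n)
    i2 <- findInterval(x, centers, all.inside = TRUE)
    lo <- pmax(i2, 1L); hi <- pmin(i2 + 1L, length(centers))
    d <- centers[hi] - centers[lo]
    whi <- ifelse(d > 0, (x - centers[lo]) / d, 0)
    whi <- pmin(pmax(whi, 0), 1)
    list(lo = lo, hi = hi, whi = whi)
  }
  ri <- interp1(rc, nr); ci <- interp1(cc, nc)
  a <- grid[ri$lo, ci$lo, drop = FALSE]; b <- grid[ri$hi, ci$lo, drop = FALSE]
  cN <- grid[ri$lo, ci$hi, drop = FALSE]; d <- grid[ri$hi, ci$hi, drop = FALSE]
  wr <- matrix(ri$whi, nr, nc); wc <- matrix(ci$whi, nr, nc, byrow = TRUE)
  (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b + (1 - wr) * wc * cN + wr * wc * d
}

# 8-connected labelling: EBImage::bwlabel (4-connective) plus a
# union-find merge of labels that touch diagonally.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    r1 <- seq_len(nr - 1L); c1 <- if (sh[2] > 0) seq_len(nc - 1L) else 2:nc
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + 1L, c1 + sh[2], drop = FALSE]
    hit <- which(a > 0 & b > 0 & a != b)
    for (h in hit) {
      ra <- find(a[h]); rb <- find(b[h])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Detect diffraction-limited objects in one frame
#'
#' The frame is decomposed with [a_trous_decompose()]; the detail plane
#' matching `wavelet_scale` is thresholded at `k` times the local noise
#' SD of that plane (tile-wise MAD estimate, bilinearly interpolated).
#' 8-connected components of at least `min_object_area` pixels become
#' objects; centroids are wavelet-coefficient-weighted centers of mass
#' and `intensity` is the integrated raw intensity over the pixel set.
#'
#' @param image numeric matrix.
#' @param params a [segmentation_params()].
#' @return data frame with columns `x`, `y` (1-based subpixel centroid,
#'   x = column), `area`, `intensity`; the per-object pixel sets are
#'   attached as attribute `"pixels"` (list of 2-column row/col
#'   matrices).
#' @export
segment_frame <- function(image, params = segmentation_params()) {
  dec <- a_trous_decompose(image, n_levels = as.integer(log2(params$wavelet_scale)))
  plane <- dec$planes[[length(dec$planes)]]
  sdmap <- local_sd_map(plane, params$tile_size)
  thr <- params$k * sdmap
  mask <- plane > thr & plane > 0
  lab <- label8(mask)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      area = integer(0), intensity = numeric(0))
  if (max(lab) == 0L) { attr(empty, "pixels") <- list(); return(empty) }
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(image) + 1L
  cols <- (idx - 1L) %/% nrow(image) + 1L
  wts <- plane[idx]
  area <- tabulate(l)
  keep <- which(area >= params$min_object_area)
  if (length(keep) == 0L) { attr(empty, "pixels") <- list(); return(empty) }
  sw  <- vapply(keep, function(g) sum(wts[l == g]), numeric(1))
  cx  <- vapply(keep, function(g) sum(cols[l == g] * wts[l == g]), numeric(1)) / sw
  cy  <- vapply(keep, function(g) sum(rows[l == g] * wts[l == g]), numeric(1)) / sw
  ii  <- vapply(keep, function(g) sum(image[idx[l == g]]), numeric(1))
  out <- data.frame(x = cx, y = cy, area = area[keep], intensity = ii)
  o <- order(out$y, out$x)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pixels") <- lapply(keep[o], function(g)
    cbind(row = rows[l == g], col = cols[l == g]))
  out
}

#' Segment every frame of a movie
#'
#' @param movie a [movie_stack()].
#' @param params a [segmentation_params()].
#' @return data frame of objects with a `frame` column (1-based).
#' @export
segment_movie <- function(movie, params = segmentation_params()) {
  res <- lapply(seq_len(n_frames(movie)), function(f) {
    df <- segment_frame(movie$frames[, , f], params)
    if (nrow(df)) df$frame <- f else df$frame <- integer(0)
    df
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), area = integer(0),
                      intensity = numeric(0), frame = integer(0))
  rownames(out) <- NULL
  out
}
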