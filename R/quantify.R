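#' Background-subtracted fluorescence at a fixed location
#'
#' The fluorescence value at each frame is the mean intensity over
#' pixels whose centers lie within `radius` pixels (default 2 px = 300
#' nm) of `(x, y)`, minus the local background. The background is the
#' mean of the annulus pixels (outer radius 5 px, inner radius 2 px)
#' whose values lie between the 20th and 80th percentiles of the
#' annulus, which excludes neighbouring fluorescent objects. Adding a
#' constant to a frame leaves the value unchanged.
#'
#' @param movie a [movie_stack()].
#' @param x,y location (1-based, possibly subpixel; x = column).
#' @param frames frame indices to measure (default all).
#' @param radius circle radius in pixels (default 2).
#' @param annulus inner/outer annulus radii in pixels (default `c(2, 5)`).
#' @param trim percentile band of annulus values kept for the background
#'   (default `c(0.2, 0.8)`; linear-interpolation quantiles).
#' @return a `fluorescence_trace` data frame with columns `frame`,
#'   `time`, `value` and, for diagnostics, `background` and `bg_sd`
#'   (trimmed-annulus SD).
#' @export
measure_fluorescence <- function(movie, x, y, frames = NULL, radius = 2,
                                 annulus = c(2, 5), trim = c(0.2, 0.8)) {
  d <- dim(movie$frames); nr <- d[1]; nc <- d[2]
  if (x < 1 || x > nc || y < 1 || y > nr)
    stop("(x, y) must lie inside the image")
  if (is.null(frames)) frames <- seq_len(d[3])
  px <- aperture_pixels(x, y, nr, nc, radius, annulus)
  if (length(px$disk) == 0L)
    stop("measurement circle falls fully outside the image")
  pp <- nr * nc
  disk_vals <- matrix(movie$frames[outer(px$disk, (frames - 1L) * pp, "+")],
                      nrow = length(px$disk))
  ann_vals <- if (length(px$annulus))
    matrix(movie$frames[outer(px$annulus, (frames - 1L) * pp, "+")],
           nrow = length(px$annulus)) else NULL
  bg <- bg_sd <- numeric(length(frames))
  for (i in seq_along(frames)) {
    if (is.null(ann_vals)) { bg[i] <- 0; bg_sd[i] <- NA_real_; next }
    v <- ann_vals[, i]
    q <- stats::quantile(v, trim, names = FALSE, type = 7)
    kept <- v[v >= q[1] & v <= q[2]]
    if (length(kept) == 0L) kept <- v
    bg[i] <- mean(kept)
    bg_sd[i] <- stats::sd(kept)
  }
  out <- data.frame(frame = frames, time = movie$frame_times[frames],
                    value = colMeans(disk_vals) - bg,
                    background = bg, bg_sd = bg_sd)
  class(out) <- c("fluorescence_trace", "data.frame")
  attr(out, "location") <- c(x = x, y = y)
  attr(out, "channel") <- movie$channel
  out
}

# Linear pixel indices of the measurement disk and trimmed-background
# annulus around a (possibly subpixel) center; membership by
# pixel-center distance.
aperture_pixels <- function(x, y, nr, nc, radius, annulus) {
  r0 <- max(1L, floor(y - annulus[2])); r1 <- min(nr, ceiling(y + annulus[2]))
  c0 <- max(1L, floor(x - annulus[2])); c1 <- min(nc, ceiling(x + annulus[2]))
  rows <- r0:r1; cols <- c0:c1
  dd <- sqrt(outer((rows - y)^2, (cols - x)^2, "+"))
  lin <- outer(rows, (cols - 1L) * nr, "+")
  list(disk = lin[dd <= radius],
       annulus = lin[dd > annulus[1] & dd <= annulus[2]])
}

#' Peak signal-to-noise ratio at a location
#'
#' SNR of a spot at its appearance frame: (peak pixel in the measurement
#' circle minus local background) divided by the trimmed-annulus SD.
#'
#' @inheritParams measure_fluorescence
#' @param frame single frame index.
#' @return numeric SNR (Inf when the background SD is 0).
#' @export
peak_snr <- function(movie, x, y, frame, radius = 2, annulus = c(2, 5),
                     trim = c(0.2, 0.8)) {
  d <- dim(movie$frames); nr <- d[1]; nc <- d[2]
  px <- aperture_pixels(x, y, nr, nc, radius, annulus)
  img <- movie$frames[, , frame]
  peak <- max(img[px$disk])
  if (length(px$annulus) == 0L) return(Inf)
  v <- img[px$annulus]
  q <- stats::quantile(v, trim, names = FALSE, type = 7)
  kept <- v[v >= q[1] & v <= q[2]]
  if (length(kept) < 2L) kept <- v
  s <- stats::sd(kept)
  if (!is.finite(s) || s == 0) return(Inf)
  (peak - mean(kept)) / s
}

#' Align fluorescence traces and average them
#'
#' Each trace is shifted so that its reference (the frame of maximum
#' intensity, or an externally supplied scission time) sits at time 0,
#' then traces are averaged pointwise over all traces covering each
#' relative timepoint. Optionally each trace is normalized to its peak
#' before averaging.
#'
#' @param traces list of `fluorescence_trace` objects (or data frames
#'   with `time` and `value`).
#' @param reference_kind `"peak"` (default) or `"scission"`; for
#'   `"scission"` each trace must carry a `reference_time` attribute or
#'   an entry in `reference_times`.
#' @param reference_times optional numeric vector of reference times,
#'   one per trace.
#' @param normalize divide each trace by its peak value before averaging.
#' @return list with `time` (relative seconds), `mean`, `n` (traces
#'   covering each timepoint) and `aligned` (list of shifted traces).
#' @export
align_traces <- function(traces, reference_kind = c("peak", "scission"),
                         reference_times = NULL, normalize = FALSE) {
  reference_kind <- match.arg(reference_kind)
  if (length(traces) == 0L) stop("no traces to align")
  aligned <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    ref <- if (reference_kind == "peak") tr$time[which.max(tr$value)]
           else if (!is.null(reference_times)) reference_times[i]
           else attr(tr, "reference_time")
    if (is.null(ref) || is.na(ref))
      stop("trace ", i, " has no scission reference time")
    v <- tr$value
    if (normalize) {
      pk <- max(v)
      if (pk > 0) v <- v / pk
    }
    aligned[[i]] <- data.frame(time = tr$time - ref, value = v)
  }
  all_t <- sort(unique(round(unlist(lapply(aligned, `[[`, "time")), 9)))
  sums <- counts <- numeric(length(all_t))
  for (a in aligned) {
    j <- match(round(a$time, 9), all_t)
    sums[j] <- sums[j] + a$value
    counts[j] <- counts[j] + 1
  }
  list(time = all_t, mean = sums / counts, n = counts, aligned = aligned)
}

#' Estimate and remove green-to-red spectral bleed-through
#'
#' In ppH two-colour recordings the green (pHluorin) signal differs
#' between pH 7.4 and pH 5.5 frames while the true red signal does not;
#' any pH dependence of the measured red trace is therefore
#' bleed-through. The factor g >= 0 minimizes
#' sum((R74 - g G74) - (R55 - g G55))^2, a 1-D quadratic with the
#' closed-form solution g = sum(dR dG) / sum(dG^2) (clamped at 0), where
#' dR = R74 - R55 and dG = G74 - G55.
#'
#' @param red_74,red_55 red-channel values at pH 7.4 / 5.5 frames
#'   (paired samples over events and timepoints).
#' @param green_74,green_55 matching green-channel values.
#' @return list with `factor` (g), `corrected_74` and `corrected_55`
#'   (red minus g times green).
#' @export
correct_bleedthrough <- function(red_74, red_55, green_74, green_55) {
  stopifnot(length(red_74) == length(red_55),
            length(green_74) == length(green_55),
            length(red_74) == length(green_74))
  dR <- red_74 - red_55
  dG <- green_74 - green_55
  den <- sum(dG^2)
  g <- if (den > 0) max(0, sum(dR * dG) / den) else 0
  list(factor = g,
       corrected_74 = red_74 - g * green_74,
       corrected_55 = red_55 - g * green_55)
}

#' Shift-based null envelope for average recruitment traces
#'
#' Builds the 95% confidence envelope for "no specific recruitment" by
#' shifting the real event coordinates within the cell mask `n_shifts`
#' times, recomputing the mean background-subtracted trace on each
#' shifted coordinate set, and taking pointwise 2.5th/97.5th
#' percentiles. By default one rigid translation is applied jointly to
#' all coordinates per shift (preserving the spatial pattern);
#' `mode = "per_event"` draws an independent translation per event.
#'
#' @param movie a [movie_stack()].
#' @param mask logical matrix (cell mask), same frame size as `movie`.
#' @param coords data frame or matrix with columns `x`, `y` (1-based).
#' @param n_shifts number of shifted coordinate sets (default 200).
#' @param seed RNG seed.
#' @param mode `"joint"` (default) or `"per_event"`.
#' @param frames frame indices over which traces are measured.
#' @param max_tries rejection-sampling cap per shift.
#' @param ... passed to [measure_fluorescence()].
#' @return a `confidence_envelope` list: `time`, `lower`, `upper`,
#'   `n_shifts`, plus the matrix of shifted mean traces.
#' @export
shift_null_envelope <- function(movie, mask, coords, n_shifts = 200,
                                seed = 1, mode = c("joint", "per_event"),
                                frames = NULL, max_tries = 10000, ...) {
  mode <- match.arg(mode)
  coords <- as.data.frame(coords)
  if (nrow(coords) == 0L) stop("need at least one event coordinate")
  if (!any(mask)) stop("cell mask is empty")
  d <- dim(movie$frames)
  if (is.null(frames)) frames <- seq_len(d[3])
  inside <- function(xs, ys) {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= d[2] & yi >= 1 & yi <= d[1]
    all(ok) && all(mask[cbind(yi, xi)])
  }
  draw_shift <- function() {
    for (t in seq_len(max_tries)) {
      dx <- sample.int(2L * d[2] - 1L, 1L) - d[2]
      dy <- sample.int(2L * d[1] - 1L, 1L) - d[1]
      if (inside(coords$x + dx, coords$y + dy)) return(c(dx, dy))
    }
    stop("cell mask too small to admit a valid shift")
  }
  mean_trace <- function(xs, ys) {
    m <- rep(0, length(frames))
    for (i in seq_along(xs))
      m <- m + measure_fluorescence(movie, xs[i], ys[i], frames, ...)$value
    m / length(xs)
  }
  shifted <- with_seed(seed, {
    sapply(seq_len(n_shifts), function(s) {
      if (mode == "joint") {
        sh <- draw_shift()
        mean_trace(coords$x + sh[1], coords$y + sh[2])
      } else {
        xs <- numeric(nrow(coords)); ys <- numeric(nrow(coords))
        for (i in seq_len(nrow(coords))) {
          repeat {
            dx <- sample.int(2L * d[2] - 1L, 1L) - d[2]
            dy <- sample.int(2L * d[1] - 1L, 1L) - d[1]
            xi <- coords$x[i] + dx; yi <- coords$y[i] + dy
            if (inside(xi, yi)) { xs[i] <- xi; ys[i] <- yi; break }
          }
        }
        mean_trace(xs, ys)
      }
    })
  })
  shifted <- matrix(shifted, nrow = length(frames))
  env <- apply(shifted, 1, stats::quantile, probs = c(0.025, 0.975),
               names = FALSE, type = 7)
  structure(list(time = movie$frame_times[frames],
                 lower = env[1, ], upper = env[2, ],
                 n_shifts = n_shifts, shifted_means = shifted),
            class = "confidence_envelope")
}

#' Two-channel registration from bead images
#'
#' Least-squares 2-D affine (or translation) transform mapping channel-2
#' bead centroids onto channel 1. With fewer than 3 point pairs, or a
#' degenerate (collinear) layout, the fit falls back to a pure
#' translation with a warning.
#'
#' @param ch1,ch2 matrices or data frames of matched bead centroids
#'   (columns x, y), one row per bead.
#' @param type `"affine"` (default) or `"translation"`.
#' @return list with `A` (2 x 3 matrix: `p1 = A %*% c(x2, y2, 1)`),
#'   `type`, and `residual_rms` in pixels.
#' @export
register_channels <- function(ch1, ch2, type = c("affine", "translation")) {
  type <- match.arg(type)
  p1 <- as.matrix(as.data.frame(ch1)[, 1:2])
  p2 <- as.matrix(as.data.frame(ch2)[, 1:2])
  if (nrow(p1) != nrow(p2) || nrow(p1) < 1L)
    stop("need matched bead centroids in both channels")
  X <- cbind(p2, 1)
  if (type == "affine" && (nrow(p1) < 3L || qr(X)$rank < 3L)) {
    warning("degenerate bead layout; falling back to translation")
    type <- "translation"
  }
  if (type == "affine") {
    B <- qr.solve(X, p1)                   # 3 x 2
    A <- t(B)                              # 2 x 3
  } else {
    tr <- colMeans(p1 - p2)
    A <- cbind(diag(2), tr)
  }
  pred <- X %*% t(A)
  list(A = A, type = type,
       residual_rms = sqrt(mean(rowSums((p1 - pred)^2))))
}

#' Apply a channel registration transform to coordinates
#' @param transform result of [register_channels()].
#' @param coords matrix/data frame with columns x, y (channel-2 frame).
#' @return matrix of transformed coordinates in the channel-1 frame.
#' @export
apply_transform <- function(transform, coords) {
  p <- as.matrix(as.data.frame(coords)[, 1:2])
  out <- cbind(p, 1) %*% t(transform$A)
  colnames(out) <- c("x", "y")
  out
}
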