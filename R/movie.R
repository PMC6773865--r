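#' Movie stack container
#'
#' A `movie_stack` holds a time-lapse fluorescence recording as a numeric
#' array of dimension `height x width x n_frames` together with per-frame
#' timestamps (seconds), a channel label and, for pulsed-pH (ppH)
#' recordings, a per-frame extracellular pH label (7.4 or 5.5). Pixel
#' coordinates inside R follow matrix convention: `y` is the row and `x`
#' the column, both 1-based; files written by the package use 0-based
#' coordinates (see [write_objects_csv()]).
#'
#' @param frames numeric array `height x width x n_frames` (a matrix is
#'   promoted to a single-frame stack).
#' @param frame_times numeric vector of acquisition times in seconds,
#'   strictly increasing, one per frame.
#' @param channel channel label, e.g. `"green"` or `"red"`.
#' @param ph optional numeric vector of per-frame pH labels (7.4 or 5.5).
#' @param pixel_size_nm pixel size in nanometers (default 150, i.e.
#'   a 2-pixel radius corresponds to 300 nm).
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_times, channel = "green", ph = NULL,
                        pixel_size_nm = 150) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a height x width x n_frames array")
  n <- dim(frames)[3L]
  if (length(frame_times) != n)
    stop("`frame_times` must have one entry per frame")
  if (n > 1L && any(diff(frame_times) <= 0))
    stop("`frame_times` must be strictly increasing")
  if (!is.null(ph)) {
    if (length(ph) != n) stop("`ph` must have one label per frame")
    if (any(!ph %in% c(7.4, 5.5)))
      stop("pH labels must be 7.4 or 5.5")
  }
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 channel = channel, ph = ph,
                 pixel_size_nm = pixel_size_nm),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d x %d px, %d frames, channel %s\n",
              d[1], d[2], d[3], x$channel))
  if (!is.null(x$ph))
    cat(sprintf("  pH labels: %s\n",
                paste(names(table(x$ph)), table(x$ph), sep = ":", collapse = ", ")))
  if (d[3] > 1)
    cat(sprintf("  t = %.1f..%.1f s (median dt %.2f s)\n",
                x$frame_times[1], x$frame_times[d[3]],
                stats::median(diff(x$frame_times))))
  invisible(x)
}

#' Number of frames in a movie stack
#' @param movie a [movie_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3L]

#' Split an interleaved ppH recording into pH 7.4 and pH 5.5 movies
#'
#' Frames are sorted by their per-frame pH label into two movies,
#' preserving acquisition order and carrying timestamps over. With 0.5 Hz
#' alternating acquisition each demultiplexed movie is sampled every 4 s.
#'
#' @param movie a [movie_stack()] with a pH label on every frame.
#' @return list with elements `ph74` and `ph55`, each a `movie_stack`
#'   (possibly with zero frames).
#' @export
demultiplex_ph <- function(movie) {
  if (!inherits(movie, "movie_stack")) stop("`movie` must be a movie_stack")
  if (is.null(movie$ph) || anyNA(movie$ph))
    stop("every frame must carry a pH label (7.4 or 5.5)")
  pick <- function(lab) {
    idx <- which(movie$ph == lab)
    d <- dim(movie$frames)
    fr <- movie$frames[, , idx, drop = FALSE]
    movie_stack(array(fr, c(d[1], d[2], length(idx))),
                movie$frame_times[idx], channel = movie$channel,
                pixel_size_nm = movie$pixel_size_nm)
  }
  list(ph74 = pick(7.4), ph55 = pick(5.5))
}

#' Read a multi-page TIFF movie with a metadata sidecar
#'
#' The sidecar (YAML or JSON, decided by file extension) must provide
#' `frame_period` (seconds) and may provide `ph_pattern` (either
#' `"alternating"`, meaning pH 7.4 on the first acquired frame and 5.5 on
#' the next, or an explicit vector of labels), `pixel_size_nm`, `channel`
#' and `intensity_scale` (counts corresponding to TIFF white; default
#' 65535).
#'
#' @param path path to a multi-page TIFF file.
#' @param sidecar path to the YAML/JSON metadata file.
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, sidecar) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stop(sprintf("TIFF page %d has dimensions %dx%d, expected %dx%d",
                 bad, dims[1, bad], dims[2, bad], dims[1, 1], dims[2, 1]))
  }
  meta <- read_sidecar(sidecar)
  if (is.null(meta$frame_period))
    stop("sidecar must provide `frame_period` (seconds)")
  scale <- if (is.null(meta$intensity_scale)) 65535 else meta$intensity_scale
  n <- length(pages)
  arr <- array(0, c(dims[1, 1], dims[2, 1], n))
  for (i in seq_len(n)) arr[, , i] <- round(pages[[i]] * scale)
  ph <- expand_ph_pattern(meta$ph_pattern, n)
  movie_stack(arr, frame_times = (seq_len(n) - 1) * meta$frame_period,
              channel = if (is.null(meta$channel)) "green" else meta$channel,
              ph = ph,
              pixel_size_nm = if (is.null(meta$pixel_size_nm)) 150
                              else meta$pixel_size_nm)
}

read_sidecar <- function(sidecar) {
  if (grepl("\\.json$", sidecar, ignore.case = TRUE))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else yaml::read_yaml(sidecar)
}

expand_ph_pattern <- function(pattern, n) {
  if (is.null(pattern)) return(NULL)
  if (is.character(pattern) && length(pattern) == 1L) {
    if (pattern != "alternating")
      stop("unknown ph_pattern: ", pattern)
    return(rep_len(c(7.4, 5.5), n))
  }
  lab <- as.numeric(pattern)
  if (length(lab) != n) lab <- rep_len(lab, n)
  lab
}

#' Write a movie stack as 16-bit multi-page TIFF plus sidecar
#'
#' Intensities are clipped to `[0, intensity_scale]` and rounded to
#' integers; writing then reading a movie whose values are integers in
#' that range reproduces the array exactly.
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path.
#' @param sidecar optional path for a YAML sidecar describing the movie.
#' @param intensity_scale counts mapped to TIFF white (default 65535).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, sidecar = NULL, intensity_scale = 65535) {
  n <- n_frames(movie)
  pages <- lapply(seq_len(n), function(i) {
    p <- movie$frames[, , i]
    pmin(pmax(round(p), 0), intensity_scale) / intensity_scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(sidecar)) {
    dt <- if (n > 1) diff(movie$frame_times)[1] else 1
    meta <- list(frame_period = dt,
                 pixel_size_nm = movie$pixel_size_nm,
                 channel = movie$channel,
                 intensity_scale = intensity_scale)
    if (!is.null(movie$ph)) meta$ph_pattern <- movie$ph
    yaml::write_yaml(meta, sidecar)
  }
  invisible(path)
}

#' Write detected objects / tracks / candidates with 0-based coordinates
#'
#' File convention: comma-separated UTF-8 with a mandatory header;
#' coordinates are 0-based pixels with `x` the column and `y` the row.
#' In-memory data frames in this package are 1-based (R convention), so
#' this writer subtracts 1 from `x` and `y` columns (and `frame`, if
#' present) and [read_objects_csv()] adds it back.
#'
#' @param df data frame with (some of) columns `x`, `y`, `frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_objects_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (cc in intersect(c("x", "y", "frame", "detection_frame"), names(out)))
    out[[cc]] <- out[[cc]] - 1
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_objects_csv
#' @export
read_objects_csv <- function(path) {
  df <- utils::read.csv(path)
  for (cc in intersect(c("x", "y", "frame", "detection_frame"), names(df)))
    df[[cc]] <- df[[cc]] + 1
  df
}
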