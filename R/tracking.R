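#' Link per-frame objects into tracks
#'
#' Frame-to-frame greedy mutual-nearest-neighbour assignment: between
#' consecutive frames the closest unmatched pair is linked first, then
#' the next closest, and so on, never beyond `max_displacement` pixels.
#' Unmatched objects start new tracks. No gap closing: an object missing
#' for one frame yields two tracks. Clathrin-coated structures are
#' essentially immobile on the 2-4 s frame interval, so the default
#' displacement bound is small.
#'
#' @param objects data frame from [segment_movie()] (columns `frame`,
#'   `x`, `y`, and optionally `area`, `intensity`).
#' @param max_displacement maximum linking distance in pixels (default 3).
#' @return a `track_set`: list with `objects` (the input plus a
#'   `track_id` column) and `tracks` (one row per track: `track_id`,
#'   `start_frame`, `end_frame`, `n_frames`).
#' @export
link_objects <- function(objects, max_displacement = 3) {
  if (max_displacement < 0) stop("`max_displacement` must be >= 0")
  objects <- as.data.frame(objects)
  n <- nrow(objects)
  track_id <- integer(n)
  if (n > 0) {
    o <- order(objects$frame)
    objects <- objects[o, , drop = FALSE]
    rownames(objects) <- NULL
    next_id <- 0L
    frames <- sort(unique(objects$frame))
    idx_by_frame <- split(seq_len(n), objects$frame)
    for (fi in seq_along(frames)) {
      cur <- idx_by_frame[[as.character(frames[fi])]]
      prev <- if (fi > 1L && frames[fi] - frames[fi - 1L] == 1L)
        idx_by_frame[[as.character(frames[fi - 1L])]] else integer(0)
      assigned <- rep(FALSE, length(cur))
      if (length(prev)) {
        d <- sqrt(outer(objects$x[prev], objects$x[cur], "-")^2 +
                  outer(objects$y[prev], objects$y[cur], "-")^2)
        d[d > max_displacement] <- Inf
        while (any(is.finite(d))) {
          m <- arrayInd(which.min(d), dim(d))
          track_id[cur[m[2]]] <- track_id[prev[m[1]]]
          assigned[m[2]] <- TRUE
          d[m[1], ] <- Inf; d[, m[2]] <- Inf
        }
      }
      for (j in which(!assigned)) {
        next_id <- next_id + 1L
        track_id[cur[j]] <- next_id
      }
    }
  }
  objects$track_id <- track_id
  summarize_tracks(objects)
}

summarize_tracks <- function(objects) {
  if (nrow(objects)) {
    sp <- split(objects$frame, objects$track_id)
    tracks <- data.frame(track_id = as.integer(names(sp)),
                         start_frame = vapply(sp, min, numeric(1)),
                         end_frame = vapply(sp, max, numeric(1)),
                         n_frames = lengths(sp))
    tracks <- tracks[order(tracks$track_id), , drop = FALSE]
    rownames(tracks) <- NULL
  } else {
    tracks <- data.frame(track_id = integer(0), start_frame = numeric(0),
                         end_frame = numeric(0), n_frames = integer(0))
  }
  structure(list(objects = objects, tracks = tracks), class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks over %d objects\n",
              nrow(x$tracks), nrow(x$objects)))
  invisible(x)
}

#' Keep tracks of sufficient duration
#'
#' Objects trackable over enough consecutive frames are retained for
#' analysis; the default keeps tracks covering at least 4 frames
#' (i.e. more than three).
#'
#' @param track_set a `track_set` from [link_objects()].
#' @param min_frames minimum number of frames (default 4).
#' @return a filtered `track_set`.
#' @export
filter_tracks <- function(track_set, min_frames = 4) {
  keep <- track_set$tracks$track_id[track_set$tracks$n_frames >= min_frames]
  objects <- track_set$objects[track_set$objects$track_id %in% keep, , drop = FALSE]
  rownames(objects) <- NULL
  summarize_tracks(objects)
}
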