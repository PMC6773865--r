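#' Detect candidate scission events in a ppH recording
#'
#' Objects appearing in the pH 5.5 movie are candidate clathrin-coated
#' vesicles (newly internalized, pHluorin-positive) if (i) they are
#' visible for more than three pH 5.5 frames, (ii) their signal-to-noise
#' ratio at the appearance frame is high enough, and (iii) a cluster
#' pre-existed at the same location in the pH 7.4 movie for at least
#' five frames before they appeared. All candidates are returned with a
#' flag per criterion; `accepted_by_rules` is the conjunction.
#'
#' @param ph74,ph55 demultiplexed [movie_stack()]s (co-registered, same
#'   frame size).
#' @param params a [segmentation_params()].
#' @param snr_threshold minimum peak SNR at the appearance frame
#'   (default 3).
#' @param colocalization_radius maximum distance (px) between the pH 5.5
#'   appearance position and a pH 7.4 track (default 2).
#' @param min_visibility minimum number of pH 5.5 frames ("more than
#'   three" = 4, the default).
#' @param min_cluster_frames minimum number of pH 7.4 frames the cluster
#'   must cover strictly before the appearance time (default 5).
#' @param max_displacement tracking displacement bound in pixels.
#' @return data frame of candidates: `event_id`, `detection_frame`
#'   (pH 5.5 frame index), `time` (s), `x`, `y`, `visibility_frames`,
#'   `snr`, `preexisting_cluster_frames`, the three rule flags and
#'   `accepted_by_rules`.
#' @export
detect_candidates <- function(ph74, ph55, params = segmentation_params(),
                              snr_threshold = 3, colocalization_radius = 2,
                              min_visibility = 4, min_cluster_frames = 5,
                              max_displacement = 3) {
  if (!identical(dim(ph74$frames)[1:2], dim(ph55$frames)[1:2]))
    stop("pH 7.4 and pH 5.5 movies must have identical image dimensions")
  empty <- data.frame(event_id = integer(0), detection_frame = integer(0),
                      time = numeric(0), x = numeric(0), y = numeric(0),
                      visibility_frames = integer(0), snr = numeric(0),
                      preexisting_cluster_frames = integer(0),
                      pass_visibility = logical(0), pass_snr = logical(0),
                      pass_cluster = logical(0), accepted_by_rules = logical(0))
  if (n_frames(ph55) == 0L) return(empty)
  ts55 <- link_objects(segment_movie(ph55, params), max_displacement)
  if (nrow(ts55$tracks) == 0L) return(empty)
  ts74 <- link_objects(segment_movie(ph74, params), max_displacement)

  res <- lapply(seq_len(nrow(ts55$tracks)), function(i) {
    tr <- ts55$tracks[i, ]
    obj <- ts55$objects[ts55$objects$track_id == tr$track_id, , drop = FALSE]
    first <- obj[which.min(obj$frame), ]
    t_appear <- ph55$frame_times[first$frame]
    snr <- peak_snr(ph55, first$x, first$y, first$frame)
    # pH 7.4 cluster frames strictly before the appearance time, for the
    # best track within the colocalization radius of the appearance site
    cl <- 0L
    if (nrow(ts74$objects)) {
      d2 <- (ts74$objects$x - first$x)^2 + (ts74$objects$y - first$y)^2
      near_tracks <- unique(ts74$objects$track_id[d2 <= colocalization_radius^2])
      for (tid in near_tracks) {
        fr <- ts74$objects$frame[ts74$objects$track_id == tid]
        cl <- max(cl, sum(ph74$frame_times[fr] < t_appear))
      }
    }
    data.frame(detection_frame = first$frame, time = t_appear,
               x = first$x, y = first$y,
               visibility_frames = tr$n_frames, snr = snr,
               preexisting_cluster_frames = cl)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$time, out$x), , drop = FALSE]
  out$pass_visibility <- out$visibility_frames >= min_visibility
  out$pass_snr <- out$snr >= snr_threshold
  out$pass_cluster <- out$preexisting_cluster_frames >= min_cluster_frames
  out$accepted_by_rules <- out$pass_visibility & out$pass_snr & out$pass_cluster
  out <- cbind(event_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Extract the classifier patch stack for a candidate event
#'
#' A 15 x 15 pixel window centred on the candidate position is cut from
#' 11 consecutive pH 5.5 frames around the detection frame, which sits
#' at position 6 of 11 — 15 x 15 x 11 = 2475 pixel values per
#' candidate. Out-of-field pixels (spatially or temporally) are
#' zero-filled and marked in `pad_mask`.
#'
#' @param ph55 pH 5.5 [movie_stack()].
#' @param x,y candidate position (1-based; rounded to the nearest pixel).
#' @param detection_frame pH 5.5 frame index of the appearance.
#' @param half half-width of the window (default 7, i.e. 15 px).
#' @param before,after frames before/after the detection frame
#'   (defaults 5 and 5, giving the 11-frame block).
#' @return a `patch_stack`: list with `values` (15 x 15 x 11 array),
#'   `pad_mask` (logical array, TRUE where padded) and the event
#'   location. `as.vector()` on a `patch_stack` flattens to length 2475.
#' @export
extract_patch_stack <- function(ph55, x, y, detection_frame,
                                half = 7L, before = 5L, after = 5L) {
  d <- dim(ph55$frames)
  side <- 2L * half + 1L
  nfr <- before + after + 1L
  xi <- round(x); yi <- round(y)
  vals <- array(0, c(side, side, nfr))
  pad <- array(TRUE, c(side, side, nfr))
  rows <- (yi - half):(yi + half)
  cols <- (xi - half):(xi + half)
  frs <- (detection_frame - before):(detection_frame + after)
  rok <- rows >= 1L & rows <= d[1]
  cok <- cols >= 1L & cols <= d[2]
  for (k in seq_len(nfr)) {
    if (frs[k] < 1L || frs[k] > d[3]) next
    vals[rok, cok, k] <- ph55$frames[rows[rok], cols[cok], frs[k]]
    pad[rok, cok, k] <- FALSE
  }
  structure(list(values = vals, pad_mask = pad,
                 x = x, y = y, detection_frame = detection_frame),
            class = "patch_stack")
}

#' @export
as.vector.patch_stack <- function(x, mode = "any") as.vector(x$values, mode)

#' Extract patch stacks for all candidates of a recording
#' @param ph55 pH 5.5 [movie_stack()].
#' @param candidates data frame from [detect_candidates()].
#' @param ... passed to [extract_patch_stack()].
#' @return list of `patch_stack` objects, one per candidate row.
#' @export
extract_patch_stacks <- function(ph55, candidates, ...) {
  lapply(seq_len(nrow(candidates)), function(i)
    extract_patch_stack(ph55, candidates$x[i], candidates$y[i],
                        candidates$detection_frame[i], ...))
}
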