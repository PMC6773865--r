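#' Configuration for the ppH movie simulator
#'
#' Defines the acquisition and biology of a simulated pulsed-pH TIRF
#' recording: frames are acquired at 0.5 Hz (`frame_period` 2 s) with
#' the extracellular pH alternating 7.4/5.5, so each demultiplexed movie
#' is sampled every 4 s. Clathrin-coated structures appear as
#' PSF-blurred Gaussian spots in pH 7.4 frames; each scission event adds
#' a vesicle spot to pH 5.5 frames from its scission time, preceded by a
#' cluster that pre-exists at the same site. Camera noise is
#' Poisson(signal x gain) plus Gaussian read noise; setting
#' `poisson_gain = 0` and `read_noise_sd = 0` gives the noiseless
#' signal.
#'
#' @param image_height,image_width frame size in pixels (default 96).
#' @param pixel_size_nm pixel size in nanometers (default 150; a
#'   2-pixel radius is then 300 nm).
#' @param frame_period acquisition period in seconds (default 2, i.e.
#'   0.5 Hz).
#' @param duration recording duration in seconds (default 480).
#' @param ph_pattern `"alternating"` (pH 7.4 on the first acquired
#'   frame) or an explicit per-frame label vector.
#' @param ccs_density standing density of non-scission transient
#'   clusters, per square micrometer (default 0.05).
#' @param ccs_lifetime_mean mean cluster lifetime in seconds
#'   (default 40).
#' @param scission_rate scission events per minute per square
#'   micrometer (default 0.2; control recordings lie around
#'   0.025-0.34).
#' @param cluster_amplitude,vesicle_amplitude spot peak amplitudes in
#'   counts (defaults 200 and 150).
#' @param vesicle_visible_duration seconds a vesicle stays visible in
#'   pH 5.5 frames after scission (default 20).
#' @param psf_sigma Gaussian PSF sigma in pixels (default 1.3).
#' @param background_level constant background in counts (default 100).
#' @param read_noise_sd Gaussian read noise SD in counts (default 5).
#' @param poisson_gain counts per photon for the shot-noise term
#'   (default 1; 0 disables shot noise).
#' @param bleedthrough_factor green-to-red bleed-through fraction used
#'   when a red channel is rendered (default 0).
#' @param orphan_fraction fraction of scission events planted without a
#'   pre-existing cluster (default 0) — detector negative controls.
#' @param mask optional logical cell mask; default is a centered
#'   ellipse covering ~60% of the field.
#' @param seed RNG seed; identical configurations and seeds give
#'   bit-identical output.
#' @return a `pph_sim_config` list.
#' @export
pph_sim_config <- function(image_height = 96, image_width = 96,
                           pixel_size_nm = 150, frame_period = 2,
                           duration = 480, ph_pattern = "alternating",
                           ccs_density = 0.05, ccs_lifetime_mean = 40,
                           scission_rate = 0.2,
                           cluster_amplitude = 200, vesicle_amplitude = 150,
                           vesicle_visible_duration = 20,
                           psf_sigma = 1.3, background_level = 100,
                           read_noise_sd = 5, poisson_gain = 1,
                           bleedthrough_factor = 0, orphan_fraction = 0,
                           mask = NULL, seed = 1) {
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              pixel_size_nm = pixel_size_nm, frame_period = frame_period,
              duration = duration, ph_pattern = ph_pattern,
              ccs_density = ccs_density,
              ccs_lifetime_mean = ccs_lifetime_mean,
              scission_rate = scission_rate,
              cluster_amplitude = cluster_amplitude,
              vesicle_amplitude = vesicle_amplitude,
              vesicle_visible_duration = vesicle_visible_duration,
              psf_sigma = psf_sigma, background_level = background_level,
              read_noise_sd = read_noise_sd, poisson_gain = poisson_gain,
              bleedthrough_factor = bleedthrough_factor,
              orphan_fraction = orphan_fraction, mask = mask, seed = seed)
  stop_if_not_scalar_num(cfg$frame_period, "frame_period", positive = TRUE)
  stop_if_not_scalar_num(cfg$duration, "duration", positive = TRUE)
  for (f in c("ccs_density", "ccs_lifetime_mean", "scission_rate",
              "cluster_amplitude", "vesicle_amplitude",
              "vesicle_visible_duration", "background_level",
              "read_noise_sd", "poisson_gain", "orphan_fraction"))
    stop_if_not_scalar_num(cfg[[f]], f, nonneg = TRUE)
  stop_if_not_scalar_num(cfg$psf_sigma, "psf_sigma", positive = TRUE)
  if (cfg$image_height < 8L || cfg$image_width < 8L)
    stop("image must be at least 8 x 8 pixels")
  structure(cfg, class = "pph_sim_config")
}

default_cell_mask <- function(h, w) {
  # centered ellipse covering ~60% of the field: pi (s w/2)(s h/2) = 0.6 w h
  s <- sqrt(2.4 / pi)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((xx - (w + 1) / 2) / (s * w / 2))^2 + ((yy - (h + 1) / 2) / (s * h / 2))^2 <= 1
}

# Add a Gaussian spot of peak `amp` at subpixel (x, y) to image `img`,
# evaluated on a +/- 6 sigma window.
add_spot <- function(img, x, y, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(6 * sigma)
  rows <- max(1L, floor(y - r)):min(h, ceiling(y + r))
  cols <- max(1L, floor(x - r)):min(w, ceiling(x + r))
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  g <- amp * exp(-outer((rows - y)^2, (cols - x)^2, "+") / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + g
  img
}

#' Simulate a ppH TIRF recording with ground truth
#'
#' Generates the interleaved acquisition implied by `config`, then
#' returns it already demultiplexed into pH 7.4 and pH 5.5 movies
#' together with the ground-truth event table (the oracle for detector
#' recall/precision) and the cell mask. Scission events are a
#' homogeneous Poisson process over the mask area and recording
#' duration; each event's parent cluster is born an Exp(lifetime) time
#' before scission and is visible in pH 7.4 frames until scission,
#' while the vesicle is visible in pH 5.5 frames from scission for
#' `vesicle_visible_duration`. Additional transient clusters that never
#' undergo scission are planted at the configured standing density.
#'
#' @param config a [pph_sim_config()].
#' @return list with `ph74`, `ph55` ([movie_stack()]s), `interleaved`
#'   (the full labeled stack), `events` (ground truth: `event_id`,
#'   `birth_s`, `scission_s`, `x_px`, `y_px`, amplitudes,
#'   `visible_s`, `has_cluster`), `mask`, and for
#'   `bleedthrough_factor > 0` a red-channel `red` movie.
#' @export
simulate_pph_movie <- function(config = pph_sim_config()) {
  h <- config$image_height; w <- config$image_width
  mask <- if (is.null(config$mask)) default_cell_mask(h, w) else config$mask
  if (!any(mask)) stop("cell mask has zero area")
  px_um <- config$pixel_size_nm / 1000
  area_um2 <- sum(mask) * px_um^2
  n_acq <- floor(config$duration / config$frame_period)
  times <- (seq_len(n_acq) - 1) * config$frame_period
  ph <- expand_ph_pattern(config$ph_pattern, n_acq)

  with_seed(config$seed, {
    # ground-truth scission events
    n_ev <- stats::rpois(1, config$scission_rate * area_um2 *
                            config$duration / 60)
    ev <- draw_positions(n_ev, mask)
    scission <- sort(stats::runif(n_ev, 0, config$duration))
    orphan <- stats::runif(n_ev) < config$orphan_fraction
    age <- stats::rexp(n_ev, rate = 1 / max(config$ccs_lifetime_mean, 1e-9))
    age[orphan] <- 0
    events <- data.frame(
      event_id = seq_len(n_ev),
      birth_s = scission - age, scission_s = scission,
      x_px = ev$x, y_px = ev$y,
      cluster_amplitude = ifelse(orphan, 0, rep(config$cluster_amplitude, n_ev)),
      vesicle_amplitude = rep(config$vesicle_amplitude, n_ev),
      visible_s = rep(config$vesicle_visible_duration, n_ev),
      has_cluster = !orphan)

    # transient non-scission clusters at the standing density
    lt <- max(config$ccs_lifetime_mean, 1e-9)
    birth_rate <- config$ccs_density * area_um2 / lt
    t_lo <- -5 * lt
    n_cl <- stats::rpois(1, birth_rate * (config$duration - t_lo))
    cl <- draw_positions(n_cl, mask)
    cl_birth <- stats::runif(n_cl, t_lo, config$duration)
    cl_death <- cl_birth + stats::rexp(n_cl, rate = 1 / lt)

    render <- function(t, ph_label) {
      img <- matrix(config$background_level, h, w)
      if (ph_label == 7.4) {
        live <- which(events$has_cluster & events$birth_s <= t &
                        t < events$scission_s)
        for (i in live)
          img <- add_spot(img, events$x_px[i], events$y_px[i],
                          events$cluster_amplitude[i], config$psf_sigma)
        live_cl <- which(cl_birth <= t & t < cl_death)
        for (i in live_cl)
          img <- add_spot(img, cl$x[i], cl$y[i],
                          config$cluster_amplitude, config$psf_sigma)
      } else {
        vis <- which(events$scission_s <= t &
                       t < events$scission_s + events$visible_s)
        for (i in vis)
          img <- add_spot(img, events$x_px[i], events$y_px[i],
                          events$vesicle_amplitude[i], config$psf_sigma)
      }
      img
    }
    clean <- array(0, c(h, w, n_acq))
    for (f in seq_len(n_acq)) clean[, , f] <- render(times[f], ph[f])
    noisy <- apply_camera_noise(clean, config)
    interleaved <- movie_stack(noisy, times, channel = "green", ph = ph,
                               pixel_size_nm = config$pixel_size_nm)
    out <- demultiplex_ph(interleaved)
    out$interleaved <- interleaved
    out$events <- events
    out$mask <- mask
    out$config <- config
    if (config$bleedthrough_factor > 0) {
      red_clean <- config$bleedthrough_factor * (clean - config$background_level) +
        config$background_level
      out$red <- movie_stack(apply_camera_noise(red_clean, config), times,
                             channel = "red", ph = ph,
                             pixel_size_nm = config$pixel_size_nm)
    }
    out
  })
}

draw_positions <- function(n, mask) {
  h <- nrow(mask); w <- ncol(mask)
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      xi <- stats::runif(1, 1, w); yi <- stats::runif(1, 1, h)
      if (mask[round(yi), round(xi)]) { x[i] <- xi; y[i] <- yi; break }
    }
  }
  list(x = x, y = y)
}

apply_camera_noise <- function(clean, config) {
  out <- clean
  if (config$poisson_gain > 0) {
    lam <- pmax(clean * config$poisson_gain, 0)
    out <- array(stats::rpois(length(lam), lam), dim(clean))
  }
  if (config$read_noise_sd > 0)
    out <- out + array(stats::rnorm(length(out), 0, config$read_noise_sd),
                       dim(out))
  out
}

#' Simulate an equilibrium binding curve
#'
#' Responses follow the one-site hyperbola `bmax X / (kd + X)` with
#' additive Gaussian noise.
#'
#' @param kd equilibrium dissociation constant, molar (> 0).
#' @param bmax response at maximal binding (> 0).
#' @param concentrations analyte concentrations, molar, >= 0.
#' @param noise_sd Gaussian noise SD in response units (default 0).
#' @param seed RNG seed.
#' @return a [binding_curve()].
#' @export
simulate_equilibrium_curve <- function(kd, bmax, concentrations,
                                       noise_sd = 0, seed = 1) {
  stop_if_not_scalar_num(kd, "kd", positive = TRUE)
  stop_if_not_scalar_num(bmax, "bmax", positive = TRUE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  y <- bmax * concentrations / (kd + concentrations)
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  binding_curve(concentrations, y)
}

#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Numerically integrates `dR/dt = kon C(t) (Rmax - R) - koff R` from
#' `R(0) = 0` over a piecewise-constant injection schedule with
#' fixed-step 4th-order Runge-Kutta (segment boundaries are stepped to
#' exactly), then adds Gaussian noise. As `dt` shrinks the trace
#' converges to the exact piecewise-exponential solution.
#'
#' @param kon association rate, 1/(M s) (> 0).
#' @param koff dissociation rate, 1/s (> 0).
#' @param rmax maximal response, RU (> 0).
#' @param schedule an [injection_schedule()].
#' @param dt integration and sampling step in seconds (default 0.1).
#' @param noise_sd Gaussian noise SD in RU (default 0).
#' @param seed RNG seed.
#' @return a `sensorgram` data frame with columns `time`, `response`
#'   and the schedule as an attribute.
#' @export
simulate_sensorgram <- function(kon, koff, rmax, schedule, dt = 0.1,
                                noise_sd = 0, seed = 1) {
  stop_if_not_scalar_num(kon, "kon", positive = TRUE)
  stop_if_not_scalar_num(koff, "koff", positive = TRUE)
  stop_if_not_scalar_num(rmax, "rmax", positive = TRUE)
  if (!inherits(schedule, "injection_schedule"))
    schedule <- injection_schedule(schedule$start, schedule$end,
                                   schedule$concentration)
  kmax <- kon * max(schedule$concentration) + koff
  if (kmax * dt > 1)
    warning(sprintf(paste("integration step dt = %g is coarse for the",
                          "fastest kinetics (rate %g /s); reduce dt"),
                    dt, kmax))
  deriv <- function(R, C) kon * C * (rmax - R) - koff * R
  n_steps <- vapply(seq_len(nrow(schedule)), function(i)
    as.integer(ceiling((schedule$end[i] - schedule$start[i]) / dt - 1e-9)),
    integer(1))
  times <- numeric(sum(n_steps) + 1L)
  resp <- numeric(sum(n_steps) + 1L)
  times[1] <- schedule$start[1]
  R <- 0
  p <- 1L
  for (i in seq_len(nrow(schedule))) {
    C <- schedule$concentration[i]
    seg_t <- schedule$end[i] - schedule$start[i]
    hs <- rep(dt, n_steps[i])
    if (n_steps[i] > 0) hs[n_steps[i]] <- seg_t - dt * (n_steps[i] - 1)
    t_cur <- schedule$start[i]
    for (s in seq_len(n_steps[i])) {
      hh <- hs[s]
      k1 <- deriv(R, C)
      k2 <- deriv(R + hh / 2 * k1, C)
      k3 <- deriv(R + hh / 2 * k2, C)
      k4 <- deriv(R + hh * k3, C)
      R <- R + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_cur <- t_cur + hh
      p <- p + 1L
      times[p] <- t_cur
      resp[p] <- R
    }
  }
  if (noise_sd > 0)
    resp <- resp + with_seed(seed, stats::rnorm(length(resp), 0, noise_sd))
  out <- data.frame(time = times, response = resp)
  class(out) <- c("sensorgram", "data.frame")
  attr(out, "schedule") <- schedule
  out
}

#' Simulate a piecewise-Poisson scission-event stream
#'
#' Homogeneous Poisson events during the cell-attached window, followed
#' by (in)homogeneous Poisson events during the whole-cell window whose
#' rate may vary with whole-cell time (e.g. declining as an inhibitory
#' peptide dialyses in). Inhomogeneous rates are realized by thinning.
#'
#' @param rate_ca cell-attached event rate, events per minute (>= 0).
#' @param rate_wc whole-cell rate: a single number (events/min) or a
#'   function of whole-cell time in seconds returning events/min.
#' @param t_ca,t_wc durations of the two windows in seconds (> 0).
#' @param cell_area optional cell footprint, square micrometers.
#' @param seed RNG seed; a fixed seed gives identical event times.
#' @return an [event_stream()] with `mode_boundary = t_ca`.
#' @export
simulate_event_stream <- function(rate_ca, rate_wc, t_ca, t_wc,
                                  cell_area = NA_real_, seed = 1) {
  stop_if_not_scalar_num(rate_ca, "rate_ca", nonneg = TRUE)
  stop_if_not_scalar_num(t_ca, "t_ca", positive = TRUE)
  stop_if_not_scalar_num(t_wc, "t_wc", positive = TRUE)
  with_seed(seed, {
    n_ca <- stats::rpois(1, rate_ca * t_ca / 60)
    ca_times <- sort(stats::runif(n_ca, 0, t_ca))
    if (is.function(rate_wc)) {
      grid <- seq(0, t_wc, length.out = 512)
      rmax <- max(vapply(grid, rate_wc, numeric(1)))
      n_prop <- stats::rpois(1, rmax * t_wc / 60)
      tt <- sort(stats::runif(n_prop, 0, t_wc))
      keep <- stats::runif(n_prop) < vapply(tt, rate_wc, numeric(1)) / rmax
      wc_times <- tt[keep]
    } else {
      stop_if_not_scalar_num(rate_wc, "rate_wc", nonneg = TRUE)
      n_wc <- stats::rpois(1, rate_wc * t_wc / 60)
      wc_times <- sort(stats::runif(n_wc, 0, t_wc))
    }
    event_stream(c(ca_times, t_ca + wc_times), mode_boundary = t_ca,
                 cell_area = cell_area)
  })
}

#' Synthetic candidate patch stacks for classifier validation
#'
#' Generates linearly separable candidate patches: "accepted" patches
#' show a centered Gaussian spot appearing at the detection frame and
#' persisting, as a bona fide internalized vesicle does; "rejected"
#' patches contain an off-center transient blob (a neighbouring
#' structure drifting through), on the same noisy background.
#'
#' @param n_accepted,n_rejected patch counts per class.
#' @param amplitude spot peak amplitude in counts (default 60).
#' @param noise_sd background noise SD (default 4).
#' @param seed RNG seed.
#' @return list with `patches` (list of `patch_stack`) and `labels`
#'   (logical, TRUE = accepted).
#' @export
simulate_patch_set <- function(n_accepted = 40, n_rejected = 40,
                               amplitude = 60, noise_sd = 4, seed = 1) {
  with_seed(seed, {
    mk <- function(accepted) {
      vals <- array(stats::rnorm(15 * 15 * 11, 100, noise_sd), c(15, 15, 11))
      if (accepted) {
        for (k in 6:11)
          vals[, , k] <- add_spot(vals[, , k], 8, 8, amplitude, 1.3)
      } else {
        cx <- sample(c(2:4, 12:14), 1); cy <- sample(c(2:4, 12:14), 1)
        for (k in sample(11, 3))
          vals[, , k] <- add_spot(vals[, , k], cx, cy, amplitude, 1.3)
      }
      structure(list(values = vals,
                     pad_mask = array(FALSE, c(15, 15, 11)),
                     x = 8, y = 8, detection_frame = 6),
                class = "patch_stack")
    }
    labels <- c(rep(TRUE, n_accepted), rep(FALSE, n_rejected))
    list(patches = lapply(labels, mk), labels = labels)
  })
}

#' Write the ground-truth event table of a simulated recording
#'
#' Columns `event_id, birth_s, scission_s, x_px, y_px,
#' cluster_amplitude, vesicle_amplitude, visible_s` with 0-based pixel
#' coordinates, matching the sidecar convention of [write_movie()].
#'
#' @param events ground-truth data frame from [simulate_pph_movie()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(events, path) {
  out <- events
  out$x_px <- out$x_px - 1
  out$y_px <- out$y_px - 1
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
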