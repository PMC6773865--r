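# Shared fixtures, all generated in code.

# Flat image with one or more planted Gaussian spots.
planted_image <- function(h = 64, w = 64, bg = 100, spots = NULL,
                          sigma = 1.5, noise_sd = 0, seed = NULL) {
  mk <- function() {
    img <- matrix(bg, h, w)
    if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
    if (!is.null(spots)) {
      for (i in seq_len(nrow(spots))) {
        g <- spots$amp[i] *
          exp(-outer((seq_len(h) - spots$y[i])^2,
                     (seq_len(w) - spots$x[i])^2, "+") / (2 * sigma^2))
        img <- img + g
      }
    }
    img
  }
  if (is.null(seed)) mk() else withr::with_seed(seed, mk())
}

# Noiseless ppH simulation used by the detection-oracle tests: sparse,
# bright, with some orphan (cluster-less) events as negative controls.
noiseless_sim <- function(seed = 11, orphan_fraction = 0.3) {
  simulate_pph_movie(pph_sim_config(
    image_height = 72, image_width = 72, duration = 360,
    scission_rate = 0.05, ccs_density = 0.01, ccs_lifetime_mean = 80,
    read_noise_sd = 0, poisson_gain = 0,
    orphan_fraction = orphan_fraction, seed = seed))
}

# Expected candidate-rule outcome computed directly from ground truth,
# independently of the detector: for each true event, count pH 7.4
# frames covered by its parent cluster strictly before the first pH 5.5
# frame at/after scission, and pH 5.5 frames in its visibility window.
expected_rule_flags <- function(sim, min_visibility = 4, min_cluster_frames = 5) {
  t74 <- sim$ph74$frame_times
  t55 <- sim$ph55$frame_times
  ev <- sim$events
  t_app <- vapply(ev$scission_s, function(s) t55[t55 >= s][1], numeric(1))
  vis <- vapply(seq_len(nrow(ev)), function(i)
    sum(t55 >= ev$scission_s[i] & t55 < ev$scission_s[i] + ev$visible_s[i]),
    numeric(1))
  clf <- vapply(seq_len(nrow(ev)), function(i) {
    if (!ev$has_cluster[i]) return(0)
    sum(t74 >= ev$birth_s[i] & t74 < ev$scission_s[i] & t74 < t_app[i])
  }, numeric(1))
  data.frame(event_id = ev$event_id, t_appear = t_app,
             visibility = vis, cluster_frames = clf,
             accepted = !is.na(t_app) & vis >= min_visibility &
               clf >= min_cluster_frames & ev$has_cluster)
}
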