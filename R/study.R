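#' Scene configurations for the synthetic desk-scale study
#'
#' Builds the clip roster of the package's synthetic study: three
#' pseudo-datasets ("synthA" at 30 fps, "synthB" at 25 fps, "synthC" at
#' 30 fps) of 14/13/13 clips over 5 subjects each, cycling through nine
#' scene types — still, x-translation, y-translation, illumination flicker,
#' z-scale oscillation, background motion, talking, combined x+y
#' translation, and talking with head jitter. Per-clip conditions are drawn
#' from continuous ranges under the clip's seed (HR 55--130 bpm; sinusoidal
#' motion 0.8--1.5 Hz at 2--10 px; scale oscillation 4--10\%; flicker
#' 1.5\%; mouth opening 70--150\% at 1.5--2.3 Hz; pixel noise sd 1.5
#' counts; pulse amplitude 4 counts; landmark tracking lag 3 frames), so
#' motion severity forms a continuum across clips as in real recordings.
#' Clips default to 60 s at 160 x 120 — the full geometry of the emulated
#' recordings scaled down so a complete study runs on a laptop.
#'
#' @param seed Integer master seed; per-clip seeds are derived from it.
#' @param width,height Frame size in pixels.
#' @param duration Clip length in seconds.
#' @param n_per_dataset Clips per pseudo-dataset (length 3).
#' @param scenarios Scene types to cycle through (subset of the nine).
#' @return List of clip descriptors: `dataset_id`, `subject_id`,
#'   `video_id`, `scenario`, `config`.
#' @export
synthetic_study_configs <- function(seed = 1L, width = 160, height = 120,
                                    duration = 60,
                                    n_per_dataset = c(14, 13, 13),
                                    scenarios = c("still", "tx", "ty",
                                                  "flicker", "scale", "bg",
                                                  "talk", "txty",
                                                  "talk_move")) {
  datasets <- data.frame(id = c("synthA", "synthB", "synthC"),
                         fps = c(30, 25, 30), stringsAsFactors = FALSE)
  clips <- list()
  gi <- 0L
  for (d in seq_len(3)) {
    for (j in seq_len(n_per_dataset[d])) {
      gi <- gi + 1L
      scen <- scenarios[((j - 1) %% length(scenarios)) + 1]
      clip_seed <- as.integer(seed) * 1000L + gi
      # per-clip condition draws: continuous ranges, as in real recordings
      pars <- with_seed(clip_seed, list(
        hr = stats::runif(1, 55, 130),
        f_mot = stats::runif(1, 0.8, 1.5),
        amp = stats::runif(1, 2, 10),
        talk_amp = stats::runif(1, 0.7, 1.5),
        f_talk = stats::runif(1, 1.5, 2.3),
        scale_amp = stats::runif(1, 0.04, 0.1)))
      hr <- pars$hr; f_mot <- pars$f_mot; amp <- pars$amp
      talk_amp <- pars$talk_amp; f_talk <- pars$f_talk
      hr_traj <- if (gi %% 5 == 0) hr_ramp(hr, hr + 8, duration) else hr
      cfg <- scene_config(
        width = width, height = height, fps = datasets$fps[d],
        duration = duration, hr_trajectory = hr_traj,
        pulse_amplitude = 4, pixel_noise_sd = 1.5, tracking_lag = 3,
        motion_x = if (scen %in% c("tx", "txty"))
          motion_sinusoid(if (scen == "txty") 0.7 * amp else amp, f_mot,
                          envelope = "ramp")
          else if (scen == "talk_move")
            motion_random_walk(0.5, envelope = "ramp")
          else motion_none(),
        motion_y = if (scen %in% c("ty", "txty"))
          motion_sinusoid(if (scen == "txty") 0.7 * amp else amp, f_mot,
                          envelope = "ramp")
          else if (scen == "talk_move")
            motion_random_walk(0.4, envelope = "ramp")
          else motion_none(),
        scale_motion = if (scen == "scale")
          list(amplitude = pars$scale_amp, freq = f_mot,
               envelope = "ramp") else NULL,
        background_motion = if (scen == "bg") background_bars(80) else NULL,
        flicker = if (scen == "flicker")
          list(amplitude = 0.015, freq = f_mot) else NULL,
        mouth_motion = if (scen %in% c("talk", "talk_move"))
          list(amplitude = talk_amp, freq = f_talk,
               envelope = "ramp") else NULL,
        seed = clip_seed)
      clips[[gi]] <- list(
        dataset_id = datasets$id[d],
        subject_id = paste0(datasets$id[d], "_s", ((j - 1) %% 5) + 1),
        video_id = paste0(datasets$id[d], "_v", j),
        scenario = scen, config = cfg)
    }
  }
  clips
}

#' Run the synthetic end-to-end study
#'
#' Generates every clip of [synthetic_study_configs()], runs the full
#' extraction pipeline (ROI trace, GREEN/CHROM/POS heart rates on 12-s
#' windows at 1-s hop, the four motion features) and labels each window by
#' its absolute error. Clips are rendered and processed one at a time, so
#' memory stays bounded by a single clip.
#'
#' @param seed Integer master seed.
#' @param methods BVP methods to run.
#' @param verbose Print one line per clip.
#' @param ... Passed to [synthetic_study_configs()].
#' @return Labeled window records (see [extract_windows()] and
#'   [label_windows()]) with an added `scenario` column.
#' @export
run_synthetic_study <- function(seed = 1L,
                                methods = c("GREEN", "CHROM", "POS"),
                                verbose = FALSE, ...) {
  clips <- synthetic_study_configs(seed = seed, ...)
  recs <- vector("list", length(clips))
  for (i in seq_along(clips)) {
    cl <- clips[[i]]
    scene <- generate_scene(cl$config)
    r <- extract_windows(scene, methods = methods,
                         video_id = cl$video_id,
                         subject_id = cl$subject_id,
                         dataset_id = cl$dataset_id)
    if (nrow(r) > 0) r$scenario <- cl$scenario
    recs[[i]] <- r
    if (verbose) {
      message(sprintf("[%2d/%d] %s (%s): %d windows", i, length(clips),
                      cl$video_id, cl$scenario, nrow(r) / length(methods)))
    }
  }
  label_windows(do.call(rbind, recs))
}
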