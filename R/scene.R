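#' Motion trajectory specifications
#'
#' Constructors for the motion trajectories a synthetic face can follow along
#' one axis: no motion, a sinusoidal oscillation, or a Gaussian random walk.
#'
#' @param amplitude Peak displacement in pixels.
#' @param freq Oscillation frequency in Hz.
#' @param step_sd Per-frame step standard deviation in pixels.
#' @return A motion specification list consumed by [scene_config()].
#' @name motion_spec
NULL

#' @rdname motion_spec
#' @export
motion_none <- function() list(type = "none")

#' @rdname motion_spec
#' @param envelope `"constant"` for a fixed amplitude, or `"ramp"` for an
#'   amplitude growing linearly from 0 at the start of the clip to
#'   `amplitude` at the end — a clip that starts still and moves ever more,
#'   sweeping the full severity range.
#' @export
motion_sinusoid <- function(amplitude, freq, envelope = c("constant",
                                                          "ramp")) {
  stopifnot(amplitude >= 0, freq > 0)
  list(type = "sinusoid", amplitude = amplitude, freq = freq,
       envelope = match.arg(envelope))
}

#' @rdname motion_spec
#' @param reversion AR(1) mean-reversion coefficient in [0, 1): each step
#'   pulls back toward the rest pose, keeping the jitter stationary around
#'   it (stationary sd is `step_sd / sqrt(1 - reversion^2)`).
#' @export
motion_random_walk <- function(step_sd, reversion = 0.95,
                               envelope = c("constant", "ramp")) {
  stopifnot(step_sd >= 0, reversion >= 0, reversion < 1)
  list(type = "random_walk", step_sd = step_sd, reversion = reversion,
       envelope = match.arg(envelope))
}

#' Background motion specification
#'
#' Drifting sinusoidal luminance bars rendered behind the face, giving the
#' scene temporal activity that is unrelated to face motion.
#'
#' @param amplitude Bar amplitude in 8-bit counts.
#' @param wavelength Spatial wavelength in pixels.
#' @param speed Drift speed in pixels/second.
#' @return A background-motion specification for [scene_config()].
#' @export
background_bars <- function(amplitude, wavelength = 20, speed = 30) {
  stopifnot(amplitude >= 0, wavelength > 0)
  list(amplitude = amplitude, wavelength = wavelength, speed = speed)
}

#' Configure a synthetic face-video scene
#'
#' Describes a deterministic synthetic scene: an elliptical skin-colored face
#' whose interior is modulated by a pulse waveform at a known heart-rate
#' trajectory, with controlled head translation, face-size (z-axis)
#' oscillation, background motion, illumination flicker and pixel noise.
#' Defaults emulate uncompressed webcam rPPG recordings: 640x480 8-bit RGB at
#' 30 fps, 60 s, with a 60 Hz oximeter-style reference trace.
#'
#' @param width,height Frame size in pixels.
#' @param fps Frame rate in frames/s.
#' @param duration Clip length in seconds.
#' @param hr_trajectory Constant bpm value or function(time_s) -> bpm within
#'   40--240 bpm (see [hr_ramp()]).
#' @param pulse_amplitude Peak green-channel pulse modulation in 8-bit counts.
#'   Per-channel amplitudes are `pulse_amplitude * channel_gains`.
#' @param channel_gains Relative R:G:B pulsatility (default 0.33, 1, 0.5,
#'   mimicking green-dominant skin pulsatility).
#' @param harmonic2 Relative second-harmonic amplitude of the pulse waveform.
#' @param motion_x,motion_y Trajectory specs for the face center
#'   ([motion_none()], [motion_sinusoid()], [motion_random_walk()]).
#' @param scale_motion List `(amplitude, freq)`: relative face-axis
#'   oscillation (e.g. amplitude 0.1 = +/-10\% size at `freq` Hz), or
#'   `NULL`. Approaching the camera also brings the face closer to the
#'   light: face brightness is multiplied by the scale factor squared
#'   (inverse-square shading), a multiplicative intensity distortion.
#' @param background_motion List `(amplitude, wavelength, speed)`: drifting
#'   sinusoidal luminance bars behind the face (amplitude in counts,
#'   wavelength in px, speed in px/s), or `NULL`. Lets full-frame temporal
#'   activity exceed face motion, decoupling scene motion from face motion.
#' @param flicker List `(amplitude, freq)`: global multiplicative
#'   illumination modulation `1 + amplitude * sin(2 pi freq t)`, or `NULL`.
#' @param lighting_gradient List with elements `x`, `y` and `z`, each an
#'   RGB triplet of relative illumination change, modelling mixed indoor
#'   lighting (e.g. a greenish fluorescent source on one side, a warm
#'   source elsewhere): the face's illumination is multiplied per channel
#'   by `1 + x_ch (cx - cx0)/width + y_ch (cy - cy0)/height +
#'   z_ch (scale - 1)`, so head translation (and approach, via the scale
#'   factor) changes the face's illumination mix chromatically — a
#'   distortion no single-direction chrominance projection can cancel. Set
#'   to `NULL` for spatially uniform lighting. Defaults to a green--magenta
#'   mix axis: `x = c(-0.3, 0.3, -0.3)`, `y = c(-0.2, 0.2, -0.2)`,
#'   `z = c(-0.75, 0.75, -0.75)`.
#' @param mouth_motion List `(amplitude, freq)`: talking — the rendered
#'   mouth opens and closes at `freq` Hz, its axes growing by up to
#'   `amplitude` relative to rest, exposing dark-red mouth pixels. The
#'   landmark-defined mouth exclusion hull keeps its rest size (lip
#'   landmarks do not track the opening), so the exposed mouth interior
#'   periodically contaminates the ROI. `NULL` for a closed mouth.
#' @param motion_specular Specular shading gain in counts per pixel of
#'   displacement: face pixels gain an additive white (equal-RGB) component
#'   proportional to the face's signed displacement from its rest pose,
#'   emulating how the glossy part of skin reflection brightens toward and
#'   dims away from the key light. Together with background contamination
#'   this gives head motion two chromatically distinct artifact directions,
#'   as in real recordings. Default 1.5.
#' @param pixel_noise_sd Per-pixel Gaussian sensor noise sd in counts.
#' @param tracking_lag Landmark latency in frames: the landmark track
#'   reports the face position `tracking_lag` frames late, emulating face
#'   detector latency. Under fast motion the lagged hull overlaps background
#'   pixels, which is the main mechanism by which motion corrupts the ROI
#'   color trace. Default 2.
#' @param tracking_jitter Landmark localisation noise gain, in px of jitter
#'   sd per px/frame of face speed: each landmark coordinate receives
#'   Gaussian noise with sd proportional to the face's instantaneous speed,
#'   emulating how detector accuracy degrades with motion blur. A static
#'   face is tracked exactly. Default 1.
#' @param face_center Face center `(x, y)` in px; default frame center.
#' @param face_axes Face semi-axes `(a, b)` in px; default
#'   `(0.18 width, 0.25 height)`.
#' @param skin_color,background_color RGB triplets in 8-bit counts.
#' @param seed Integer seed; identical configs with identical seeds render
#'   bit-identical scenes.
#'
#' @return An object of class `scene_config`.
#' @seealso [generate_scene()]
#' @export
scene_config <- function(width = 640, height = 480, fps = 30, duration = 60,
                         hr_trajectory = 72, pulse_amplitude = 4,
                         channel_gains = c(0.33, 1, 0.5), harmonic2 = 0.3,
                         motion_x = motion_none(), motion_y = motion_none(),
                         scale_motion = NULL, background_motion = NULL,
                         flicker = NULL,
                         lighting_gradient = list(x = c(-0.3, 0.3, -0.3),
                                                  y = c(-0.2, 0.2, -0.2),
                                                  z = c(-0.75, 0.75, -0.75)),
                         mouth_motion = NULL,
                         motion_specular = 1.5,
                         pixel_noise_sd = 0,
                         tracking_lag = 2, tracking_jitter = 1,
                         face_center = NULL, face_axes = NULL,
                         skin_color = c(200, 140, 120),
                         background_color = c(60, 70, 90),
                         seed = 1L) {
  stopifnot(width >= 16, height >= 16, fps > 0, duration > 0,
            pulse_amplitude >= 0, pixel_noise_sd >= 0, tracking_lag >= 0,
            length(channel_gains) == 3, all(channel_gains >= 0),
            length(skin_color) == 3, length(background_color) == 3)
  if (is.null(face_center)) face_center <- c((width - 1) / 2, (height - 1) / 2)
  if (is.null(face_axes)) face_axes <- c(0.18 * width, 0.25 * height)
  stopifnot(length(face_center) == 2, length(face_axes) == 2,
            all(face_axes > 2))
  f_bpm <- as_hr_function(hr_trajectory)
  hr <- f_bpm(seq(0, duration, length.out = 257))
  if (any(hr < 40) || any(hr > 240)) {
    stop("hr_trajectory must stay within [40, 240] bpm")
  }
  cfg <- list(width = width, height = height, fps = fps, duration = duration,
              hr_trajectory = f_bpm, pulse_amplitude = pulse_amplitude,
              channel_gains = channel_gains, harmonic2 = harmonic2,
              motion_x = motion_x, motion_y = motion_y,
              scale_motion = scale_motion,
              background_motion = background_motion, flicker = flicker,
              lighting_gradient = lighting_gradient,
              mouth_motion = mouth_motion,
              motion_specular = motion_specular,
              pixel_noise_sd = pixel_noise_sd,
              tracking_lag = as.integer(tracking_lag),
              tracking_jitter = tracking_jitter,
              face_center = face_center, face_axes = face_axes,
              skin_color = skin_color, background_color = background_color,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

# Linear 0 -> 1 amplitude envelope when a motion spec asks for "ramp".
ramp_env <- function(spec, t) {
  if (identical(spec$envelope, "ramp")) t / max(t) else 1
}

# Sample a motion trajectory at frame times. Random-walk draws come from the
# caller's RNG stream (generate_scene seeds it).
sample_motion <- function(spec, t, n) {
  switch(spec$type,
         none = rep(0, n),
         sinusoid = {
           env <- if (identical(spec$envelope, "ramp")) t / max(t) else 1
           env * spec$amplitude * sin(2 * pi * spec$freq * t)
         },
         random_walk = {
           steps <- ramp_env(spec, t) * stats::rnorm(n, sd = spec$step_sd)
           as.numeric(stats::filter(steps, spec$reversion,
                                    method = "recursive"))
         },
         stop("unknown motion type: ", spec$type))
}

#' Render a synthetic scene
#'
#' Renders the frame sequence, analytic landmark track, 60 Hz reference trace
#' and per-frame ground truth described by a [scene_config()]. Landmarks are
#' placed analytically on the face ellipse (12 boundary points) and on the
#' two eye hulls and mouth hull (4 points each, 24 landmarks total), so no
#' face detector is involved and the track is exactly reproducible. The
#' landmark track reports the face position `tracking_lag` frames late.
#'
#' @param config A [scene_config()].
#' @return An object of class `rppg_scene`: a list with elements
#'   \describe{
#'     \item{frames}{list of H x W x 3 integer arrays (8-bit values 0--255);
#'       pixel (x, y) with 0-based x = column, y = row, origin top-left.}
#'     \item{fps}{frame rate.}
#'     \item{landmarks}{n x 24 x 2 array of landmark (x, y) coordinates.}
#'     \item{landmark_groups}{named list of landmark index vectors:
#'       `face`, `eye_left`, `eye_right`, `mouth`.}
#'     \item{reference}{60 Hz [generate_pulse_waveform()] trace.}
#'     \item{truth}{data frame `time_s`, `hr_bpm` at frame times.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' cfg <- scene_config(width = 64, height = 48, fps = 10, duration = 2,
#'                     pulse_amplitude = 0, tracking_lag = 0)
#' sc <- generate_scene(cfg)
#' length(sc$frames)
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  w <- config$width; h <- config$height; fps <- config$fps
  n <- round(fps * config$duration)
  stopifnot(n >= 2)
  t <- (seq_len(n) - 1) / fps

  with_seed(config$seed, {
    mx <- sample_motion(config$motion_x, t, n)
    my <- sample_motion(config$motion_y, t, n)
    sc <- if (is.null(config$scale_motion)) rep(1, n) else
      1 + ramp_env(config$scale_motion, t) * config$scale_motion$amplitude *
        sin(2 * pi * config$scale_motion$freq * t)

    cx <- config$face_center[1] + mx
    cy <- config$face_center[2] + my
    a <- config$face_axes[1] * sc
    b <- config$face_axes[2] * sc
    if (any(cx - a < 1) || any(cx + a > w - 2) ||
        any(cy - b < 1) || any(cy + b > h - 2)) {
      stop("face leaves frame bounds under the configured motion")
    }

    # signed pose term: displacement toward the key light brightens the
    # specular lobe, away dims it (z-approach counts via the scale factor)
    spec <- config$motion_specular *
      (mx + my + (sc - 1) * config$face_axes[2])

    hr <- config$hr_trajectory(t)
    phase <- 2 * pi * cumsum(hr / 60) / fps
    wave <- sin(phase) + config$harmonic2 * sin(2 * phase)
    flick <- if (is.null(config$flicker)) rep(1, n) else
      1 + config$flicker$amplitude * sin(2 * pi * config$flicker$freq * t)
    mouth_sc <- if (is.null(config$mouth_motion)) rep(1, n) else
      1 + ramp_env(config$mouth_motion, t) * config$mouth_motion$amplitude *
        (0.5 + 0.5 * sin(2 * pi * config$mouth_motion$freq * t))

    xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
    yg <- matrix(0:(h - 1), h, w)

    frames <- vector("list", n)
    lmk <- array(NA_real_, dim = c(n, 24, 2))
    bgm <- config$background_motion
    for (i in seq_len(n)) {
      bgpat <- NULL
      if (!is.null(bgm) && bgm$amplitude > 0) {
        row <- bgm$amplitude *
          sin(2 * pi * (0:(w - 1) - bgm$speed * t[i]) / bgm$wavelength)
        bgpat <- matrix(row, h, w, byrow = TRUE)
      }
      frames[[i]] <- render_face_frame(
        xg, yg, cx[i], cy[i], a[i], b[i], config,
        pulse = config$pulse_amplitude * wave[i], flick = flick[i],
        bgpat = bgpat, spec = spec[i], mouth_sc = mouth_sc[i],
        illum = sc[i]^2 * chroma_ill(config, mx[i], my[i], sc[i]))
      il <- max(1L, i - config$tracking_lag)
      pts <- face_landmarks(cx[il], cy[il], a[il], b[il])
      if (config$tracking_jitter > 0 && i > 1) {
        speed <- sqrt((cx[i] - cx[i - 1])^2 + (cy[i] - cy[i - 1])^2 +
                        ((sc[i] - sc[i - 1]) * config$face_axes[2])^2)
        if (speed > 0) {
          pts <- pts + stats::rnorm(length(pts),
                                    sd = config$tracking_jitter * speed)
        }
      }
      lmk[i, , ] <- pts
    }
  })

  reference <- generate_pulse_waveform(config$hr_trajectory, config$duration,
                                       sample_rate = 60,
                                       harmonic2 = config$harmonic2)
  out <- list(frames = frames, fps = fps,
              landmarks = lmk, landmark_groups = landmark_groups(),
              reference = reference,
              truth = data.frame(time_s = t, hr_bpm = hr),
              config = config)
  class(out) <- "rppg_scene"
  out
}

# Landmark layout: 12 points on the face ellipse, 4 on each eye, 4 on the
# mouth. Eye/mouth geometry is proportional to the face axes.
landmark_groups <- function() {
  list(face = 1:12, eye_left = 13:16, eye_right = 17:20, mouth = 21:24)
}

face_landmarks <- function(cx, cy, a, b) {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  face <- cbind(cx + a * cos(th), cy + b * sin(th))
  quad <- function(ecx, ecy, ea, eb) {
    cbind(ecx + c(-ea, ea, 0, 0), ecy + c(0, 0, -eb, eb))
  }
  eye_l <- quad(cx - 0.40 * a, cy - 0.35 * b, 0.18 * a, 0.14 * b)
  eye_r <- quad(cx + 0.40 * a, cy - 0.35 * b, 0.18 * a, 0.14 * b)
  mouth <- quad(cx, cy + 0.45 * b, 0.32 * a, 0.14 * b)
  rbind(face, eye_l, eye_r, mouth)
}

# Per-channel illumination factor of the face at offset (mx, my) from its
# rest position under the mixed-lighting gradient.
chroma_ill <- function(config, mx, my, sc = 1) {
  lg <- config$lighting_gradient
  if (is.null(lg)) return(rep(1, 3))
  z <- if (is.null(lg$z)) rep(0, 3) else lg$z
  1 + lg$x * mx / config$width + lg$y * my / config$height + z * (sc - 1)
}

render_face_frame <- function(xg, yg, cx, cy, a, b, config, pulse, flick,
                              bgpat = NULL, spec = 0, mouth_sc = 1,
                              illum = 1) {
  h <- nrow(xg); w <- ncol(xg)
  in_ell <- function(ecx, ecy, ea, eb) {
    ((xg - ecx) / ea)^2 + ((yg - ecy) / eb)^2 <= 1
  }
  face <- in_ell(cx, cy, a, b)
  eyes <- in_ell(cx - 0.40 * a, cy - 0.35 * b, 0.18 * a, 0.14 * b) |
    in_ell(cx + 0.40 * a, cy - 0.35 * b, 0.18 * a, 0.14 * b)
  mouth <- in_ell(cx, cy + 0.45 * b, 0.32 * a * mouth_sc,
                  0.14 * b * mouth_sc)

  eye_col <- c(45, 35, 35)
  mouth_col <- if (mouth_sc > 1) c(120, 45, 50) else c(150, 75, 70)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    m <- matrix(config$background_color[ch], h, w)
    if (!is.null(bgpat)) m <- m + bgpat
    m[face] <- illum[ch] *
      (config$skin_color[ch] + config$channel_gains[ch] * pulse + spec)
    m[eyes] <- illum[ch] * eye_col[ch]
    m[mouth] <- illum[ch] * mouth_col[ch]
    img[, , ch] <- m
  }
  if (flick != 1) img <- img * flick
  if (config$pixel_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = config$pixel_noise_sd)
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}
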