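# Synthetic embryo time-lapse generator.
#
# Every event class maps to a parametric "motif": a spatial pattern (disc,
# spotted disc, shelled disc, empty capsule, speckle field) rendered inside an
# egg-like boundary, plus a deterministic motion (none, intensity pulse, rigid
# rotation, oscillatory translation, linear drift). Frames are rendered
# analytically from the motif geometry at each time point, so Fourier and
# displacement oracles exist for the motion, and (motif, seed) fully
# determines the output bits. Appearances are test proxies with
# distinguishable signatures, not renderings of real embryo morphology.

SPATIAL_MOTIFS <- c("blob", "blob_with_spots", "shelled_blob",
                    "empty_capsule", "speckled_decay")
MOTIONS <- c("none", "pulse", "rotate", "translate", "drift")

# Run code with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  stats::runif(16)  # burn-in: decorrelate streams from near-identical seeds
  force(code)
}

# Deterministic integer seed mixing (kept below 2^31). Two multiplicative
# rounds plus a final avalanche so near-identical inputs give uncorrelated
# seeds (the generator's first draws are sensitive to seed similarity).
mix_seed <- function(...) {
  parts <- c(...)
  h <- 104729
  for (p in parts) {
    vs <- if (is.character(p)) utf8ToInt(p) else as.numeric(p)
    for (v in vs) {
      h <- (h * 69069 + v + 1) %% 2147483647
      h <- (h * 60493) %% 2147483647
    }
  }
  # avalanche: mix high bits back into low bits
  h <- (h + floor(h / 65536)) * 40503 %% 2147483647
  h <- h %% 2147483647
  as.integer(h + 1)
}

#' Construct a motif specification
#'
#' @param event_label One of the ten event classes ([event_levels()]).
#' @param spatial_motif One of `"blob"`, `"blob_with_spots"`, `"shelled_blob"`,
#'   `"empty_capsule"`, `"speckled_decay"`.
#' @param motion One of `"none"`, `"pulse"`, `"rotate"`, `"translate"`,
#'   `"drift"`.
#' @param motion_amplitude Fractional intensity per cycle (pulse) or pixels
#'   (translate: oscillation amplitude; drift: pixels per second).
#' @param motion_frequency Cycles per second (>= 0).
#' @param noise_sd Additive Gaussian noise s.d. in 8-bit grayscale units.
#' @param radius_frac Motif radius as a fraction of the frame size.
#' @param intensity Peak 8-bit intensity of the motif body.
#' @param n_spots Number of spots for `blob_with_spots`.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(event_label, spatial_motif, motion = "none",
                       motion_amplitude = 0, motion_frequency = 0,
                       noise_sd = 2, radius_frac = 0.3, intensity = 140,
                       n_spots = 3) {
  if (!spatial_motif %in% SPATIAL_MOTIFS)
    stop("invalid spatial_motif '", spatial_motif, "'; must be one of: ",
         paste(SPATIAL_MOTIFS, collapse = ", "))
  if (!motion %in% MOTIONS)
    stop("invalid motion '", motion, "'; must be one of: ",
         paste(MOTIONS, collapse = ", "))
  if (motion_frequency < 0) stop("motion_frequency must be >= 0")
  event_code(event_label)  # validates the label
  structure(list(event_label = event_label, spatial_motif = spatial_motif,
                 motion = motion, motion_amplitude = motion_amplitude,
                 motion_frequency = motion_frequency, noise_sd = noise_sd,
                 radius_frac = radius_frac, intensity = intensity,
                 n_spots = as.integer(n_spots)),
            class = "motif_spec")
}

#' Default motif library
#'
#' Maps each of the ten event classes to exactly one motif. Classes differ in
#' spatial pattern, size and intensity, and several carry a characteristic
#' motion (pulsation for heart beat, translation for crawling, drift for the
#' decaying dead embryo), so spatial and temporal signatures are both
#' represented.
#'
#' @param noise_sd Gaussian noise s.d. applied to every motif.
#' @return Named list of `motif_spec`, one per event class.
#' @export
default_motif_library <- function(noise_sd = 2) {
  lib <- list(
    motif_spec("Pre-Gastrula", "blob", "none", radius_frac = 0.16, intensity = 90,
               noise_sd = noise_sd),
    motif_spec("Gastrula", "blob", "pulse", motion_amplitude = 0.3,
               motion_frequency = 7.5, radius_frac = 0.22, intensity = 110,
               noise_sd = noise_sd),
    motif_spec("Trochophore", "blob_with_spots", "rotate", motion_frequency = 2,
               radius_frac = 0.26, intensity = 120, n_spots = 3, noise_sd = noise_sd),
    motif_spec("Veliger", "shelled_blob", "rotate", motion_frequency = 2,
               radius_frac = 0.30, intensity = 130, noise_sd = noise_sd),
    motif_spec("Eye spots", "blob_with_spots", "none", radius_frac = 0.32,
               intensity = 155, n_spots = 2, noise_sd = noise_sd),
    motif_spec("Heart beat", "shelled_blob", "pulse", motion_amplitude = 0.35,
               motion_frequency = 5, radius_frac = 0.33, intensity = 165,
               noise_sd = noise_sd),
    motif_spec("Crawling", "blob", "translate", motion_amplitude = 4,
               motion_frequency = 1.5, radius_frac = 0.28, intensity = 185,
               noise_sd = noise_sd),
    motif_spec("Radula", "blob_with_spots", "pulse", motion_amplitude = 0.3,
               motion_frequency = 3, radius_frac = 0.34, intensity = 205,
               n_spots = 5, noise_sd = noise_sd),
    motif_spec("Hatch", "empty_capsule", "none", radius_frac = 0.38,
               intensity = 170, noise_sd = noise_sd),
    motif_spec("Dead", "speckled_decay", "drift", motion_amplitude = 0.8,
               radius_frac = 0.34, intensity = 140, noise_sd = noise_sd))
  names(lib) <- vapply(lib, function(m) m$event_label, "")
  lib
}

# Deterministic hash-noise in [0,1) for the speckle pattern.
.speckle <- function(x, y) {
  s <- sin(x * 12.9898 + y * 78.233) * 43758.5453
  s - floor(s)
}

# Render one noiseless frame of a motif at time t (seconds).
render_frame <- function(motif, size, t) {
  bg <- 30
  cx <- (size + 1) / 2; cy <- (size + 1) / 2
  theta <- 0; dx <- 0; scale <- 1
  amp <- motif$motion_amplitude; f <- motif$motion_frequency
  switch(motif$motion,
    none = NULL,
    pulse = { scale <- 1 + amp * sin(2 * pi * f * t) },
    rotate = { theta <- 2 * pi * f * t },
    translate = { dx <- amp * sin(2 * pi * f * t) },
    drift = { dx <- amp * t })
  r <- motif$radius_frac * size
  xs <- matrix(seq_len(size), size, size) - cx - dx
  ys <- matrix(seq_len(size), size, size, byrow = TRUE) - cy
  d <- sqrt(xs^2 + ys^2)
  soft <- function(edge, width = 1.5) pmin(pmax(edge / width, 0), 1)
  I <- motif$intensity
  img <- matrix(bg, size, size)
  body <- switch(motif$spatial_motif,
    blob = soft(r - d) * (I - bg),
    blob_with_spots = {
      b <- soft(r - d) * (I - bg)
      k <- motif$n_spots
      ang <- 2 * pi * (seq_len(k) - 1) / k + theta
      sr <- 0.55 * r; spot_r <- 0.18 * r
      for (j in seq_len(k)) {
        sxj <- sr * cos(ang[j]); syj <- sr * sin(ang[j])
        dj <- sqrt((xs - sxj)^2 + (ys - syj)^2)
        b <- b - soft(spot_r - dj) * 0.65 * (I - bg)
      }
      b
    },
    shelled_blob = {
      b <- soft(r - d) * 0.8 * (I - bg)
      ring <- soft(2 - abs(d - r)) * 0.5 * I
      # a notch in the shell makes rotation visible
      phi <- atan2(ys, xs) - theta
      notch <- soft(0.4 - abs(((phi + pi) %% (2 * pi)) - pi))
      b + ring * (1 - 0.8 * notch)
    },
    empty_capsule = soft(2.5 - abs(d - r)) * (I - bg) + soft(r - d) * 8,
    speckled_decay = {
      sp <- .speckle(round(xs + cx), round(ys + cy))
      soft(r - d) * (0.4 + 0.6 * sp) * (I - bg)
    })
  if (motif$motion == "pulse") body <- body * scale
  img <- img + body
  pmin(pmax(img, 0), 255)
}

#' Render a clip from a motif
#'
#' Deterministic: identical (motif, n_frames, size, seed) give bit-identical
#' output. Noise is additive Gaussian, clipped to the 8-bit range.
#'
#' @param motif A `motif_spec`.
#' @param n_frames Number of frames (>= 1).
#' @param size Frame edge length in pixels (>= 16; default 64).
#' @param seed Integer seed for the noise.
#' @param fps Frame rate used to convert frame index to seconds (default 30).
#' @return A [clip()] with `n_frames` x `size` x `size` x 1 8-bit frames.
#' @export
render_clip <- function(motif, n_frames, size = 64, seed = 1L, fps = 30) {
  stopifnot(inherits(motif, "motif_spec"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (size < 16) stop("size must be >= 16")
  frames <- array(0, c(n_frames, size, size, 1))
  with_seed(seed, {
    for (l in seq_len(n_frames)) {
      fr <- render_frame(motif, size, (l - 1) / fps)
      if (motif$noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(size * size, sd = motif$noise_sd), size, size)
      frames[l, , , 1] <- round(pmin(pmax(fr, 0), 255))
    }
  })
  clip(frames, source_id = motif$event_label)
}

#' Construct a synthetic event schedule
#'
#' @param embryo_id Identifier string.
#' @param onsets Named numeric vector: event label -> onset hour (integers
#'   >= 0). Must be strictly increasing along the canonical event order unless
#'   `allow_heterochrony = TRUE`.
#' @param total_hours Total imaged hours (>= max onset).
#' @param frame_rate Frames per second of the emulated recording.
#' @param clip_seconds Seconds recorded per hour.
#' @param allow_heterochrony Permit onsets out of canonical order.
#' @return A `synthetic_schedule` object.
#' @export
synthetic_schedule <- function(embryo_id, onsets, total_hours,
                               frame_rate = 30, clip_seconds = 20,
                               allow_heterochrony = FALSE) {
  if (is.null(names(onsets)) || any(!nzchar(names(onsets))))
    stop("onsets must be a named vector of event -> onset hour")
  event_code(names(onsets))
  if (any(onsets < 0)) stop("onset hours must be >= 0")
  ord <- order(event_code(names(onsets)))
  if (!allow_heterochrony && is.unsorted(onsets[ord], strictly = TRUE))
    stop("onsets must be strictly increasing in canonical event order ",
         "(set allow_heterochrony = TRUE to override)")
  if (total_hours < max(onsets)) stop("total_hours must be >= the last onset")
  structure(list(embryo_id = embryo_id, onsets = onsets,
                 total_hours = as.integer(total_hours),
                 frame_rate = frame_rate, clip_seconds = clip_seconds),
            class = "synthetic_schedule")
}

# Event active at hour h under the previous-event-until-next rule.
schedule_label_at <- function(schedule, hour) {
  on <- schedule$onsets[schedule$onsets <= hour]
  if (length(on) == 0) return("Pre-Gastrula")
  names(on)[which.max(on)]
}

#' Generate one embryo's hourly time-lapse with known event schedule
#'
#' Renders one clip per hour from 0 to `total_hours`; the clip at hour h uses
#' the motif of the latest event with onset <= h (Pre-Gastrula before the
#' first onset), matching the labelling rule used for annotation: a clip is
#' labelled as the previous event until the subsequent event occurs.
#'
#' @param schedule A [synthetic_schedule()].
#' @param library Motif library (named list of `motif_spec`).
#' @param seed Integer seed; per-hour render seeds are derived from it.
#' @param size Frame size in pixels.
#' @param n_frames Frames per hourly clip (default
#'   `frame_rate * clip_seconds`).
#' @return list(timelapse = [timelapse()], annotation = data.frame with
#'   columns embryo_id, event, onset_hour equal to the schedule's onsets,
#'   labels = per-hour ground-truth label).
#' @export
generate_embryo_series <- function(schedule, library = default_motif_library(),
                                   seed = 1L, size = 64, n_frames = NULL) {
  stopifnot(inherits(schedule, "synthetic_schedule"))
  if (is.null(n_frames)) n_frames <- schedule$frame_rate * schedule$clip_seconds
  hours <- 0:schedule$total_hours
  labels <- vapply(hours, function(h) schedule_label_at(schedule, h), "")
  clips <- vector("list", length(hours))
  for (i in seq_along(hours)) {
    motif <- library[[labels[i]]]
    if (is.null(motif)) stop("motif library has no entry for ", labels[i])
    clips[[i]] <- render_clip(motif, n_frames, size,
                              seed = mix_seed(seed, schedule$embryo_id, hours[i]),
                              fps = schedule$frame_rate)
  }
  ann <- data.frame(embryo_id = schedule$embryo_id,
                    event = names(schedule$onsets),
                    onset_hour = as.numeric(schedule$onsets),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(timelapse = timelapse(schedule$embryo_id, hours, clips),
       annotation = ann, labels = labels)
}

#' Random plausible schedules for a cohort of embryos
#'
#' Event onsets are drawn around canonical mean hours with small integer
#' jitter, kept strictly increasing.
#'
#' @param n_embryos Number of embryos.
#' @param seed Integer seed.
#' @param mean_onsets Named vector of mean onset hours in canonical order.
#' @param jitter Maximum +/- integer jitter per onset.
#' @param ... Passed to [synthetic_schedule()].
#' @return List of `synthetic_schedule`.
#' @export
random_schedules <- function(n_embryos, seed = 1L,
                             mean_onsets = c("Gastrula" = 3, "Trochophore" = 6,
                                             "Veliger" = 9, "Eye spots" = 12,
                                             "Heart beat" = 15, "Crawling" = 18,
                                             "Radula" = 21, "Hatch" = 24,
                                             "Dead" = 27),
                             jitter = 1, ...) {
  with_seed(seed, {
    lapply(seq_len(n_embryos), function(i) {
      repeat {
        on <- round(mean_onsets + sample(-jitter:jitter, length(mean_onsets),
                                         replace = TRUE))
        if (!is.unsorted(on, strictly = TRUE) && all(on >= 0)) break
      }
      synthetic_schedule(sprintf("embryo%03d", i), on,
                         total_hours = max(on) + 2, ...)
    })
  })
}

#' A pair of motifs distinguishable only through time
#'
#' Returns two motifs with the same static appearance and noise level whose
#' rendered clips have identical first frames (the pulse phase is zero at
#' t = 0) but differ in motion: A is static, B pulses in intensity. A
#' classifier restricted to first frames cannot exceed chance on this pair;
#' one that uses temporal structure separates them easily.
#'
#' @param noise_sd Gaussian noise s.d. (shared).
#' @param amplitude Pulse fractional amplitude for B.
#' @param frequency Pulse frequency in cycles per second for B.
#' @return list(A = static `motif_spec`, B = pulsing `motif_spec`).
#' @export
make_temporal_only_pair <- function(noise_sd = 4, amplitude = 0.3, frequency = 7.5) {
  A <- motif_spec("Pre-Gastrula", "blob", "none", radius_frac = 0.3,
                  intensity = 140, noise_sd = noise_sd)
  B <- motif_spec("Gastrula", "blob", "pulse", motion_amplitude = amplitude,
                  motion_frequency = frequency, radius_frac = 0.3,
                  intensity = 140, noise_sd = noise_sd)
  list(A = A, B = B)
}

#' Render a labelled clip dataset from motifs
#'
#' @param motifs Named list of `motif_spec` (names = labels) or a motif
#'   library subset.
#' @param n_per_class Clips per motif.
#' @param n_frames,size,fps Clip geometry.
#' @param seed Integer seed; clip i of class j gets a derived seed.
#' @return A [clip_dataset()].
#' @export
synth_clip_dataset <- function(motifs, n_per_class, n_frames = 8, size = 32,
                               fps = 30, seed = 1L) {
  clips <- list(); labels <- character(0); ids <- character(0)
  for (j in seq_along(motifs)) {
    m <- motifs[[j]]
    lab <- m$event_label
    for (i in seq_len(n_per_class)) {
      clips[[length(clips) + 1]] <- render_clip(m, n_frames, size,
                                                seed = mix_seed(seed, lab, i),
                                                fps = fps)
      labels <- c(labels, lab)
      ids <- c(ids, sprintf("%s_%04d", gsub("[^A-Za-z]", "", lab), i))
    }
  }
  clip_dataset(clips, labels, ids)
}

#' Simulate per-embryo event timings across thermal treatments
#'
#' Onset hours follow a Gaussian thermal performance curve for developmental
#' rate: rate(T) peaks at an event-specific optimum temperature and onset =
#' baseline onset at 20 degrees C scaled by rate(20)/rate(T), with Normal
#' noise. By default later events have a lower optimum (30 down to 25 degrees
#' C), emulating heightened thermal sensitivity of late development, so the
#' recovered T_opt decreases from early to late events.
#'
#' @param temperatures Assayed temperatures (degrees C).
#' @param n_per_temp Embryos per temperature (recycled).
#' @param base_onsets Named mean onset hours at 20 degrees C, canonical order.
#' @param t_opt_early,t_opt_late Optimum temperature of the first and last
#'   event; intermediate events interpolate linearly.
#' @param breadth Gaussian breadth of the performance curve (degrees C).
#' @param cv Coefficient of variation of the Normal onset noise.
#' @param seed Integer seed.
#' @return data.frame(embryo_id, event, onset_hour, treatment).
#' @export
simulate_thermal_timings <- function(temperatures = c(15, 17.5, 20, 22.5, 25, 27.5, 30, 32.5),
                                     n_per_temp = c(58, 60, 38, 55, 38, 59, 37, 60),
                                     base_onsets = c("Gastrula" = 12, "Trochophore" = 40,
                                                     "Veliger" = 70, "Eye spots" = 110,
                                                     "Heart beat" = 135, "Crawling" = 165,
                                                     "Radula" = 190, "Hatch" = 230,
                                                     "Dead" = 260),
                                     t_opt_early = 30, t_opt_late = 25,
                                     breadth = 8, cv = 0.05, seed = 1L) {
  n_per_temp <- rep_len(n_per_temp, length(temperatures))
  ev <- names(base_onsets)
  topt <- seq(t_opt_early, t_opt_late, length.out = length(ev))
  names(topt) <- ev
  rate_shape <- function(T, to) exp(-((T - to)^2) / (2 * breadth^2))
  rows <- list()
  with_seed(seed, {
    k <- 0L
    for (i in seq_along(temperatures)) {
      T <- temperatures[i]
      for (e in seq_len(n_per_temp[i])) {
        k <- k + 1L
        id <- sprintf("sim%04d", k)
        mu <- base_onsets * rate_shape(20, topt) / rate_shape(T, topt)
        on <- stats::rnorm(length(mu), mean = mu, sd = cv * mu)
        rows[[k]] <- data.frame(embryo_id = id, event = ev,
                                onset_hour = pmax(on, 1), treatment = T,
                                row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}
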