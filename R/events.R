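# Event probability trajectories and onset extraction.
#
# Applying the classifier to every imaged hour of one embryo yields a
# probability trajectory: an hours x classes matrix of softmax outputs.
# Onsets are read from per-event probability columns with one of two rules:
# for events whose trajectory peaks at onset, the hour of the (earliest)
# maximum; for events that rise to a plateau (radula, hatch, death), the
# first hour strictly above a per-event threshold. Columns are read
# independently, so changes in the relative timing of events (heterochrony)
# are detectable.

#' Construct a probability trajectory
#'
#' @param embryo_id Identifier.
#' @param hours Strictly increasing hour stamps.
#' @param probs hours x classes matrix; each row must sum to 1 (+- 1e-6).
#'   Columns are named by event label.
#' @param treatment Optional treatment metadata (temperature, degrees C).
#' @return A `prob_trajectory`.
#' @export
prob_trajectory <- function(embryo_id, hours, probs, treatment = NULL) {
  if (is.unsorted(hours, strictly = TRUE)) stop("hours must be strictly increasing")
  if (nrow(probs) != length(hours)) stop("one probability row per hour required")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  if (is.null(colnames(probs))) colnames(probs) <- event_levels()[seq_len(ncol(probs))]
  structure(list(embryo_id = embryo_id, hours = as.numeric(hours), probs = probs,
                 treatment = treatment),
            class = "prob_trajectory")
}

#' Predict an embryo's probability trajectory
#'
#' Runs the classifier on every hourly clip of a time-lapse, standardising
#' and temporally subsampling each clip to the model's input shape, and
#' returns the per-hour class probabilities in hour order.
#'
#' @param net A trained classifier `devnet`.
#' @param tl A [timelapse()].
#' @param start_frame,n_source_frames,stride Subsampling parameters applied
#'   per clip when its length differs from the model input; `NULL`
#'   `n_source_frames` means clips are used as-is (they must then match).
#' @param treatment Optional treatment metadata carried into the trajectory.
#' @return A [prob_trajectory()] with one row per imaged hour.
#' @export
predict_trajectory <- function(net, tl, start_frame = 0L,
                               n_source_frames = NULL, stride = 1L,
                               treatment = NULL) {
  spec <- net$spec
  L <- spec$input_shape[1]; size <- spec$input_shape[2]
  xs <- vector("list", length(tl$hours))
  for (i in seq_along(tl$hours)) {
    cl <- tl$clips[[i]]
    if (!is.null(n_source_frames)) {
      cl <- subsample_clip(cl, start_frame, n_source_frames, stride)
    }
    if (clip_length(cl) != L)
      stop("clip at hour ", tl$hours[i], " has ", clip_length(cl),
           " frames but the model expects ", L)
    cl <- standardize_clip(cl, size)
    xs[[i]] <- clip_input_array(cl)
  }
  p <- predict_proba(net, xs)
  colnames(p) <- if (spec$n_classes == length(event_levels())) event_levels()
                 else colnames(p)
  prob_trajectory(tl$embryo_id, tl$hours, p, treatment = treatment)
}

#' Event timing extraction configuration
#'
#' Per-event onset rule. Defaults: peak mode
#' for Gastrula through Crawling (transient probability peaks), threshold
#' mode for the plateau events with thresholds Radula 0.6, Hatch 0.4 and
#' Dead 0.3, and Pre-Gastrula excluded (it denotes development before any
#' event rather than an event itself).
#'
#' @param modes Named character vector event -> `"peak"`, `"threshold"` or
#'   `"excluded"`; every event must have exactly one mode.
#' @param thresholds Named numeric vector of probabilities in (0, 1) for
#'   threshold-mode events.
#' @return An `event_timing_config`.
#' @export
timing_config <- function(modes = NULL, thresholds = NULL) {
  default_modes <- c("Pre-Gastrula" = "excluded", "Gastrula" = "peak",
                     "Trochophore" = "peak", "Veliger" = "peak",
                     "Eye spots" = "peak", "Heart beat" = "peak",
                     "Crawling" = "peak", "Radula" = "threshold",
                     "Hatch" = "threshold", "Dead" = "threshold")
  default_thr <- c("Radula" = 0.6, "Hatch" = 0.4, "Dead" = 0.3)
  if (!is.null(modes)) default_modes[names(modes)] <- modes
  if (!is.null(thresholds)) default_thr[names(thresholds)] <- thresholds
  if (!all(default_modes %in% c("peak", "threshold", "excluded")))
    stop("modes must be 'peak', 'threshold' or 'excluded'")
  thr_ev <- names(default_modes)[default_modes == "threshold"]
  missing_thr <- setdiff(thr_ev, names(default_thr))
  if (length(missing_thr) > 0)
    stop("no threshold given for: ", paste(missing_thr, collapse = ", "))
  thr <- default_thr[thr_ev]
  if (length(thr) > 0 && (any(thr <= 0) || any(thr >= 1)))
    stop("thresholds must lie in (0, 1)")
  structure(list(modes = default_modes, thresholds = default_thr),
            class = "event_timing_config")
}

#' Extract event onset timings from a probability trajectory
#'
#' Peak mode: the hour of that event's maximum probability (earliest hour on
#' ties); a numerically zero column yields an absent onset with a warning.
#' Threshold mode: the earliest hour with probability strictly greater than
#' the event's threshold, absent if never exceeded. Excluded events are
#' never reported. Missing imaged hours are skipped, not interpolated:
#' onsets are reported on the imaged-hour grid. Absent events are reported
#' as NA, never as sentinel numbers.
#'
#' @param traj A [prob_trajectory()].
#' @param config An [timing_config()].
#' @return An `event_timings`: list(embryo_id, onsets = named numeric with
#'   NA for absent, treatment).
#' @export
extract_timing <- function(traj, config = timing_config()) {
  stopifnot(inherits(traj, "prob_trajectory"))
  events <- names(config$modes)[config$modes != "excluded"]
  events <- intersect(events, colnames(traj$probs))
  onsets <- stats::setNames(rep(NA_real_, length(events)), events)
  for (ev in events) {
    col <- traj$probs[, ev]
    if (config$modes[[ev]] == "peak") {
      if (max(col) <= 0) {
        warning("event ", ev, " has an all-zero trajectory; onset absent")
        next
      }
      onsets[ev] <- traj$hours[which.max(col)]
    } else {
      thr <- config$thresholds[[ev]]
      hit <- which(col > thr)
      if (length(hit) > 0) onsets[ev] <- traj$hours[hit[1]]
    }
  }
  structure(list(embryo_id = traj$embryo_id, onsets = onsets,
                 treatment = traj$treatment),
            class = "event_timings")
}

#' @export
print.event_timings <- function(x, ...) {
  cat("event timings for", x$embryo_id, "\n")
  print(x$onsets)
  invisible(x)
}

#' Timings of several embryos as a data.frame
#'
#' @param timings List of `event_timings` (or a single one).
#' @param drop_absent Drop events with absent onsets.
#' @return data.frame(embryo_id, event, onset_hour, treatment).
#' @export
timings_table <- function(timings, drop_absent = FALSE) {
  if (inherits(timings, "event_timings")) timings <- list(timings)
  out <- do.call(rbind, lapply(timings, function(tm) {
    data.frame(embryo_id = tm$embryo_id, event = names(tm$onsets),
               onset_hour = as.numeric(tm$onsets),
               treatment = if (is.null(tm$treatment)) NA else tm$treatment,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (drop_absent) out <- out[!is.na(out$onset_hour), ]
  out
}

#' Calibrate per-event probability thresholds against ground truth
#'
#' For every threshold-mode event, evaluates each candidate threshold by the
#' mean absolute error between extracted and annotated onsets over the
#' supplied trajectories, and keeps the grid value minimising it (ties go to
#' the lower threshold). Embryos for which a candidate threshold yields no
#' onset contribute a penalty equal to the trajectory's hour span. An event
#' never predicted above any grid value is flagged with a warning and its
#' threshold left unchanged.
#'
#' @param trajectories List of [prob_trajectory()].
#' @param ground_truth Annotation data.frame (embryo_id, event, onset_hour).
#' @param grid Candidate thresholds in (0, 1); must be non-empty.
#' @param config Starting [timing_config()]; calibrated thresholds replace
#'   the current ones.
#' @return An updated `event_timing_config`. The per-event grid MAEs are
#'   attached as attribute `"mae"`.
#' @export
calibrate_thresholds <- function(trajectories, ground_truth, grid,
                                 config = timing_config()) {
  if (length(grid) == 0) stop("threshold grid is empty")
  if (any(grid <= 0 | grid >= 1)) stop("grid thresholds must lie in (0, 1)")
  grid <- sort(grid)
  validate_annotations(ground_truth)
  thr_events <- names(config$modes)[config$modes == "threshold"]
  maes <- list()
  for (ev in thr_events) {
    gt <- ground_truth[ground_truth$event == ev, ]
    if (nrow(gt) == 0) next
    err <- vapply(grid, function(tau) {
      errs <- c()
      for (tr in trajectories) {
        truth <- gt$onset_hour[gt$embryo_id == tr$embryo_id]
        if (length(truth) == 0) next
        col <- tr$probs[, ev]
        hit <- which(col > tau)
        e <- if (length(hit) > 0) abs(tr$hours[hit[1]] - truth)
             else diff(range(tr$hours))
        errs <- c(errs, e)
      }
      if (length(errs) == 0) NA_real_ else mean(errs)
    }, 0.0)
    if (all(is.na(err))) next
    best <- grid[which.min(err)]   # which.min takes the first (lowest) on ties
    ever <- any(vapply(trajectories, function(tr) any(tr$probs[, ev] > min(grid)),
                       logical(1)))
    if (!ever) {
      warning("event ", ev, " never exceeds any grid threshold; left unchanged")
      next
    }
    config$thresholds[ev] <- best
    maes[[ev]] <- stats::setNames(err, grid)
  }
  attr(config, "mae") <- maes
  config
}

#' Write / read probability trajectories as CSV
#'
#' One row per imaged hour: `hour` followed by one probability column per
#' event class.
#'
#' @param traj A [prob_trajectory()].
#' @param path CSV path.
#' @return The path (write) or a `prob_trajectory` (read).
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(hour = traj$hours, traj$probs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param embryo_id,treatment Metadata to attach on read.
#' @export
read_trajectory <- function(path, embryo_id = NA_character_, treatment = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  prob_trajectory(embryo_id, df$hour, as.matrix(df[, -1, drop = FALSE]),
                  treatment = treatment)
}

#' Optional moving-average smoothing of a trajectory
#'
#' Centred moving average of each event's probability column, renormalised
#' per row. Off by default throughout the pipeline: extraction operates on
#' raw trajectories; smoothing is provided for noisy real-data trajectories
#' where a user explicitly opts in.
#'
#' @param traj A [prob_trajectory()].
#' @param width Odd window width in imaged hours (1 = no smoothing).
#' @return A smoothed [prob_trajectory()].
#' @export
smooth_trajectory <- function(traj, width = 1L) {
  if (width <= 1) return(traj)
  if (width %% 2 == 0) stop("width must be odd")
  half <- (width - 1) / 2
  n <- length(traj$hours)
  p <- traj$probs
  out <- p
  for (i in seq_len(n)) {
    w <- max(1, i - half):min(n, i + half)
    out[i, ] <- colMeans(p[w, , drop = FALSE])
  }
  out <- out / rowSums(out)
  prob_trajectory(traj$embryo_id, traj$hours, out, traj$treatment)
}
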