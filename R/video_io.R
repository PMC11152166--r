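# Time-lapse and clip containers plus on-disk formats.
#
# Clips are stored in memory as L x W x H x 1 arrays of 8-bit values
# (0..255); model input is produced by standardize_clip (grayscale, resized,
# scaled to [0,1]). On disk a clip is a multi-page 8-bit grayscale TIFF; a
# clip dataset is a directory of such stacks with a CSV label manifest; raw
# acquisitions are accepted as directories of single-frame TIFFs named
# `<embryo>_h<hour>_f<frame>.tif`.

#' Construct a clip
#'
#' @param frames L x W x H x C array (C must be 1; a 3D array is promoted),
#'   8-bit grayscale values in 0..255 or standardised values in [0, 1].
#' @param source_id Optional identifier (embryo + hour).
#' @return A `clip` object.
#' @export
clip <- function(frames, source_id = NULL) {
  if (length(dim(frames)) == 3) dim(frames) <- c(dim(frames), 1L)
  d <- dim(frames)
  if (length(d) != 4) stop("frames must be an L x W x H x C array")
  if (d[4] != 1) stop("clips must be single-channel (C = 1)")
  if (d[1] < 1) stop("clip must have at least one frame")
  structure(list(frames = frames, source_id = source_id), class = "clip")
}

#' @export
dim.clip <- function(x) dim(x$frames)

#' Number of frames in a clip
#' @param x A `clip`.
#' @return Integer frame count.
#' @export
clip_length <- function(x) dim(x$frames)[1]

#' @export
print.clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("clip %s: %d frames, %dx%d, range [%g, %g]\n",
              if (is.null(x$source_id)) "" else x$source_id,
              d[1], d[2], d[3], min(x$frames), max(x$frames)))
  invisible(x)
}

#' Construct a time-lapse
#'
#' @param embryo_id Identifier.
#' @param hours Integer hour stamps, strictly increasing, no duplicates.
#' @param clips List of [clip()], one per hour.
#' @return A `timelapse` object.
#' @export
timelapse <- function(embryo_id, hours, clips) {
  hours <- as.integer(hours)
  if (anyDuplicated(hours)) stop("duplicate hour stamps")
  if (is.unsorted(hours, strictly = TRUE)) stop("hours must be strictly increasing")
  if (length(hours) != length(clips)) stop("one clip per hour required")
  structure(list(embryo_id = embryo_id, hours = hours, clips = clips),
            class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
  cat(sprintf("timelapse %s: %d hourly clips (hours %d..%d)\n",
              x$embryo_id, length(x$hours), min(x$hours), max(x$hours)))
  invisible(x)
}

.read_tiff_frame <- function(path) {
  m <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) stop("unreadable frame file: ", path,
                                         " (", conditionMessage(e), ")", call. = FALSE))
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Assemble a time-lapse from a directory of single-frame TIFF files
#'
#' File names must follow `<embryo>_h<hour>_f<frame>.tif` (configurable via
#' `pattern`, whose three capture groups are embryo, hour and frame). Hours
#' and frames are ordered numerically, not lexically. Missing hours in the
#' covered range produce a warning and are recorded as gaps (no
#' interpolation).
#'
#' @param frame_dir Directory containing the frame files.
#' @param pattern Regular expression with three capture groups
#'   (embryo, hour, frame).
#' @param embryo_id Select one embryo when the directory holds several.
#' @return A [timelapse()].
#' @export
concat_tiff_sequence <- function(frame_dir,
                                 pattern = "^(.+)_h(\\d+)_f(\\d+)\\.tiff?$",
                                 embryo_id = NULL) {
  files <- list.files(frame_dir)
  m <- regmatches(files, regexec(pattern, files))
  keep <- lengths(m) == 4
  if (!any(keep)) stop("no frame files matching the naming pattern in ", frame_dir)
  info <- data.frame(file = files[keep],
                     embryo = vapply(m[keep], `[`, "", 2),
                     hour = as.integer(vapply(m[keep], `[`, "", 3)),
                     frame = as.integer(vapply(m[keep], `[`, "", 4)),
                     stringsAsFactors = FALSE)
  if (!is.null(embryo_id)) info <- info[info$embryo == embryo_id, ]
  ids <- unique(info$embryo)
  if (length(ids) != 1)
    stop("directory contains ", length(ids),
         " embryos; select one with embryo_id = ...")
  hours <- sort(unique(info$hour))
  full <- seq(min(hours), max(hours))
  if (length(missing <- setdiff(full, hours)) > 0)
    warning("missing hour(s) in sequence: ", paste(missing, collapse = ", "),
            "; gap retained")
  clips <- lapply(hours, function(h) {
    sub <- info[info$hour == h, ]
    sub <- sub[order(sub$frame), ]
    frames <- lapply(file.path(frame_dir, sub$file), .read_tiff_frame)
    arr <- array(0, c(length(frames), dim(frames[[1]]), 1))
    for (i in seq_along(frames)) arr[i, , , 1] <- frames[[i]]
    clip(arr, source_id = sprintf("%s_h%d", ids, h))
  })
  timelapse(ids, hours, clips)
}

#' Write a time-lapse as single-frame TIFF files
#'
#' Inverse of [concat_tiff_sequence()]: frame f of hour h is written as
#' `<embryo>_h<hour>_f<frame>.tif` (8-bit grayscale).
#'
#' @param tl A [timelapse()] with 8-bit clips.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file names.
#' @export
write_timelapse_frames <- function(tl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (i in seq_along(tl$hours)) {
    fr <- tl$clips[[i]]$frames
    for (l in seq_len(dim(fr)[1])) {
      f <- file.path(dir, sprintf("%s_h%d_f%d.tif", tl$embryo_id, tl$hours[i], l))
      tiff::writeTIFF(fr[l, , , 1] / 255, f, bits.per.sample = 8)
      out <- c(out, f)
    }
  }
  invisible(out)
}

#' Temporal subsampling of a clip
#'
#' Keeps frames `start_frame, start_frame + stride, ...` within the first
#' `n_source_frames` frames, yielding exactly `ceiling(n_source_frames /
#' stride)` frames. With the defaults (120 source frames, stride 10) a clip
#' is reduced to 12 frames; at 30 frames/s this is an effective rate of
#' 3 frames/s.
#'
#' @param clip A [clip()].
#' @param start_frame 0-based index of the first retained frame.
#' @param n_source_frames Number of source frames considered.
#' @param stride Keep every `stride`-th frame.
#' @return A [clip()] of length `ceiling(n_source_frames / stride)`.
#' @export
subsample_clip <- function(clip, start_frame = 0L, n_source_frames = 120L,
                           stride = 10L) {
  L <- clip_length(clip)
  need <- start_frame + n_source_frames
  if (L < need)
    stop("clip has ", L, " frames; subsampling requires at least ", need)
  keep <- seq(start_frame, start_frame + n_source_frames - 1L, by = stride) + 1L
  clip(clip$frames[keep, , , , drop = FALSE], source_id = clip$source_id)
}

# Separable area-average (box) resampling weights: out x in matrix in which
# row i holds the fractional overlap of output cell i with each input cell.
.area_weights <- function(n_in, n_out) {
  key <- sprintf("%d_%d", n_in, n_out)
  w <- .devevent_cache[[key]]
  if (!is.null(w)) return(w)
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * scale; b <- i * scale
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      lo <- max(a, j - 1); hi <- min(b, j)
      if (hi > lo) W[i, j] <- (hi - lo) / scale
    }
  }
  .devevent_cache[[key]] <- W
  W
}

.devevent_cache <- new.env(parent = emptyenv())

#' Area-interpolated resize of a matrix
#'
#' Anti-aliased box resampling (each output pixel is the area-weighted mean
#' of the input pixels it covers); exact for integer downscale factors and
#' the fixed, documented choice for reducing acquisition frames to model
#' resolution.
#'
#' @param m Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @return Resized matrix.
#' @export
resize_area <- function(m, out_h, out_w = out_h) {
  Rh <- .area_weights(nrow(m), out_h)
  Rw <- .area_weights(ncol(m), out_w)
  Rh %*% m %*% t(Rw)
}

#' Standardise a clip for model input
#'
#' Converts to grayscale if needed, resizes each frame to `size` x `size`
#' with area interpolation, and scales pixel values from 0..255 to [0, 1].
#' Already-standardised clips are returned unchanged.
#'
#' @param clip A [clip()].
#' @param size Target edge length (model input resolution; default 128).
#' @return A standardised [clip()] with values in [0, 1].
#' @export
standardize_clip <- function(clip, size = 128L) {
  fr <- clip$frames
  d <- dim(fr)
  scale <- if (max(fr) > 1 || isTRUE(all.equal(max(fr), 0))) 255 else 1
  out <- array(0, c(d[1], size, size, 1))
  same <- d[2] == size && d[3] == size
  for (l in seq_len(d[1])) {
    m <- fr[l, , , 1]
    out[l, , , 1] <- if (same) m / scale else resize_area(m, size, size) / scale
  }
  cl <- clip(out, source_id = clip$source_id)
  attr(cl, "standardized") <- TRUE
  cl
}

# (L,H,W) array for the model from a standardised clip.
clip_input_array <- function(clip) {
  fr <- clip$frames
  dim(fr) <- dim(fr)[1:3]
  if (max(fr) > 1) fr <- fr / 255
  fr
}

#' Construct a labelled clip dataset
#'
#' @param clips List of [clip()].
#' @param labels Character or factor of event labels (validated against
#'   [event_levels()] by default).
#' @param ids Optional sample identifiers.
#' @param levels Label universe (defaults to the event taxonomy).
#' @return A `clip_dataset`.
#' @export
clip_dataset <- function(clips, labels, ids = NULL, levels = event_levels()) {
  if (length(clips) != length(labels)) stop("one label per clip required")
  bad <- setdiff(unique(as.character(labels)), levels)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (is.null(ids)) ids <- sprintf("clip%05d", seq_along(clips))
  structure(list(clips = clips, labels = factor(as.character(labels), levels = levels),
                 ids = as.character(ids)),
            class = "clip_dataset")
}

#' @export
length.clip_dataset <- function(x) length(x$clips)

#' @export
`[.clip_dataset` <- function(x, i) {
  clip_dataset(x$clips[i], as.character(x$labels[i]), x$ids[i],
               levels = levels(x$labels))
}

#' @export
print.clip_dataset <- function(x, ...) {
  cat("clip_dataset with", length(x), "clips\n")
  print(table(droplevels(x$labels)))
  invisible(x)
}

#' Combine clip datasets
#' @param ... `clip_dataset` objects sharing a label universe.
#' @return A combined `clip_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  clip_dataset(do.call(c, lapply(ds, `[[`, "clips")),
               unlist(lapply(ds, function(d) as.character(d$labels))),
               unlist(lapply(ds, `[[`, "ids")),
               levels = levels(ds[[1]]$labels))
}

#' Reproducible train/validation/test split
#'
#' @param ds A [clip_dataset()].
#' @param fractions Length-3 fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed Integer seed; identical seeds give identical membership.
#' @return list(train =, val =, test =) forming a disjoint, exhaustive
#'   partition with sizes within rounding of the fractions.
#' @export
split_dataset <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(ds)
  if (n == 0) stop("cannot split an empty dataset")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  counts <- diff(c(0, round(cumsum(fractions) * n)))
  perm <- with_seed(seed, sample.int(n))
  b <- cumsum(counts)
  list(train = ds[perm[seq_len(counts[1])]],
       val = ds[perm[seq(b[1] + 1, length.out = counts[2])]],
       test = ds[perm[seq(b[2] + 1, length.out = counts[3])]])
}

#' Write a clip dataset to disk
#'
#' Each clip becomes an 8-bit grayscale multi-page TIFF stack
#' (`clip_00001.tif`, ...) with a `manifest.csv` mapping file to label and
#' id. Lossless: reading back gives bit-identical frames and labels.
#'
#' @param ds A [clip_dataset()] with 8-bit clips.
#' @param dir Output directory.
#' @return Invisibly, the manifest data.frame.
#' @export
write_clip_dataset <- function(ds, dir) {
  bad <- setdiff(levels(droplevels(ds$labels)), event_levels())
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("clip_%05d.tif", seq_along(ds$clips))
  for (i in seq_along(ds$clips)) {
    fr <- ds$clips[[i]]$frames
    pages <- lapply(seq_len(dim(fr)[1]), function(l) fr[l, , , 1] / 255)
    tiff::writeTIFF(pages, file.path(dir, files[i]), bits.per.sample = 8)
  }
  manifest <- data.frame(file = files, label = as.character(ds$labels),
                         id = ds$ids, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a clip dataset written by [write_clip_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A [clip_dataset()].
#' @export
read_clip_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  clips <- lapply(manifest$file, function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), dim(pages[[1]])[1:2], 1))
    for (l in seq_along(pages)) {
      p <- pages[[l]]
      if (length(dim(p)) == 3) p <- p[, , 1]
      arr[l, , , 1] <- p
    }
    clip(arr)
  })
  clip_dataset(clips, manifest$label, manifest$id)
}

#' Read / write annotation tables
#'
#' Annotation tables are CSV files with columns `embryo_id`, `event`,
#' `onset_hour` and optionally `treatment` (temperature in degrees C). One
#' onset per (embryo, event); labels must belong to the event taxonomy.
#'
#' @param path CSV path.
#' @return data.frame of annotations.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df)
  df
}

#' @rdname read_annotation_table
#' @param df Annotation data.frame.
#' @export
write_annotation_table <- function(df, path) {
  validate_annotations(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

validate_annotations <- function(df) {
  need <- c("embryo_id", "event", "onset_hour")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  event_code(df$event)
  if (any(df$onset_hour < 0)) stop("onset hours must be >= 0")
  if (anyDuplicated(df[, c("embryo_id", "event")]))
    stop("more than one onset for the same (embryo, event)")
  invisible(df)
}
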