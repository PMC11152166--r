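# Sample-deterministic video augmentation and selective class balancing.
#
# A plan drawn for a (sample id, seed) pair fully determines the transform,
# and the SAME transform — including the salt-and-pepper noise mask — is
# applied to every frame of the clip, so augmentation never introduces
# spurious temporal signal. Activation probabilities and noise magnitudes
# are package defaults (flip/blur/salt-pepper each at 0.5, intensity factor
# uniform on {0.5, 1, 2}); they are exposed through the augment.* config
# block.

#' Draw a deterministic augmentation plan
#'
#' @param sample_id Sample identifier (string); the plan is a pure function
#'   of (sample_id, seed).
#' @param seed Integer seed.
#' @param p_flip,p_salt_pepper,p_blur Activation probability of each
#'   augmentation.
#' @param salt_pepper_fraction Fraction of pixels corrupted when active.
#' @param blur_sigma_range Range of the Gaussian blur sigma (pixels) when
#'   active.
#' @return An `aug_plan`: flip_h, flip_v, intensity_factor in {0.5, 1, 2},
#'   salt_pepper_fraction, gaussian_blur_sigma, and a derived noise seed.
#' @export
sample_plan <- function(sample_id, seed = 1L, p_flip = 0.5,
                        p_salt_pepper = 0.5, p_blur = 0.5,
                        salt_pepper_fraction = 0.02,
                        blur_sigma_range = c(0.5, 1.5)) {
  with_seed(mix_seed(seed, "plan", sample_id), {
    plan <- list(
      sample_id = sample_id,
      flip_h = stats::runif(1) < p_flip,
      flip_v = stats::runif(1) < p_flip,
      intensity_factor = sample(c(0.5, 1, 2), 1),
      salt_pepper_fraction = if (stats::runif(1) < p_salt_pepper) salt_pepper_fraction else 0,
      gaussian_blur_sigma = if (stats::runif(1) < p_blur)
        stats::runif(1, blur_sigma_range[1], blur_sigma_range[2]) else 0,
      noise_seed = mix_seed(seed, "mask", sample_id))
    structure(plan, class = "aug_plan")
  })
}

is_identity_plan <- function(plan) {
  !plan$flip_h && !plan$flip_v && plan$intensity_factor == 1 &&
    plan$salt_pepper_fraction == 0 && plan$gaussian_blur_sigma == 0
}

#' Apply an augmentation plan to a clip
#'
#' Applies, in order: horizontal/vertical flips, intensity scaling (clipped
#' to the 8-bit range), Gaussian blur, and salt-and-pepper noise with a
#' single mask shared by all frames. Output shape equals input shape.
#'
#' @param plan An [sample_plan()] result.
#' @param clip A [clip()] with 8-bit values.
#' @return The augmented [clip()].
#' @export
apply_plan <- function(plan, clip) {
  fr <- clip$frames
  d <- dim(fr)
  if (plan$flip_h) fr <- fr[, , rev(seq_len(d[3])), , drop = FALSE]
  if (plan$flip_v) fr <- fr[, rev(seq_len(d[2])), , , drop = FALSE]
  if (plan$intensity_factor != 1)
    fr <- pmin(pmax(fr * plan$intensity_factor, 0), 255)
  if (plan$gaussian_blur_sigma > 0) {
    for (l in seq_len(d[1]))
      fr[l, , , 1] <- EBImage::gblur(fr[l, , , 1], sigma = plan$gaussian_blur_sigma)
    fr <- pmin(pmax(fr, 0), 255)
  }
  if (plan$salt_pepper_fraction > 0) {
    npix <- d[2] * d[3]
    k <- max(1L, round(plan$salt_pepper_fraction * npix))
    mask <- with_seed(plan$noise_seed, {
      list(pix = sample.int(npix, k), salt = stats::runif(k) < 0.5)
    })
    vals <- ifelse(mask$salt, 255, 0)
    for (l in seq_len(d[1])) {
      pg <- fr[l, , , 1]
      pg[mask$pix] <- vals
      fr[l, , , 1] <- pg
    }
  }
  clip(round(fr), source_id = clip$source_id)
}

#' Remove class imbalance by selective augmentation
#'
#' Upsamples every class to the pre-balancing maximum class count by adding
#' augmented copies of clips drawn (with replacement, uniformly) from that
#' class's originals. Originals are retained unmodified; identity plans are
#' redrawn so every added copy differs from its source.
#'
#' @param ds A [clip_dataset()].
#' @param seed Integer seed.
#' @param classes Classes that must be present; defaults to those observed.
#'   A listed class with no samples is an error.
#' @param ... Passed to [sample_plan()] (activation probabilities etc.).
#' @return A [clip_dataset()] with a uniform class histogram.
#' @export
balance_classes <- function(ds, seed = 1L, classes = NULL, ...) {
  counts <- table(ds$labels)
  present <- names(counts)[counts > 0]
  if (is.null(classes)) classes <- present
  empty <- setdiff(classes, present)
  if (length(empty) > 0)
    stop("class(es) with no samples: ", paste(empty, collapse = ", "))
  target <- max(counts[classes])
  add_clips <- list(); add_labels <- character(0); add_ids <- character(0)
  for (cl in classes) {
    idx <- which(as.character(ds$labels) == cl)
    need <- target - length(idx)
    if (need <= 0) next
    src <- with_seed(mix_seed(seed, "bal", cl),
                     sample(idx, need, replace = TRUE))
    for (k in seq_len(need)) {
      pid <- sprintf("%s_aug%04d", ds$ids[src[k]], k)
      plan <- sample_plan(pid, seed, ...)
      tries <- 0L
      while (is_identity_plan(plan) && tries < 100L) {
        tries <- tries + 1L
        plan <- sample_plan(sprintf("%s_r%d", pid, tries), seed, ...)
      }
      add_clips[[length(add_clips) + 1]] <- apply_plan(plan, ds$clips[[src[k]]])
      add_labels <- c(add_labels, cl)
      add_ids <- c(add_ids, pid)
    }
  }
  if (length(add_clips) == 0) return(ds)
  bind_datasets(ds, clip_dataset(add_clips, add_labels, add_ids,
                                 levels = levels(ds$labels)))
}

#' Non-selective augmentation (upsample without rebalancing)
#'
#' Adds `factor - 1` augmented copies of every clip, growing the dataset
#' while leaving class imbalances untouched. Provided to compare selective
#' balancing against plain upsampling.
#'
#' @param ds A [clip_dataset()].
#' @param factor Integer multiplier (>= 1).
#' @param seed Integer seed.
#' @param ... Passed to [sample_plan()].
#' @return A [clip_dataset()] `factor` times the size.
#' @export
augment_dataset <- function(ds, factor = 2L, seed = 1L, ...) {
  if (factor < 1) stop("factor must be >= 1")
  out <- ds
  for (r in seq_len(factor - 1L)) {
    add <- lapply(seq_along(ds$clips), function(i) {
      plan <- sample_plan(sprintf("%s_up%d", ds$ids[i], r), seed, ...)
      apply_plan(plan, ds$clips[[i]])
    })
    out <- bind_datasets(out, clip_dataset(add, as.character(ds$labels),
                                           sprintf("%s_up%d", ds$ids, r),
                                           levels = levels(ds$labels)))
  }
  out
}
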