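# Shared fixtures, built in code and cached for the session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(builder)
  .fx[[name]]
}

# Three static motifs separable by spatial pattern alone; labelled with the
# first three canonical classes so 2- and 3-way heads can consume them.
spatial_only_motifs <- function(noise_sd = 2) {
  list(motif_spec("Pre-Gastrula", "blob", "none", radius_frac = 0.16,
                  intensity = 90, noise_sd = noise_sd),
       motif_spec("Gastrula", "shelled_blob", "none", radius_frac = 0.30,
                  intensity = 130, noise_sd = noise_sd),
       motif_spec("Trochophore", "empty_capsule", "none", radius_frac = 0.38,
                  intensity = 170, noise_sd = noise_sd))
}

# Random probability trajectory with rows summing to 1.
random_trajectory <- function(n_hours, n_classes = 10, id = "rnd") {
  p <- matrix(stats::runif(n_hours * n_classes), n_hours, n_classes)
  p <- p / rowSums(p)
  colnames(p) <- event_levels()[seq_len(n_classes)]
  prob_trajectory(id, seq_len(n_hours), p)
}

# Compressed event schedule used for CPU-scale end-to-end runs.
compressed_onsets <- c("Gastrula" = 2, "Trochophore" = 4, "Veliger" = 6,
                       "Eye spots" = 8, "Heart beat" = 10, "Crawling" = 12,
                       "Radula" = 14, "Hatch" = 16, "Dead" = 18)

# Generate a cohort: clip dataset + timelapses + annotations.
gen_cohort <- function(n_embryos, schedule_seed, render_seed, size = 32,
                       n_frames = 8, mean_onsets = compressed_onsets) {
  schedules <- random_schedules(n_embryos, seed = schedule_seed,
                                mean_onsets = mean_onsets,
                                clip_seconds = n_frames / 30)
  clips <- list(); labels <- character(0); tls <- list(); anns <- list()
  for (sc in schedules) {
    g <- generate_embryo_series(sc, seed = render_seed, size = size,
                                n_frames = n_frames)
    tls[[sc$embryo_id]] <- g$timelapse
    anns[[sc$embryo_id]] <- g$annotation
    clips <- c(clips, g$timelapse$clips)
    labels <- c(labels, g$labels)
  }
  list(ds = clip_dataset(clips, labels), tls = tls, ann = do.call(rbind, anns))
}
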