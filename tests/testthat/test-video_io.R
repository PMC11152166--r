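test_that("tiff frame sequences round-trip and sort numerically", {
  dir <- withr::local_tempdir()
  m <- motif_spec("Gastrula", "blob", "pulse", motion_amplitude = 0.3,
                  motion_frequency = 3, noise_sd = 3)
  clips <- lapply(1:3, function(h) render_clip(m, 12, 32, seed = h))
  tl <- timelapse("emb1", 0:2, clips)
  write_timelapse_frames(tl, dir)
  back <- concat_tiff_sequence(dir)
  expect_equal(back$embryo_id, "emb1")
  expect_equal(back$hours, 0:2)
  expect_equal(vapply(back$clips, clip_length, 1L), rep(12L, 3))
  for (h in 1:3) expect_equal(back$clips[[h]]$frames, tl$clips[[h]]$frames)
})

test_that("frame files are ordered by number, not lexically", {
  dir <- withr::local_tempdir()
  # frame 2 darker than frame 10: lexical order would swap them
  f2 <- matrix(10, 16, 16); f10 <- matrix(200, 16, 16)
  tiff::writeTIFF(f2 / 255, file.path(dir, "e_h0_f2.tif"), bits.per.sample = 8)
  tiff::writeTIFF(f10 / 255, file.path(dir, "e_h0_f10.tif"), bits.per.sample = 8)
  tl <- concat_tiff_sequence(dir)
  expect_equal(tl$clips[[1]]$frames[1, 1, 1, 1], 10)
  expect_equal(tl$clips[[1]]$frames[2, 1, 1, 1], 200)
})

test_that("missing hours warn and are retained as gaps", {
  dir <- withr::local_tempdir()
  for (h in c(0, 2)) tiff::writeTIFF(matrix(0.5, 16, 16),
                                     file.path(dir, sprintf("e_h%d_f1.tif", h)),
                                     bits.per.sample = 8)
  expect_warning(tl <- concat_tiff_sequence(dir), "missing hour")
  expect_equal(tl$hours, c(0L, 2L))
})

test_that("unreadable frames and mixed embryos are informative errors", {
  dir <- withr::local_tempdir()
  writeLines("not a tiff", file.path(dir, "e_h0_f1.tif"))
  expect_error(concat_tiff_sequence(dir), "e_h0_f1")
  dir2 <- withr::local_tempdir()
  for (e in c("a", "b")) tiff::writeTIFF(matrix(0.5, 16, 16),
                                         file.path(dir2, sprintf("%s_h0_f1.tif", e)),
                                         bits.per.sample = 8)
  expect_error(concat_tiff_sequence(dir2), "embryo_id")
  expect_silent(concat_tiff_sequence(dir2, embryo_id = "a"))
})

test_that("subsampling yields ceiling(n/stride) frames with the stated defaults", {
  m <- motif_spec("Gastrula", "blob", noise_sd = 0)
  cl <- render_clip(m, 120, 16, seed = 1)
  expect_equal(clip_length(subsample_clip(cl, 0, 120, 10)), 12L)
  expect_equal(clip_length(subsample_clip(cl, 0, 120, 1)), 120L)
  expect_equal(clip_length(subsample_clip(cl, 0, 120, 3)), 40L)
  expect_equal(clip_length(subsample_clip(cl, 0, 120, 5)), 24L)
  # identity at stride 1
  expect_identical(subsample_clip(cl, 0, 120, 1)$frames, cl$frames)
  # property over all strides at several source lengths
  for (n in c(7, 30, 120)) {
    cln <- render_clip(m, n, 16, seed = 1)
    for (s in seq_len(n))
      expect_equal(clip_length(subsample_clip(cln, 0, n, s)), as.integer(ceiling(n / s)))
  }
  expect_error(subsample_clip(cl, 10, 120, 10), "at least 130")
})

test_that("effective sampled rate is frame rate over stride", {
  expect_equal(30 / 10, 3)  # 30 fps at stride 10 -> 3 frames per second
  # the subsampled frames are exactly every stride-th source frame
  m <- motif_spec("Gastrula", "blob", "pulse", motion_amplitude = 0.5,
                  motion_frequency = 1, noise_sd = 0)
  cl <- render_clip(m, 120, 16, seed = 1, fps = 30)
  sub <- subsample_clip(cl, 0, 120, 10)
  for (k in 0:11)
    expect_identical(sub$frames[k + 1, , , ], cl$frames[10 * k + 1, , , ])
})

test_that("standardisation resizes with area interpolation and scales to [0,1]", {
  # acquisition-sized frame reduces to the model resolution
  big <- clip(array(stats::runif(1 * 1024 * 1026, 0, 255), c(1, 1024, 1026, 1)))
  std <- standardize_clip(big, 128)
  expect_equal(dim(std$frames), c(1L, 128L, 128L, 1L))
  expect_true(all(std$frames >= 0 & std$frames <= 1))
  # constant frame stays constant
  const <- clip(array(100, c(2, 64, 64, 1)))
  stdc <- standardize_clip(const, 32)
  expect_equal(max(abs(stdc$frames - 100 / 255)), 0, tolerance = 1e-12)
  # already at size: values unchanged up to scaling
  sm <- clip(array(seq(0, 255, length.out = 3 * 32 * 32), c(3, 32, 32, 1)))
  stds <- standardize_clip(sm, 32)
  expect_equal(stds$frames, sm$frames / 255, tolerance = 1e-12)
  # area resize averages exactly for integer factors: each 2x2 block of a
  # (0,0,255,255)-column matrix collapses to its block mean
  mtx <- matrix(rep(c(0, 0, 255, 255), 8), 4, 8)
  expect_equal(resize_area(mtx, 2, 4), matrix(rep(c(0, 255), 4), 2, 4))
})

test_that("splits are disjoint, exhaustive, sized by fractions and seeded", {
  m <- motif_spec("Gastrula", "blob", noise_sd = 0)
  tiny <- render_clip(m, 1, 16, seed = 1)
  ds <- clip_dataset(rep(list(tiny), 1000),
                     rep(event_levels()[1:10], each = 100))
  sp <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 5)
  expect_equal(length(sp$train), 800L)
  expect_equal(length(sp$val), 100L)
  expect_equal(length(sp$test), 100L)
  ids <- c(sp$train$ids, sp$val$ids, sp$test$ids)
  expect_setequal(ids, ds$ids)
  expect_equal(anyDuplicated(ids), 0L)
  sp2 <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(sp$train$ids, sp2$train$ids)
  expect_error(split_dataset(ds[0], seed = 1), "empty")
  expect_error(split_dataset(ds, c(0.5, 0.2, 0.2), 1), "sum to 1")
})

test_that("clip datasets round-trip losslessly with matching manifest", {
  dir <- withr::local_tempdir()
  m <- default_motif_library()
  ds <- synth_clip_dataset(m[c("Gastrula", "Hatch")], n_per_class = 3,
                           n_frames = 5, size = 24, seed = 2)
  manifest <- write_clip_dataset(ds, dir)
  expect_equal(nrow(manifest), length(ds))
  back <- read_clip_dataset(dir)
  expect_equal(length(back), length(ds))
  expect_equal(as.character(back$labels), as.character(ds$labels))
  expect_equal(back$ids, ds$ids)
  for (i in seq_along(ds$clips))
    expect_equal(back$clips[[i]]$frames, ds$clips[[i]]$frames)
})

test_that("labels outside the event taxonomy are rejected", {
  m <- motif_spec("Gastrula", "blob", noise_sd = 0)
  tiny <- render_clip(m, 1, 16, seed = 1)
  expect_error(clip_dataset(list(tiny), "Juvenile"), "Juvenile")
})

test_that("annotation tables validate structure and round-trip", {
  dir <- withr::local_tempdir()
  ann <- data.frame(embryo_id = c("a", "a"), event = c("Gastrula", "Hatch"),
                    onset_hour = c(5, 20))
  p <- file.path(dir, "ann.csv")
  write_annotation_table(ann, p)
  expect_equal(read_annotation_table(p), ann)
  expect_error(write_annotation_table(
    data.frame(embryo_id = "a", event = "Juvenile", onset_hour = 1), p), "Juvenile")
  expect_error(write_annotation_table(
    rbind(ann, ann[1, ]), p), "more than one onset")
})
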