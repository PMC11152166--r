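traj_from_cols <- function(hours, cols, id = "t", pad = 1e-9) {
  # build a full 10-class trajectory embedding the given named columns,
  # spreading the remaining mass over Pre-Gastrula; untouched event columns
  # get a negligible positive floor so peak extraction stays silent on them
  p <- matrix(0, length(hours), 10, dimnames = list(NULL, event_levels()))
  for (nm in setdiff(colnames(p), c(names(cols), "Pre-Gastrula"))) p[, nm] <- pad
  for (nm in names(cols)) p[, nm] <- cols[[nm]]
  p[, "Pre-Gastrula"] <- 1 - rowSums(p[, setdiff(colnames(p), "Pre-Gastrula")])
  prob_trajectory(id, hours, p)
}

test_that("peak-mode onset is the hour of the maximum, earliest on ties", {
  tr <- traj_from_cols(4:6, list("Gastrula" = c(0.1, 0.9, 0.2)))
  tm <- extract_timing(tr, timing_config())
  expect_equal(tm$onsets[["Gastrula"]], 5)
  # tie at hours 7 and 9 resolves to 7
  tr2 <- traj_from_cols(c(7, 8, 9), list("Veliger" = c(0.5, 0.1, 0.5)))
  expect_equal(extract_timing(tr2)$onsets[["Veliger"]], 7)
})

test_that("threshold-mode onset is the first strict crossing, absent if never", {
  tr <- traj_from_cols(10:13, list("Hatch" = c(0.1, 0.39, 0.41, 0.8)))
  tm <- extract_timing(tr)
  expect_equal(tm$onsets[["Hatch"]], 12)  # default Hatch threshold 0.4
  # exactly at the threshold does not cross (strict inequality)
  tr2 <- traj_from_cols(1:3, list("Dead" = c(0.3, 0.3, 0.3)))
  expect_true(is.na(extract_timing(tr2)$onsets[["Dead"]]))
})

test_that("excluded events are never reported and zero columns warn", {
  tr <- traj_from_cols(1:3, list("Gastrula" = c(0.2, 0.3, 0.2)))
  tm <- extract_timing(tr)
  expect_false("Pre-Gastrula" %in% names(tm$onsets))
  # a peak-mode event with an all-zero column is absent with a warning
  trz <- traj_from_cols(1:3, list(), pad = 0)
  w <- capture_warnings(tmz <- extract_timing(trz))
  expect_true(any(grepl("all-zero", w)))
  expect_true(all(is.na(tmz$onsets[c("Gastrula", "Veliger")])))
})

test_that("peak extraction equals a brute-force argmax oracle on random trajectories", {
  set.seed(19)
  cfg <- timing_config(modes = stats::setNames(rep("peak", 9),
                                               setdiff(event_levels(), "Pre-Gastrula")))
  for (r in 1:1000) {
    tr <- random_trajectory(sample(5:40, 1), id = paste0("r", r))
    tm <- extract_timing(tr, cfg)
    for (ev in names(tm$onsets)) {
      col <- tr$probs[, ev]
      # brute force scan for the earliest maximum
      best <- -Inf; at <- NA
      for (i in seq_along(col)) if (col[i] > best) { best <- col[i]; at <- tr$hours[i] }
      expect_identical(tm$onsets[[ev]], at)
    }
  }
})

test_that("threshold-mode onsets are monotone non-decreasing in the threshold", {
  set.seed(23)
  evs <- c("Radula", "Hatch", "Dead")
  for (r in 1:50) {
    tr <- random_trajectory(30, id = paste0("m", r))
    prev <- stats::setNames(rep(-Inf, 3), evs)
    for (tau in seq(0.05, 0.95, by = 0.05)) {
      cfg <- timing_config(thresholds = stats::setNames(rep(tau, 3), evs))
      tm <- extract_timing(tr, cfg)
      for (ev in evs) {
        cur <- tm$onsets[[ev]]
        if (!is.na(cur)) {
          expect_gte(cur, prev[[ev]])
          prev[[ev]] <- cur
        } else {
          prev[[ev]] <- Inf  # once absent, must stay absent for larger tau
        }
      }
    }
  }
})

test_that("timing extraction reads only its own event's column", {
  base <- traj_from_cols(1:5, list("Gastrula" = c(0, 0.8, 0.1, 0, 0),
                                   "Hatch" = c(0, 0, 0, 0.9, 0.9)))
  tm1 <- extract_timing(base)
  # perturbing a different column leaves Gastrula's onset unchanged
  pert <- traj_from_cols(1:5, list("Gastrula" = c(0, 0.8, 0.1, 0, 0),
                                   "Hatch" = c(0.05, 0.9, 0, 0, 0.9)))
  tm2 <- extract_timing(pert)
  expect_equal(tm1$onsets[["Gastrula"]], tm2$onsets[["Gastrula"]])
})

test_that("threshold calibration minimises onset error over the grid", {
  # perfect step trajectories: any threshold below the step is optimal, so
  # the lowest grid value is returned
  hours <- 1:20
  mk_step <- function(at, id) traj_from_cols(
    hours, list("Hatch" = ifelse(hours >= at, 0.85, 0)), id = id)
  trajs <- list(mk_step(7, "a"), mk_step(12, "b"))
  truth <- data.frame(embryo_id = c("a", "b"), event = "Hatch",
                      onset_hour = c(7, 12))
  cfg <- calibrate_thresholds(trajs, truth, grid = c(0.2, 0.5, 0.8),
                              config = timing_config())
  expect_equal(cfg$thresholds[["Hatch"]], 0.2)
  expect_error(calibrate_thresholds(trajs, truth, grid = numeric(0)), "empty")

  # noisy trajectories: the returned threshold attains the exhaustive-grid
  # minimum of the mean absolute error, computed independently here
  set.seed(3)
  noisy <- lapply(1:8, function(i) {
    at <- sample(5:15, 1)
    col <- ifelse(hours >= at, 0.7, 0) + stats::runif(20, 0, 0.25)
    p <- pmin(col, 0.95)
    traj_from_cols(hours, list("Hatch" = p), id = paste0("n", i))
  })
  truth_n <- data.frame(embryo_id = paste0("n", 1:8), event = "Hatch",
                        onset_hour = vapply(noisy, function(tr)
                          tr$hours[which(tr$probs[, "Hatch"] >= 0.7)[1]], 0.0))
  grid <- seq(0.1, 0.9, by = 0.1)
  cfg_n <- calibrate_thresholds(noisy, truth_n, grid, timing_config())
  mae_at <- function(tau) {
    mean(vapply(seq_along(noisy), function(i) {
      hit <- which(noisy[[i]]$probs[, "Hatch"] > tau)
      if (length(hit) == 0) diff(range(hours))
      else abs(noisy[[i]]$hours[hit[1]] - truth_n$onset_hour[i])
    }, 0.0))
  }
  maes <- vapply(grid, mae_at, 0.0)
  expect_equal(mae_at(cfg_n$thresholds[["Hatch"]]), min(maes))
})

test_that("trajectories round-trip through CSV", {
  dir <- withr::local_tempdir()
  tr <- random_trajectory(12, id = "rt")
  p <- file.path(dir, "traj.csv")
  write_trajectory(tr, p)
  back <- read_trajectory(p, embryo_id = "rt")
  expect_equal(back$hours, tr$hours)
  expect_equal(back$probs, tr$probs, tolerance = 1e-12)
})

test_that("trajectory invariants are enforced", {
  p <- matrix(0.1, 3, 10, dimnames = list(NULL, event_levels()))
  expect_error(prob_trajectory("x", c(1, 1, 2), p), "strictly increasing")
  expect_error(prob_trajectory("x", 1:3, p * 2), "sum to 1")
  expect_error(timing_config(thresholds = c("Hatch" = 1.2)), "\\(0, 1\\)")
  expect_error(timing_config(modes = c("Gastrula" = "sideways")), "peak")
})
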