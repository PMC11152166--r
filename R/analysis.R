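# Treatment-level summaries, thermal performance descriptors and 2D
# projections of learned embeddings.

#' Treatment-level summaries of event timings
#'
#' Mean, standard deviation and sample size of onset hours per (treatment,
#' event). Pre-Gastrula rows are excluded: that class marks development
#' before any event rather than an event itself. Embryos lacking an event
#' (absent onset) reduce that event's n; they are never imputed. A single
#' contributing embryo gives s.d. 0 with `n = 1` flagged.
#'
#' @param timings data.frame(embryo_id, event, onset_hour, treatment), e.g.
#'   from [timings_table()] or [simulate_thermal_timings()].
#' @return data.frame(treatment, event, mean_onset, sd_onset, n,
#'   single_embryo).
#' @export
summarize_treatments <- function(timings) {
  stopifnot(all(c("event", "onset_hour", "treatment") %in% names(timings)))
  d <- timings[timings$event != "Pre-Gastrula" & !is.na(timings$onset_hour), ]
  if (nrow(d) == 0) stop("no usable timings (at least one embryo per treatment required)")
  out <- do.call(rbind, lapply(split(d, list(d$treatment, d$event), drop = TRUE),
    function(g) data.frame(treatment = g$treatment[1], event = g$event[1],
                           mean_onset = mean(g$onset_hour),
                           sd_onset = if (nrow(g) > 1) stats::sd(g$onset_hour) else 0,
                           n = nrow(g), single_embryo = nrow(g) == 1,
                           stringsAsFactors = FALSE)))
  out <- out[order(match(out$event, event_levels()), out$treatment), ]
  rownames(out) <- NULL
  class(out) <- c("treatment_summary", "data.frame")
  out
}

#' Thermal performance curve of developmental rate for one event
#'
#' Developmental rate is the reciprocal of the mean onset hour at each
#' assayed temperature; T_opt is the assayed temperature at which the rate
#' is highest (ties resolved to the lower temperature). T_opt is reported on
#' the assayed grid — no curve fitting — matching a direct comparison of
#' treatments; optional quadratic interpolation around the grid maximum is
#' available but off by default.
#'
#' @param summaries A [summarize_treatments()] result (>= 2 temperatures).
#' @param event Event label.
#' @param interpolate Refine T_opt by a quadratic fit through the grid
#'   maximum and its neighbours.
#' @return A `thermal_curve`: data.frame(temperature, mean_onset, rate) with
#'   attribute `t_opt`.
#' @export
thermal_curve <- function(summaries, event, interpolate = FALSE) {
  d <- summaries[summaries$event == event, ]
  if (nrow(d) < 2) stop("need >= 2 temperatures for a thermal curve")
  d <- d[order(d$treatment), ]
  curve <- data.frame(temperature = d$treatment, mean_onset = d$mean_onset,
                      rate = 1 / d$mean_onset)
  i <- which(curve$rate == max(curve$rate))[1]  # first index = lower temperature
  topt <- curve$temperature[i]
  if (interpolate && i > 1 && i < nrow(curve)) {
    x <- curve$temperature[(i - 1):(i + 1)]; y <- curve$rate[(i - 1):(i + 1)]
    co <- stats::coef(stats::lm(y ~ stats::poly(x, 2, raw = TRUE)))
    if (co[3] < 0) topt <- -co[2] / (2 * co[3])
  }
  structure(curve, t_opt = topt, event = event, class = c("thermal_curve", "data.frame"))
}

#' Optimum temperature of a thermal curve
#'
#' @param curve A [thermal_curve()].
#' @return T_opt in degrees C.
#' @export
t_opt <- function(curve) attr(curve, "t_opt")

#' Relative developmental time
#'
#' Hours normalised to the embryo's terminal event (time of hatch or death):
#' `hour / terminal_hour`, clamped to [0, 1].
#'
#' @param hours Imaged hour stamps.
#' @param terminal_hour Onset hour of the terminal event (> 0).
#' @return Numeric vector in [0, 1], monotone in `hours`.
#' @export
relative_time <- function(hours, terminal_hour) {
  if (is.na(terminal_hour) || terminal_hour <= 0)
    stop("terminal event (hatch or death) is required to normalise time")
  pmin(pmax(hours / terminal_hour, 0), 1)
}

#' Terminal hour (hatch or death) from extracted timings
#'
#' @param tm An `event_timings`.
#' @return The earlier of the Hatch and Dead onsets, or NA with a warning if
#'   neither is present (such samples are excluded from relative-time
#'   colouring).
#' @export
terminal_hour <- function(tm) {
  cand <- tm$onsets[intersect(c("Hatch", "Dead"), names(tm$onsets))]
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0) {
    warning("embryo ", tm$embryo_id, " has neither hatch nor death; excluded")
    return(NA_real_)
  }
  min(cand)
}

# Symmetric k-nearest-neighbour adjacency (Euclidean).
.knn_graph <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    A[i, nb] <- 1
  }
  pmax(A, t(A))
}

#' Project embeddings to two dimensions
#'
#' `linear_pca` returns the first two principal components. The nonlinear
#' neighbour method is a k-nearest-neighbour Laplacian eigenmap: a symmetric
#' kNN graph (Euclidean metric, 15 neighbours by default) whose normalised
#' graph Laplacian's two smallest non-trivial eigenvectors give the
#' coordinates — a deterministic spectral embedding that, like other
#' neighbour-graph methods, preserves local structure rather than global
#' distances.
#'
#' @param embeddings N x D matrix of (unit-norm) embedding vectors.
#' @param method `"linear_pca"` or `"nonlinear_neighbor"`.
#' @param labels Optional event labels carried into the output.
#' @param rel_time Optional relative developmental time in [0, 1] per sample.
#' @param n_neighbors Neighbourhood size for the nonlinear method; there must
#'   be more samples than neighbours.
#' @return data.frame(x, y, label, relative_time); one row per sample, in
#'   input order.
#' @export
project_embeddings <- function(embeddings,
                               method = c("linear_pca", "nonlinear_neighbor"),
                               labels = NULL, rel_time = NULL,
                               n_neighbors = 15L) {
  method <- match.arg(method)
  n <- nrow(embeddings)
  if (method == "linear_pca") {
    pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
    xy <- pc$x[, 1:2, drop = FALSE]
  } else {
    if (n <= n_neighbors)
      stop("need more samples (", n, ") than neighbours (", n_neighbors, ")")
    A <- .knn_graph(embeddings, n_neighbors)
    deg <- pmax(rowSums(A), 1e-12)
    Lsym <- diag(n) - diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
    e <- eigen(Lsym, symmetric = TRUE)
    xy <- e$vectors[, c(n - 1, n - 2), drop = FALSE]
    # fix sign for determinism
    for (j in 1:2) if (xy[which.max(abs(xy[, j])), j] < 0) xy[, j] <- -xy[, j]
  }
  data.frame(x = xy[, 1], y = xy[, 2],
             label = if (is.null(labels)) NA_character_ else as.character(labels),
             relative_time = if (is.null(rel_time)) NA_real_ else rel_time,
             stringsAsFactors = FALSE)
}

#' Mean silhouette width of labelled points
#'
#' @param xy Matrix or data.frame of coordinates.
#' @param labels Class labels (>= 2 classes).
#' @return Mean silhouette width over all samples.
#' @export
silhouette_score <- function(xy, labels) {
  xy <- as.matrix(xy)
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2) stop("silhouette needs >= 2 classes")
  if (requireNamespace("cluster", quietly = TRUE)) {
    return(mean(cluster::silhouette(cl, stats::dist(xy))[, 3]))
  }
  # plain computation: a(i) mean intra-class, b(i) min mean other-class
  d <- as.matrix(stats::dist(xy))
  s <- vapply(seq_along(cl), function(i) {
    own <- cl == cl[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(d[i, cl == k]), 0.0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0.0)
  mean(s)
}

#' Mean intra- and inter-class embedding distances
#'
#' @param embeddings N x D matrix.
#' @param labels Class labels.
#' @return list(intra =, inter =): mean pairwise Euclidean distance within
#'   and between classes.
#' @export
class_distances <- function(embeddings, labels) {
  d <- as.matrix(stats::dist(embeddings))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  list(intra = mean(d[same & !is.na(same)]),
       inter = mean(d[!same & !is.na(same)]))
}

#' Plot helpers
#'
#' Quick base-graphics panels: a stacked probability-trajectory plot, a 2D
#' embedding scatter coloured by class, and thermal performance curves.
#'
#' @param traj A [prob_trajectory()].
#' @param ... Passed to plotting primitives.
#' @return Invisibly, the input.
#' @export
plot_trajectory <- function(traj, ...) {
  k <- ncol(traj$probs)
  cols <- grDevices::hcl.colors(k, "Dark 3")
  graphics::matplot(traj$hours, traj$probs, type = "l", lty = 1, col = cols,
                    xlab = "hour", ylab = "event probability",
                    main = traj$embryo_id, ylim = c(0, 1), ...)
  graphics::legend("topleft", colnames(traj$probs), col = cols, lty = 1,
                   cex = 0.6, bty = "n")
  invisible(traj)
}

#' @rdname plot_trajectory
#' @param projection A [project_embeddings()] result.
#' @export
plot_projection <- function(projection, ...) {
  lab <- factor(projection$label)
  cols <- grDevices::hcl.colors(max(2L, nlevels(lab)), "Dark 3")
  graphics::plot(projection$x, projection$y, col = cols[as.integer(lab)],
                 pch = 16, xlab = "dim 1", ylab = "dim 2", ...)
  graphics::legend("topright", levels(lab), col = cols[seq_len(nlevels(lab))],
                   pch = 16, cex = 0.6, bty = "n")
  invisible(projection)
}

#' @rdname plot_trajectory
#' @param curve A [thermal_curve()].
#' @export
plot_thermal <- function(curve, ...) {
  graphics::plot(curve$temperature, curve$rate, type = "b", pch = 16,
                 xlab = "temperature (deg C)", ylab = "developmental rate (1/h)",
                 main = attr(curve, "event"), ...)
  graphics::abline(v = t_opt(curve), lty = 2)
  invisible(curve)
}
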