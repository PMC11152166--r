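# Training and evaluation.
#
# Classifier training follows the fixed-epoch protocol: sparse categorical
# cross-entropy with Adam at a fixed learning rate, no early stopping or
# best-checkpoint selection — final-epoch weights are returned. The
# validation set is monitored each epoch but never used for selection.
# After training, batch-normalisation running statistics are re-estimated
# from one pass over the training inputs so that evaluation-mode inference
# is well calibrated even after short runs.

#' Training configuration
#'
#' @param loss `"sparse_categorical_cross_entropy"` (classifier) or
#'   `"triplet_semi_hard"` (embedder).
#' @param learning_rate Fixed Adam learning rate; defaults to 1e-6 for the
#'   classifier and 1e-3 for triplet training.
#' @param epochs Training epochs; defaults to 50 (classifier) or
#'   20 (triplet).
#' @param batch_size Clips per batch (default 32).
#' @param seed Integer seed controlling initialisation, data order and
#'   augmentation.
#' @param n_repeats Number of repeat runs for seed-averaged comparisons.
#' @param margin Triplet margin.
#' @param calibrate_bn Re-estimate batch-norm statistics on the training set
#'   after the final epoch.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(loss = c("sparse_categorical_cross_entropy",
                                  "triplet_semi_hard"),
                         learning_rate = NULL, epochs = NULL, batch_size = 32L,
                         seed = 1L, n_repeats = 3L, margin = 1.0,
                         calibrate_bn = TRUE, verbose = FALSE) {
  loss <- match.arg(loss)
  if (is.null(learning_rate))
    learning_rate <- if (loss == "triplet_semi_hard") 1e-3 else 1e-6
  if (is.null(epochs)) epochs <- if (loss == "triplet_semi_hard") 20L else 50L
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(loss = loss, optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), n_repeats = as.integer(n_repeats),
                 margin = margin, calibrate_bn = calibrate_bn, verbose = verbose),
            class = "train_config")
}

# Standardise a dataset against a spec: resize/scale frames, check L.
as_model_inputs <- function(ds, spec) {
  L <- spec$input_shape[1]; size <- spec$input_shape[2]
  xs <- vector("list", length(ds))
  for (i in seq_along(ds$clips)) {
    cl <- ds$clips[[i]]
    if (clip_length(cl) != L)
      stop("clip ", i, " has ", clip_length(cl), " frames but the model expects ",
           L, "; subsample_clip() first")
    d <- dim(cl$frames)
    if (d[2] != size || d[3] != size) cl <- standardize_clip(cl, size)
    xs[[i]] <- clip_input_array(cl)
  }
  xs
}

labels0_of <- function(ds, n_classes) {
  y <- as.integer(ds$labels) - 1L
  if (anyNA(y) || any(y < 0) || any(y >= n_classes))
    stop("labels outside 0..", n_classes - 1,
         " (check the dataset's label levels against the model's classes)")
  y
}

set_bn_collect <- function(net, on) {
  walk_layers(net$layers, function(ly) {
    if (ly$type == "bn") {
      ly$collect <- on
      if (on) { ly$acc_n <- 0; ly$acc_sum <- 0; ly$acc_sumsq <- 0 }
    }
  })
}

finalize_bn <- function(net) {
  walk_layers(net$layers, function(ly) {
    if (ly$type == "bn" && isTRUE(ly$collect) && ly$acc_n > 0) {
      m <- ly$acc_sum / ly$acc_n
      ly$run_mean <- m
      ly$run_var <- pmax(ly$acc_sumsq / ly$acc_n - m^2, 0)
    }
  })
  set_bn_collect(net, FALSE)
}

# One pass over the inputs with full-dataset batch-norm statistics.
calibrate_bn <- function(net, xs, batch_size = 32L) {
  set_bn_collect(net, TRUE)
  for (s in seq(1, length(xs), by = batch_size)) {
    e <- min(s + batch_size - 1L, length(xs))
    net_forward(net, clips_to_act(xs[s:e]), training = TRUE)
  }
  finalize_bn(net)
  invisible(net)
}

#' Train the classifier
#'
#' @param net A classifier `devnet` from [build_classifier()].
#' @param train_set,val_set [clip_dataset()]s; clips must match the model's
#'   input length (subsample first) and are standardised automatically.
#' @param config A [train_config()].
#' @return list(model = trained `devnet`, history = data.frame with per-epoch
#'   loss and accuracy).
#' @export
train_classifier <- function(net, train_set, val_set = NULL,
                             config = train_config()) {
  spec <- net$spec
  y <- labels0_of(train_set, spec$n_classes)
  xs <- as_model_inputs(train_set, spec)
  val <- if (!is.null(val_set) && length(val_set) > 0)
    list(xs = as_model_inputs(val_set, spec), y = labels0_of(val_set, spec$n_classes))
  n <- length(xs)
  hist <- list()
  with_seed(mix_seed(config$seed, "train"), {
    adam_init(net$layers)
    t <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (s in seq(1, n, by = config$batch_size)) {
        e <- min(s + config$batch_size - 1L, n)
        bi <- ord[s:e]
        act <- clips_to_act(xs[bi])
        z <- net_forward(net, act, training = TRUE)
        l <- loss_softmax_xent(z, y[bi])
        tot_loss <- tot_loss + l$loss * length(bi)
        tot_correct <- tot_correct + sum(max.col(z) - 1L == y[bi])
        d <- l$grad
        for (ly in rev(net$layers)) d <- ly_backward(ly, d)
        t <- t + 1L
        adam_step(net$layers, config$learning_rate, t)
        zero_grads(net$layers)
      }
      row <- data.frame(epoch = ep, loss = tot_loss / n, accuracy = tot_correct / n,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(val)) {
        vz <- NULL
        for (s in seq(1, length(val$xs), by = config$batch_size)) {
          e <- min(s + config$batch_size - 1L, length(val$xs))
          vz <- rbind(vz, net_forward(net, clips_to_act(val$xs[s:e]), training = FALSE))
        }
        vl <- loss_softmax_xent(vz, val$y)
        row$val_loss <- vl$loss
        row$val_accuracy <- mean(max.col(vz) - 1L == val$y)
      }
      if (config$verbose)
        message(sprintf("epoch %d/%d loss %.4f acc %.3f%s", ep, config$epochs,
                        row$loss, row$accuracy,
                        if (!is.null(val)) sprintf(" val_acc %.3f", row$val_accuracy) else ""))
      hist[[ep]] <- row
    }
  })
  if (config$calibrate_bn) calibrate_bn(net, xs, config$batch_size)
  list(model = net, history = do.call(rbind, hist))
}

#' Evaluate a classifier on a test set
#'
#' @param net A trained classifier `devnet`.
#' @param test_set A [clip_dataset()] (non-empty).
#' @return An `eval_report`: `top1_accuracy`, `confusion_matrix`
#'   (n_classes x n_classes counts, rows = ground truth), `per_class_recall`,
#'   `n`.
#' @export
evaluate <- function(net, test_set) {
  if (length(test_set) == 0) stop("empty test set")
  spec <- net$spec
  y <- labels0_of(test_set, spec$n_classes)
  xs <- as_model_inputs(test_set, spec)
  p <- predict_proba(net, xs)
  pred <- max.col(p) - 1L
  k <- spec$n_classes
  cm <- matrix(0L, k, k,
               dimnames = list(truth = levels(test_set$labels)[seq_len(k)],
                               predicted = levels(test_set$labels)[seq_len(k)]))
  for (i in seq_along(y)) cm[y[i] + 1L, pred[i] + 1L] <- cm[y[i] + 1L, pred[i] + 1L] + 1L
  rs <- rowSums(cm)
  structure(list(top1_accuracy = sum(diag(cm)) / length(y),
                 confusion_matrix = cm,
                 per_class_recall = ifelse(rs > 0, diag(cm) / rs, NA_real_),
                 n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: top-1 accuracy %.3f on %d samples\n",
              x$top1_accuracy, x$n))
  invisible(x)
}

#' Train the embedder with triplet semi-hard loss
#'
#' Batches are composed by class-balanced sampling (several samples from each
#' of several classes) so that every batch contains valid triplets; a batch
#' without any valid triplet is skipped with a counted warning.
#'
#' @param net An embedding `devnet` from [build_embedder()].
#' @param train_set A [clip_dataset()] with >= 2 classes of >= 2 samples.
#' @param config A [train_config()] with `loss = "triplet_semi_hard"`.
#' @param samples_per_class Samples drawn per class per batch.
#' @return list(model = trained embedder, history = per-epoch mean loss,
#'   skipped = number of batches without a valid triplet).
#' @export
train_triplet <- function(net, train_set, config = train_config("triplet_semi_hard"),
                          samples_per_class = 4L) {
  spec <- net$spec
  y <- labels0_of(train_set, spec$n_classes)
  xs <- as_model_inputs(train_set, spec)
  classes <- sort(unique(y))
  if (length(classes) < 2 || any(table(y) < 2))
    stop("triplet training needs >= 2 classes with >= 2 samples each")
  by_class <- split(seq_along(y), y)
  n_batches <- max(1L, floor(length(y) / config$batch_size))
  classes_per_batch <- max(2L, min(length(classes),
                                   config$batch_size %/% samples_per_class))
  hist <- list(); skipped <- 0L
  with_seed(mix_seed(config$seed, "triplet"), {
    adam_init(net$layers)
    t <- 0L
    for (ep in seq_len(config$epochs)) {
      tot <- 0; nb <- 0L
      for (b in seq_len(n_batches)) {
        cls <- sample(as.character(classes), classes_per_batch)
        bi <- unlist(lapply(cls, function(cl) {
          pool <- by_class[[cl]]
          sample(pool, min(samples_per_class, length(pool)),
                 replace = length(pool) < 2)
        }))
        act <- clips_to_act(xs[bi])
        emb <- net_forward(net, act, training = TRUE)
        l <- loss_triplet_semihard(emb, y[bi], config$margin)
        if (l$n_triplets == 0L) {
          skipped <- skipped + 1L
          warning("batch without a valid triplet skipped")
          next
        }
        tot <- tot + l$loss; nb <- nb + 1L
        d <- l$grad
        for (ly in rev(net$layers)) d <- ly_backward(ly, d)
        t <- t + 1L
        adam_step(net$layers, config$learning_rate, t)
        zero_grads(net$layers)
      }
      if (config$verbose)
        message(sprintf("epoch %d/%d triplet loss %.4f", ep, config$epochs,
                        if (nb > 0) tot / nb else NA))
      hist[[ep]] <- data.frame(epoch = ep, loss = if (nb > 0) tot / nb else NA_real_)
    }
  })
  if (config$calibrate_bn) calibrate_bn(net, xs, config$batch_size)
  list(model = net, history = do.call(rbind, hist), skipped = skipped)
}

#' Reduce a dataset to the first frame of every clip
#'
#' Used by the 2D baseline so that it sees exactly the same examples as the
#' 3D model, but without temporal information.
#'
#' @param ds A [clip_dataset()].
#' @return A [clip_dataset()] of single-frame clips.
#' @export
first_frame_dataset <- function(ds) {
  clip_dataset(lapply(ds$clips, function(cl)
    clip(cl$frames[1, , , , drop = FALSE], source_id = cl$source_id)),
    as.character(ds$labels), ds$ids, levels = levels(ds$labels))
}

# Train + evaluate once for a given spec and seed.
fit_and_score <- function(spec, train_set, test_set, config, seed) {
  cfg <- config
  cfg$seed <- seed
  net <- build_classifier(spec, seed = mix_seed(seed, "init"))
  fit <- train_classifier(net, train_set, val_set = NULL, config = cfg)
  evaluate(fit$model, test_set)
}

#' Ablation harnesses: 2D baseline, temporal stride, clip length
#'
#' `variant = "baseline_2d"` trains the 3D classifier on full clips and an
#' equivalent 2D residual classifier on only the first frame of the same
#' examples, repeating over seeds, and reports mean top-1 for both.
#' `variant = "stride"` retrains the 3D classifier on the same source clips
#' subsampled at each temporal stride; `variant = "length"` varies the number
#' of seconds of source video at a fixed stride. Each training/test split and
#' initialisation is re-seeded per repeat.
#'
#' @param source_train,source_test [clip_dataset()]s. For stride/length
#'   variants these hold unsubsampled source clips; for `baseline_2d` they
#'   hold model-ready clips.
#' @param variant One of `"baseline_2d"`, `"stride"`, `"length"`.
#' @param values Strides (default c(3, 5, 10)) or lengths in seconds
#'   (default c(4, 8, 16)).
#' @param spec The 3D `devnet_spec` template; its input length is adjusted
#'   per stride/length.
#' @param config A [train_config()]; `n_repeats` controls the seeds.
#' @param fps Source frame rate (length variant).
#' @param baseline_filters Width of the 2D baseline's first stage (scaled
#'   down together with the 3D spec for CPU-sized runs).
#' @param seeds Seeds for the repeats.
#' @return list(reports = nested list of `eval_report`, summary = data.frame
#'   of per-variant per-seed top-1 accuracies).
#' @export
run_ablation <- function(source_train, source_test,
                         variant = c("baseline_2d", "stride", "length"),
                         values = NULL, spec = tiny_model_spec(),
                         config = train_config(), fps = 30,
                         baseline_filters = 8L,
                         seeds = seq_len(config$n_repeats)) {
  variant <- match.arg(variant)
  reports <- list(); rows <- list()
  if (variant == "baseline_2d") {
    tr2 <- first_frame_dataset(source_train)
    te2 <- first_frame_dataset(source_test)
    spec2 <- model_spec(input_shape = c(1, spec$input_shape[2], spec$input_shape[3], 1),
                        n_classes = spec$n_classes,
                        stem = list(filters = baseline_filters, kernel = c(1, 7, 7),
                                    stride = c(1, 2, 2), pool_kernel = c(1, 3, 3),
                                    pool_stride = c(1, 2, 2)),
                        stages = list(stage_spec(2, baseline_filters, 1),
                                      stage_spec(2, 2 * baseline_filters, 2),
                                      stage_spec(2, 4 * baseline_filters, 2),
                                      stage_spec(2, 8 * baseline_filters, 2)),
                        block_type = "conv2d")
    for (s in seeds) {
      r3 <- fit_and_score(spec, source_train, source_test, config, mix_seed(s, "3d"))
      r2 <- fit_and_score(spec2, tr2, te2, config, mix_seed(s, "2d"))
      reports[[as.character(s)]] <- list(model_3d = r3, baseline_2d = r2)
      rows[[length(rows) + 1]] <- data.frame(variant = c("3d", "2d"), seed = s,
                                             top1 = c(r3$top1_accuracy, r2$top1_accuracy))
    }
  } else {
    if (is.null(values)) values <- if (variant == "stride") c(3, 5, 10) else c(4, 8, 16)
    src_len <- clip_length(source_train$clips[[1]])
    for (v in values) {
      if (variant == "stride") { nsf <- src_len; stride <- v }
      else { nsf <- round(v * fps); stride <- 10L }
      Lv <- as.integer(ceiling(nsf / stride))
      sub <- function(ds) clip_dataset(
        lapply(ds$clips, subsample_clip, start_frame = 0L,
               n_source_frames = nsf, stride = stride),
        as.character(ds$labels), ds$ids, levels = levels(ds$labels))
      trv <- sub(source_train); tev <- sub(source_test)
      specv <- spec
      specv$input_shape[1] <- Lv
      for (s in seeds) {
        r <- fit_and_score(specv, trv, tev, config, mix_seed(s, variant, v))
        reports[[paste(variant, v, s, sep = "_")]] <- r
        rows[[length(rows) + 1]] <- data.frame(variant = as.character(v), seed = s,
                                               top1 = r$top1_accuracy)
      }
    }
  }
  summary <- do.call(rbind, rows)
  list(reports = reports, summary = summary)
}

#' Mean and standard error of ablation accuracies
#'
#' @param summary The `summary` data.frame from [run_ablation()].
#' @return data.frame(variant, mean_top1, se, n); `lo`/`hi` give the
#'   mean +/- 2 standard error band used as the overlap criterion.
#' @export
ablation_summary <- function(summary) {
  out <- do.call(rbind, lapply(split(summary, summary$variant), function(d) {
    se <- if (nrow(d) > 1) stats::sd(d$top1) / sqrt(nrow(d)) else 0
    data.frame(variant = d$variant[1], mean_top1 = mean(d$top1), se = se,
               n = nrow(d), lo = mean(d$top1) - 2 * se, hi = mean(d$top1) + 2 * se)
  }))
  rownames(out) <- NULL
  out
}

#' Predict class probabilities / embeddings for a clip dataset
#'
#' Convenience wrappers that standardise a [clip_dataset()] against the
#' network's input shape and run evaluation-mode inference.
#'
#' @param net A trained `devnet`.
#' @param ds A [clip_dataset()].
#' @return `dataset_proba`: N x n_classes probability matrix;
#'   `dataset_embeddings`: N x D unit-norm embedding matrix.
#' @export
dataset_proba <- function(net, ds) predict_proba(net, as_model_inputs(ds, net$spec))

#' @rdname dataset_proba
#' @export
dataset_embeddings <- function(net, ds) predict_embedding(net, as_model_inputs(ds, net$spec))
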