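# Training-loop behaviour at deliberately small scale: short runs on small
# synthetic sets, checking learning dynamics and contracts rather than
# final accuracy.

test_that("training configuration applies the documented defaults and checks", {
  c1 <- train_config()
  expect_equal(c1$learning_rate, 1e-6)
  expect_equal(c1$epochs, 50L)
  expect_equal(c1$batch_size, 32L)
  c2 <- train_config("triplet_semi_hard")
  expect_equal(c2$learning_rate, 1e-3)
  expect_equal(c2$epochs, 20L)
  expect_error(train_config(learning_rate = 0), "> 0")
  expect_error(train_config(epochs = 0), ">= 1")
})

test_that("training loss decreases over two epochs on a small synthetic set", {
  motifs <- spatial_only_motifs()
  ds <- fixture("sep64", synth_clip_dataset(motifs[1:2], 32, n_frames = 8,
                                            size = 32, seed = 1))
  net <- build_classifier(tiny_model_spec(n_classes = 2), seed = 5)
  cfg <- train_config(learning_rate = 1e-3, epochs = 2, batch_size = 32, seed = 2)
  fit <- train_classifier(net, ds, config = cfg)
  expect_lt(fit$history$loss[2], fit$history$loss[1])
})

test_that("identical seeds give identical final weights and histories", {
  motifs <- spatial_only_motifs()
  ds <- fixture("sep64", synth_clip_dataset(motifs[1:2], 32, n_frames = 8,
                                            size = 32, seed = 1))
  cfg <- train_config(learning_rate = 1e-3, epochs = 2, batch_size = 16, seed = 7)
  run <- function() {
    net <- build_classifier(tiny_model_spec(n_classes = 2), seed = 5)
    train_classifier(net, ds, config = cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  w1 <- devevent:::collect_param_layers(f1$model$layers)
  w2 <- devevent:::collect_param_layers(f2$model$layers)
  for (i in seq_along(w1)) expect_identical(w1[[i]]$W, w2[[i]]$W)
})

test_that("a tiny model reaches high validation accuracy on separable classes", {
  motifs <- spatial_only_motifs()
  tr <- synth_clip_dataset(motifs[1:2], 30, n_frames = 8, size = 32, seed = 3)
  va <- synth_clip_dataset(motifs[1:2], 10, n_frames = 8, size = 32, seed = 44)
  net <- build_classifier(tiny_model_spec(n_classes = 2), seed = 1)
  cfg <- train_config(learning_rate = 1e-3, epochs = 5, batch_size = 32, seed = 1)
  fit <- train_classifier(net, tr, va, cfg)
  expect_gte(max(fit$history$val_accuracy), 0.95)
  expect_lte(nrow(fit$history), 20)
})

test_that("labels outside the model's classes fail before training", {
  motifs <- spatial_only_motifs()
  ds <- synth_clip_dataset(motifs[3], 4, n_frames = 8, size = 32, seed = 1)  # code 2
  net <- build_classifier(tiny_model_spec(n_classes = 2), seed = 1)
  expect_error(train_classifier(net, ds, config = train_config(epochs = 1)),
               "labels outside")
})

test_that("evaluation reports satisfy the confusion-matrix contracts", {
  motifs <- spatial_only_motifs()
  tr <- fixture("sep64", synth_clip_dataset(motifs[1:2], 32, n_frames = 8,
                                            size = 32, seed = 1))
  te <- synth_clip_dataset(motifs[1:2], 10, n_frames = 8, size = 32, seed = 99)
  net <- build_classifier(tiny_model_spec(n_classes = 2), seed = 5)
  cfg <- train_config(learning_rate = 1e-3, epochs = 4, batch_size = 32, seed = 2)
  fit <- train_classifier(net, tr, config = cfg)
  rep <- evaluate(fit$model, te)
  # rows sum to per-class test counts regardless of prediction quality
  expect_equal(unname(rowSums(rep$confusion_matrix)),
               unname(as.integer(table(droplevels(te$labels)))))
  expect_equal(rep$top1_accuracy,
               sum(diag(rep$confusion_matrix)) / rep$n)
  # a near-perfect predictor has an identity-structured confusion matrix
  expect_gte(rep$top1_accuracy, 0.9)
  expect_error(evaluate(fit$model, te[0]), "empty")
})

test_that("triplet training separates classes and honours its contracts", {
  motifs <- spatial_only_motifs()
  tr <- synth_clip_dataset(motifs, 16, n_frames = 8, size = 32, seed = 4)
  spec <- tiny_model_spec(n_classes = 10, head = "l2_embedding")
  emb <- build_embedder(spec, seed = 2)
  cfg <- train_config("triplet_semi_hard", learning_rate = 1e-3, epochs = 4,
                      batch_size = 18, seed = 6)
  expect_error(train_triplet(emb, synth_clip_dataset(motifs[1], 4, n_frames = 8,
                                                     size = 32, seed = 1), cfg),
               ">= 2 classes")
  fit <- train_triplet(emb, tr, cfg, samples_per_class = 6)
  te <- synth_clip_dataset(motifs, 8, n_frames = 8, size = 32, seed = 321)
  E <- dataset_embeddings(fit$model, te)
  expect_equal(sqrt(rowSums(E^2)), rep(1, nrow(E)), tolerance = 1e-5)
  cd <- class_distances(E, as.character(te$labels))
  expect_lt(cd$intra, cd$inter)
})

test_that("selective balancing never hurts minority recall on imbalanced data", {
  m <- default_motif_library()
  imb <- bind_datasets(
    synth_clip_dataset(m["Gastrula"], 40, n_frames = 8, size = 32, seed = 1),
    synth_clip_dataset(m["Heart beat"], 6, n_frames = 8, size = 32, seed = 2))
  te <- bind_datasets(
    synth_clip_dataset(m["Gastrula"], 12, n_frames = 8, size = 32, seed = 71),
    synth_clip_dataset(m["Heart beat"], 12, n_frames = 8, size = 32, seed = 72))
  bal <- balance_classes(imb, seed = 3)
  rec <- function(train_set, seed) {
    cfg <- train_config(learning_rate = 1e-3, epochs = 3, batch_size = 32,
                        seed = seed)
    net <- build_classifier(tiny_model_spec(n_classes = 10), seed = seed)
    fit <- train_classifier(net, train_set, config = cfg)
    evaluate(fit$model, te)$per_class_recall[["Heart beat"]]
  }
  seeds <- 1:3
  r_bal <- mean(vapply(seeds, function(s) rec(bal, s), 0.0))
  r_imb <- mean(vapply(seeds, function(s) rec(imb, s), 0.0))
  expect_gte(r_bal, r_imb)
})

test_that("the clip-length ablation harness subsamples and trains per value", {
  motifs <- spatial_only_motifs()
  tr <- synth_clip_dataset(motifs[1:2], 16, n_frames = 12, size = 32, seed = 2)
  te <- synth_clip_dataset(motifs[1:2], 8, n_frames = 12, size = 32, seed = 81)
  cfg <- train_config(learning_rate = 1e-3, epochs = 2, batch_size = 16,
                      n_repeats = 1)
  ab <- run_ablation(tr, te, "length", values = c(0.2, 0.4),
                     spec = tiny_model_spec(n_classes = 2),
                     config = cfg, fps = 30, seeds = 1)
  expect_equal(sort(unique(ab$summary$variant)), c("0.2", "0.4"))
  expect_equal(nrow(ab$summary), 2)
  s <- ablation_summary(ab$summary)
  expect_true(all(c("mean_top1", "se", "lo", "hi") %in% names(s)))
})
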