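test_that("default architecture calibrates to ~5.2M parameters and ~3.7 GFLOPs", {
  spec <- default_model_spec()
  p <- count_parameters(spec)
  expect_equal(round(p / 1e6, 1), 5.2)
  g <- count_flops(spec, ops_per_mac = 2)
  expect_equal(round(g / 1e9, 1), 3.7)
  # analytic count equals the built network's count exactly
  net <- build_classifier(spec, seed = 1)
  expect_identical(network_parameters(net), as.integer(p))
})

test_that("closed-form counts hold for elementary specs", {
  # a single 1x3x3 convolution from 1 channel to F filters with bias: 9F + F
  for (F in c(4, 16, 48)) {
    spec <- model_spec(input_shape = c(4, 16, 16, 1), n_classes = 2,
                       stem = list(filters = F, kernel = c(1, 3, 3),
                                   stride = c(1, 1, 1), pool_kernel = c(1, 2, 2),
                                   pool_stride = c(1, 2, 2)),
                       stages = list())
    # stem conv (9F + F) + stem BN (2F) + head dense (2F + 2)
    expect_equal(count_parameters(spec), 9 * F + F + 2 * F + 2 * F + 2)
  }
  # parameter count is independent of input length/width/height
  base <- count_parameters(tiny_model_spec())
  expect_equal(count_parameters(tiny_model_spec(input_shape = c(16, 64, 64, 1))), base)
  # halving W and H divides spatial conv ops by 4 (zero-stage spec: stem only)
  sp0 <- model_spec(input_shape = c(4, 32, 32, 1), n_classes = 2,
                    stem = list(filters = 8, kernel = c(1, 3, 3), stride = c(1, 1, 1),
                                pool_kernel = c(1, 2, 2), pool_stride = c(1, 2, 2)),
                    stages = list())
  f_full <- count_flops(sp0)
  f_half <- count_flops(sp0, input_shape = c(4, 16, 16, 1))
  # stem conv dominates; dense contributes 2 * 8 * 2 ops in both
  dense_ops <- 2 * 8 * 2
  expect_equal((f_full - dense_ops) / (f_half - dense_ops), 4)
  # hand-computed stem + head: conv 2*9*1*8 per position, 4*32*32 positions
  expect_equal(f_full, 2 * 9 * 8 * 4 * 32 * 32 + dense_ops)
})

test_that("analytic parameter count equals built count for random specs", {
  set.seed(31)
  for (r in 1:20) {
    n_stages <- sample(1:3, 1)
    filters <- sample(c(4, 6, 8, 12), n_stages, replace = TRUE)
    stages <- lapply(seq_len(n_stages), function(i)
      list(blocks = sample(1:2, 1), filters = filters[i],
           stride = sample(1:2, 1)))
    spec <- model_spec(input_shape = c(4, 16, 16, 1), n_classes = sample(2:10, 1),
                       stem = list(filters = sample(c(4, 8), 1), kernel = c(1, 3, 3),
                                   stride = c(1, 1, 1), pool_kernel = c(1, 2, 2),
                                   pool_stride = c(1, 2, 2)),
                       stages = stages,
                       mid_channel_policy = sample(c("equal_to_out", "matched_3d"), 1))
    net <- build_classifier(spec, seed = r)
    expect_identical(network_parameters(net), as.integer(count_parameters(spec)))
  }
})

test_that("classifier outputs are softmax probabilities, batch-independent in eval", {
  spec <- tiny_model_spec(n_classes = 5)
  net <- build_classifier(spec, seed = 2)
  zeros <- lapply(1:3, function(i) array(0, c(8, 32, 32)))
  p <- predict_proba(net, zeros)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  # doubling the batch leaves per-sample outputs identical in eval mode
  set.seed(4)
  xs <- lapply(1:4, function(i) array(stats::runif(8 * 32 * 32), c(8, 32, 32)))
  p1 <- predict_proba(net, xs[1:2])
  p2 <- predict_proba(net, xs)
  expect_equal(p2[1:2, ], p1, tolerance = 1e-12)
  # identical inputs give identical rows
  expect_equal(p2[1, ], predict_proba(net, xs[c(1, 1)])[2, ], tolerance = 1e-12)
})

test_that("stride-2 stages halve every spatio-temporal dimension", {
  spec <- tiny_model_spec()
  tr <- model_summary(spec)
  # last conv of the stride-2 stage sees halved L, H, W relative to stage 1
  s1 <- tr[grepl("stage1", tr$layer) & tr$kind == "conv", ][1, ]
  s2 <- tr[grepl("stage2", tr$layer) & tr$kind == "conv", ]
  s2last <- s2[nrow(s2), ]
  expect_equal(s2last$out_l, ceiling(s1$out_l / 2))
  expect_equal(s2last$out_h, s1$out_h / 2)
  expect_equal(s2last$out_w, s1$out_w / 2)
})

test_that("projection shortcuts appear exactly when stride or width changes", {
  count_proj <- function(spec) {
    tr <- model_summary(spec)
    sum(grepl("proj", tr$layer))
  }
  same <- model_spec(input_shape = c(4, 16, 16, 1), n_classes = 2,
                     stem = list(filters = 8, kernel = c(1, 3, 3), stride = c(1, 1, 1),
                                 pool_kernel = c(1, 2, 2), pool_stride = c(1, 2, 2)),
                     stages = list(list(blocks = 2, filters = 8, stride = 1)))
  expect_equal(count_proj(same), 0)
  widen <- model_spec(input_shape = c(4, 16, 16, 1), n_classes = 2,
                      stem = list(filters = 8, kernel = c(1, 3, 3), stride = c(1, 1, 1),
                                  pool_kernel = c(1, 2, 2), pool_stride = c(1, 2, 2)),
                      stages = list(list(blocks = 2, filters = 16, stride = 1)))
  expect_equal(count_proj(widen), 1)  # only the first (width-changing) block
  strided <- model_spec(input_shape = c(4, 16, 16, 1), n_classes = 2,
                        stem = list(filters = 8, kernel = c(1, 3, 3), stride = c(1, 1, 1),
                                    pool_kernel = c(1, 2, 2), pool_stride = c(1, 2, 2)),
                        stages = list(list(blocks = 2, filters = 8, stride = 2)))
  expect_equal(count_proj(strided), 1)
})

test_that("embedder outputs unit-norm vectors with width equal to the last stage", {
  spec <- tiny_model_spec(n_classes = 10, head = "l2_embedding")
  net <- build_embedder(spec, seed = 6)
  set.seed(8)
  xs <- lapply(1:4, function(i) array(stats::runif(8 * 32 * 32), c(8, 32, 32)))
  e <- predict_embedding(net, xs)
  expect_equal(ncol(e), spec$stages[[length(spec$stages)]]$filters)
  expect_equal(sqrt(rowSums(e^2)), rep(1, 4), tolerance = 1e-5)
  # identical inputs -> identical embeddings
  e2 <- predict_embedding(net, xs[c(2, 2)])
  expect_equal(e2[1, ], e2[2, ], tolerance = 1e-12)
  # the default embedder inherits the 288-wide pooled features
  expect_equal(count_parameters(default_model_spec(), head = "l2_embedding") -
                 count_parameters(default_model_spec()) ,
               (288 * 288 + 288) - (288 * 10 + 10))
})

test_that("the 2D first-frame baseline is the standard 18-layer design", {
  spec <- baseline_2d_spec(n_classes = 10, size = 128)
  expect_equal(round(count_parameters(spec) / 1e6, 1), 11.2)
  net <- build_2d_baseline(n_classes = 10, size = 32, base_filters = 8, seed = 1)
  expect_identical(network_parameters(net),
                   as.integer(count_parameters(baseline_2d_spec(10, 32, 8))))
  p <- predict_proba(net, list(array(stats::runif(32 * 32), c(1, 32, 32))))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("invalid specs fail with informative errors", {
  expect_error(model_spec(input_shape = c(12, 128, 128, 3)), "single-channel")
  expect_error(model_spec(stages = list(list(blocks = 1, filters = 0, stride = 1))),
               "stage 1")
  expect_error(model_spec(stages = list(list(blocks = 1, filters = 8, stride = 3))),
               "stride")
})

test_that("matched_3d mid-channels reproduce the full 3D convolution cost", {
  # with the matched policy a factorised pair has (approximately, floor-rounded)
  # the parameter count of one 3x3x3 convolution
  cin <- 16; cout <- 32
  mid <- devevent:::mid_channels("matched_3d", cin, cout)
  expect_equal(mid, floor(27 * cin * cout / (9 * cin + 3 * cout)))
  pair <- 9 * cin * mid + 3 * mid * cout
  expect_lt(abs(pair - 27 * cin * cout) / (27 * cin * cout), 0.05)
})
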