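# Architecture specification and builders for the (2+1)D residual video
# classifier, its metric-embedding variant, and the 2D single-frame baseline.
#
# The default configuration is a four-stage residual network in which each
# block factorises 3D convolution into a 2D spatial convolution (1x3x3)
# followed by a 1D temporal convolution (3x1x1), each followed by batch
# normalisation and ReLU. A stage with stride 2 halves the temporal and both
# spatial dimensions; a 1x1x1 projection shortcut is inserted whenever the
# stride or the channel width changes. Classification uses 3D global average
# pooling and a fully connected softmax layer.

EVENT_LEVELS <- c("Pre-Gastrula", "Gastrula", "Trochophore", "Veliger",
                  "Eye spots", "Heart beat", "Crawling", "Radula",
                  "Hatch", "Dead")

#' Event taxonomy
#'
#' The ten developmental event classes in canonical order (integer codes
#' 0 to 9): Pre-Gastrula, Gastrula, Trochophore, Veliger, Eye spots,
#' Heart beat, Crawling, Radula, Hatch, Dead.
#'
#' @return Character vector of the ten event labels in canonical order.
#' @export
event_levels <- function() EVENT_LEVELS

#' Integer code of an event label
#'
#' @param label Character vector of event labels.
#' @return Integer codes, 0-based, in canonical event order.
#' @export
event_code <- function(label) {
  i <- match(label, EVENT_LEVELS)
  if (anyNA(i)) stop("unknown event label(s): ",
                     paste(unique(label[is.na(i)]), collapse = ", "))
  i - 1L
}

stage_spec <- function(blocks, filters, stride) {
  stopifnot(blocks >= 1, filters > 0, stride %in% c(1, 2))
  list(blocks = as.integer(blocks), filters = as.integer(filters),
       stride = as.integer(stride))
}

#' Construct a model specification
#'
#' @param input_shape Integer vector (L, W, H, C): frames, width, height,
#'   channels. Channels must be 1.
#' @param n_classes Number of output classes (10 for the event taxonomy).
#' @param stem List with `filters`, `kernel`, `stride`, `pool_kernel`,
#'   `pool_stride` (length-3 vectors over l, h, w).
#' @param stages List of stages, each `list(blocks, filters, stride)` with
#'   stride 1 or 2.
#' @param mid_channel_policy Width of the intermediate (spatial-conv output)
#'   channel in each factorised block: `"equal_to_out"` (spatial conv already
#'   maps to the block's output width) or `"matched_3d"` (width chosen so the
#'   factorised pair has the same parameter count as a full 3x3x3 convolution).
#' @param head `"softmax_classifier"` or `"l2_embedding"`.
#' @param block_type `"conv2plus1d"` (factorised spatio-temporal blocks) or
#'   `"conv2d"` (plain spatial blocks; used by the 2D baseline).
#' @return A `devnet_spec` object.
#' @export
model_spec <- function(input_shape = c(12, 128, 128, 1),
                       n_classes = 10,
                       stem = list(filters = 48, kernel = c(1, 3, 3),
                                   stride = c(1, 2, 2),
                                   pool_kernel = c(1, 2, 2),
                                   pool_stride = c(1, 2, 2)),
                       stages = list(stage_spec(2, 40, 1),
                                     stage_spec(2, 80, 2),
                                     stage_spec(2, 160, 2),
                                     stage_spec(2, 288, 2)),
                       mid_channel_policy = c("equal_to_out", "matched_3d"),
                       head = c("softmax_classifier", "l2_embedding"),
                       block_type = c("conv2plus1d", "conv2d")) {
  mid_channel_policy <- match.arg(mid_channel_policy)
  head <- match.arg(head)
  block_type <- match.arg(block_type)
  if (length(input_shape) != 4 || any(input_shape < 1))
    stop("input_shape must be (L, W, H, C) with positive entries")
  if (input_shape[4] != 1)
    stop("only single-channel input is supported (C = 1)")
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (st$filters <= 0) stop("stage ", i, ": filter count must be positive")
    if (!st$stride %in% c(1L, 2L)) stop("stage ", i, ": stride must be 1 or 2")
  }
  structure(list(input_shape = as.integer(input_shape), n_classes = as.integer(n_classes),
                 stem = stem, stages = stages,
                 spatial_kernel = c(1L, 3L, 3L), temporal_kernel = c(3L, 1L, 1L),
                 mid_channel_policy = mid_channel_policy, head = head,
                 block_type = block_type),
            class = "devnet_spec")
}

#' Default model specification
#'
#' The calibrated default architecture: 12x128x128x1 input, stem with 48
#' filters (stride-2 spatial convolution and 1x2x2 max-pool), four stages of
#' two factorised residual blocks with widths 40/80/160/288 and strides
#' 1/2/2/2, global average pooling and a 10-way softmax. This configuration
#' has ~5.2 million trainable parameters and ~3.7 GFLOPs per forward pass.
#'
#' @return A `devnet_spec`.
#' @export
default_model_spec <- function() model_spec()

#' Small specification for CPU-scale experiments
#'
#' @param input_shape Input shape, default 8 frames at 32x32.
#' @param n_classes Number of classes.
#' @param base_filters Width of the first stage (doubled in the second).
#' @param head Network head.
#' @return A `devnet_spec`.
#' @export
tiny_model_spec <- function(input_shape = c(8, 32, 32, 1), n_classes = 10,
                            base_filters = 8,
                            head = c("softmax_classifier", "l2_embedding")) {
  head <- match.arg(head)
  model_spec(input_shape = input_shape, n_classes = n_classes,
             stem = list(filters = base_filters, kernel = c(1, 3, 3),
                         stride = c(1, 1, 1),
                         pool_kernel = c(1, 2, 2), pool_stride = c(1, 2, 2)),
             stages = list(stage_spec(1, base_filters, 1),
                           stage_spec(1, 2 * base_filters, 2)),
             head = head)
}

#' Specification of the 18-layer 2D residual baseline
#'
#' A standard 18-layer 2D residual classifier (7x7 stride-2 stem, 3x3 max-pool,
#' four stages of two plain blocks with widths 64/128/256/512) consuming a
#' single grayscale frame. Used to test the value of temporal information by
#' training on only the first frame of each clip.
#'
#' @param n_classes Number of classes.
#' @param size Spatial input size.
#' @param base_filters First-stage width (64 for the standard baseline).
#' @return A `devnet_spec` with `block_type = "conv2d"` and L = 1.
#' @export
baseline_2d_spec <- function(n_classes = 10, size = 128, base_filters = 64) {
  model_spec(input_shape = c(1, size, size, 1), n_classes = n_classes,
             stem = list(filters = base_filters, kernel = c(1, 7, 7),
                         stride = c(1, 2, 2),
                         pool_kernel = c(1, 3, 3), pool_stride = c(1, 2, 2)),
             stages = list(stage_spec(2, base_filters, 1),
                           stage_spec(2, 2 * base_filters, 2),
                           stage_spec(2, 4 * base_filters, 2),
                           stage_spec(2, 8 * base_filters, 2)),
             block_type = "conv2d")
}

## ---- structural plan ---------------------------------------------------

# Flat structural description shared by the builder and the analytic
# counters, so the built network and the closed-form counts cannot diverge.
pl_conv <- function(name, kernel, stride, cin, cout)
  list(kind = "conv", name = name, kernel = as.integer(kernel),
       stride = as.integer(stride), cin = as.integer(cin), cout = as.integer(cout))
pl_bn <- function(ch) list(kind = "bn", ch = as.integer(ch))
pl_relu <- function() list(kind = "relu")
pl_pool <- function(kernel, stride) list(kind = "maxpool", kernel = as.integer(kernel),
                                         stride = as.integer(stride))
pl_gap <- function() list(kind = "gap")
pl_dense <- function(name, cin, cout) list(kind = "dense", name = name,
                                           cin = as.integer(cin), cout = as.integer(cout))
pl_l2 <- function() list(kind = "l2norm")

mid_channels <- function(policy, cin, cout, t = 3L, d2 = 9L) {
  if (policy == "equal_to_out") return(cout)
  max(1L, as.integer(floor((t * d2 * cin * cout) / (d2 * cin + t * cout))))
}

block_plan <- function(spec, stage_i, block_i, cin, cout, s) {
  nm <- function(x) sprintf("stage%d.block%d.%s", stage_i, block_i, x)
  if (spec$block_type == "conv2d") {
    branch <- list(
      pl_conv(nm("conv1"), c(1, 3, 3), c(1, s, s), cin, cout), pl_bn(cout), pl_relu(),
      pl_conv(nm("conv2"), c(1, 3, 3), c(1, 1, 1), cout, cout), pl_bn(cout))
    shortcut <- if (s != 1 || cin != cout)
      list(pl_conv(nm("proj"), c(1, 1, 1), c(1, s, s), cin, cout), pl_bn(cout))
    list(branch = branch, shortcut = shortcut, post_relu = TRUE)
  } else {
    m1 <- mid_channels(spec$mid_channel_policy, cin, cout)
    m2 <- mid_channels(spec$mid_channel_policy, cout, cout)
    branch <- list(
      pl_conv(nm("spatial1"), spec$spatial_kernel, c(1, s, s), cin, m1),
      pl_bn(m1), pl_relu(),
      pl_conv(nm("temporal1"), spec$temporal_kernel, c(s, 1, 1), m1, cout),
      pl_bn(cout), pl_relu(),
      pl_conv(nm("spatial2"), spec$spatial_kernel, c(1, 1, 1), cout, m2),
      pl_bn(m2), pl_relu(),
      pl_conv(nm("temporal2"), spec$temporal_kernel, c(1, 1, 1), m2, cout),
      pl_bn(cout), pl_relu())
    shortcut <- if (s != 1 || cin != cout)
      list(pl_conv(nm("proj"), c(1, 1, 1), c(s, s, s), cin, cout), pl_bn(cout))
    list(branch = branch, shortcut = shortcut, post_relu = FALSE)
  }
}

# Returns list of elements: either list(kind = "block", ...) or a flat layer.
spec_plan <- function(spec, head = spec$head) {
  st <- spec$stem
  plan <- list(
    pl_conv("stem.conv", st$kernel, st$stride, spec$input_shape[4], st$filters),
    pl_bn(st$filters), pl_relu(),
    pl_pool(st$pool_kernel, st$pool_stride))
  cin <- st$filters
  for (i in seq_along(spec$stages)) {
    sg <- spec$stages[[i]]
    for (b in seq_len(sg$blocks)) {
      s <- if (b == 1) sg$stride else 1L
      bp <- block_plan(spec, i, b, cin, sg$filters, s)
      plan[[length(plan) + 1]] <- c(list(kind = "block"), bp)
      cin <- sg$filters
    }
  }
  plan[[length(plan) + 1]] <- pl_gap()
  if (head == "softmax_classifier") {
    plan[[length(plan) + 1]] <- pl_dense("head.fc", cin, spec$n_classes)
  } else {
    plan[[length(plan) + 1]] <- pl_dense("head.embed", cin, cin)
    plan[[length(plan) + 1]] <- pl_l2()
  }
  plan
}

build_flat <- function(descr) {
  switch(descr$kind,
    conv = layer_conv(descr$kernel, descr$stride, descr$cin, descr$cout),
    bn = layer_bn(descr$ch),
    relu = layer_relu(),
    maxpool = layer_maxpool(descr$kernel, descr$stride),
    gap = layer_gap(),
    dense = layer_dense(descr$cin, descr$cout),
    l2norm = layer_l2norm())
}

build_plan <- function(plan) {
  lapply(plan, function(el) {
    if (el$kind == "block") {
      layer_resblock(branch = lapply(el$branch, build_flat),
                     shortcut = if (!is.null(el$shortcut)) lapply(el$shortcut, build_flat),
                     post_relu = el$post_relu)
    } else build_flat(el)
  })
}

# Analytic trace: per-layer shapes, trainable parameters and conv/dense MACs.
plan_trace <- function(plan, input_shape) {
  L <- input_shape[1]; H <- input_shape[2]; W <- input_shape[3]
  rows <- list()
  add <- function(name, kind, params, macs, L, H, W, C)
    rows[[length(rows) + 1]] <<- data.frame(
      layer = name, kind = kind, params = params, macs = macs,
      out_l = L, out_h = H, out_w = W, out_c = C, stringsAsFactors = FALSE)
  trace_flat <- function(el, L, H, W) {
    switch(el$kind,
      conv = {
        Lo <- ceil_div(L, el$stride[1]); Ho <- ceil_div(H, el$stride[2])
        Wo <- ceil_div(W, el$stride[3])
        K <- prod(el$kernel)
        add(el$name, "conv", K * el$cin * el$cout + el$cout,
            K * el$cin * el$cout * Lo * Ho * Wo, Lo, Ho, Wo, el$cout)
        list(L = Lo, H = Ho, W = Wo, C = el$cout)
      },
      bn = { add("", "bn", 2 * el$ch, 0, L, H, W, el$ch); list(L = L, H = H, W = W, C = el$ch) },
      relu = list(L = L, H = H, W = W, C = NA),
      maxpool = {
        Lo <- ceil_div(L, el$stride[1]); Ho <- ceil_div(H, el$stride[2])
        Wo <- ceil_div(W, el$stride[3])
        add("pool", "maxpool", 0, 0, Lo, Ho, Wo, NA)
        list(L = Lo, H = Ho, W = Wo, C = NA)
      },
      gap = { add("global_pool", "gap", 0, 0, 1, 1, 1, NA); list(L = 1, H = 1, W = 1, C = NA) },
      dense = {
        add(el$name, "dense", el$cin * el$cout + el$cout, el$cin * el$cout, 1, 1, 1, el$cout)
        list(L = 1, H = 1, W = 1, C = el$cout)
      },
      l2norm = list(L = L, H = H, W = W, C = NA))
  }
  cur <- list(L = L, H = H, W = W)
  for (el in plan) {
    if (el$kind == "block") {
      inL <- cur$L; inH <- cur$H; inW <- cur$W
      for (d in el$branch) {
        r <- trace_flat(d, cur$L, cur$H, cur$W)
        cur$L <- r$L; cur$H <- r$H; cur$W <- r$W
      }
      if (!is.null(el$shortcut)) {
        sc <- list(L = inL, H = inH, W = inW)
        for (d in el$shortcut) {
          r <- trace_flat(d, sc$L, sc$H, sc$W)
          sc$L <- r$L; sc$H <- r$H; sc$W <- r$W
        }
        if (!identical(unlist(sc), unlist(cur)))
          stop("residual shapes disagree in block ", el$branch[[1]]$name)
      }
    } else {
      r <- trace_flat(el, cur$L, cur$H, cur$W)
      cur$L <- r$L; cur$H <- r$H; cur$W <- r$W
    }
  }
  do.call(rbind, rows)
}

## ---- public model API --------------------------------------------------

new_devnet <- function(spec, head) {
  net <- new.env(parent = emptyenv())
  net$spec <- spec
  net$head <- head
  net$plan <- spec_plan(spec, head)
  net$layers <- build_plan(net$plan)
  class(net) <- "devnet"
  net
}

#' Build the (2+1)D classifier network
#'
#' @param spec A `devnet_spec` with `head = "softmax_classifier"`.
#' @param seed Integer seed for weight initialisation.
#' @return A `devnet` object mapping (N, L, H, W) input to (N, n_classes)
#'   class probabilities.
#' @export
build_classifier <- function(spec = default_model_spec(), seed = 1L) {
  set.seed(seed)
  new_devnet(spec, "softmax_classifier")
}

#' Build the unit-norm embedding network
#'
#' Same body as the classifier, but the final classification layer is replaced
#' by a linear fully connected layer (with as many neurons as the preceding
#' average-pooling layer) followed by L2 normalisation, for training with
#' triplet loss.
#'
#' @inheritParams build_classifier
#' @return A `devnet` whose outputs have unit Euclidean norm.
#' @export
build_embedder <- function(spec = default_model_spec(), seed = 1L) {
  set.seed(seed)
  new_devnet(spec, "l2_embedding")
}

#' Build the 2D first-frame baseline
#'
#' @param n_classes Number of classes.
#' @param size Spatial input size.
#' @param base_filters First-stage width; 64 gives the standard 18-layer
#'   baseline (~11.2 M parameters at 10 classes).
#' @param seed Seed for weight initialisation.
#' @return A `devnet` consuming a single frame (L = 1).
#' @export
build_2d_baseline <- function(n_classes = 10, size = 128, base_filters = 64, seed = 1L) {
  set.seed(seed)
  new_devnet(baseline_2d_spec(n_classes, size, base_filters), "softmax_classifier")
}

#' Analytic trainable-parameter count
#'
#' Computed layer-by-layer in closed form from the specification (convolution
#' kernels with bias, batch-normalisation scale/shift, dense weights with
#' bias). Equals the parameter count of the built network.
#'
#' @param spec A `devnet_spec`.
#' @param head Network head to count (defaults to the spec's head).
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, head = spec$head) {
  tr <- plan_trace(spec_plan(spec, head), spec$input_shape)
  sum(tr$params)
}

#' Forward-pass floating point operation count
#'
#' Counts convolution and dense-layer operations; batch normalisation and
#' activations are excluded as negligible. By convention one
#' multiply-accumulate is two floating point operations
#' (`ops_per_mac = 2`); set `ops_per_mac = 1` for the MAC-counting convention.
#'
#' @param spec A `devnet_spec`.
#' @param input_shape Input shape (L, W, H, C); defaults to the spec's.
#' @param ops_per_mac Operations counted per multiply-accumulate.
#' @return FLOPs per sample (numeric).
#' @export
count_flops <- function(spec, input_shape = spec$input_shape, ops_per_mac = 2) {
  tr <- plan_trace(spec_plan(spec, spec$head), input_shape)
  ops_per_mac * sum(tr$macs)
}

#' Parameter count of a built network
#'
#' @param net A `devnet`.
#' @return Integer count of trainable parameters.
#' @export
network_parameters <- function(net) n_params_built(net$layers)

#' Layer-by-layer summary table
#'
#' @param spec A `devnet_spec`.
#' @return data.frame with one row per parameterised layer: output shape,
#'   parameters and MACs.
#' @export
model_summary <- function(spec = default_model_spec()) {
  tr <- plan_trace(spec_plan(spec, spec$head), spec$input_shape)
  tr$gflops <- 2 * tr$macs / 1e9
  tr
}

#' @export
print.devnet_spec <- function(x, ...) {
  cat("Model spec:", x$block_type, "| input",
      paste(x$input_shape, collapse = "x"), "|", x$n_classes, "classes\n")
  cat("  stem:", x$stem$filters, "filters; stages:",
      paste(vapply(x$stages, function(s)
        sprintf("%dx%d(s%d)", s$blocks, s$filters, s$stride), ""), collapse = ", "),
      "\n")
  cat(sprintf("  parameters: %.2fM; forward: %.2f GFLOPs\n",
              count_parameters(x) / 1e6, count_flops(x) / 1e9))
  invisible(x)
}

#' @export
print.devnet <- function(x, ...) {
  cat("devnet (", x$head, "), ", format(network_parameters(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# Assemble a list of (L,H,W) arrays (values in [0,1]) into an engine activation.
clips_to_act <- function(clips) {
  n <- length(clips)
  d <- dim(clips[[1]])
  arr <- array(0, c(n, d))
  for (i in seq_len(n)) arr[i, , , ] <- clips[[i]]
  act_new(matrix(as.vector(arr), ncol = 1L), n, d)
}

net_forward <- function(net, act, training = FALSE) {
  for (ly in net$layers) act <- ly_forward(ly, act, training)
  act$a
}

#' Class probabilities for a batch of clips
#'
#' @param net A classifier `devnet`.
#' @param clips List of (L, H, W) arrays with values in [0, 1], already
#'   standardised and subsampled to the network's input shape.
#' @param batch_size Clips per forward pass.
#' @return N x n_classes matrix of softmax probabilities (rows sum to 1).
#' @export
predict_proba <- function(net, clips, batch_size = 32L) {
  n <- length(clips)
  out <- NULL
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    z <- net_forward(net, clips_to_act(clips[s:e]), training = FALSE)
    p <- if (net$head == "softmax_classifier") softmax_rows(z) else z
    out <- rbind(out, p)
  }
  colnames(out) <- if (net$head == "softmax_classifier" &&
                       ncol(out) == length(EVENT_LEVELS)) EVENT_LEVELS else NULL
  out
}

#' Embeddings for a batch of clips
#'
#' @param net An embedding `devnet`.
#' @inheritParams predict_proba
#' @return N x D matrix of unit-norm embeddings.
#' @export
predict_embedding <- function(net, clips, batch_size = 32L) {
  n <- length(clips)
  out <- NULL
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    out <- rbind(out, net_forward(net, clips_to_act(clips[s:e]), training = FALSE))
  }
  out
}
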