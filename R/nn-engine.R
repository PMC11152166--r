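# Minimal spatio-temporal network engine.
#
# Activations are stored as a P x C matrix where P = N * L * H * W and rows are
# ordered with the sample index n fastest, then l, h, w (i.e. an array of dim
# c(N, L, H, W) flattened). Convolutions gather neighbour rows through a
# precomputed index map and reduce to a single BLAS matrix multiply; gradients
# are scattered back per kernel offset (injective for a fixed offset, so plain
# indexed addition is safe).

# An activation is list(a = P x C matrix, n = batch size, dims = c(L, H, W))
# or, after global pooling, list(a = N x C matrix, n = N, dims = NULL).
act_new <- function(a, n, dims) list(a = a, n = n, dims = dims)

ceil_div <- function(a, b) as.integer(ceiling(a / b))

# Neighbour index map for 'same'-padded convolution/pooling.
# kernel, stride: length-3 integer vectors over (l, h, w).
# Returns list(idx = P_out x K matrix into the padded input (pad row = P_in+1),
#              out_dims = c(Lo, Ho, Wo)).
conv_index_map <- function(n, dims, kernel, stride) {
  L <- dims[1]; H <- dims[2]; W <- dims[3]
  Lo <- ceil_div(L, stride[1]); Ho <- ceil_div(H, stride[2]); Wo <- ceil_div(W, stride[3])
  off <- function(k) if (k %% 2 == 1) seq_len(k) - (k + 1) / 2 else seq_len(k) - 1
  ol <- off(kernel[1]); oh <- off(kernel[2]); ow <- off(kernel[3])
  cl <- (seq_len(Lo) - 1L) * stride[1] + 1L
  ch <- (seq_len(Ho) - 1L) * stride[2] + 1L
  cw <- (seq_len(Wo) - 1L) * stride[3] + 1L
  P_in <- n * L * H * W
  P_out <- n * Lo * Ho * Wo
  pad <- P_in + 1L
  K <- kernel[1] * kernel[2] * kernel[3]
  idx <- matrix(pad, nrow = P_out, ncol = K)
  nn <- seq_len(n)
  k <- 0L
  for (jw in seq_along(ow)) for (jh in seq_along(oh)) for (jl in seq_along(ol)) {
    k <- k + 1L
    li <- cl + ol[jl]; hi <- ch + oh[jh]; wi <- cw + ow[jw]
    li[li < 1L | li > L] <- NA; hi[hi < 1L | hi > H] <- NA; wi[wi < 1L | wi > W] <- NA
    v <- rep(nn, times = Lo * Ho * Wo) +
      n * rep(rep(li - 1L, each = n), times = Ho * Wo) +
      (n * L) * rep(rep(hi - 1L, each = n * Lo), times = Wo) +
      (n * L * H) * rep(wi - 1L, each = n * Lo * Ho)
    v[is.na(v)] <- pad
    idx[, k] <- v
  }
  list(idx = idx, out_dims = c(Lo, Ho, Wo))
}

.map_cache_get <- function(layer, n, dims, kernel, stride) {
  key <- paste(c(n, dims), collapse = "x")
  m <- layer$map_cache[[key]]
  if (is.null(m)) {
    m <- conv_index_map(n, dims, kernel, stride)
    layer$map_cache[[key]] <- m
  }
  m
}

pad_rows <- function(a, value = 0) {
  ap <- matrix(value, nrow = nrow(a) + 1L, ncol = ncol(a))
  ap[seq_len(nrow(a)), ] <- a
  ap
}

## ---- layer constructors ------------------------------------------------

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$map_cache <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- "nn_layer"
  e
}

layer_conv <- function(kernel, stride, in_ch, out_ch) {
  K <- prod(kernel)
  ly <- new_layer("conv", kernel = as.integer(kernel), stride = as.integer(stride),
                  in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
  ly$W <- matrix(stats::rnorm(K * in_ch * out_ch, sd = sqrt(2 / (K * in_ch))),
                 nrow = K * in_ch, ncol = out_ch)
  ly$b <- numeric(out_ch)
  ly$param_names <- c("W", "b")
  ly
}

layer_bn <- function(ch, momentum = 0.9, eps = 1e-5) {
  ly <- new_layer("bn", ch = as.integer(ch), momentum = momentum, eps = eps)
  ly$gamma <- rep(1, ch); ly$beta <- rep(0, ch)
  ly$run_mean <- rep(0, ch); ly$run_var <- rep(1, ch)
  ly$param_names <- c("gamma", "beta")
  ly$collect <- FALSE
  ly
}

layer_relu <- function() new_layer("relu", param_names = character(0))

layer_maxpool <- function(kernel, stride) {
  new_layer("maxpool", kernel = as.integer(kernel), stride = as.integer(stride),
            param_names = character(0))
}

layer_gap <- function() new_layer("gap", param_names = character(0))

layer_dense <- function(in_ch, out_ch) {
  ly <- new_layer("dense", in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
  ly$W <- matrix(stats::rnorm(in_ch * out_ch, sd = sqrt(2 / in_ch)),
                 nrow = in_ch, ncol = out_ch)
  ly$b <- numeric(out_ch)
  ly$param_names <- c("W", "b")
  ly
}

layer_l2norm <- function(eps = 1e-12) new_layer("l2norm", eps = eps, param_names = character(0))

# Residual block: y = branch(x) + shortcut(x), with optional ReLU after the add.
layer_resblock <- function(branch, shortcut = NULL, post_relu = FALSE) {
  new_layer("resblock", branch = branch, shortcut = shortcut,
            post_relu = post_relu, param_names = character(0))
}

## ---- forward / backward ------------------------------------------------

ly_forward <- function(ly, act, training = FALSE) {
  switch(ly$type,
    conv = {
      m <- .map_cache_get(ly, act$n, act$dims, ly$kernel, ly$stride)
      K <- prod(ly$kernel); C <- ncol(act$a); P <- nrow(m$idx)
      xp <- pad_rows(act$a)
      X <- xp[as.vector(m$idx), , drop = FALSE]
      dim(X) <- c(P, K * C)
      y <- X %*% ly$W
      y <- y + rep(ly$b, each = P)
      if (training) { ly$in_act <- act; ly$map <- m }
      act_new(y, act$n, m$out_dims)
    },
    bn = {
      x <- act$a; P <- nrow(x)
      if (training) {
        mu <- colMeans(x)
        xc <- x - rep(mu, each = P)
        v <- colMeans(xc * xc)
        invstd <- 1 / sqrt(v + ly$eps)
        xh <- xc * rep(invstd, each = P)
        if (ly$collect) {
          ly$acc_n <- ly$acc_n + P
          ly$acc_sum <- ly$acc_sum + mu * P
          ly$acc_sumsq <- ly$acc_sumsq + (v + mu^2) * P
        } else {
          ly$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
          ly$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * v
        }
        ly$xh <- xh; ly$invstd <- invstd
      } else {
        invstd <- 1 / sqrt(ly$run_var + ly$eps)
        xh <- (x - rep(ly$run_mean, each = P)) * rep(invstd, each = P)
      }
      y <- xh * rep(ly$gamma, each = P) + rep(ly$beta, each = P)
      act_new(y, act$n, act$dims)
    },
    relu = {
      y <- act$a
      y[y < 0] <- 0
      if (training) ly$mask <- act$a > 0
      act_new(y, act$n, act$dims)
    },
    maxpool = {
      m <- .map_cache_get(ly, act$n, act$dims, ly$kernel, ly$stride)
      K <- ncol(m$idx); P <- nrow(m$idx); C <- ncol(act$a)
      xp <- pad_rows(act$a, value = -Inf)
      y <- matrix(-Inf, P, C)
      arg <- matrix(1L, P, C)
      for (k in seq_len(K)) {
        g <- xp[m$idx[, k], , drop = FALSE]
        wh <- g > y
        if (any(wh)) { y[wh] <- g[wh]; arg[wh] <- k }
      }
      if (training) { ly$arg <- arg; ly$map <- m; ly$in_rows <- nrow(act$a) }
      act_new(y, act$n, m$out_dims)
    },
    gap = {
      P <- nrow(act$a); n <- act$n; per <- P %/% n
      grp <- rep_len(seq_len(n), P)
      y <- rowsum(act$a, grp, reorder = TRUE) / per
      rownames(y) <- NULL
      if (training) { ly$per <- per; ly$in_P <- P }
      act_new(y, n, NULL)
    },
    dense = {
      y <- act$a %*% ly$W
      y <- y + rep(ly$b, each = nrow(y))
      if (training) ly$in_act <- act
      act_new(y, act$n, NULL)
    },
    l2norm = {
      nrm <- sqrt(rowSums(act$a^2) + ly$eps)
      y <- act$a / nrm
      if (training) { ly$y <- y; ly$nrm <- nrm }
      act_new(y, act$n, NULL)
    },
    resblock = {
      if (training) ly$in_act <- act
      b <- act
      for (l in ly$branch) b <- ly_forward(l, b, training)
      s <- act
      if (!is.null(ly$shortcut)) for (l in ly$shortcut) s <- ly_forward(l, s, training)
      y <- b$a + s$a
      if (ly$post_relu) {
        if (training) ly$post_mask <- y > 0
        y[y < 0] <- 0
      }
      act_new(y, act$n, b$dims)
    },
    stop("unknown layer type: ", ly$type)
  )
}

ly_backward <- function(ly, dy) {
  switch(ly$type,
    conv = {
      m <- ly$map; act <- ly$in_act
      K <- prod(ly$kernel); C <- ncol(act$a); P <- nrow(m$idx)
      xp <- pad_rows(act$a)
      X <- xp[as.vector(m$idx), , drop = FALSE]
      dim(X) <- c(P, K * C)
      ly$gW <- crossprod(X, dy)
      ly$gb <- colSums(dy)
      dX <- tcrossprod(dy, ly$W)            # P x (K*C)
      P_in <- nrow(act$a)
      da <- matrix(0, P_in, C)
      for (k in seq_len(K)) {
        rows <- m$idx[, k]
        sel <- rows <= P_in
        cols <- k + (seq_len(C) - 1L) * K
        if (all(sel)) {
          da[rows, ] <- da[rows, ] + dX[, cols, drop = FALSE]
        } else {
          da[rows[sel], ] <- da[rows[sel], ] + dX[sel, cols, drop = FALSE]
        }
      }
      ly$in_act <- NULL; ly$map <- NULL
      da
    },
    bn = {
      xh <- ly$xh; invstd <- ly$invstd; P <- nrow(xh)
      dxh <- dy * rep(ly$gamma, each = P)
      ly$ggamma <- colSums(dy * xh)
      ly$gbeta <- colSums(dy)
      s1 <- colMeans(dxh)
      s2 <- colMeans(dxh * xh)
      dx <- (dxh - rep(s1, each = P) - xh * rep(s2, each = P)) * rep(invstd, each = P)
      ly$xh <- NULL
      dx
    },
    relu = {
      dx <- dy
      dx[!ly$mask] <- 0
      ly$mask <- NULL
      dx
    },
    maxpool = {
      m <- ly$map; arg <- ly$arg
      P_in <- ly$in_rows; K <- ncol(m$idx); C <- ncol(dy)
      da <- matrix(0, P_in, C)
      for (k in seq_len(K)) {
        contrib <- dy * (arg == k)
        rows <- m$idx[, k]
        sel <- rows <= P_in
        da[rows[sel], ] <- da[rows[sel], ] + contrib[sel, , drop = FALSE]
      }
      ly$arg <- NULL; ly$map <- NULL
      da
    },
    gap = {
      n <- nrow(dy)
      dy[rep_len(seq_len(n), ly$in_P), , drop = FALSE] / ly$per
    },
    dense = {
      ly$gW <- crossprod(ly$in_act$a, dy)
      ly$gb <- colSums(dy)
      dx <- tcrossprod(dy, ly$W)
      ly$in_act <- NULL
      dx
    },
    l2norm = {
      y <- ly$y
      dx <- (dy - y * rowSums(dy * y)) / ly$nrm
      ly$y <- NULL
      dx
    },
    resblock = {
      if (ly$post_relu) {
        dy[!ly$post_mask] <- 0
        ly$post_mask <- NULL
      }
      d <- dy
      for (l in rev(ly$branch)) d <- ly_backward(l, d)
      if (!is.null(ly$shortcut)) {
        ds <- dy
        for (l in rev(ly$shortcut)) ds <- ly_backward(l, ds)
        d <- d + ds
      } else {
        d <- d + dy
      }
      ly$in_act <- NULL
      d
    },
    stop("unknown layer type: ", ly$type)
  )
}

## ---- parameter walking and Adam ---------------------------------------

walk_layers <- function(layers, fn) {
  for (ly in layers) {
    fn(ly)
    if (ly$type == "resblock") {
      walk_layers(ly$branch, fn)
      if (!is.null(ly$shortcut)) walk_layers(ly$shortcut, fn)
    }
  }
  invisible(NULL)
}

collect_param_layers <- function(layers) {
  out <- list()
  walk_layers(layers, function(ly) {
    if (length(ly$param_names) > 0) out[[length(out) + 1]] <<- ly
  })
  out
}

n_params_built <- function(layers) {
  tot <- 0
  walk_layers(layers, function(ly) {
    for (nm in ly$param_names) tot <<- tot + length(get(nm, envir = ly))
  })
  as.integer(tot)
}

adam_init <- function(layers) {
  walk_layers(layers, function(ly) {
    if (length(ly$param_names) == 0) return(invisible(NULL))
    ly$adam_m <- lapply(ly$param_names, function(nm) {
      p <- get(nm, envir = ly); p[] <- 0; p
    })
    ly$adam_v <- ly$adam_m
    names(ly$adam_m) <- names(ly$adam_v) <- ly$param_names
  })
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  walk_layers(layers, function(ly) {
    for (nm in ly$param_names) {
      g <- switch(nm,
                  W = ly$gW, b = ly$gb, gamma = ly$ggamma, beta = ly$gbeta)
      if (is.null(g)) next
      m <- beta1 * ly$adam_m[[nm]] + (1 - beta1) * g
      v <- beta2 * ly$adam_v[[nm]] + (1 - beta2) * g * g
      ly$adam_m[[nm]] <- m
      ly$adam_v[[nm]] <- v
      p <- get(nm, envir = ly)
      assign(nm, p - lr * (m / bc1) / (sqrt(v / bc2) + eps), envir = ly)
    }
  })
}

zero_grads <- function(layers) {
  walk_layers(layers, function(ly) {
    ly$gW <- NULL; ly$gb <- NULL; ly$ggamma <- NULL; ly$gbeta <- NULL
  })
}

## ---- losses ------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Sparse categorical cross-entropy. labels: integer codes 0-based.
loss_softmax_xent <- function(logits, labels0) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  ix <- cbind(seq_len(n), labels0 + 1L)
  loss <- -mean(log(pmax(p[ix], 1e-12)))
  d <- p
  d[ix] <- d[ix] - 1
  list(loss = loss, grad = d / n)
}

# Triplet loss with semi-hard negative mining (batch-wise), Euclidean distance.
# For each anchor-positive pair, the negative is the closest one farther than
# the positive but within the margin; if none exists, the hardest (closest)
# negative is used. Mining is treated as constant under differentiation.
loss_triplet_semihard <- function(emb, labels0, margin = 1.0) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(emb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2 + 1e-16)
  same <- outer(labels0, labels0, "==")
  loss <- 0
  grad <- matrix(0, n, ncol(emb))
  n_trip <- 0L
  for (a in seq_len(n)) {
    pos <- which(same[a, ] & seq_len(n) != a)
    neg <- which(!same[a, ])
    if (length(pos) == 0 || length(neg) == 0) next
    for (p in pos) {
      dap <- d[a, p]
      dn <- d[a, neg]
      semi <- neg[dn > dap & dn < dap + margin]
      nsel <- if (length(semi) > 0) semi[which.min(d[a, semi])] else neg[which.min(dn)]
      l <- dap - d[a, nsel] + margin
      if (l > 0) {
        loss <- loss + l
        # d/demb of ||a-p|| - ||a-n||
        uap <- (emb[a, ] - emb[p, ]) / max(dap, 1e-8)
        uan <- (emb[a, ] - emb[nsel, ]) / max(d[a, nsel], 1e-8)
        grad[a, ] <- grad[a, ] + uap - uan
        grad[p, ] <- grad[p, ] - uap
        grad[nsel, ] <- grad[nsel, ] + uan
      }
      n_trip <- n_trip + 1L
    }
  }
  if (n_trip == 0L) return(list(loss = NA_real_, grad = NULL, n_triplets = 0L))
  list(loss = loss / n_trip, grad = grad / n_trip, n_triplets = n_trip)
}
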