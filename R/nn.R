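# A small, self-contained neural-network engine for the residual window
# classifier. Convolution is im2col + GEMM; gradients are hand-derived and
# mirrored against the forward pass. Everything runs on plain R doubles and
# the base RNG stream, so fixed seeds give bit-identical training runs.
#
# Feature maps are arrays of dim (H, W, C, B). Conv weights are matrices of
# dim (C_out, KH*KW*C_in); the row-block order of the im2col matrix is
# kernel offset fastest, then input channel.

.nn_idx_cache <- new.env(parent = emptyenv())

# Gather-index matrix mapping a padded (Hp, Wp, C, B) array to the im2col
# matrix of dim (KH*KW*C) x (OH*OW*B). Cached per geometry.
.im2col_idx <- function(Hp, Wp, C, B, k, stride, OH, OW) {
  key <- paste(Hp, Wp, C, B, k, stride, OH, OW, sep = "_")
  hit <- .nn_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  kk <- k * k
  # spatial index for one channel, one image: rows kernel offsets (kh fastest),
  # cols output positions (oh fastest)
  kh <- rep(seq_len(k), k); kw <- rep(seq_len(k), each = k)
  oh <- rep(seq_len(OH), OW); ow <- rep(seq_len(OW), each = OH)
  ih <- outer(kh, (oh - 1L) * stride, `+`)          # kk x OH*OW
  iw <- outer(kw, (ow - 1L) * stride, `+`)
  M <- ih + (iw - 1L) * Hp                          # linear idx in Hp x Wp
  # expand over channels (rows) and batch (cols)
  rows <- M[rep(seq_len(kk), C), , drop = FALSE] +
    rep((seq_len(C) - 1L) * Hp * Wp, each = kk)
  boff <- rep((seq_len(B) - 1L) * (Hp * Wp * C), each = OH * OW)
  full <- sweep(rows[, rep(seq_len(OH * OW), B), drop = FALSE], 2, boff, `+`)
  storage.mode(full) <- "integer"
  # per-kernel-offset index vectors for the col2im scatter in the backward
  # pass (for a fixed offset, all target positions are distinct)
  scatter <- lapply(seq_len(kk), function(o) {
    as.vector(full[o + (seq_len(C) - 1L) * kk, , drop = FALSE])
  })
  out <- list(idx = full, scatter = scatter, kk = kk, C = C)
  .nn_idx_cache[[key]] <- out
  out
}

.pad_hw <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

.unpad_hw <- function(x, pad, H, W) {
  if (pad == 0) return(x)
  x[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
}

.conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# Forward convolution. Returns out (OH,OW,Cout,B) and a cache for backward.
.conv_fwd <- function(x, W, b, k, stride, pad) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  OH <- .conv_out_dim(H, k, stride, pad)
  OW <- .conv_out_dim(Wd, k, stride, pad)
  xp <- .pad_hw(x, pad)
  dp <- dim(xp)
  ix <- .im2col_idx(dp[1], dp[2], C, B, k, stride, OH, OW)
  cols <- xp[ix$idx]
  dim(cols) <- dim(ix$idx)
  out_mat <- W %*% cols + b                         # Cout x (OH*OW*B)
  out <- aperm(array(out_mat, c(nrow(W), OH, OW, B)), c(2, 3, 1, 4))
  list(out = out,
       cache = list(cols = cols, ix = ix, dims_pad = dp,
                    H = H, W = Wd, C = C, B = B, OH = OH, OW = OW,
                    k = k, stride = stride, pad = pad))
}

# Backward convolution: dout (OH,OW,Cout,B) -> gradients and dx.
.conv_bwd <- function(dout, W, cache, need_dx = TRUE) {
  cc <- cache
  dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = nrow(W))
  dW <- tcrossprod(dmat, cc$cols)
  db <- rowSums(dmat)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(W, dmat)
    # col2im scatter-add, one kernel offset at a time: for a fixed offset
    # the padded-input positions hit by distinct output positions (and
    # channels/batches) are distinct, so a plain indexed add suffices.
    dxp_vec <- numeric(prod(cc$dims_pad))
    kk <- cc$ix$kk
    C <- cc$ix$C
    for (o in seq_len(kk)) {
      iv <- cc$ix$scatter[[o]]
      dxp_vec[iv] <- dxp_vec[iv] +
        as.vector(dcols[o + (seq_len(C) - 1L) * kk, , drop = FALSE])
    }
    dxp <- array(dxp_vec, cc$dims_pad)
    dx <- .unpad_hw(dxp, cc$pad, cc$H, cc$W)
  }
  list(dW = dW, db = db, dx = dx)
}

.relu_fwd <- function(x) {
  out <- x; out[out < 0] <- 0
  list(out = out, cache = x > 0)
}
.relu_bwd <- function(dout, cache) dout * cache

# Inverted dropout; mask drawn from the ambient RNG stream.
.dropout_fwd <- function(x, rate, active) {
  if (!active || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}
.dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---------------------------------------------------------------------------
# Network layout construction

# Resolve the conv/block layout for a backbone config. Each conv entry:
# list(name, cin, cout, k, stride, pad). Blocks know their shortcut type.
.nn_layout <- function(cfg) {
  stages <- cfg$stages
  layout <- list(stem = list(name = "stem", cin = cfg$in_channels,
                             cout = cfg$stem_channels, k = cfg$stem_kernel,
                             stride = cfg$stem_stride,
                             pad = (cfg$stem_kernel - 1L) %/% 2L))
  cin <- cfg$stem_channels
  blocks <- list()
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    cout <- st$channels
    expansion <- if (identical(cfg$block_type, "bottleneck")) 4L else 1L
    for (b in seq_len(st$blocks)) {
      stride <- if (b == 1L) st$stride else 1L
      nm <- sprintf("s%d.b%d", s, b)
      out_ch <- cout * expansion
      if (identical(cfg$block_type, "bottleneck")) {
        convs <- list(
          list(name = paste0(nm, ".conv1"), cin = cin, cout = cout,
               k = 1L, stride = 1L, pad = 0L),
          list(name = paste0(nm, ".conv2"), cin = cout, cout = cout,
               k = 3L, stride = stride, pad = 1L),
          list(name = paste0(nm, ".conv3"), cin = cout, cout = out_ch,
               k = 1L, stride = 1L, pad = 0L))
      } else {
        convs <- list(
          list(name = paste0(nm, ".conv1"), cin = cin, cout = cout,
               k = 3L, stride = stride, pad = 1L),
          list(name = paste0(nm, ".conv2"), cin = cout, cout = out_ch,
               k = 3L, stride = 1L, pad = 1L))
      }
      proj <- NULL
      if (stride != 1L || cin != out_ch) {
        proj <- list(name = paste0(nm, ".proj"), cin = cin, cout = out_ch,
                     k = 1L, stride = stride, pad = 0L)
      }
      blocks[[nm]] <- list(convs = convs, proj = proj, name = nm)
      cin <- out_ch
    }
  }
  layout$blocks <- blocks
  layout$feat_channels <- cin
  layout
}

# He-initialised parameter list (flat, named) for a layout.
.nn_init <- function(layout) {
  params <- list()
  add_conv <- function(spec) {
    fan_in <- spec$k * spec$k * spec$cin
    params[[paste0(spec$name, ".W")]] <<-
      matrix(stats::rnorm(spec$cout * fan_in, sd = sqrt(2 / fan_in)),
             nrow = spec$cout)
    params[[paste0(spec$name, ".b")]] <<- numeric(spec$cout)
  }
  add_conv(layout$stem)
  for (blk in layout$blocks) {
    for (cv in blk$convs) add_conv(cv)
    if (!is.null(blk$proj)) add_conv(blk$proj)
  }
  C <- layout$feat_channels
  params[["head.W"]] <- matrix(stats::rnorm(C, sd = sqrt(1 / C)), nrow = 1)
  params[["head.b"]] <- 0
  params
}

# ---------------------------------------------------------------------------
# Forward / backward through the whole network

# x: (H, W, C_in, B). Returns logits (length B) and, if `grad`, a tape.
.nn_forward <- function(params, layout, cfg, x, dropout_active = FALSE,
                        grad = FALSE) {
  tape <- list()
  run_conv <- function(spec, x) {
    r <- .conv_fwd(x, params[[paste0(spec$name, ".W")]],
                   params[[paste0(spec$name, ".b")]],
                   spec$k, spec$stride, spec$pad)
    if (grad) tape[[paste0(spec$name, ".cache")]] <<- r$cache
    r$out
  }
  run_relu <- function(key, x) {
    r <- .relu_fwd(x)
    if (grad) tape[[key]] <<- r$cache
    r$out
  }
  run_drop <- function(key, x) {
    r <- .dropout_fwd(x, cfg$dropout_rate, dropout_active)
    if (grad) tape[[key]] <<- r$cache else if (!is.null(r$cache)) NULL
    r$out
  }

  h <- run_conv(layout$stem, x)
  h <- run_relu("stem.relu", h)
  for (blk in layout$blocks) {
    shortcut <- if (is.null(blk$proj)) h else run_conv(blk$proj, h)
    f <- h
    ncv <- length(blk$convs)
    for (i in seq_len(ncv)) {
      f <- run_conv(blk$convs[[i]], f)
      if (i < ncv) {
        f <- run_relu(paste0(blk$name, ".relu", i), f)
        if (cfg$dropout_in_blocks)
          f <- run_drop(paste0(blk$name, ".drop", i), f)
      }
    }
    h <- f + shortcut
    h <- run_relu(paste0(blk$name, ".relu_out"), h)
    if (cfg$dropout_in_blocks)
      h <- run_drop(paste0(blk$name, ".drop_out"), h)
  }
  d <- dim(h)
  feat <- apply(h, c(3, 4), mean)                    # C x B global avg pool
  if (is.null(dim(feat))) feat <- matrix(feat, ncol = d[4])
  logits <- as.vector(params[["head.W"]] %*% feat + params[["head.b"]])
  if (grad) {
    tape$gap_dims <- d
    tape$feat <- feat
  }
  list(logits = logits, tape = if (grad) tape else NULL)
}

.nn_backward <- function(params, layout, cfg, tape, dlogits) {
  grads <- list()
  B <- length(dlogits)
  dl <- matrix(dlogits, nrow = 1)
  grads[["head.W"]] <- dl %*% t(tape$feat)
  grads[["head.b"]] <- sum(dlogits)
  dfeat <- crossprod(params[["head.W"]], dl)          # C x B
  d <- tape$gap_dims
  dh <- aperm(array(rep(dfeat / (d[1] * d[2]), each = d[1] * d[2]),
                    c(d[1], d[2], d[3], d[4])), c(1, 2, 3, 4))

  back_conv <- function(spec, dout, need_dx = TRUE) {
    r <- .conv_bwd(dout, params[[paste0(spec$name, ".W")]],
                   tape[[paste0(spec$name, ".cache")]], need_dx)
    grads[[paste0(spec$name, ".W")]] <<- r$dW
    grads[[paste0(spec$name, ".b")]] <<- r$db
    r$dx
  }

  for (blk in rev(layout$blocks)) {
    if (cfg$dropout_in_blocks)
      dh <- .dropout_bwd(dh, tape[[paste0(blk$name, ".drop_out")]])
    dh <- .relu_bwd(dh, tape[[paste0(blk$name, ".relu_out")]])
    dshort <- dh
    df <- dh
    ncv <- length(blk$convs)
    for (i in rev(seq_len(ncv))) {
      df <- back_conv(blk$convs[[i]], df)
      if (i > 1) {
        if (cfg$dropout_in_blocks)
          df <- .dropout_bwd(df, tape[[paste0(blk$name, ".drop", i - 1)]])
        df <- .relu_bwd(df, tape[[paste0(blk$name, ".relu", i - 1)]])
      }
    }
    if (is.null(blk$proj)) {
      dh <- df + dshort
    } else {
      dh <- df + back_conv(blk$proj, dshort)
    }
  }
  dh <- .relu_bwd(dh, tape[["stem.relu"]])
  back_conv(layout$stem, dh, need_dx = FALSE)
  grads
}

# ---------------------------------------------------------------------------
# Adam optimiser over a flat parameter list

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Weighted binary cross-entropy on logits; returns loss and dlogits.
.bce_loss <- function(logits, y, w = NULL) {
  p <- .sigmoid(logits)
  eps <- 1e-12
  if (is.null(w)) w <- rep(1, length(y))
  loss <- -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
  dlogits <- w * (p - y) / length(y)
  list(loss = loss, dlogits = dlogits)
}
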