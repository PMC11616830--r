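# The binary Bayesian residual window classifier: a dropout-augmented
# residual CNN over log-mel windows. Keeping the dropout layers active at
# inference and averaging T stochastic forward passes gives the Monte Carlo
# approximation to a Bayesian predictive distribution: the pass mean is the
# predictive probability, the pass standard deviation the uncertainty.

#' Configuration for the residual window classifier
#'
#' @param backbone `"resnet18-lite"` (a width- and depth-reduced basic-block
#'   residual network, the desk-scale default) or `"resnet50"` (bottleneck
#'   blocks, stage layout 3-4-6-3). Both run through the identical code
#'   path; only the layout differs.
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.2).
#'   With rate 0 the model is the plain "Res" baseline.
#' @param dropout_in_blocks Insert dropout after each intra-block activation
#'   of every residual block (default TRUE). FALSE yields a dropout-free
#'   module inventory.
#' @param mc_passes Default number of Monte Carlo forward passes T
#'   (default 20).
#' @param pretrained_weights Optional path to a saved parameter list used to
#'   initialise matching layers. Default `NULL`: He-normal random
#'   initialisation. (The published pipeline initialised from
#'   ImageNet-pretrained weights; no such checkpoint ships with this
#'   package, so random initialisation is the documented, non-canonical
#'   default.)
#' @param in_channels Input channels; spectrograms are tiled to this count
#'   (1 for the lite backbone, 3 for stems expecting RGB-like input).
#' @param lr,epochs,batch_size Optimiser settings (Adam; non-canonical
#'   defaults, the source work does not report its schedule).
#' @param class_weighting Apply inverse-class-frequency weights in the
#'   binary cross-entropy (default TRUE; murmur labels are heavily
#'   imbalanced).
#' @param val_fraction Fraction of *patients* held out inside training for
#'   checkpoint selection and early stopping (default 0.2).
#' @param seed Integer seed controlling initialisation, batching and
#'   dropout masks.
#' @return List of class `bbres_config`.
#' @export
bbres_config <- function(backbone = c("resnet18-lite", "resnet50"),
                         dropout_rate = 0.2, dropout_in_blocks = TRUE,
                         mc_passes = 20L, pretrained_weights = NULL,
                         in_channels = NULL, lr = 1e-3, epochs = 8L,
                         batch_size = 32L, class_weighting = TRUE,
                         val_fraction = 0.2, seed = 1L) {
  backbone <- match.arg(backbone)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (mc_passes < 1) stop("mc_passes must be >= 1")
  arch <- switch(backbone,
    "resnet18-lite" = list(
      in_channels = 1L, stem_channels = 8L, stem_kernel = 7L,
      stem_stride = 4L, block_type = "basic",
      stages = list(list(blocks = 2L, channels = 12L, stride = 2L),
                    list(blocks = 2L, channels = 24L, stride = 2L))),
    "resnet50" = list(
      in_channels = 3L, stem_channels = 64L, stem_kernel = 7L,
      stem_stride = 4L, block_type = "bottleneck",
      stages = list(list(blocks = 3L, channels = 64L, stride = 1L),
                    list(blocks = 4L, channels = 128L, stride = 2L),
                    list(blocks = 6L, channels = 256L, stride = 2L),
                    list(blocks = 3L, channels = 512L, stride = 2L))))
  if (!is.null(in_channels)) arch$in_channels <- as.integer(in_channels)
  structure(c(list(backbone = backbone, dropout_rate = dropout_rate,
                   dropout_in_blocks = isTRUE(dropout_in_blocks),
                   mc_passes = as.integer(mc_passes),
                   pretrained_weights = pretrained_weights,
                   lr = lr, epochs = as.integer(epochs),
                   batch_size = as.integer(batch_size),
                   class_weighting = isTRUE(class_weighting),
                   val_fraction = val_fraction, seed = as.integer(seed)),
              arch),
            class = "bbres_config")
}

#' Build a window classifier from a config
#'
#' @param config A [bbres_config()].
#' @return Object of class `bbres_model`: `config`, `layout`, `params`
#'   (flat named list of weight matrices), `n_params`.
#' @export
build_bbres <- function(config) {
  stopifnot(inherits(config, "bbres_config"))
  layout <- .nn_layout(config)
  set.seed(config$seed)
  params <- .nn_init(layout)
  if (!is.null(config$pretrained_weights)) {
    init <- readRDS(config$pretrained_weights)
    for (nm in intersect(names(init), names(params))) {
      if (all(dim(init[[nm]]) == dim(params[[nm]]))) params[[nm]] <- init[[nm]]
    }
  }
  structure(list(config = config, layout = layout, params = params,
                 n_params = sum(vapply(params, length, 0L)),
                 trained = FALSE),
            class = "bbres_model")
}

#' @export
print.bbres_model <- function(x, ...) {
  cat(sprintf("<bbres_model %s> %d parameters, dropout=%.2f (%s), %s\n",
              x$config$backbone, x$n_params, x$config$dropout_rate,
              if (x$config$dropout_in_blocks) "in blocks" else "none",
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Module inventory of a model, in forward order
#'
#' Lists convolution, activation and dropout sites, so dropout placement is
#' introspectable (e.g. to assert that `dropout_in_blocks = FALSE` removes
#' every in-block dropout module).
#'
#' @param model A `bbres_model`.
#' @return Character vector of module names.
#' @export
bbres_modules <- function(model) {
  cfg <- model$config
  out <- c("stem.conv", "stem.relu")
  for (blk in model$layout$blocks) {
    ncv <- length(blk$convs)
    for (i in seq_len(ncv)) {
      out <- c(out, paste0(blk$name, ".conv", i))
      if (i < ncv) {
        out <- c(out, paste0(blk$name, ".relu", i))
        if (cfg$dropout_in_blocks) out <- c(out, paste0(blk$name, ".drop", i))
      }
    }
    if (!is.null(blk$proj)) out <- c(out, paste0(blk$name, ".proj"))
    out <- c(out, paste0(blk$name, ".relu_out"))
    if (cfg$dropout_in_blocks) out <- c(out, paste0(blk$name, ".drop_out"))
  }
  c(out, "global_avg_pool", "head.dense")
}

# Stack a window_set (or plain image list/array) into the (H, W, C, B)
# input tensor, tiling the single spectrogram channel to cfg$in_channels.
.stack_input <- function(images, idx, in_channels) {
  d <- dim(images)
  x <- images[, , idx, drop = FALSE]
  arr <- array(0, c(d[1], d[2], in_channels, length(idx)))
  for (c in seq_len(in_channels)) arr[, , c, ] <- x
  arr
}

# Deterministic (or single stochastic) forward over all windows, batched.
.forward_probs <- function(model, images, idx = NULL, dropout_active = FALSE,
                           batch_size = NULL) {
  idx <- idx %||% seq_len(dim(images)[3])
  bs <- batch_size %||% model$config$batch_size
  probs <- numeric(length(idx))
  pos <- 1L
  while (pos <= length(idx)) {
    take <- idx[pos:min(pos + bs - 1L, length(idx))]
    x <- .stack_input(images, take, model$config$in_channels)
    fw <- .nn_forward(model$params, model$layout, model$config, x,
                      dropout_active = dropout_active, grad = FALSE)
    probs[pos:(pos + length(take) - 1L)] <- .sigmoid(fw$logits)
    pos <- pos + length(take)
  }
  probs
}

#' Train the window classifier
#'
#' Supervised training on weakly labelled windows (every window inherits its
#' patient's binary label). A patient-grouped validation slice (stratified
#' by patient label) drives checkpoint selection on validation loss; the
#' split is checked for patient leakage and the training slice for both
#' classes being present.
#'
#' @param model An untrained `bbres_model` from [build_bbres()].
#' @param window_set A `window_set` from [preprocess_catalog()].
#' @param val_patients Optional explicit character vector of validation
#'   patient ids; default: seeded stratified draw of `val_fraction` of
#'   patients.
#' @param seed RNG seed for batching/dropout (default the config seed).
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `history` (data frame of epoch, train
#'   loss, validation loss) and `val_patients` attached.
#' @export
train_bbres <- function(model, window_set, val_patients = NULL, seed = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "bbres_model"),
            inherits(window_set, "window_set"))
  cfg <- model$config
  meta <- window_set$meta
  images <- window_set$images
  set.seed(seed %||% cfg$seed)

  pat_label <- tapply(meta$label, meta$patient_id, function(l) l[1])
  pats <- names(pat_label)
  if (is.null(val_patients)) {
    val_patients <- unlist(lapply(split(pats, pat_label[pats]), function(g) {
      n_val <- max(1L, round(length(g) * cfg$val_fraction))
      sample(g, min(n_val, length(g)))
    }), use.names = FALSE)
  }
  train_patients <- setdiff(pats, val_patients)
  if (length(intersect(train_patients, val_patients)) > 0)
    stop("patient leakage between train and validation slices")
  tr_idx <- which(meta$patient_id %in% train_patients)
  va_idx <- which(meta$patient_id %in% val_patients)
  y_tr <- meta$label[tr_idx]
  if (length(unique(y_tr)) < 2)
    stop("training set contains a single class; cannot train")

  w_class <- c(1, 1)
  if (cfg$class_weighting) {
    frac <- mean(y_tr)
    w_class <- c(1 / (2 * (1 - frac)), 1 / (2 * frac))
  }

  adam <- .adam_init(model$params)
  params <- model$params
  best <- list(loss = Inf, params = params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; n_batches <- 0L
    pos <- 1L
    while (pos <= length(ord)) {
      take <- ord[pos:min(pos + cfg$batch_size - 1L, length(ord))]
      x <- .stack_input(images, take, cfg$in_channels)
      y <- meta$label[take]
      fw <- .nn_forward(params, model$layout, cfg, x,
                        dropout_active = TRUE, grad = TRUE)
      ls <- .bce_loss(fw$logits, y, w = w_class[y + 1L])
      grads <- .nn_backward(params, model$layout, cfg, fw$tape, ls$dlogits)
      upd <- .adam_step(params, grads, adam, lr = cfg$lr)
      params <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + ls$loss; n_batches <- n_batches + 1L
      pos <- pos + cfg$batch_size
    }
    model$params <- params
    val_probs <- .forward_probs(model, images, va_idx, dropout_active = FALSE)
    y_va <- meta$label[va_idx]
    vl <- .bce_loss(log(pmax(val_probs, 1e-12) / pmax(1 - val_probs, 1e-12)),
                    y_va, w = w_class[y_va + 1L])$loss
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n_batches,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.4f  val %.4f", ep,
                      ep_loss / n_batches, vl))
    if (vl < best$loss) best <- list(loss = vl, params = params)
  }

  model$params <- best$params
  model$trained <- TRUE
  model$history <- hist
  model$val_patients <- sort(val_patients)
  model
}

#' Monte Carlo dropout prediction for spectrogram windows
#'
#' Runs `T` stochastic forward passes with dropout active and returns the
#' per-window mean and standard deviation of the positive-class
#' probability. With dropout disabled (rate 0, `dropout_in_blocks = FALSE`,
#' or `mc_dropout = FALSE`) a single deterministic pass is made and the
#' standard deviation is exactly 0; likewise `T = 1` has zero spread by
#' definition (the SD uses the 1/T population form).
#'
#' @param model A trained `bbres_model`.
#' @param windows A `window_set`, or a 3-d array `n_mels x n_frames x n`.
#' @param T Number of MC passes (default config `mc_passes`).
#' @param mc_dropout Keep dropout active at inference (default TRUE).
#' @param seed Optional seed for the dropout masks.
#' @return Data frame with `p_mean`, `p_std`, and provenance columns when a
#'   `window_set` was given.
#' @export
predict_window_mc <- function(model, windows, T = NULL, mc_dropout = TRUE,
                              seed = NULL) {
  stopifnot(inherits(model, "bbres_model"))
  T <- as.integer(T %||% model$config$mc_passes)
  if (T < 1) stop("T must be >= 1")
  images <- if (inherits(windows, "window_set")) windows$images else windows
  if (length(dim(images)) == 2) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[3]
  stochastic <- isTRUE(mc_dropout) && model$config$dropout_rate > 0 &&
    model$config$dropout_in_blocks
  if (!is.null(seed)) set.seed(seed)
  if (!stochastic || T == 1L) {
    p <- .forward_probs(model, images, dropout_active = stochastic)
    out <- data.frame(p_mean = p, p_std = rep(0, n))
  } else {
    acc <- matrix(0, T, n)
    for (t in seq_len(T))
      acc[t, ] <- .forward_probs(model, images, dropout_active = TRUE)
    out <- data.frame(p_mean = colMeans(acc),
                      p_std = sqrt(pmax(colMeans(acc^2) - colMeans(acc)^2, 0)))
  }
  if (inherits(windows, "window_set")) out <- cbind(windows$meta, out)
  out
}

#' Save / load a model checkpoint (config and seed embedded)
#' @param model A `bbres_model`.
#' @param path Destination file.
#' @return `path` invisibly; `load_bbres` returns the model.
#' @export
save_bbres <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_bbres
#' @export
load_bbres <- function(path) readRDS(path)
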