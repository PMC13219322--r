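# Objective and optimization protocol: composite pixel + structural +
# perceptual loss with a two-phase weight schedule, cosine-annealed AdamW
# (warm restarts by default), and a scaled-down training loop.

#' Training configuration
#'
#' Defaults mirror the full-scale protocol: initial learning rate 1e-4
#' annealed on a 50-epoch cosine period to 1e-18, 1000 epochs, loss-weight
#' phase switch at epoch 50, batch size 8 (use 4 when generating 7-8
#' frames per block).  Desk-scale runs override `total_epochs`.
#'
#' @param lr_init initial learning rate
#' @param lr_min minimum learning rate
#' @param cosine_period cosine annealing period in epochs
#' @param total_epochs total training epochs
#' @param phase1_epochs epochs with phase-1 loss weights (1, 1, 0, 0)
#' @param batch_size gradient accumulation batch size
#' @param seed RNG seed controlling sampling and any initialization
#' @param lr_restart if `TRUE` (default) the cosine schedule warm-restarts
#'   every period; if `FALSE` it anneals once over one period and stays
#'   at `lr_min`
#' @param weight_decay AdamW decoupled weight decay
#' @param max_gap maximum frame gap (N+1) sampled during training
#' @return a `train_config` list
#' @export
train_config <- function(lr_init = 1e-4, lr_min = 1e-18, cosine_period = 50L,
                         total_epochs = 1000L, phase1_epochs = 50L,
                         batch_size = 8L, seed = 1L, lr_restart = TRUE,
                         weight_decay = 1e-2, max_gap = 7L) {
  if (lr_min >= lr_init) stop("lr_min must be < lr_init")
  if (phase1_epochs > total_epochs) stop("phase1_epochs must be <= total_epochs")
  structure(list(lr_init = lr_init, lr_min = lr_min,
                 cosine_period = as.integer(cosine_period),
                 total_epochs = as.integer(total_epochs),
                 phase1_epochs = as.integer(phase1_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 lr_restart = lr_restart, weight_decay = weight_decay,
                 max_gap = as.integer(max_gap)),
            class = "train_config")
}

#' Batch size convention by generated-frame count
#' @param n_generated frames generated per real frame (N)
#' @return 8 for N <= 6, 4 for N in 7..8
#' @export
default_batch_size <- function(n_generated) if (n_generated <= 6) 8L else 4L

#' Loss weights
#' @param alpha pixel L1 weight
#' @param beta structural (1 - SSIM) weight
#' @param gamma perceptual L1 weight
#' @param delta perceptual MSE weight
#' @export
loss_weights <- function(alpha, beta, gamma, delta) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(w < 0)) stop("loss weights must be non-negative")
  structure(as.list(w), class = "loss_weights")
}

#' Loss-weight schedule
#'
#' Phase 1 (epochs `0 .. phase1_epochs-1`): (1, 1, 0, 0) — pixel and
#' structural constraints only.  Phase 2 (remaining epochs):
#' (0.5, 0.7, 40, 40) — perceptual terms switched on.
#'
#' @param epoch 0-based epoch index
#' @param cfg a [train_config()]
#' @return a [loss_weights()]
#' @export
loss_weights_at_epoch <- function(epoch, cfg = train_config()) {
  if (epoch < 0 || epoch >= cfg$total_epochs) stop("epoch out of range")
  if (epoch < cfg$phase1_epochs) loss_weights(1, 1, 0, 0)
  else loss_weights(0.5, 0.7, 40, 40)
}

#' Cosine-annealed learning rate
#'
#' `lr = lr_min + (lr_init - lr_min) * (1 + cos(pi * e / period)) / 2`
#' where `e` is the epoch position within the period: with warm restarts
#' (default) `e = epoch mod period`; with a single anneal `e =
#' min(epoch, period)`.
#'
#' @param epoch 0-based epoch index
#' @param cfg a [train_config()]
#' @return learning rate
#' @export
lr_at_epoch <- function(epoch, cfg = train_config()) {
  if (epoch < 0 || epoch >= cfg$total_epochs) stop("epoch out of range")
  p <- cfg$cosine_period
  e <- if (cfg$lr_restart) epoch %% p else min(epoch, p)
  cfg$lr_min + 0.5 * (cfg$lr_init - cfg$lr_min) * (1 + cos(pi * e / p))
}

# --- perceptual feature extractor ------------------------------------------

#' Fixed random perceptual feature extractor
#'
#' A seeded, randomly initialized 3-stage strided convolutional extractor
#' standing in for a pretrained backbone so that no weight download is
#' needed.  Its weights are frozen; features from all three stages feed
#' the perceptual loss terms.
#'
#' @param seed integer seed
#' @param channels stage widths
#' @return a `feature_extractor` (list of fixed weight arrays)
#' @export
make_feature_extractor <- function(seed = 7L, channels = c(8L, 16L, 32L)) {
  with_seed(seed, {
    cin <- 1L
    stages <- list()
    for (c_out in channels) {
      stages[[length(stages) + 1L]] <- list(
        w = array(rnorm(3 * 3 * cin * c_out, 0, sqrt(2 / (9 * cin))),
                  c(3, 3, cin, c_out)),
        b = numeric(c_out))
      cin <- c_out
    }
    structure(list(stages = stages, pretrained = FALSE),
              class = "feature_extractor")
  })
}

.extract_feats <- function(fx, x) {
  out <- vector("list", length(fx$stages))
  h <- x
  for (i in seq_along(fx$stages)) {
    st <- fx$stages[[i]]
    h <- ad_relu(ad_conv2d(h, ad_const(st$w), ad_const(st$b),
                           stride = 2L, pad = 1L))
    out[[i]] <- h
  }
  out
}

# --- differentiable SSIM ----------------------------------------------------

.gauss11 <- local({
  g <- outer(dnorm(-5:5, sd = 1.5), dnorm(-5:5, sd = 1.5))
  g / sum(g)
})

# x, y: (H, W, 1) nodes in [0, 1]; 11x11 Gaussian window (applied as two
# separable 1-D passes), valid padding
.ssim_node <- function(x, y, C1 = 0.01^2, C2 = 0.03^2) {
  g1 <- dnorm(-5:5, sd = 1.5)
  g1 <- g1 / sum(g1)
  kv <- ad_const(array(g1, c(11, 1, 1, 1)))
  kh <- ad_const(array(g1, c(1, 11, 1, 1)))
  zb <- ad_const(numeric(1))
  gc <- function(z) ad_conv2d(ad_conv2d(z, kv, zb, stride = 1L, pad = 0L),
                              kh, zb, stride = 1L, pad = 0L)
  mx <- gc(x); my <- gc(y)
  mxx <- gc(ad_mul(x, x)); myy <- gc(ad_mul(y, y)); mxy <- gc(ad_mul(x, y))
  sx <- ad_sub(mxx, ad_mul(mx, mx))
  sy <- ad_sub(myy, ad_mul(my, my))
  sxy <- ad_sub(mxy, ad_mul(mx, my))
  num <- ad_mul(ad_shift(ad_scale(ad_mul(mx, my), 2), C1),
                ad_shift(ad_scale(sxy, 2), C2))
  den <- ad_mul(ad_shift(ad_add(ad_mul(mx, mx), ad_mul(my, my)), C1),
                ad_shift(ad_add(sx, sy), C2))
  ad_mean(ad_div(num, den))
}

#' Composite training loss
#'
#' `L = alpha * mean|pred - target| + beta * (1 - SSIM(pred, target)) +
#' gamma * sum_l mean|phi_l(pred) - phi_l(target)| + delta * sum_l
#' mean((phi_l(pred) - phi_l(target))^2)`, with `phi_l` the stages of the
#' perceptual extractor.  Inputs in \[-1, 1\] are shifted to \[0, 1\]
#' before the SSIM and perceptual terms.  Zero iff `pred == target`
#' whenever `alpha > 0`.
#'
#' @param pred,target frames in \[-1, 1\] (matrices, or ad nodes
#'   internally during training)
#' @param weights a [loss_weights()]
#' @param feat_extractor a [make_feature_extractor()]; required when
#'   `gamma` or `delta` is positive
#' @return non-negative scalar (or scalar node for node inputs)
#' @export
composite_loss <- function(pred, target, weights, feat_extractor = NULL) {
  if (!inherits(weights, "loss_weights"))
    weights <- do.call(loss_weights, as.list(weights))
  node_in <- inherits(pred, "ad_node")
  if (!node_in) {
    if (!identical(dim(pred), dim(target))) stop("pred/target shape mismatch")
    ad_tape_reset()
    d <- dim(pred)
    pred <- ad_const(array(pred, c(d[1], d[2], 1L)))
    target <- ad_const(array(target, c(d[1], d[2], 1L)))
  }
  terms <- list()
  if (weights$alpha > 0)
    terms <- c(terms, list(ad_scale(ad_mean(ad_abs(ad_sub(pred, target))),
                                    weights$alpha)))
  p01 <- ad_scale(ad_shift(pred, 1), 0.5)
  t01 <- ad_scale(ad_shift(target, 1), 0.5)
  if (weights$beta > 0) {
    dssim <- ad_shift(ad_scale(.ssim_node(p01, t01), -1), 1)  # 1 - SSIM
    terms <- c(terms, list(ad_scale(dssim, weights$beta)))
  }
  if (weights$gamma > 0 || weights$delta > 0) {
    if (is.null(feat_extractor))
      stop("feat_extractor required for perceptual loss terms")
    fp <- .extract_feats(feat_extractor, p01)
    ft <- .extract_feats(feat_extractor, t01)
    for (l in seq_along(fp)) {
      dl <- ad_sub(fp[[l]], ft[[l]])
      if (weights$gamma > 0)
        terms <- c(terms, list(ad_scale(ad_mean(ad_abs(dl)), weights$gamma)))
      if (weights$delta > 0)
        terms <- c(terms, list(ad_scale(ad_mean(ad_square(dl)), weights$delta)))
    }
  }
  loss <- terms[[1]]
  if (length(terms) > 1) for (k in 2:length(terms)) loss <- ad_add(loss, terms[[k]])
  if (node_in) loss else { v <- ad_value(loss); ad_tape_reset(); v }
}

# --- optimizer and training loop -------------------------------------------

.adamw_step <- function(params, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, scale = 1) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    m <- state$m[[nm]]
    v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    p$value <- p$value - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * p$value)
  }
  invisible(state)
}

.trainable_params <- function(model) Filter(function(p) isTRUE(p$is_param),
                                            model$params)

#' Train an interpolation model
#'
#' Runs the two-phase loss schedule with cosine-annealed AdamW.  Each
#' epoch visits every sequence once (shuffled), sampling one
#' (frame0, target, frame1) triple per sequence with a random frame gap
#' up to `cfg$max_gap + 1`; gradients are accumulated over
#' `cfg$batch_size` samples per optimizer step.  Fully deterministic for
#' a fixed `cfg$seed`.
#'
#' @param model an [build_interp_model()] model (updated in place and
#'   returned)
#' @param dataset list of sequences: H x W x T arrays in \[-1, 1\] (or
#'   [frame_sequence()] objects already normalized)
#' @param cfg a [train_config()]
#' @param feat_extractor perceptual extractor for phase-2 weights;
#'   created automatically when needed
#' @param verbose print per-epoch progress
#' @return `list(model, history)`; `history` is a data frame with
#'   epoch, lr, mean loss and the four loss weights.
#' @export
train_model <- function(model, dataset, cfg = train_config(),
                        feat_extractor = NULL, verbose = FALSE) {
  if (!length(dataset)) stop("dataset is empty")
  dataset <- lapply(dataset, function(s) {
    if (is.list(s) && !is.null(s$frames)) s$frames else s  # sequences or raw arrays
  })
  nt <- vapply(dataset, function(s) dim(s)[3], numeric(1))
  if (any(nt < 3))
    stop("every training sequence needs >= 3 frames (an interior frame to predict)")
  needs_fx <- cfg$total_epochs > cfg$phase1_epochs
  if (needs_fx && is.null(feat_extractor)) feat_extractor <- make_feature_extractor()

  d <- dim(dataset[[1]])
  .check_divisible(d, model$config$n_scales)
  # create the learned positional table for this input size if absent
  hb <- d[1] %/% 2L^(model$config$n_scales - 1L)
  wb <- d[2] %/% 2L^(model$config$n_scales - 1L)
  pos_key <- paste0("attn_pos_", hb, "x", wb)
  if (is.null(model$params[[pos_key]])) {
    Cc <- channels_at_scale(model$config, model$config$n_scales - 1L)
    model$params[[pos_key]] <- with_seed(cfg$seed + 1L,
      ad_param(matrix(rnorm(hb * wb * Cc, 0, 0.02), hb * wb, Cc)))
  }

  params <- .trainable_params(model)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- list()
  state$v <- list()
  hist <- vector("list", cfg$total_epochs)

  with_seed(cfg$seed, {
    for (epoch in 0:(cfg$total_epochs - 1L)) {
      lr <- lr_at_epoch(epoch, cfg)
      wts <- loss_weights_at_epoch(epoch, cfg)
      ord <- sample(length(dataset))
      ep_loss <- 0
      nb <- 0L
      for (si in ord) {
        fr <- dataset[[si]]
        T <- dim(fr)[3]
        gaps <- 2:min(T - 1L, cfg$max_gap + 1L)
        gap <- if (length(gaps) == 1L) gaps else sample(gaps, 1L)
        i0 <- sample.int(T - gap, 1L)
        i1 <- i0 + gap
        it <- if (gap == 2L) i0 + 1L else i0 + sample.int(gap - 1L, 1L)
        tstep <- -1 + 2 * (it - i0) / gap
        ad_tape_reset()
        f0 <- ad_const(array(fr[, , i0], c(d[1], d[2], 1L)))
        f1 <- ad_const(array(fr[, , i1], c(d[1], d[2], 1L)))
        tgt <- ad_const(array(fr[, , it], c(d[1], d[2], 1L)))
        out <- .forward_synth(model, f0, f1, tstep)
        loss <- composite_loss(out$pred, tgt, wts, feat_extractor)
        ad_backward(loss)
        ep_loss <- ep_loss + ad_value(loss)
        nb <- nb + 1L
        if (nb %% cfg$batch_size == 0L || si == ord[length(ord)]) {
          nacc <- if (nb %% cfg$batch_size == 0L) cfg$batch_size
                  else nb %% cfg$batch_size
          .adamw_step(params, state, lr, cfg$weight_decay, scale = 1 / nacc)
          ad_zero_grads(params)
        }
      }
      ad_tape_reset()
      hist[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                       loss = ep_loss / nb,
                                       alpha = wts$alpha, beta = wts$beta,
                                       gamma = wts$gamma, delta = wts$delta)
      if (verbose)
        message(sprintf("epoch %3d  lr %.3g  loss %.5f", epoch, lr, ep_loss / nb))
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' Save a model checkpoint
#'
#' Single-file archive holding the configuration and all weight arrays.
#'
#' @param model an interpolation model
#' @param path output file
#' @param history optional training history to embed
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  ck <- list(config = unclass(model$config),
             values = lapply(model$params, function(p) p$value),
             is_param = lapply(model$params, function(p) isTRUE(p$is_param)),
             history = history)
  saveRDS(ck, path)
  invisible(path)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file
#' @return an `interp_model` producing outputs identical to the saved one
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[c("base_channels", "n_scales",
                                           "n_heads", "orientations")])
  P <- list()
  for (nm in names(ck$values)) {
    P[[nm]] <- if (isTRUE(ck$is_param[[nm]])) ad_param(ck$values[[nm]])
               else ad_const(ck$values[[nm]])
  }
  structure(list(config = cfg, params = P), class = "interp_model")
}

# --- synthetic training data -----------------------------------------------

#' Build a synthetic training/evaluation set
#'
#' Generates DSA-like sequences with the simulator (mixed 2D/3D modes and
#' morphologies by default), preprocessed to `resolution` and normalized
#' per sequence so that temporal intensity relations are preserved.
#'
#' @param n_sequences number of sequences
#' @param resolution frame side length in px
#' @param n_frames frames per sequence
#' @param seed integer seed
#' @param modes acquisition modes to cycle through
#' @param morphologies morphology classes to cycle through
#' @param noise_sd rendering noise level
#' @return list of `list(frames, mode, morphology, tree, truth)`;
#'   `frames` is an H x W x T array in \[-1, 1\]
#' @export
make_synthetic_dataset <- function(n_sequences, resolution = 64L,
                                   n_frames = 16L, seed = 1L,
                                   modes = c("2D", "3D"),
                                   morphologies = c("normal", "aneurysm",
                                                    "stenosis", "av_shunt",
                                                    "collateral_net"),
                                   noise_sd = 0.01) {
  out <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    md <- modes[1L + (i - 1L) %% length(modes)]
    mo <- morphologies[1L + (i - 1L) %% length(morphologies)]
    sd_i <- seed * 10000L + i
    tree <- generate_vessel_tree(sd_i, n_branches = 3L + i %% 3L,
                                 morphology_class = mo,
                                 domain_px = resolution)
    op <- simulate_bolus(tree, t_peak = 4 + (i %% 3), alpha = 2,
                         n_frames = n_frames)
    rs <- render_sequence(tree, op, mode = md, resolution = resolution,
                          seed = sd_i + 1L, noise_sd = noise_sd)
    ns <- normalize_sequence(rs$sequence, per = "sequence")
    out[[i]] <- list(frames = ns$frames, mode = md, morphology = mo,
                     tree = tree, truth = rs$truth)
  }
  out
}
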