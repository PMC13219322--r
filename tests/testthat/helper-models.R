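# Shared fixtures.  Trained tiny models are expensive, so they are built
# once per test run and memoized here; every consumer test uses the same
# seeded training run.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# random texture in [-1, 1] with coarse structure plus dominant fine
# detail (fine detail makes sub-pixel misalignment expensive, which is
# what lets photometric training recover the full displacement)
make_texture <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ii <- matrix(seq_len(n) / n, n, n)
  jj <- t(ii)
  f <- matrix(0, n, n)
  for (k in 1:4)
    f <- f + 0.7 * rnorm(1) * cos(2 * pi * (runif(1, 0.5, 3) * ii + runif(1, 0.5, 3) * jj + runif(1)))
  for (k in 1:8)
    f <- f + rnorm(1) * cos(2 * pi * (runif(1, 3, 9) * ii + runif(1, 3, 9) * jj + runif(1)))
  (f - min(f)) / (max(f) - min(f)) * 2 - 1
}

shift_image <- function(img, dx, dy = 0) {
  fl <- array(0, c(dim(img), 2))
  fl[, , 1] <- -dx
  fl[, , 2] <- -dy
  backward_warp(img, fl)
}

# pure-translation world: f0, midframe (+d/2), f1 (+d); d = 3 px
translation_dataset <- function(n_seq = 40L, n = 32L, d = 3, seed = 11L) {
  set.seed(seed)
  lapply(seq_len(n_seq), function(i) {
    f0 <- make_texture(n)
    array(c(f0, shift_image(f0, d / 2), shift_image(f0, d)), c(n, n, 3))
  })
}

# model trained on pure-translation pairs (flow diagnostic)
trained_translation_model <- function() .memo("translation", function() {
  ds <- translation_dataset()
  mod <- build_interp_model(model_config(base_channels = 8L, n_scales = 3L),
                            seed = 42L)
  fit <- train_model(mod, ds,
                     train_config(lr_init = 2e-3, total_epochs = 150L,
                                  phase1_epochs = 150L, cosine_period = 30L,
                                  batch_size = 8L, seed = 5L, max_gap = 2L))
  fit$model
})

# model trained on static scenes (identical frames)
trained_static_model <- function() .memo("static", function() {
  set.seed(21)
  ds <- lapply(1:20, function(i) {
    f0 <- make_texture(32L)
    array(c(f0, f0, f0), c(32L, 32L, 3L))
  })
  mod <- build_interp_model(model_config(base_channels = 8L, n_scales = 3L),
                            seed = 43L)
  fit <- train_model(mod, ds,
                     train_config(lr_init = 5e-4, total_epochs = 30L,
                                  phase1_epochs = 30L, cosine_period = 30L,
                                  batch_size = 8L, seed = 6L, max_gap = 2L))
  fit$model
})

# model trained on constant sequences (every frame a constant level)
trained_constant_model <- function() .memo("constant", function() {
  set.seed(31)
  ds <- lapply(1:24, function(i) {
    array(runif(1, -0.8, 0.8), c(32L, 32L, 3L))
  })
  mod <- build_interp_model(model_config(base_channels = 8L, n_scales = 3L),
                            seed = 44L)
  fit <- train_model(mod, ds,
                     train_config(lr_init = 5e-4, total_epochs = 30L,
                                  phase1_epochs = 30L, cosine_period = 30L,
                                  batch_size = 8L, seed = 7L, max_gap = 2L))
  fit$model
})

# The desk-scale reference run: base 8 channels, 64 x 64, 200 synthetic
# bolus sequences, 30 epochs (all inside loss phase 1, since the phase
# switch sits at epoch 50).  Used by the learning-efficacy acceptance
# criterion and by the training-module tests.
TINY_TRAIN_SEQS <- 200L
TINY_TRAIN_EPOCHS <- 30L

trained_bolus_model <- function() .memo("bolus", function() {
  ds <- make_synthetic_dataset(TINY_TRAIN_SEQS, resolution = 64L,
                               n_frames = 16L, seed = 100L)
  mod <- build_interp_model(model_config(base_channels = 8L, n_scales = 4L),
                            seed = 42L)
  fit <- train_model(mod, ds,
                     train_config(total_epochs = TINY_TRAIN_EPOCHS,
                                  phase1_epochs = TINY_TRAIN_EPOCHS,
                                  batch_size = 8L, seed = 10L))
  fit
})

heldout_bolus_set <- function() .memo("heldout", function() {
  make_synthetic_dataset(20L, resolution = 64L, n_frames = 16L, seed = 900L)
})
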