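# Interpolation network: DACB masking, warping, flow estimation, and the
# full synthesis contract.

test_that("DACB preserves spatial shape and masks kernel support", {
  set.seed(20)
  x <- array(rnorm(24 * 24 * 2), c(24, 24, 2))
  out <- apply_dacb(x, orientations = c(0, 45, 90, 135), seed = 5)
  expect_equal(dim(out), c(24, 24, 2))

  # zero the input on row r: the 0-degree branch (horizontal mask) sees
  # nothing at row r, so its output there is the bias-only response
  r <- 12
  x0 <- x
  x0[r, , ] <- 0
  res <- apply_dacb(x0, orientations = c(0, 90), seed = 5,
                    return_branches = TRUE)
  br0 <- res$branches[[1]]  # 0-degree branch, bias initialized to zero
  expect_equal(max(abs(br0[r, 2:23, ])), 0, tolerance = 1e-12)

  # orientation selectivity with mask-aligned averaging kernels: a
  # bipolar stimulus (bright line on dark background) is preserved by
  # the aligned branch but attenuated by the orthogonal one
  line <- matrix(-1, 24, 24)
  line[12, ] <- 1  # horizontal stimulus
  sel <- apply_dacb(line, orientations = c(0, 90), init = "aligned",
                    return_branches = TRUE)
  expect_gt(mean(abs(sel$branches[[1]])), mean(abs(sel$branches[[2]])))
})

test_that("orientation masks trace lines through the kernel center", {
  expect_equal(orientation_mask(0), rbind(0, 1, 0) %x% t(c(1, 1, 1)))
  expect_equal(orientation_mask(90), cbind(0, 1, 0) %x% c(1, 1, 1))
  expect_equal(diag(orientation_mask(45))[c(1, 3)], c(0, 0))
  expect_equal(orientation_mask(45)[1, 3] + orientation_mask(45)[3, 1], 2)
  expect_equal(diag(orientation_mask(135)), c(1, 1, 1))
})

test_that("backward_warp: identity, integer shift, and exactness on ramps", {
  set.seed(21)
  img <- matrix(rnorm(64), 8, 8)
  zf <- array(0, c(8, 8, 2))
  expect_identical(backward_warp(img, zf), img)

  # dx = 1: output(r, c) = source(r, c + 1), border column duplicated
  fl <- zf
  fl[, , 1] <- 1
  shifted <- backward_warp(img, fl)
  expect_identical(shifted[, 1:7], img[, 2:8])
  expect_identical(shifted[, 8], img[, 8])

  # bilinear is exact on a linear ramp: f(x) = x sampled at x + 0.5
  ramp <- matrix(rep(1:8, each = 8), 8, 8)
  fl <- zf
  fl[, , 1] <- 0.5
  wr <- backward_warp(ramp, fl)
  expect_equal(wr[, 1:7], ramp[, 1:7] + 0.5, tolerance = 1e-12)
  expect_error(backward_warp(img, array(0, c(4, 4, 2))), "shape")
})

test_that("channel widths double per scale in the built model", {
  cfg <- model_config(base_channels = 8L, n_scales = 3L)
  expect_identical(vapply(0:2, function(s) channels_at_scale(cfg, s),
                          integer(1)), c(8L, 16L, 32L))
  mod <- build_interp_model(cfg, seed = 1)
  expect_equal(dim(mod$params$enc_in_w$value)[4], 8L)
  expect_equal(dim(mod$params$enc_down1_w$value)[4], 16L)
  expect_equal(dim(mod$params$enc_down2_w$value)[4], 32L)
  expect_error(model_config(n_scales = 1L), "n_scales")
})

test_that("synthesis contract: shape, range, endpoint rejection, determinism", {
  mod <- build_interp_model(model_config(8L, 3L), seed = 2)
  f0 <- matrix(runif(32 * 32) * 2 - 1, 32, 32)
  f1 <- matrix(runif(32 * 32) * 2 - 1, 32, 32)
  p <- synthesize_intermediate(synthesis_request(f0, f1, 0.3), mod)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= -1 & p <= 1))
  expect_error(synthesis_request(f0, f1, 1), "strictly inside")
  expect_error(synthesis_request(f0, f1, -1), "strictly inside")
  expect_error(synthesis_request(f0, matrix(0, 16, 16), 0), "same shape")
  p2 <- synthesize_intermediate(synthesis_request(f0, f1, 0.3), mod)
  expect_identical(p, p2)

  fl <- estimate_bidirectional_flow(mod, f0, f1, 0.3)
  expect_equal(dim(fl$flow0), c(32, 32, 2))
  expect_equal(dim(fl$flow1), c(32, 32, 2))
  expect_true(all(is.finite(fl$flow0)) && all(is.finite(fl$flow1)))
})

test_that("trained flow recovers pure translation at the midpoint", {
  mod <- trained_translation_model()
  set.seed(202)
  mags <- replicate(3, {
    f0 <- make_texture(32L)
    f1 <- shift_image(f0, 3)
    fl <- estimate_bidirectional_flow(mod, f0, f1, 0)
    (mean(sqrt(fl$flow0[, , 1]^2 + fl$flow0[, , 2]^2)) +
     mean(sqrt(fl$flow1[, , 1]^2 + fl$flow1[, , 2]^2))) / 2
  })
  expect_gte(mean(mags), 1)   # ~ d * (t - (-1)) / 2 = 1.5 at t = 0
  expect_lte(mean(mags), 2)
  # and the direction is consistent: sample frame0 backward, frame1 forward
  f0 <- make_texture(32L)
  f1 <- shift_image(f0, 3)
  fl <- estimate_bidirectional_flow(mod, f0, f1, 0)
  expect_lt(mean(fl$flow0[, , 1]), 0)
  expect_gt(mean(fl$flow1[, , 1]), 0)
})

test_that("a static-scene model reports near-zero flow", {
  mod <- trained_static_model()
  set.seed(203)
  f0 <- make_texture(32L)
  fl <- estimate_bidirectional_flow(mod, f0, f0, 0)
  m <- (mean(sqrt(fl$flow0[, , 1]^2 + fl$flow0[, , 2]^2)) +
        mean(sqrt(fl$flow1[, , 1]^2 + fl$flow1[, , 2]^2))) / 2
  expect_lt(m, 0.5)
})

test_that("a model trained on constants reproduces the constant", {
  mod <- trained_constant_model()
  for (cc in c(-0.5, 0, 0.4)) {
    f <- matrix(cc, 32, 32)
    p <- synthesize_intermediate(synthesis_request(f, f, 0), mod)
    expect_lt(mean(abs(p - cc)), 0.05)
  }
})

test_that("time-symmetry is reported (smoke property, not asserted)", {
  mod <- trained_translation_model()
  set.seed(204)
  f0 <- make_texture(32L)
  f1 <- shift_image(f0, 3)
  a <- synthesize_intermediate(synthesis_request(f0, f1, 0.4), mod)
  b <- synthesize_intermediate(synthesis_request(f1, f0, -0.4), mod)
  mad <- mean(abs(a - b))
  succeed(sprintf("time-symmetry mean |difference| at t = +/-0.4: %.4f", mad))
})
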