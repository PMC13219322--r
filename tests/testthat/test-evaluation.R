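# Image-quality metrics, bootstrap intervals, TIC error, and guidewire
# tip localization.

test_that("metric identities hold", {
  x <- matrix(runif(32 * 32), 32, 32)
  m <- compute_image_metrics(x, x)
  expect_equal(m$ssim, 1)
  expect_equal(m$mse, 0)
  expect_identical(m$psnr, Inf)

  a <- matrix(0.5, 32, 32)
  b <- matrix(0.6, 32, 32)
  m <- compute_image_metrics(b, a)
  expect_equal(m$mse, 0.01, tolerance = 1e-12)
  expect_equal(m$psnr, 20, tolerance = 1e-9)

  set.seed(8)
  for (k in 1:20) {
    p <- matrix(runif(24 * 24), 24, 24)
    q <- matrix(runif(24 * 24), 24, 24)
    expect_equal(ssim_index(p, q), ssim_index(q, p), tolerance = 1e-12)
    m <- compute_image_metrics(p, q)
    expect_equal(m$psnr, -10 * log10(m$mse), tolerance = 1e-12)
  }
  expect_error(compute_image_metrics(matrix(0, 16, 16), matrix(0, 16, 17)),
               "mismatch")
})

test_that("SSIM matches a brute-force windowed oracle", {
  # direct per-window computation of the Gaussian SSIM definition
  brute_ssim <- function(x, y, sd = 1.5, K1 = 0.01, K2 = 0.03) {
    g <- outer(dnorm(-5:5, sd = sd), dnorm(-5:5, sd = sd))
    g <- g / sum(g)
    C1 <- K1^2; C2 <- K2^2
    H <- nrow(x); W <- ncol(x)
    vals <- c()
    for (i in 1:(H - 10)) for (j in 1:(W - 10)) {
      wx <- x[i:(i + 10), j:(j + 10)]
      wy <- y[i:(i + 10), j:(j + 10)]
      mx <- sum(g * wx); my <- sum(g * wy)
      sx <- sum(g * wx^2) - mx^2
      sy <- sum(g * wy^2) - my^2
      sxy <- sum(g * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                      ((mx^2 + my^2 + C1) * (sx + sy + C2)))
    }
    mean(vals)
  }
  set.seed(9)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- pmin(pmax(x + matrix(rnorm(256, 0, 0.1), 16, 16), 0), 1)
  expect_equal(ssim_index(x, y), brute_ssim(x, y), tolerance = 1e-10)
})

test_that("SSIM orders noise below identity", {
  set.seed(10)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  expect_lt(ssim_index(a, b), ssim_index(a, a))
})

test_that("bootstrap CI degenerate and deterministic cases", {
  expect_equal(bootstrap_ci(rep(3.2, 10)), c(3.2, 3.2))
  v <- rnorm(30)
  expect_identical(bootstrap_ci(v, seed = 4), bootstrap_ci(v, seed = 4))
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("bootstrap CI coverage is near nominal", {
  set.seed(123)
  hits <- 0L
  trials <- 1000L
  for (k in seq_len(trials)) {
    v <- rnorm(50)
    ci <- bootstrap_ci(v, reps = 400L, seed = k)
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.93)
  expect_lte(hits / trials, 0.97)
})

test_that("residual maps and the amplified variant", {
  x <- matrix(runif(16 * 16), 16, 16)
  r <- residual_map(x, x)
  expect_true(all(r$residual == 0))
  y <- x
  y[3, 4] <- x[3, 4] + 1
  r <- residual_map(y, x)
  expect_equal(sum(r$residual), 1)
  expect_equal(r$residual[3, 4], 1)
  set.seed(11)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  r <- residual_map(a, b)
  expect_equal(r$amplified, pmin(10 * abs(a - b), 1))
})

test_that("TIC error: identity, affine invariance, and shifted-peak form", {
  n <- 16L
  mk <- function(series) {
    fr <- array(0.5, c(n, n, length(series)))
    for (t in seq_along(series)) fr[5, 7, t] <- series[t]
    fr
  }
  tri <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0, 0) / 5  # triangular TIC
  px <- list(c(6, 4))  # (x, y) 0-based -> row 5, col 7
  expect_equal(time_intensity_error(mk(tri), mk(tri), px)$max_error, 0)
  expect_equal(time_intensity_error(mk(2.5 * tri + 0.2), mk(tri), px)$max_error,
               0, tolerance = 1e-12)
  shifted <- c(tri[-1], 0)
  err <- time_intensity_error(mk(shifted), mk(tri), px)$max_error
  expect_equal(err, 1 / 5, tolerance = 1e-9)  # per-frame slope of the triangle
  expect_error(time_intensity_error(mk(tri), mk(tri), list(c(99, 99))),
               "bounds")
})

gw_scene <- function(seed = 30) {
  tree <- generate_vessel_tree(seed, 3, "normal")
  op <- simulate_bolus(tree, n_frames = 10)
  render_sequence(tree, op, mode = "2D", resolution = 96, seed = seed + 1,
                  guidewire = TRUE)
}

test_that("guidewire tip is localized within 1 px on clean frames", {
  rs <- gw_scene()
  res <- guidewire_tip_error(rs$sequence$frames, rs$truth$tip_xy)
  expect_identical(res$n_flagged, 0L)
  expect_lte(res$max_error, 1.0)
})

test_that("a 1 px translation shifts the tip estimate by about 1 px", {
  rs <- gw_scene(41)
  fr <- rs$sequence$frames
  deltas <- matrix(NA_real_, dim(fr)[3], 2)
  for (t in seq_len(dim(fr)[3])) {
    fl <- array(0, c(dim(fr)[1:2], 2))
    fl[, , 1] <- -1   # content moves +1 px in x
    sh_frame <- backward_warp(fr[, , t], fl)
    t0 <- locate_guidewire_tip(fr[, , t])
    t1 <- locate_guidewire_tip(sh_frame)
    if (!is.null(t0) && !is.null(t1)) deltas[t, ] <- t1 - t0
  }
  expect_true(all(!is.na(deltas)))
  expect_equal(mean(deltas[, 1]), 1, tolerance = 0.3)   # x moves by the shift
  expect_equal(mean(abs(deltas[, 2])), 0, tolerance = 0.3)  # y unchanged
})

test_that("empty frames are flagged, not scored", {
  fr <- array(0.8, c(32, 32, 4))
  res <- guidewire_tip_error(fr, matrix(5, 4, 2))
  expect_identical(res$n_flagged, 4L)
  expect_true(is.na(res$mean_error))
})

test_that("evaluate_sequences aggregates and is [-1,1]/[0,1] agnostic", {
  set.seed(12)
  real <- lapply(1:3, function(i) array(runif(32 * 32 * 4), c(32, 32, 4)))
  gen <- lapply(real, function(r) pmin(pmax(r + rnorm(length(r), 0, 0.02), 0), 1))
  rep01 <- evaluate_sequences(gen, real, reps = 200L, seed = 5)
  rep11 <- evaluate_sequences(lapply(gen, function(g) 2 * g - 1),
                              lapply(real, function(r) 2 * r - 1),
                              reps = 200L, seed = 5)
  expect_equal(rep01$ssim$mean, rep11$ssim$mean, tolerance = 1e-9)
  expect_equal(rep01$psnr$mean, rep11$psnr$mean, tolerance = 1e-9)
  expect_lte(rep01$ssim$ci[1], rep01$ssim$mean)
  expect_gte(rep01$ssim$ci[2], rep01$ssim$mean)
  expect_identical(rep01$n_sequences, 3L)
})
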