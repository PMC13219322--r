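# Synthetic angiography simulator: vessel trees, bolus dynamics,
# rendering, and artifact injection.

test_that("vessel tree generation is deterministic and validates", {
  t1 <- generate_vessel_tree(7, 5, "normal", 128)
  t2 <- generate_vessel_tree(7, 5, "normal", 128)
  expect_identical(t1, t2)
  expect_gte(nrow(t1$segments), 5)
  expect_silent(validate_vessel_tree(t1))
})

test_that("invalid morphology class is rejected with the valid list", {
  expect_error(generate_vessel_tree(1, 3, "tumour"),
               "normal.*aneurysm.*stenosis.*av_shunt.*collateral_net")
  expect_error(generate_vessel_tree(1, 0, "normal"), "n_branches")
  expect_error(generate_vessel_tree(1, 3, "normal", 16), "domain_px")
})

test_that("stenosis morphology yields exactly one focally narrowed segment", {
  for (seed in c(7, 19, 103)) {
    tree <- generate_vessel_tree(seed, 5, "stenosis", 128)
    df <- tree$segments
    narrow <- 0L
    for (i in seq_len(nrow(df))) {
      p <- df$parent[i]
      kids <- which(df$parent == i)
      if (p == 0L || !length(kids)) next
      if (df$radius[i] < 0.5 * df$radius[p] &&
          all(df$radius[i] < 0.5 * df$radius[kids]))
        narrow <- narrow + 1L
    }
    expect_identical(narrow, 1L)
  }
})

test_that("morphology classes realize their structures", {
  an <- generate_vessel_tree(3, 4, "aneurysm")
  expect_false(is.null(an$aneurysm))
  expect_gt(an$aneurysm$radius_px, an$segments$radius[an$aneurysm$parent_seg])

  sh <- generate_vessel_tree(3, 4, "av_shunt")
  expect_identical(sum(sh$segments$kind == "shunt"), 1L)
  expect_lt(sh$segments$radius[sh$segments$kind == "shunt"], 1)

  co <- generate_vessel_tree(3, 4, "collateral_net")
  expect_gte(sum(co$segments$kind == "collateral"), 8L)
  expect_true(all(co$segments$radius[co$segments$kind == "collateral"] < 1))
})

test_that("taper and arrival invariants hold across 50 seeded trees", {
  for (seed in 0:49) {
    tree <- generate_vessel_tree(seed, 4, "normal", 128)
    df <- tree$segments
    for (i in seq_len(nrow(df))) {
      p <- df$parent[i]
      if (p == 0L) next
      expect_lte(df$radius[i], df$radius[p] + 1e-9)
      expect_gte(tree$arrival_time[i], tree$arrival_time[p] - 1e-9)
    }
  }
})

test_that("gamma-variate bolus peaks at arrival + t_peak and rises before it", {
  tree <- generate_vessel_tree(5, 4, "normal")
  # closed form: peak value exactly 1 at dt = t_peak
  tp <- 4.7; al <- 2.3
  gv <- function(t, t0) ifelse(t > t0, ((t - t0) / tp)^al * exp(al * (1 - (t - t0) / tp)), 0)
  for (i in seq_len(nrow(tree$segments))) {
    t0 <- tree$arrival_time[i]
    expect_equal(gv(t0 + tp, t0), 1, tolerance = 1e-9)
    grid <- seq(t0 + 1e-3, t0 + tp - 1e-3, length.out = 40)
    expect_true(all(diff(gv(grid, t0)) > 0))  # strictly rising to the peak
  }
  op <- simulate_bolus(tree, t_peak = tp, alpha = al, n_frames = 20)
  expect_true(all(op >= 0))
  expect_true(all(op <= 1 + 1e-12))
  # sampled argmax within one frame of the true peak for segments peaking in range
  for (i in seq_len(nrow(tree$segments))) {
    tpk <- tree$arrival_time[i] + tp
    if (tpk < 18) expect_lte(abs((which.max(op[i, ]) - 1) - tpk), 1)
  }
  expect_error(simulate_bolus(tree, t_peak = -1), "positive")
  expect_error(simulate_bolus(tree, alpha = 0), "positive")
  expect_error(simulate_bolus(tree, n_frames = 1), "n_frames")
})

test_that("rendering honours mode contracts", {
  tree <- generate_vessel_tree(9, 4, "normal")
  op <- simulate_bolus(tree, n_frames = 24)
  r3 <- render_sequence(tree, op, mode = "3D", resolution = 64, seed = 2)
  expect_equal(r3$sequence$angles_deg[1], 0)
  expect_equal(r3$sequence$angles_deg[24], 180)
  expect_equal(diff(r3$sequence$angles_deg), rep(180 / 23, 23), tolerance = 1e-12)

  op10 <- simulate_bolus(tree, n_frames = 10)
  r2 <- render_sequence(tree, op10, mode = "2D", resolution = 48, seed = 2)
  expect_true(all(r2$sequence$angles_deg == 0))
  expect_equal(dim(r2$sequence$frames), c(48, 48, 10))
})

test_that("vessels are dark: mean intensity inside the mask is lower", {
  tree <- generate_vessel_tree(11, 4, "normal")
  op <- simulate_bolus(tree, n_frames = 16)
  rs <- render_sequence(tree, op, mode = "2D", resolution = 64, seed = 4)
  for (t in seq_len(16)) {
    if (max(op[, t]) <= 0.05) next
    msk <- rs$truth$vessel_mask[, , t]
    if (!any(msk)) next
    fr <- rs$sequence$frames[, , t]
    expect_lt(mean(fr[msk]), mean(fr[!msk]))
  }
  # inversion flag flips the convention
  ri <- render_sequence(tree, op, mode = "2D", resolution = 64, seed = 4,
                        invert = TRUE)
  msk <- ri$truth$vessel_mask[, , 8]
  expect_gt(mean(ri$sequence$frames[, , 8][msk]),
            mean(ri$sequence$frames[, , 8][!msk]))
})

test_that("3D projection follows the geometric rotation oracle", {
  # single off-axis segment; centroid x of its mask must follow
  # ((x-0.5) cos a + (z-0.5) sin a + 0.5) * (R-1)
  seg <- data.frame(x0 = 0.75, y0 = 0.4, z0 = 0.55, x1 = 0.75, y1 = 0.6,
                    z1 = 0.55, radius = 2, parent = 0L, kind = "trunk")
  tree <- structure(list(segments = seg, arrival_time = 0,
                         morphology_class = "normal", domain_px = 128L,
                         aneurysm = NULL), class = "vessel_tree")
  n <- 24
  op <- matrix(1, 1, n)
  rs <- render_sequence(tree, op, mode = "3D", resolution = 96, seed = 1,
                        noise_sd = 0)
  angles <- rs$sequence$angles_deg * pi / 180
  for (t in seq(1, n, by = 4)) {
    msk <- rs$truth$vessel_mask[, , t]
    if (!any(msk)) next
    cx_meas <- mean(which(msk, arr.ind = TRUE)[, 2]) - 1  # 0-based column
    cx_true <- ((0.75 - 0.5) * cos(angles[t]) + (0.55 - 0.5) * sin(angles[t]) + 0.5) * 95
    expect_lt(abs(cx_meas - cx_true), 1.5)
  }
})

test_that("artifact injection: identity at zero, monotone, deterministic", {
  tree <- generate_vessel_tree(13, 3, "normal")
  op <- simulate_bolus(tree, n_frames = 8)
  sq <- render_sequence(tree, op, mode = "2D", resolution = 48, seed = 6)$sequence

  expect_identical(inject_artifacts(sq, 0, "motion", seed = 3)$frames, sq$frames)

  for (kind in c("motion", "subtraction_ghost")) {
    lo <- inject_artifacts(sq, 0.2, kind, seed = 3)
    hi <- inject_artifacts(sq, 0.8, kind, seed = 3)
    frac <- function(out) mean(out$frames != sq$frames)
    expect_gt(frac(hi), frac(lo))
    again <- inject_artifacts(sq, 0.8, kind, seed = 3)
    expect_identical(hi$frames, again$frames)
  }
  expect_error(inject_artifacts(sq, 1.2, "motion"), "severity")
})

test_that("sequence I/O round-trips through PGM + JSON", {
  tree <- generate_vessel_tree(17, 3, "normal")
  op <- simulate_bolus(tree, n_frames = 6)
  rs <- render_sequence(tree, op, mode = "3D", resolution = 32, seed = 8,
                        guidewire = TRUE)
  dir <- withr::local_tempdir()
  write_frame_sequence(rs$sequence, dir, truth = rs$truth)
  back <- read_frame_sequence(dir)
  expect_equal(back$mode, "3D")
  expect_equal(back$angles_deg, rs$sequence$angles_deg)
  expect_equal(back$frames, rs$sequence$frames, tolerance = 1 / 65535)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
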