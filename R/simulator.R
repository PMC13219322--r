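# Procedural angiography simulator.
#
# A vessel tree is grown in a unit cube (x, z horizontal, y vertical,
# which is the screen row axis).  Radii are in pixels at the reference
# domain of 128 px and are scaled with the rendering resolution.
# Rendering follows the subtracted-image convention: vessels are dark
# (high optical density) on a light, smoothly varying background.
# 2D mode projects at a fixed angle; 3D mode projects orthographically
# while rotating the tree about the vertical axis over 180 degrees.

.morphology_classes <- c("normal", "aneurysm", "stenosis", "av_shunt",
                         "collateral_net")

.unit3 <- function(v) v / sqrt(sum(v * v))

#' Generate a procedural vessel tree
#'
#' Grows a branching tree in the unit cube: a tapering trunk plus
#' `n_branches` side branches (Murray-law-like taper, child radius =
#' 0.79 x parent with -10% jitter).  Bolus arrival times increase with
#' path length from the root.  Disease-like morphologies add:
#' a saccular bulge (`"aneurysm"`), a focally narrowed segment
#' (`"stenosis"`, radius < 0.5 x both neighbours), a thin direct
#' artery-to-vein connection (`"av_shunt"`), or a dense fine-radius
#' subnetwork (`"collateral_net"`).
#'
#' @param seed integer seed; the same seed yields an identical tree.
#' @param n_branches number of side branches (>= 1).
#' @param morphology_class one of `"normal"`, `"aneurysm"`, `"stenosis"`,
#'   `"av_shunt"`, `"collateral_net"`.
#' @param domain_px nominal image domain in pixels (>= 32); radii scale
#'   with it.
#'
#' @return A `vessel_tree` list: `segments` (data frame with 3-D
#'   endpoints, `radius` in px, `parent` index, `kind`), `arrival_time`
#'   (frames), `morphology_class`, `domain_px`, optional `aneurysm`.
#' @export
generate_vessel_tree <- function(seed, n_branches, morphology_class = "normal",
                                 domain_px = 128L) {
  if (!morphology_class %in% .morphology_classes)
    stop("invalid morphology_class '", morphology_class, "'; valid classes: ",
         paste(.morphology_classes, collapse = ", "))
  if (n_branches < 1) stop("n_branches must be >= 1")
  if (domain_px < 32) stop("domain_px must be >= 32")

  with_seed(seed, {
    speed <- 0.12  # unit-cube path length per frame of bolus travel
    r0 <- max(2.2, domain_px / 48)

    segs <- list()
    arrival <- numeric(0)
    add_seg <- function(p0, p1, radius, parent, kind, arr) {
      segs[[length(segs) + 1L]] <<- c(p0, p1, radius, parent)
      attr(segs[[length(segs)]], "kind") <<- kind
      arrival[length(segs)] <<- arr
      length(segs)
    }

    # trunk: chain growing downward from the top with lateral drift
    m <- max(4L, ceiling(n_branches / 2) + 3L)
    pos <- c(0.5 + runif(1, -0.06, 0.06), 0.08, 0.5 + runif(1, -0.06, 0.06))
    dirv <- .unit3(c(runif(1, -0.2, 0.2), 1, runif(1, -0.2, 0.2)))
    r <- r0
    arr <- 0
    trunk_idx <- integer(m)
    parent <- 0L
    for (i in seq_len(m)) {
      len <- runif(1, 0.10, 0.15)
      dirv <- .unit3(dirv + c(rnorm(1, 0, 0.18), 0.1, rnorm(1, 0, 0.18)))
      p1 <- pmin(pmax(pos + dirv * len, 0.06), 0.94)
      arr1 <- arr + sqrt(sum((p1 - pos)^2)) / speed
      parent <- add_seg(pos, p1, r, parent, "trunk", arr1)
      trunk_idx[i] <- parent
      pos <- p1
      arr <- arr1
      r <- r * runif(1, 0.96, 1.0)
    }

    # side branches: chains of 2 segments sprouting from trunk nodes
    branch_tips <- integer(0)
    for (b in seq_len(n_branches)) {
      at <- trunk_idx[1L + (b - 1L) %% (m - 1L)]
      s <- segs[[at]]
      base <- s[4:6]
      tdir <- .unit3(s[4:6] - s[1:3])
      side <- .unit3(c(rnorm(1), 0.2, rnorm(1)))
      bdir <- .unit3(0.55 * tdir + side * runif(1, 0.7, 1.1) * sample(c(-1, 1), 1))
      br <- s[7] * 0.79 * runif(1, 0.9, 1.0)
      bp <- at
      barr <- arrival[at]
      bpos <- base
      for (k in 1:2) {
        len <- runif(1, 0.08, 0.14)
        bdir <- .unit3(bdir + c(rnorm(1, 0, 0.2), 0.15, rnorm(1, 0, 0.2)))
        p1 <- pmin(pmax(bpos + bdir * len, 0.06), 0.94)
        barr <- barr + sqrt(sum((p1 - bpos)^2)) / speed
        bp <- add_seg(bpos, p1, br, bp, "branch", barr)
        bpos <- p1
        br <- br * runif(1, 0.95, 1.0)
      }
      branch_tips <- c(branch_tips, bp)
    }

    tree <- list(segments = NULL, arrival_time = NULL,
                 morphology_class = morphology_class,
                 domain_px = as.integer(domain_px), aneurysm = NULL)

    to_df <- function() {
      df <- as.data.frame(do.call(rbind, lapply(segs, unclass)))
      names(df) <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "parent")
      df$parent <- as.integer(df$parent)
      df$kind <- vapply(segs, function(s) attr(s, "kind"), character(1))
      df
    }

    if (morphology_class == "stenosis") {
      # split a mid-trunk segment into pre / narrow / post collinear parts
      i <- trunk_idx[max(2L, m %/% 2L)]
      s <- segs[[i]]
      p0 <- s[1:3]; p1 <- s[4:6]; r_i <- s[7]; par <- as.integer(s[8])
      a <- p0 + 0.40 * (p1 - p0)
      b <- p0 + 0.60 * (p1 - p0)
      arr_i <- arrival[i]
      kids <- which(vapply(segs, function(x) as.integer(x[8]), integer(1)) == i)
      segs[[i]] <- c(p0, a, r_i, par)
      attr(segs[[i]], "kind") <- "trunk"
      narrow <- add_seg(a, b, 0.40 * r_i, i, "stenosis", arr_i)
      post <- add_seg(b, p1, r_i, narrow, "post_stenosis", arr_i)
      for (kid in kids) segs[[kid]][8] <- post
      arrival[narrow] <- arr_i
      arrival[post] <- arr_i
    } else if (morphology_class == "aneurysm") {
      at <- trunk_idx[2L]
      s <- segs[[at]]
      off <- .unit3(c(rnorm(1), rnorm(1, 0, 0.3), rnorm(1))) * (2.2 * s[7] / domain_px)
      tree$aneurysm <- list(center = s[4:6] + off,
                            radius_px = 2.2 * s[7],
                            parent_seg = at)
    } else if (morphology_class == "av_shunt") {
      a_idx <- trunk_idx[min(3L, m)]
      v_idx <- branch_tips[length(branch_tips)]
      from <- segs[[a_idx]][4:6]
      to <- segs[[v_idx]][4:6] + rnorm(3, 0, 0.01)
      add_seg(from, pmin(pmax(to, 0.06), 0.94), 0.6, a_idx, "shunt",
              arrival[a_idx] + 0.5)
    } else if (morphology_class == "collateral_net") {
      at <- branch_tips[1L]
      pos_c <- segs[[at]][4:6]
      prev <- at
      rr <- min(0.55, segs[[at]][7])
      arr_c <- arrival[at]
      for (k in 1:12) {
        stp <- c(rnorm(1, 0, 0.03), abs(rnorm(1, 0.015, 0.015)), rnorm(1, 0, 0.03))
        p1 <- pmin(pmax(pos_c + stp, 0.06), 0.94)
        arr_c <- arr_c + sqrt(sum(stp^2)) / (speed * 0.5)
        prev <- add_seg(pos_c, p1, rr, prev, "collateral", arr_c)
        pos_c <- p1
        rr <- rr * 0.995
        if (k %% 4 == 0) { prev <- at; pos_c <- segs[[at]][4:6]; arr_c <- arrival[at]; rr <- min(0.55, segs[[at]][7]) }
      }
    }

    tree$segments <- to_df()
    tree$arrival_time <- arrival
    class(tree) <- "vessel_tree"
    validate_vessel_tree(tree)
    tree
  })
}

#' Validate vessel-tree invariants
#'
#' Checks connectivity (every non-root parent index is a valid earlier
#' segment), strictly positive radii, the branching taper (child radius
#' <= parent radius, except immediately distal to a stenosis, where the
#' lumen recovers by construction), and arrival times non-decreasing
#' from root to leaf.
#'
#' @param tree a `vessel_tree`
#' @return `tree` invisibly; stops on violation.
#' @export
validate_vessel_tree <- function(tree) {
  df <- tree$segments
  n <- nrow(df)
  if (any(df$radius <= 0)) stop("vessel radii must be strictly positive")
  for (i in seq_len(n)) {
    p <- df$parent[i]
    if (p == 0L) next
    if (p < 1L || p > n) stop("invalid parent index for segment ", i)
    if (df$kind[p] != "stenosis" && df$radius[i] > df$radius[p] + 1e-9)
      stop("child radius exceeds parent radius at segment ", i)
    if (tree$arrival_time[i] < tree$arrival_time[p] - 1e-9)
      stop("arrival time decreases from parent to child at segment ", i)
  }
  invisible(tree)
}

#' Gamma-variate bolus opacity per segment
#'
#' Each segment's contrast opacity follows the gamma-variate curve
#' `c(t) = ((t - t0)/tp)^alpha * exp(alpha * (1 - (t - t0)/tp))` for
#' `t > t0` and 0 otherwise, where `t0` is the segment's bolus arrival
#' time.  The curve peaks at exactly 1 when `t = t0 + tp`.
#'
#' @param tree a `vessel_tree`
#' @param t_peak time to peak `tp` in frames (> 0)
#' @param alpha shape parameter (> 0); larger values give a narrower bolus
#' @param n_frames number of frames (>= 2); frame times are 0-based indices
#'
#' @return An `n_segments x n_frames` opacity matrix in \[0, 1\].
#' @export
simulate_bolus <- function(tree, t_peak = 4, alpha = 2, n_frames = 16L) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (t_peak <= 0 || alpha <= 0) stop("t_peak and alpha must be positive")
  times <- seq_len(n_frames) - 1
  t0 <- tree$arrival_time
  op <- matrix(0, nrow(tree$segments), n_frames)
  for (i in seq_along(t0)) {
    dt <- times - t0[i]
    pos <- dt > 0
    u <- dt[pos] / t_peak
    op[i, pos] <- u^alpha * exp(alpha * (1 - u))
  }
  op
}

# smooth low-frequency random field in [0, 1], seeded by the caller's RNG
.smooth_field <- function(h, w, n_modes = 4L) {
  ii <- matrix(seq_len(h) / h, h, w)
  jj <- matrix(rep(seq_len(w) / w, each = h), h, w)
  f <- matrix(0, h, w)
  for (k in seq_len(n_modes)) {
    f <- f + rnorm(1) * cos(2 * pi * (runif(1, 0.4, 1.6) * ii +
                                      runif(1, 0.4, 1.6) * jj + runif(1)))
  }
  rng <- range(f)
  if (diff(rng) == 0) return(f * 0)
  (f - rng[1]) / diff(rng)
}

.project_segments <- function(df, angle_deg, resolution, scale) {
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  px <- function(x, z) ((x - 0.5) * co + (z - 0.5) * si + 0.5) * (resolution - 1)
  cbind(px(df$x0, df$z0), df$y0 * (resolution - 1),
        px(df$x1, df$z1), df$y1 * (resolution - 1),
        pmax(df$radius * scale, 0.35))
}

.guidewire_path <- function(resolution) {
  # fixed-shape smooth curve entering from the left edge; caller's RNG jitters it
  xs <- c(0, 0.3, 0.55, 0.75, 0.88) + c(0, rnorm(4, 0, 0.02))
  ys <- c(0.55, 0.48, 0.55, 0.42, 0.5) + c(0, rnorm(4, 0, 0.03))
  sx <- stats::spline(seq_along(xs), xs, n = 400)$y
  sy <- stats::spline(seq_along(ys), ys, n = 400)$y
  steps <- sqrt(diff(sx)^2 + diff(sy)^2)
  alen <- c(0, cumsum(steps))
  cbind(x = sx * (resolution - 1), y = sy * (resolution - 1), s = alen / max(alen))
}

#' Render a frame sequence from a vessel tree
#'
#' Vessels are rasterized as anti-aliased thick segments accumulating
#' optical density (darkness), drawn over a smooth light background with
#' Gaussian noise.  In 3D mode the tree rotates about the vertical axis,
#' with per-frame angles spanning 0 to 180 degrees uniformly.  An optional
#' guidewire advances along a fixed smooth path at constant arc length per
#' frame; its tip coordinates are recorded as ground truth.
#'
#' @param tree a `vessel_tree`
#' @param opacity per-segment opacity matrix from [simulate_bolus()]
#' @param n_frames number of frames (defaults to `ncol(opacity)`)
#' @param mode `"2D"` or `"3D"`
#' @param resolution output size in pixels (>= 32)
#' @param guidewire add a moving guidewire with ground-truth tip
#' @param seed integer seed for background/noise/guidewire jitter
#' @param invert if `TRUE`, invert the display convention (vessels bright)
#' @param noise_sd Gaussian noise standard deviation
#' @param background_level mean background intensity
#'
#' @return `list(sequence = frame_sequence, truth = list(vessel_mask,
#'   tic_points, tip_xy))`.  `tic_points` holds three annotated vessel
#'   pixels (proximal / mid or stenotic / distal) with their true
#'   normalized time-intensity series; `tip_xy` is a frames x 2 matrix of
#'   0-based (x, y) tip coordinates or `NULL`.
#' @export
render_sequence <- function(tree, opacity, n_frames = ncol(opacity),
                            mode = c("2D", "3D"), resolution = 128L,
                            guidewire = FALSE, seed = 1L, invert = FALSE,
                            noise_sd = 0.01, background_level = 0.85) {
  mode <- match.arg(mode)
  if (resolution < 32) stop("resolution must be >= 32")
  if (n_frames > ncol(opacity)) stop("opacity matrix has too few frames")
  df <- tree$segments
  scale <- resolution / 128
  angles <- if (mode == "3D") seq(0, 180, length.out = n_frames) else rep(0, n_frames)

  with_seed(seed, {
    bg <- background_level + 0.06 * (.smooth_field(resolution, resolution) - 0.5)
    gw <- if (guidewire) .guidewire_path(resolution) else NULL
    frames <- array(0, dim = c(resolution, resolution, n_frames))
    mask <- array(FALSE, dim = c(resolution, resolution, n_frames))
    tip_xy <- if (guidewire) matrix(NA_real_, n_frames, 2) else NULL

    for (t in seq_len(n_frames)) {
      segs <- .project_segments(df, angles[t], resolution, scale)
      dens <- opacity[, t] * (0.30 + 0.08 * pmin(df$radius, 4))
      D <- cpp_draw_segments(resolution, resolution, segs, dens)
      D <- pmin(D, 0.6)
      if (!is.null(tree$aneurysm)) {
        an <- tree$aneurysm
        th <- angles[t] * pi / 180
        cx <- ((an$center[1] - 0.5) * cos(th) + (an$center[3] - 0.5) * sin(th) + 0.5) * (resolution - 1)
        cy <- an$center[2] * (resolution - 1)
        D <- cpp_draw_disc(D, cx, cy, an$radius_px * scale,
                           opacity[an$parent_seg, t] * 0.55)
        D <- pmin(D, 0.65)
      }
      if (guidewire) {
        frac <- 0.25 + 0.7 * (t - 1) / max(n_frames - 1, 1)  # constant advance
        keep <- gw[, "s"] <= frac
        pts <- gw[keep, , drop = FALSE]
        tip_xy[t, ] <- pts[nrow(pts), c("x", "y")]
        if (nrow(pts) >= 3) {
          # pull the drawn end back by one capsule half-width so the
          # rounded rasterization cap lands at the recorded tip
          hw <- 0.7 * scale
          k <- nrow(pts)
          dvec <- pts[k, c("x", "y")] - pts[k - 1, c("x", "y")]
          dlen <- sqrt(sum(dvec^2))
          if (dlen > 0) pts[k, c("x", "y")] <- pts[k, c("x", "y")] -
            dvec / dlen * min(hw, dlen)
          wsegs <- cbind(pts[-k, "x"], pts[-k, "y"],
                         pts[-1, "x"], pts[-1, "y"], hw)
          G <- cpp_draw_segments(resolution, resolution, wsegs,
                                 rep(1.2, nrow(wsegs)))
          D <- D + pmin(G, 1.2)
        }
      }
      noise <- matrix(rnorm(resolution^2, 0, noise_sd), resolution, resolution)
      fr <- pmin(pmax(bg + noise - D, 0.02), 1)
      if (invert) fr <- 1 - fr
      frames[, , t] <- fr
      cov <- cpp_draw_segments(resolution, resolution, segs,
                               as.numeric(opacity[, t] > 0.05))
      mask[, , t] <- cov > 0.5
    }

    # annotated TIC pixels: proximal trunk, mid (stenotic if present), distal
    mid_seg <- if (any(df$kind == "stenosis")) which(df$kind == "stenosis")[1]
               else max(1L, nrow(df) %/% 2L)
    distal_seg <- which.max(tree$arrival_time)
    tic_points <- lapply(c(proximal = 1L, mid = mid_seg, distal = distal_seg),
      function(i) {
        s0 <- .project_segments(df[i, , drop = FALSE], angles[1], resolution, scale)
        list(pixel = round(c((s0[1] + s0[3]) / 2, (s0[2] + s0[4]) / 2)),
             series = opacity[i, seq_len(n_frames)])
      })

    fs <- frame_sequence(frames, mode = mode, angles_deg = angles)
    list(sequence = fs,
         truth = list(vessel_mask = mask, tic_points = tic_points,
                      tip_xy = tip_xy))
  })
}

#' Inject acquisition artifacts into a sequence
#'
#' Applies either local motion corruption (`"motion"`: pixels inside an
#' affected region are resampled from a smoothly displaced copy of the
#' frame) or subtraction ghosting (`"subtraction_ghost"`: a bright
#' low-frequency residual added inside the region), emulating incomplete
#' mask subtraction.  The affected region is the top `severity` fraction
#' of a seeded smooth random field, so the affected-pixel fraction is
#' monotone in `severity` and `severity = 0` returns the input unchanged.
#'
#' @param seq a [frame_sequence()]
#' @param severity fraction of pixels affected, in \[0, 1\]
#' @param kind `"motion"` or `"subtraction_ghost"`
#' @param frames_affected integer frame indices (default: all frames)
#' @param seed integer seed
#' @return A corrupted [frame_sequence()].
#' @export
inject_artifacts <- function(seq, severity,
                             kind = c("motion", "subtraction_ghost"),
                             frames_affected = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (severity == 0) return(seq)
  d <- dim(seq$frames)
  if (is.null(frames_affected)) frames_affected <- seq_len(d[3])

  with_seed(seed, {
    g <- .smooth_field(d[1], d[2], n_modes = 6L)
    k <- round(severity * d[1] * d[2])
    region <- array(FALSE, d[1:2])
    region[order(g, decreasing = TRUE)[seq_len(k)]] <- TRUE
    out <- seq$frames
    if (kind == "subtraction_ghost") {
      amp <- 0.08 + 0.30 * g
      for (t in frames_affected) {
        fr <- out[, , t]
        fr[region] <- pmin(fr[region] + amp[region], 1)
        out[, , t] <- fr
      }
    } else {
      dxf <- 3 * (.smooth_field(d[1], d[2]) - 0.5)
      dyf <- 3 * (.smooth_field(d[1], d[2]) - 0.5)
      flow <- array(c(dxf, dyf), dim = c(d[1], d[2], 2))
      for (t in frames_affected) {
        fr <- out[, , t]
        wr <- cpp_warp_forward(array(fr, c(d[1], d[2], 1)), flow)[, , 1]
        fr[region] <- wr[region]
        out[, , t] <- fr
      }
    }
    frame_sequence(out, frame_times = seq$frame_times, mode = seq$mode,
                   angles_deg = seq$angles_deg, pixel_spacing = seq$pixel_spacing)
  })
}
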