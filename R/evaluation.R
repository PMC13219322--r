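# Quantitative evaluation: SSIM / PSNR / MSE with bootstrap confidence
# intervals, residual maps, time-intensity-curve error, and guidewire
# tip localization error.

.ssim_window <- local({
  g <- outer(dnorm(-5:5, sd = 1.5), dnorm(-5:5, sd = 1.5))
  g / sum(g)
})

#' Structural similarity index (Gaussian-window form)
#'
#' 11x11 Gaussian window with sigma 1.5, K1 = 0.01, K2 = 0.03, data
#' range 1.0, computed over valid window positions.  Symmetric in its
#' arguments.
#'
#' @param x,y matrices in \[0, 1\], at least 11 x 11
#' @return mean SSIM over the image
#' @export
ssim_index <- function(x, y, K1 = 0.01, K2 = 0.03, data_range = 1) {
  if (!identical(dim(x), dim(y))) stop("image shape mismatch")
  if (any(dim(x) < 11)) stop("images must be at least 11 x 11 for the SSIM window")
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  k <- array(.ssim_window, c(11, 11, 1, 1))
  zb <- 0
  gc <- function(m) cpp_conv2d_forward(array(m, c(dim(m), 1L)), k, zb, 1L, 0L)[, , 1]
  mx <- gc(x); my <- gc(y)
  sx <- gc(x * x) - mx^2
  sy <- gc(y * y) - my^2
  sxy <- gc(x * y) - mx * my
  mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
       ((mx^2 + my^2 + C1) * (sx + sy + C2)))
}

#' SSIM, PSNR and MSE between a generated and a real frame
#'
#' Inputs are expected in \[0, 1\] (rescale upstream from \[-1, 1\] with
#' `(x + 1) / 2`).  PSNR uses peak = 1.0 so `PSNR = -10 log10(MSE)`;
#' identical images give SSIM 1, MSE 0 and `Inf` PSNR.
#'
#' @param gen,real matrices in \[0, 1\], same shape
#' @return `list(ssim, psnr, mse)`
#' @export
compute_image_metrics <- function(gen, real) {
  if (!identical(dim(gen), dim(real))) stop("image shape mismatch")
  mse <- mean((gen - real)^2)
  psnr <- if (mse == 0) Inf else -10 * log10(mse)
  list(ssim = ssim_index(gen, real), psnr = psnr, mse = mse)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the per-sequence values with replacement `reps` times and
#' returns the percentile interval of the resampled means.
#' Deterministic for a fixed seed.
#'
#' @param values numeric vector (>= 2 values)
#' @param level confidence level (default 0.95)
#' @param reps bootstrap replicates
#' @param seed integer seed
#' @return `c(lo, hi)`
#' @export
bootstrap_ci <- function(values, level = 0.95, reps = 1000L, seed = 1L) {
  if (length(values) < 2) stop("need at least 2 values")
  if (max(values) == min(values)) return(c(values[1], values[1]))
  means <- with_seed(seed, vapply(seq_len(reps), function(i)
    mean(sample(values, replace = TRUE)), numeric(1)))
  a <- (1 - level) / 2
  unname(quantile(means, c(a, 1 - a), type = 7))
}

#' Evaluate generated sequences against real ones
#'
#' Computes per-frame SSIM/PSNR/MSE on \[0, 1\]-rescaled frames,
#' aggregates per sequence, and reports means with 95% percentile
#' bootstrap intervals resampled over sequences.
#'
#' @param gen_list,real_list lists of H x W x T arrays (or
#'   [frame_sequence()]s) in \[-1, 1\] or \[0, 1\]
#' @param frame_subset optional frame indices to score (e.g. only
#'   synthesized frames); default all
#' @param reps,seed bootstrap parameters
#' @return a `metric_report` list: per-metric mean, CI, per-sequence and
#'   per-frame values, `n_sequences`
#' @export
evaluate_sequences <- function(gen_list, real_list, frame_subset = NULL,
                               reps = 1000L, seed = 1L) {
  stopifnot(length(gen_list) == length(real_list))
  as01 <- function(a) {
    a <- if (inherits(a, "frame_sequence")) a$frames else a
    if (min(a) < 0) (a + 1) / 2 else a
  }
  per_seq <- lapply(seq_along(gen_list), function(i) {
    g <- as01(gen_list[[i]])
    r <- as01(real_list[[i]])
    ts <- frame_subset %||% seq_len(dim(g)[3])
    vals <- vapply(ts, function(t) {
      m <- compute_image_metrics(g[, , t], r[, , t])
      c(m$ssim, m$psnr, m$mse)
    }, numeric(3))
    data.frame(sequence = i, frame = ts, ssim = vals[1, ], psnr = vals[2, ],
               mse = vals[3, ])
  })
  per_frame <- do.call(rbind, per_seq)
  agg <- function(metric) {
    v <- vapply(per_seq, function(df) mean(df[[metric]][is.finite(df[[metric]])]),
                numeric(1))
    ci <- if (length(v) >= 2) bootstrap_ci(v, reps = reps, seed = seed)
          else c(v, v)
    list(mean = mean(v), ci = ci, per_sequence = v)
  }
  structure(list(ssim = agg("ssim"), psnr = agg("psnr"), mse = agg("mse"),
                 per_frame = per_frame, n_sequences = length(gen_list)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d sequences\n", x$n_sequences))
  cat(sprintf("  SSIM %.4f [%.4f, %.4f]\n", x$ssim$mean, x$ssim$ci[1], x$ssim$ci[2]))
  cat(sprintf("  PSNR %.3f dB [%.3f, %.3f]\n", x$psnr$mean, x$psnr$ci[1], x$psnr$ci[2]))
  cat(sprintf("  MSE  %.6f\n", x$mse$mean))
  invisible(x)
}

#' Residual map between generated and real frames
#'
#' Absolute difference plus a 10x amplified, clipped display variant
#' mirroring zoomed residual inspection.
#'
#' @param gen,real matrices, same shape
#' @return `list(residual, amplified)`
#' @export
residual_map <- function(gen, real) {
  if (!identical(dim(gen), dim(real))) stop("image shape mismatch")
  r <- abs(gen - real)
  list(residual = r, amplified = pmin(10 * r, 1))
}

#' Time-intensity-curve error at annotated pixels
#'
#' Each pixel's temporal intensity series is min-max normalized to
#' \[0, 1\] independently for the generated and the real sequence; the
#' error is the maximum absolute difference over time and pixels.  The
#' normalization makes the measure invariant to per-pixel affine
#' intensity distortions.
#'
#' @param gen_seq,real_seq H x W x T arrays (or [frame_sequence()]s)
#' @param pixels list of 0-based `c(x, y)` pixel coordinates
#' @return `list(max_error, per_pixel)` with per-pixel max errors
#' @export
time_intensity_error <- function(gen_seq, real_seq, pixels) {
  g <- if (inherits(gen_seq, "frame_sequence")) gen_seq$frames else gen_seq
  r <- if (inherits(real_seq, "frame_sequence")) real_seq$frames else real_seq
  if (dim(g)[3] != dim(r)[3]) stop("sequences must have the same length")
  norm01 <- function(v) {
    rg <- range(v)
    if (rg[1] == rg[2]) return(v * 0)
    (v - rg[1]) / (rg[2] - rg[1])
  }
  errs <- vapply(pixels, function(p) {
    i <- p[2] + 1L  # row from y
    j <- p[1] + 1L  # col from x
    if (i < 1 || j < 1 || i > dim(g)[1] || j > dim(g)[2])
      stop("TIC pixel out of bounds")
    max(abs(norm01(g[i, j, ]) - norm01(r[i, j, ])))
  }, numeric(1))
  list(max_error = max(errs), per_pixel = errs)
}

# 8-connected component containing the most pixels of a binary matrix
.largest_component <- function(bin) {
  lab <- matrix(0L, nrow(bin), ncol(bin))
  cur <- 0L
  H <- nrow(bin); W <- ncol(bin)
  for (j0 in seq_len(W)) for (i0 in seq_len(H)) {
    if (!bin[i0, j0] || lab[i0, j0]) next
    cur <- cur + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= H && j >= 1 && j <= W && bin[i, j] && !lab[i, j]) {
          lab[i, j] <- cur
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  if (cur == 0L) return(bin & FALSE)
  best <- which.max(tabulate(lab[lab > 0L], cur))
  lab == best
}

#' Localize a guidewire tip in one frame
#'
#' Thresholds the darkest pixels, keeps the largest connected
#' component (the wire), skeletonizes it (Zhang-Suen) to confirm a
#' curvilinear shape, and returns the distal tip: the component pixel
#' at maximal geodesic (along-structure) distance from the wire's
#' entry point, taken as the component pixel nearest the image border.
#' Working on the full component rather than the skeleton avoids the
#' 1-2 px end-erosion of thinning.
#'
#' @param frame intensity matrix in \[0, 1\] (vessels/wire dark)
#' @param threshold intensity below which a pixel is wire candidate
#' @return 0-based `c(x, y)` tip coordinates, or `NULL` if no
#'   curvilinear structure is found
#' @export
locate_guidewire_tip <- function(frame, threshold = 0.12) {
  bin <- frame < threshold
  if (sum(bin) < 5) return(NULL)
  comp <- .largest_component(bin)
  sk <- cpp_thin(matrix(as.integer(comp), nrow(comp), ncol(comp)))
  if (sum(sk) < 3) return(NULL)         # not curvilinear
  if (sum(sk) < 0.05 * sum(comp)) return(NULL)  # blob, not a wire
  H <- nrow(frame); W <- ncol(frame)
  pts <- which(comp, arr.ind = TRUE)
  bdist <- pmin(pts[, 1] - 1, H - pts[, 1], pts[, 2] - 1, W - pts[, 2])
  entry <- pts[which.min(bdist), ]
  # BFS geodesic distance from the entry over the 8-connected component
  dist <- matrix(NA_real_, H, W)
  dist[entry[1], entry[2]] <- 0
  queue <- list(entry)
  qi <- 1L
  while (qi <= length(queue)) {
    p <- queue[[qi]]
    qi <- qi + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i <- p[1] + di; j <- p[2] + dj
      if (i < 1 || i > H || j < 1 || j > W) next
      if (!comp[i, j] || !is.na(dist[i, j])) next
      dist[i, j] <- dist[p[1], p[2]] + sqrt(di^2 + dj^2)
      queue[[length(queue) + 1L]] <- c(i, j)
    }
  }
  # sub-pixel tip: centroid of the pixels within 1 px (geodesically) of
  # the farthest point, i.e. the rounded end cap
  dmax <- max(dist, na.rm = TRUE)
  cap <- which(!is.na(dist) & dist >= dmax - 1, arr.ind = TRUE)
  c(mean(cap[, 2]) - 1, mean(cap[, 1]) - 1)  # (x, y), 0-based
}

#' Guidewire tip displacement error
#'
#' Localizes the tip in every generated frame and reports the Euclidean
#' distance to the ground-truth tip.  Frames where no curvilinear
#' structure is detected are flagged and excluded from the mean.
#'
#' @param gen_seq H x W x T array (or [frame_sequence()]) in \[0, 1\]
#' @param real_tip_xy T x 2 matrix of true 0-based (x, y) tip positions
#' @param threshold see [locate_guidewire_tip()]
#' @return `list(per_frame, mean_error, max_error, n_flagged, flagged)`
#' @export
guidewire_tip_error <- function(gen_seq, real_tip_xy, threshold = 0.12) {
  g <- if (inherits(gen_seq, "frame_sequence")) gen_seq$frames else gen_seq
  Tn <- dim(g)[3]
  if (nrow(real_tip_xy) != Tn) stop("one ground-truth tip per frame required")
  err <- rep(NA_real_, Tn)
  for (t in seq_len(Tn)) {
    tip <- locate_guidewire_tip(g[, , t], threshold)
    if (!is.null(tip))
      err[t] <- sqrt(sum((tip - real_tip_xy[t, ])^2))
  }
  flagged <- which(is.na(err))
  ok <- err[!is.na(err)]
  list(per_frame = err,
       mean_error = if (length(ok)) mean(ok) else NA_real_,
       max_error = if (length(ok)) max(ok) else NA_real_,
       n_flagged = length(flagged), flagged = flagged)
}
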