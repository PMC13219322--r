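# Standardization pipeline: pad-to-square, bilinear resize, crop,
# min-max intensity normalization to [-1, 1], and timestep assignment.

#' Preprocessing configuration
#'
#' @param train_size square training resolution in px (default 128)
#' @param finetune_crop square fine-tuning crop size in px (default 512)
#' @param pad_value padding intensity; `NULL` uses each image's minimum,
#'   which marks padding as vessel-free background under the dark-vessel
#'   convention.
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(train_size = 128L, finetune_crop = 512L,
                              pad_value = NULL) {
  if (train_size <= 0 || finetune_crop <= 0) stop("sizes must be positive")
  if (train_size > finetune_crop) stop("train_size must be <= finetune_crop")
  structure(list(train_size = as.integer(train_size),
                 finetune_crop = as.integer(finetune_crop),
                 pad_value = pad_value),
            class = "preprocess_config")
}

#' Pad an image to a square and resize
#'
#' The image is first padded symmetrically to `max(H, W)` x `max(H, W)`
#' (preserving the aspect ratio of the content — no anisotropic scaling)
#' and then resampled bilinearly to `target` x `target`.  Already-square
#' images at the target size are returned unchanged.
#'
#' @param image numeric matrix (H x W)
#' @param target output side length in px
#' @param pad_value padding intensity; default is the image minimum
#' @return a `target` x `target` matrix
#' @export
pad_and_resize <- function(image, target, pad_value = NULL) {
  if (!is.matrix(image) || nrow(image) < 1 || ncol(image) < 1)
    stop("`image` must be a non-empty matrix")
  h <- nrow(image); w <- ncol(image)
  if (is.null(pad_value)) pad_value <- min(image)
  side <- max(h, w)
  if (h != w) {
    sq <- matrix(pad_value, side, side)
    r0 <- (side - h) %/% 2L
    c0 <- (side - w) %/% 2L
    sq[r0 + seq_len(h), c0 + seq_len(w)] <- image
  } else sq <- image
  if (side == target) return(sq)
  cpp_resize_bilinear(sq, as.integer(target), as.integer(target))
}

#' Min-max normalize an image to [-1, 1]
#'
#' Maps the minimum to -1 and the maximum to +1 via
#' `2 * (x - min) / (max - min) - 1`.  A constant image maps to all
#' zeros (degenerate case).
#'
#' @param image numeric array with finite values
#' @return array of the same shape with range \[-1, 1\]
#' @export
minmax_normalize <- function(image) {
  if (any(!is.finite(image))) stop("`image` contains NaN or infinite values")
  rng <- range(image)
  if (rng[1] == rng[2]) return(image * 0)
  2 * (image - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Normalize a whole sequence to [-1, 1]
#'
#' `per = "frame"` applies [minmax_normalize()] to each frame
#' independently (the default reading of per-image min-max);
#' `per = "sequence"` uses the global range so that relative intensities
#' across time — and hence time-intensity curves — are preserved.
#'
#' @param seq a [frame_sequence()]
#' @param per `"frame"` or `"sequence"`
#' @return a [frame_sequence()] with frames in \[-1, 1\]
#' @export
normalize_sequence <- function(seq, per = c("frame", "sequence")) {
  per <- match.arg(per)
  fr <- seq$frames
  if (per == "sequence") {
    fr <- minmax_normalize(fr)
  } else {
    for (t in seq_len(dim(fr)[3])) fr[, , t] <- minmax_normalize(fr[, , t])
  }
  frame_sequence(fr, frame_times = seq$frame_times, mode = seq$mode,
                 angles_deg = seq$angles_deg, pixel_spacing = seq$pixel_spacing)
}

#' Crop a square region from an image
#'
#' Center placement is deterministic; random placement (seeded) is used
#' for fine-tuning so crops focus on varying vascular regions.
#'
#' @param image numeric matrix
#' @param size crop side length
#' @param placement `"center"` or `"random"`
#' @param seed seed for random placement
#' @return `size` x `size` matrix
#' @export
crop_image <- function(image, size, placement = c("center", "random"), seed = 1L) {
  placement <- match.arg(placement)
  h <- nrow(image); w <- ncol(image)
  if (size > h || size > w) stop("crop size exceeds image dimensions")
  if (placement == "center") {
    r0 <- (h - size) %/% 2L
    c0 <- (w - size) %/% 2L
  } else {
    off <- with_seed(seed, c(sample.int(h - size + 1L, 1L),
                             sample.int(w - size + 1L, 1L))) - 1L
    r0 <- off[1]; c0 <- off[2]
  }
  image[r0 + seq_len(size), c0 + seq_len(size)]
}

#' Uniform timesteps on [-1, 1]
#'
#' Assigns `t_i = -1 + 2 i / (n - 1)` for `i = 0, ..., n-1`: the first
#' frame gets exactly -1, the last exactly +1, and interior frames are
#' evenly spaced (the conditioning variable of the interpolation model).
#'
#' @param n_frames number of frames (>= 2)
#' @return numeric vector of length `n_frames`
#' @export
assign_timesteps <- function(n_frames) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  -1 + 2 * (seq_len(n_frames) - 1) / (n_frames - 1)
}

#' Preprocess a sequence for training
#'
#' Pads, resizes and normalizes every frame, returning frames in
#' \[-1, 1\] at `size` x `size`.
#'
#' @param seq a [frame_sequence()]
#' @param size target side length
#' @param per normalization scope, see [normalize_sequence()]
#' @return a [frame_sequence()]
#' @export
preprocess_sequence <- function(seq, size = 128L, per = "frame") {
  fr <- seq$frames
  out <- array(0, dim = c(size, size, dim(fr)[3]))
  for (t in seq_len(dim(fr)[3])) out[, , t] <- pad_and_resize(fr[, , t], size)
  normalize_sequence(
    frame_sequence(out, frame_times = seq$frame_times, mode = seq$mode,
                   angles_deg = seq$angles_deg, pixel_spacing = seq$pixel_spacing),
    per = per)
}
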