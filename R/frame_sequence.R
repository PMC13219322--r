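# FrameSequence: the package's container for grayscale angiographic
# sequences.  Frames are stored as an H x W x T array (frame t is
# frames[, , t]); intensities are in [0, 1] unless a preprocessing step
# has rescaled them.

#' Construct a frame sequence
#'
#' @param frames numeric H x W x T array of intensities.
#' @param frame_times numeric vector of length T, strictly increasing.
#'   Defaults to 0-based frame indices (1 frame = 1 time unit).
#' @param mode acquisition mode, `"2D"` (fixed view) or `"3D"`
#'   (continuous C-arm rotation).
#' @param angles_deg per-frame C-arm angle in degrees.  All zero for 2D;
#'   must be monotone non-decreasing for 3D.
#' @param pixel_spacing pixel spacing in mm/px (metadata only).
#'
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_times = NULL,
                           mode = c("2D", "3D"), angles_deg = NULL,
                           pixel_spacing = 0.3) {
  mode <- match.arg(mode)
  if (length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array")
  d <- dim(frames)
  if (d[3] < 2L) stop("a frame sequence needs at least 2 frames")
  if (d[1] < 16L || d[2] < 16L) stop("frames must be at least 16 x 16 pixels")
  n <- d[3]
  if (is.null(frame_times)) frame_times <- seq_len(n) - 1
  if (length(frame_times) != n || any(diff(frame_times) <= 0))
    stop("`frame_times` must be strictly increasing, one per frame")
  if (is.null(angles_deg)) angles_deg <- rep(0, n)
  if (length(angles_deg) != n) stop("`angles_deg` must have one angle per frame")
  if (mode == "3D" && any(diff(angles_deg) < 0))
    stop("3D sequences require monotone angles")
  structure(list(frames = frames, frame_times = frame_times, mode = mode,
                 angles_deg = angles_deg, pixel_spacing = pixel_spacing),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, mode %s, angles %.0f-%.0f deg\n",
              d[3], d[1], d[2], x$mode, min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) dim(x$frames)[3]

#' Extract one frame as a matrix
#' @param seq a [frame_sequence()]
#' @param t frame index (1-based)
#' @export
get_frame <- function(seq, t) seq$frames[, , t]

# --- plain-text image I/O ---------------------------------------------------
# Frames are written as one 16-bit ASCII PGM (P2) per frame plus a JSON
# sidecar carrying mode/angles/times/spacing.  PGM is used instead of TIFF
# because it is a plain-text standard format that round-trips without any
# imaging dependency.

.write_pgm <- function(mat, path, maxval = 65535L) {
  v <- as.integer(round(pmin(pmax(mat, 0), 1) * maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  m <- matrix(v, nrow(mat), ncol(mat))
  # row-major pixel order per PGM convention
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

.read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1] != "P2") stop("only ASCII (P2) PGM is supported: ", path)
  w <- as.integer(txt[2]); h <- as.integer(txt[3]); maxval <- as.numeric(txt[4])
  v <- as.numeric(txt[-(1:4)])
  matrix(v, h, w, byrow = TRUE) / maxval
}

#' Write a frame sequence to a directory
#'
#' Emits `frame_%04d.pgm` (16-bit ASCII PGM) per frame plus
#' `sequence.json` with acquisition metadata, and optionally the ground
#' truth (`ground_truth.json` + per-frame `mask_%04d.pgm`).
#'
#' @param seq a [frame_sequence()]
#' @param dir output directory (created if missing)
#' @param truth optional ground-truth list from [render_sequence()]
#' @return `dir`, invisibly.
#' @export
write_frame_sequence <- function(seq, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(seq)
  for (t in seq_len(n))
    .write_pgm(seq$frames[, , t], file.path(dir, sprintf("frame_%04d.pgm", t)))
  meta <- list(mode = seq$mode, angles_deg = seq$angles_deg,
               frame_times = seq$frame_times, pixel_spacing = seq$pixel_spacing)
  jsonlite::write_json(meta, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    gt <- list(tip_xy = truth$tip_xy,
               tic_points = lapply(truth$tic_points, function(p)
                 list(pixel = p$pixel, series = p$series)))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(truth$vessel_mask))
      for (t in seq_len(n))
        .write_pgm(truth$vessel_mask[, , t] * 1, file.path(dir, sprintf("mask_%04d.pgm", t)),
                   maxval = 1L)
  }
  invisible(dir)
}

#' Read a frame sequence written by [write_frame_sequence()]
#' @param dir directory containing `frame_*.pgm` and `sequence.json`
#' @return a [frame_sequence()]
#' @export
read_frame_sequence <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sequence.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.pgm$", full.names = TRUE))
  if (!length(files)) stop("no frame_*.pgm files in ", dir)
  mats <- lapply(files, .read_pgm)
  frames <- array(unlist(mats), dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  frame_sequence(frames, frame_times = meta$frame_times, mode = meta$mode,
                 angles_deg = meta$angles_deg, pixel_spacing = meta$pixel_spacing)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so
#' that generator calls are reproducible without disturbing the session.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
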