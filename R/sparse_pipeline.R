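# Sparse acquisition and reconstruction: acquire 1 real frame per
# (N+1)-frame block, synthesize the N interior frames, reassemble, and
# account for radiation dose (dose is strictly proportional to the number
# of acquired frames at fixed exposure parameters).

#' Acquisition protocol
#'
#' @param n_generated N, the number of frames generated per real frame
#'   acquired (0 <= N <= 8, the evaluated range)
#' @return list with `n_generated`, `block` (N+1), `dose_fraction`
#'   (1/(N+1)) and `percent_reduction` (100 N/(N+1))
#' @export
acquisition_protocol <- function(n_generated) {
  if (n_generated < 0) stop("N must be >= 0")
  if (n_generated > 8) stop("N must be <= 8 (evaluated protocol range)")
  N <- as.integer(n_generated)
  structure(list(n_generated = N, block = N + 1L,
                 dose_fraction = 1 / (N + 1),
                 percent_reduction = 100 * N / (N + 1)),
            class = "acquisition_protocol")
}

#' Radiation dose fraction under sparse acquisition
#'
#' Acquiring one real frame per (N+1)-frame block reduces the dose to
#' `1/(N+1)` of the full-sampling protocol; the companion percentage
#' reduction is `100 * N / (N+1)` (85.71% at N = 6).
#'
#' @param N frames generated per real frame (>= 0)
#' @return `list(dose_fraction, percent_reduction)`
#' @export
dose_fraction <- function(N) {
  if (N < 0) stop("N must be >= 0")
  list(dose_fraction = 1 / (N + 1), percent_reduction = 100 * N / (N + 1))
}

#' Subsample a sequence under the sparse protocol
#'
#' Keeps frames at indices `{0, N+1, 2(N+1), ...}` (0-based) plus the
#' final frame if it does not fall on the grid — a clinical sequence
#' always ends on a real frame, so a trailing partial block retains its
#' real endpoint.  Kept frames are bit-identical to the source.
#'
#' @param seq a [frame_sequence()] (or H x W x T array)
#' @param N frames to generate per real frame
#' @return `list(real_frames, real_indices)`; indices are 1-based into
#'   the original sequence
#' @export
subsample <- function(seq, N) {
  fr <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  N <- as.integer(N)
  L <- dim(fr)[3]
  if (L < N + 2) stop("sequence too short: need L >= N + 2 so there is something to synthesize")
  idx0 <- seq.int(0L, L - 1L, by = N + 1L)
  if (idx0[length(idx0)] != L - 1L) idx0 <- c(idx0, L - 1L)
  idx <- idx0 + 1L
  list(real_frames = fr[, , idx, drop = FALSE], real_indices = idx)
}

#' Linear-blend oracle interpolator
#'
#' `(1 - w) * frame0 + w * frame1` with `w = (t + 1)/2`; used as the
#' closed-form reference interpolator in pipeline tests and as the
#' baseline the trained model must beat.
#'
#' @param frame0,frame1 matrices
#' @param t timestep in (-1, 1)
#' @return interpolated matrix
#' @export
linear_blend_interpolator <- function(frame0, frame1, t) {
  w <- (t + 1) / 2
  (1 - w) * frame0 + w * frame1
}

#' Reconstruct a full sequence from sparse real frames
#'
#' Interior frame `i` of the block between real frames at (0-based)
#' indices `a < b` is synthesized at timestep `t = -1 + 2 (i - a)/(b - a)`
#' (the [assign_timesteps()] grid).  Real frames are passed through
#' bit-exact; the output has exactly `L` frames.  The interpolator is
#' pluggable: a trained model (via [model_interpolator()]) or a
#' closed-form oracle such as [linear_blend_interpolator()].
#'
#' @param real_frames H x W x K array of kept frames
#' @param real_indices sorted 1-based indices of the kept frames; must
#'   include 1 and `L`
#' @param L full sequence length
#' @param interpolator `function(frame0, frame1, t)` returning a matrix
#' @return H x W x L array
#' @export
reconstruct_sequence <- function(real_frames, real_indices, L, interpolator) {
  if (is.unsorted(real_indices, strictly = TRUE))
    stop("real_indices must be strictly increasing")
  if (real_indices[1] != 1L || real_indices[length(real_indices)] != L)
    stop("real_indices must include the first and last frame")
  d <- dim(real_frames)
  out <- array(NA_real_, c(d[1], d[2], L))
  for (k in seq_along(real_indices)) out[, , real_indices[k]] <- real_frames[, , k]
  for (k in seq_len(length(real_indices) - 1L)) {
    a <- real_indices[k]
    b <- real_indices[k + 1L]
    if (b - a < 2L) next  # adjacent real frames: nothing to synthesize
    f0 <- real_frames[, , k]
    f1 <- real_frames[, , k + 1L]
    for (i in (a + 1L):(b - 1L)) {
      t <- -1 + 2 * (i - a) / (b - a)
      out[, , i] <- interpolator(f0, f1, t)
    }
  }
  out
}

#' Wrap a trained model as a pipeline interpolator
#' @param model an interpolation model
#' @return `function(frame0, frame1, t)` for [reconstruct_sequence()]
#' @export
model_interpolator <- function(model) {
  function(frame0, frame1, t)
    synthesize_intermediate(synthesis_request(frame0, frame1, t), model)
}

#' Run the sparse-acquisition pipeline end to end
#'
#' Subsamples, reconstructs, and reports dose accounting.
#'
#' @param seq a [frame_sequence()]
#' @param N frames generated per real frame
#' @param interpolator see [reconstruct_sequence()]
#' @return `list(sequence, dose_report)`; the dose report holds N,
#'   acquired/total frame counts, dose fraction, and percent reduction
#' @export
sparse_reconstruct <- function(seq, N, interpolator) {
  L <- length(seq)
  sub <- subsample(seq, N)
  rec <- reconstruct_sequence(sub$real_frames, sub$real_indices, L, interpolator)
  dose <- dose_fraction(N)
  out <- frame_sequence(rec, frame_times = seq$frame_times, mode = seq$mode,
                        angles_deg = seq$angles_deg,
                        pixel_spacing = seq$pixel_spacing)
  list(sequence = out,
       dose_report = list(N = N, acquired = length(sub$real_indices),
                          total = L,
                          dose_fraction = length(sub$real_indices) / L,
                          nominal_dose_fraction = dose$dose_fraction,
                          percent_reduction = dose$percent_reduction))
}
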