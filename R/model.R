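# Flow-guided frame interpolation network.
#
# Layout: a shared multi-scale encoder with direction-aware convolution
# blocks (DACB), a coarse-to-fine bidirectional optical-flow estimator
# conditioned on the target timestep, a spatio-temporal attention
# bottleneck over the two warped coarse feature maps, and a decoder with
# skip connections producing a fusion mask and residual.  The synthesized
# frame is tanh(alpha * warp(frame0) + (1 - alpha) * warp(frame1) +
# residual), bounded to [-1, 1].
#
# Channel width at scale s is base_channels * 2^s.  All weights live in a
# flat named list of autodiff parameter nodes, so a model is an ordinary
# R list and serializes trivially.

#' Model configuration
#'
#' @param base_channels channels at the finest scale; widths double per
#'   scale (default 16; tests use 8 for speed)
#' @param n_scales number of pyramid scales (>= 2)
#' @param n_heads attention heads in the bottleneck
#' @param orientations DACB mask angles in degrees
#' @return a `model_config` list
#' @export
model_config <- function(base_channels = 16L, n_scales = 3L, n_heads = 4L,
                         orientations = c(0, 45, 90, 135)) {
  if (n_scales < 2) stop("n_scales must be >= 2")
  if (length(orientations) < 1) stop("at least one orientation is required")
  structure(list(base_channels = as.integer(base_channels),
                 n_scales = as.integer(n_scales),
                 n_heads = as.integer(n_heads),
                 orientations = orientations),
            class = "model_config")
}

#' Channel width at a pyramid scale
#' @param config a [model_config()]
#' @param s 0-based scale index
#' @export
channels_at_scale <- function(config, s) as.integer(config$base_channels * 2^as.integer(s))

#' Orientation mask for a 3x3 direction-aware kernel
#'
#' Returns a 0/1 matrix whose support is the line through the kernel
#' center at the given angle (0 = horizontal, 90 = vertical).
#'
#' @param angle_deg angle in degrees
#' @return 3x3 numeric matrix
#' @export
orientation_mask <- function(angle_deg) {
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))
  m <- matrix(0, 3, 3)
  for (di in -1:1) for (dj in -1:1) {
    p <- c(dj, -di)  # x right, y up
    if ((di == 0 && dj == 0) || abs(p[1] * u[2] - p[2] * u[1]) < 0.45)
      m[di + 2, dj + 2] <- 1
  }
  m
}

.conv_w <- function(k, cin, cout, gain = 1) {
  ad_param(array(rnorm(k * k * cin * cout, 0, gain * sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)))
}
.conv_b <- function(cout) ad_param(numeric(cout))
.mat_w <- function(nin, nout, gain = 1) {
  ad_param(matrix(rnorm(nin * nout, 0, gain * sqrt(1 / nin)), nin, nout))
}

.dacb_init <- function(P, prefix, cin, cout, orientations, init = "he") {
  K <- length(orientations)
  for (k in seq_len(K)) {
    mk <- orientation_mask(orientations[k])
    if (init == "aligned") {
      w <- array(0, c(3, 3, cin, cout))
      for (ci in seq_len(cin)) for (co in seq_len(cout))
        w[, , ci, co] <- mk / (sum(mk) * cin)
      P[[paste0(prefix, "_br", k, "_w")]] <- ad_param(w)
    } else {
      P[[paste0(prefix, "_br", k, "_w")]] <- .conv_w(3, cin, cout)
    }
    P[[paste0(prefix, "_br", k, "_b")]] <- .conv_b(cout)
  }
  P[[paste0(prefix, "_mix_w")]] <- .conv_w(1, K * cout, cout)
  P[[paste0(prefix, "_mix_b")]] <- .conv_b(cout)
  P
}

.dacb_fwd <- function(x, P, prefix, orientations, want_branches = FALSE) {
  K <- length(orientations)
  # fuse all orientation branches into one convolution: masked kernels are
  # concatenated along the output-channel axis, so a single im2col/GEMM
  # serves every branch (outputs are contiguous channel blocks)
  ws <- vector("list", K)
  bs <- vector("list", K)
  for (k in seq_len(K)) {
    w <- P[[paste0(prefix, "_br", k, "_w")]]
    mk <- orientation_mask(orientations[k])
    ws[[k]] <- ad_mul(w, ad_const(array(mk, dim(w$value))))
    bs[[k]] <- P[[paste0(prefix, "_br", k, "_b")]]
  }
  allout <- ad_conv2d(x, ad_concat_w4(ws), ad_concat_vec(bs))
  cat <- ad_leaky_relu(allout)
  out <- ad_leaky_relu(ad_conv2d(cat, P[[paste0(prefix, "_mix_w")]],
                                 P[[paste0(prefix, "_mix_b")]], pad = 0L))
  if (!want_branches) return(out)
  cout <- dim(ad_value(allout))[3] %/% K
  branches <- lapply(seq_len(K), function(k)
    ad_slice_ch(allout, ((k - 1) * cout + 1):(k * cout)))
  list(out = out, branches = branches)
}

#' Apply a direction-aware convolution block
#'
#' One 3x3 convolution branch per orientation, with the kernel support
#' masked to the line through the center at that angle (masked positions
#' contribute exactly zero), followed by concatenation and a 1x1 fusion
#' convolution.  Spatial shape is preserved.
#'
#' @param features H x W x C numeric array
#' @param orientations mask angles in degrees
#' @param params optional parameter list from a built model; if `NULL`,
#'   fresh parameters are initialized (seeded)
#' @param init `"he"` or `"aligned"` (each branch kernel set to its
#'   mask-aligned averaging filter; useful for orientation-response
#'   analysis)
#' @param seed seed for fresh parameter initialization
#' @param return_branches also return each branch's pre-fusion output
#' @return the fused H x W x C array, or a list with `output` and
#'   `branches` when `return_branches = TRUE`
#' @export
apply_dacb <- function(features, orientations = c(0, 45, 90, 135),
                       params = NULL, init = c("he", "aligned"), seed = 1L,
                       return_branches = FALSE) {
  init <- match.arg(init)
  if (length(dim(features)) == 2L) features <- array(features, c(dim(features), 1L))
  cin <- dim(features)[3]
  if (is.null(params)) {
    params <- with_seed(seed, .dacb_init(list(), "dacb", cin, cin,
                                         orientations, init = init))
  }
  ad_tape_reset()
  res <- .dacb_fwd(ad_const(features), params, "dacb", orientations,
                   want_branches = TRUE)
  ad_tape_reset()
  if (return_branches)
    list(output = ad_value(res$out),
         branches = lapply(res$branches, ad_value))
  else ad_value(res$out)
}

#' Build an interpolation model
#'
#' Initializes all parameters (He initialization; flow and output heads
#' start near zero so the initial model is close to a 50/50 blend of the
#' two warped inputs with zero flow).
#'
#' @param config a [model_config()]
#' @param seed integer seed for weight initialization
#' @return an `interp_model` list with `config` and `params`
#' @export
build_interp_model <- function(config = model_config(), seed = 42L) {
  S <- config$n_scales
  ors <- config$orientations
  with_seed(seed, {
    P <- list()
    C <- vapply(0:(S - 1), function(s) channels_at_scale(config, s), integer(1))
    # encoder
    P$enc_in_w <- .conv_w(3, 1, C[1]); P$enc_in_b <- .conv_b(C[1])
    P <- .dacb_init(P, "enc_dacb0", C[1], C[1], ors)
    for (s in 2:S) {
      P[[paste0("enc_down", s - 1, "_w")]] <- .conv_w(3, C[s - 1], C[s])
      P[[paste0("enc_down", s - 1, "_b")]] <- .conv_b(C[s])
      P <- .dacb_init(P, paste0("enc_dacb", s - 1), C[s], C[s], ors)
    }
    # flow estimator (coarse-to-fine)
    Cc <- C[S]
    P$flow_top_c1_w <- .conv_w(3, 2 * Cc + 1, Cc); P$flow_top_c1_b <- .conv_b(Cc)
    P$flow_top_c2_w <- .conv_w(3, Cc, 4, gain = 0.01); P$flow_top_c2_b <- .conv_b(4)
    for (s in seq_len(S - 1)) {  # refinement at scales S-1 .. 1 (1 = finest)
      cs <- C[s]
      P[[paste0("flow_ref", s, "_c1_w")]] <- .conv_w(3, 2 * cs + 5, cs)
      P[[paste0("flow_ref", s, "_c1_b")]] <- .conv_b(cs)
      P[[paste0("flow_ref", s, "_c2_w")]] <- .conv_w(3, cs, 4, gain = 0.01)
      P[[paste0("flow_ref", s, "_c2_b")]] <- .conv_b(4)
    }
    # bottleneck attention (lazily sized positional table, see .attn_fwd)
    P$attn_q_w <- .mat_w(Cc, Cc); P$attn_k_w <- .mat_w(Cc, Cc)
    P$attn_v_w <- .mat_w(Cc, Cc); P$attn_o_w <- .mat_w(Cc, Cc, gain = 0.1)
    P$attn_frame_emb <- ad_param(matrix(rnorm(2 * Cc, 0, 0.02), 2, Cc))
    P$fuse_w <- .conv_w(1, 2 * Cc, Cc); P$fuse_b <- .conv_b(Cc)
    # decoder
    for (s in S:2) {
      P[[paste0("dec_up", s, "_w")]] <- .conv_w(3, C[s], C[s - 1])
      P[[paste0("dec_up", s, "_b")]] <- .conv_b(C[s - 1])
      P[[paste0("dec_skip", s, "_w")]] <- .conv_w(3, 3 * C[s - 1], C[s - 1])
      P[[paste0("dec_skip", s, "_b")]] <- .conv_b(C[s - 1])
    }
    P <- .dacb_init(P, "dec_dacb", C[1], C[1], ors)
    P$head_w <- .conv_w(3, C[1], 2, gain = 0.01); P$head_b <- .conv_b(2)
    structure(list(config = config, params = P), class = "interp_model")
  })
}

#' @export
print.interp_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<interp_model> base %d ch, %d scales, %d heads, %d parameters\n",
              x$config$base_channels, x$config$n_scales, x$config$n_heads, np))
  invisible(x)
}

.encode <- function(P, cfg, x) {
  S <- cfg$n_scales
  feats <- vector("list", S)
  h <- ad_leaky_relu(ad_conv2d(x, P$enc_in_w, P$enc_in_b))
  feats[[1]] <- .dacb_fwd(h, P, "enc_dacb0", cfg$orientations)
  for (s in 2:S) {
    h <- ad_leaky_relu(ad_conv2d(feats[[s - 1]],
                                 P[[paste0("enc_down", s - 1, "_w")]],
                                 P[[paste0("enc_down", s - 1, "_b")]],
                                 stride = 2L, pad = 1L))
    feats[[s]] <- .dacb_fwd(h, P, paste0("enc_dacb", s - 1), cfg$orientations)
  }
  feats
}

.tchan <- function(t, h, w) ad_const(array(t, c(h, w, 1)))

# single multi-head self-attention layer over the two warped coarse
# feature maps (intra- and inter-frame jointly), with learned positional
# encoding; a lazily created positional table is stored on the model
# params list by the caller (train step) or created as a constant.
.attn_fwd <- function(P, cfg, w0, w1, pos_node) {
  d <- dim(ad_value(w0))
  hw <- d[1] * d[2]
  Cc <- d[3]
  t0 <- ad_reshape(w0, c(hw, Cc))
  t1 <- ad_reshape(w1, c(hw, Cc))
  t0 <- ad_add(t0, pos_node)
  t1 <- ad_add(t1, pos_node)
  t0 <- ad_add_rowvec(t0, ad_slice_rows(P$attn_frame_emb, 1L))
  t1 <- ad_add_rowvec(t1, ad_slice_rows(P$attn_frame_emb, 2L))
  tok <- ad_vstack(t0, t1)
  q <- ad_matmul(tok, P$attn_q_w)
  k <- ad_matmul(tok, P$attn_k_w)
  v <- ad_matmul(tok, P$attn_v_w)
  nh <- cfg$n_heads
  dh <- Cc %/% nh
  heads <- vector("list", nh)
  for (hh in seq_len(nh)) {
    idx <- ((hh - 1) * dh + 1):(hh * dh)
    A <- ad_softmax_rows(ad_scale(
      ad_matmul(ad_slice_cols(q, idx), ad_transpose(ad_slice_cols(k, idx))),
      1 / sqrt(dh)))
    heads[[hh]] <- ad_matmul(A, ad_slice_cols(v, idx))
  }
  out <- ad_matmul(ad_hstack(heads), P$attn_o_w)
  tok <- ad_add(tok, out)  # residual connection
  b0 <- ad_reshape(ad_slice_rows(tok, seq_len(hw)), c(d[1], d[2], Cc))
  b1 <- ad_reshape(ad_slice_rows(tok, hw + seq_len(hw)), c(d[1], d[2], Cc))
  ad_leaky_relu(ad_conv2d(ad_concat(list(b0, b1)), P$fuse_w, P$fuse_b, pad = 0L))
}

# full forward pass; f0n, f1n are (H, W, 1) ad nodes in [-1, 1]
.forward_synth <- function(model, f0n, f1n, t) {
  P <- model$params
  cfg <- model$config
  S <- cfg$n_scales
  feats0 <- .encode(P, cfg, f0n)
  feats1 <- .encode(P, cfg, f1n)

  # coarse-to-fine bidirectional flow
  dS <- dim(ad_value(feats0[[S]]))
  inp <- ad_concat(list(feats0[[S]], feats1[[S]], .tchan(t, dS[1], dS[2])))
  h <- ad_leaky_relu(ad_conv2d(inp, P$flow_top_c1_w, P$flow_top_c1_b))
  flow <- ad_conv2d(h, P$flow_top_c2_w, P$flow_top_c2_b)
  w0s <- vector("list", S)
  w1s <- vector("list", S)
  w0s[[S]] <- ad_warp(feats0[[S]], ad_slice_ch(flow, 1:2))
  w1s[[S]] <- ad_warp(feats1[[S]], ad_slice_ch(flow, 3:4))

  for (s in (S - 1):1) {
    up <- ad_scale(ad_upsample2(flow), 2)
    w0 <- ad_warp(feats0[[s]], ad_slice_ch(up, 1:2))
    w1 <- ad_warp(feats1[[s]], ad_slice_ch(up, 3:4))
    ds <- dim(ad_value(feats0[[s]]))
    inp <- ad_concat(list(w0, w1, up, .tchan(t, ds[1], ds[2])))
    h <- ad_leaky_relu(ad_conv2d(inp, P[[paste0("flow_ref", s, "_c1_w")]],
                                 P[[paste0("flow_ref", s, "_c1_b")]]))
    delta <- ad_conv2d(h, P[[paste0("flow_ref", s, "_c2_w")]],
                       P[[paste0("flow_ref", s, "_c2_b")]])
    flow <- ad_add(up, delta)
    w0s[[s]] <- ad_warp(feats0[[s]], ad_slice_ch(flow, 1:2))
    w1s[[s]] <- ad_warp(feats1[[s]], ad_slice_ch(flow, 3:4))
  }

  # bottleneck attention over warped coarse features
  pos_key <- paste0("attn_pos_", dS[1], "x", dS[2])
  if (is.null(P[[pos_key]])) {
    # deterministic sinusoidal table when no learned one has been created
    hw <- dS[1] * dS[2]
    Cc <- dS[3]
    ii <- (seq_len(hw) - 1) %% dS[1]
    jj <- (seq_len(hw) - 1) %/% dS[1]
    tab <- outer(ii / dS[1], seq_len(Cc), function(a, b) sin(2 * pi * a * ((b %% 4) + 1))) +
           outer(jj / dS[2], seq_len(Cc), function(a, b) cos(2 * pi * a * ((b %% 5) + 1)))
    pos_node <- ad_const(0.05 * tab)
  } else pos_node <- P[[pos_key]]
  B <- .attn_fwd(P, cfg, w0s[[S]], w1s[[S]], pos_node)

  # decoder with warped-feature skip connections
  d <- B
  for (s in S:2) {
    d <- ad_leaky_relu(ad_conv2d(ad_upsample2(d),
                                 P[[paste0("dec_up", s, "_w")]],
                                 P[[paste0("dec_up", s, "_b")]]))
    d <- ad_leaky_relu(ad_conv2d(ad_concat(list(d, w0s[[s - 1]], w1s[[s - 1]])),
                                 P[[paste0("dec_skip", s, "_w")]],
                                 P[[paste0("dec_skip", s, "_b")]]))
  }
  d <- .dacb_fwd(d, P, "dec_dacb", cfg$orientations)
  head <- ad_conv2d(d, P$head_w, P$head_b)
  res <- ad_slice_ch(head, 1L)
  alpha <- ad_sigmoid(ad_slice_ch(head, 2L))

  I0w <- ad_warp(f0n, ad_slice_ch(flow, 1:2))
  I1w <- ad_warp(f1n, ad_slice_ch(flow, 3:4))
  one_minus_alpha <- ad_shift(ad_scale(alpha, -1), 1)
  blend <- ad_add(ad_mul(alpha, I0w), ad_mul(one_minus_alpha, I1w))
  # residual kept weak so photometric alignment is carried by the flow
  pred <- ad_tanh(ad_scale(ad_add(blend, ad_scale(res, 0.2)), 1.25))
  list(pred = pred, flow = flow, alpha = alpha, residual = res)
}

#' Construct a synthesis request
#'
#' @param frame0,frame1 normalized frames (matrices in \[-1, 1\], same shape)
#' @param t target timestep, strictly inside (-1, 1); the endpoints are
#'   real frames and are never synthesized
#' @return a `synthesis_request`
#' @export
synthesis_request <- function(frame0, frame1, t) {
  if (!identical(dim(frame0), dim(frame1)))
    stop("frame0 and frame1 must have the same shape")
  if (!is.finite(t) || t <= -1 || t >= 1)
    stop("timestep t must be strictly inside (-1, 1)")
  structure(list(frame0 = frame0, frame1 = frame1, t = t),
            class = "synthesis_request")
}

.check_divisible <- function(dims, S) {
  f <- 2L^(S - 1L)
  if (any(dims[1:2] %% f != 0))
    stop("frame side lengths must be divisible by 2^(n_scales - 1) = ", f)
}

#' Synthesize an intermediate frame
#'
#' Full forward pass: encode both frames, estimate bidirectional flow
#' coarse-to-fine, warp features and images toward the target time, fuse
#' in the attention bottleneck, decode, and blend.  Output values are
#' bounded to \[-1, 1\].
#'
#' @param req a [synthesis_request()]
#' @param model an [build_interp_model()] model
#' @return matrix of the same shape as the inputs, values in \[-1, 1\]
#' @export
synthesize_intermediate <- function(req, model) {
  stopifnot(inherits(req, "synthesis_request"))
  d <- dim(req$frame0)
  .check_divisible(d, model$config$n_scales)
  ad_tape_reset()
  out <- .forward_synth(model,
                        ad_const(array(req$frame0, c(d, 1L))),
                        ad_const(array(req$frame1, c(d, 1L))),
                        req$t)
  ad_tape_reset()
  matrix(ad_value(out$pred), d[1], d[2])
}

#' Estimate bidirectional optical flow
#'
#' Coarse-to-fine estimation conditioned on the target timestep: flows at
#' scale s are upsampled x2 and scaled x2 to initialize scale s-1.  Both
#' returned fields are backward-sampling flows at full resolution — the
#' displacement at which to sample frame0 (respectively frame1) to land
#' at time `t`.
#'
#' @param model an interpolation model
#' @param frame0,frame1 normalized frames (matrices)
#' @param t target timestep in (-1, 1)
#' @return `list(flow0, flow1)`, each an H x W x 2 array (dx, dy in px)
#' @export
estimate_bidirectional_flow <- function(model, frame0, frame1, t = 0) {
  d <- dim(frame0)
  .check_divisible(d, model$config$n_scales)
  ad_tape_reset()
  out <- .forward_synth(model,
                        ad_const(array(frame0, c(d, 1L))),
                        ad_const(array(frame1, c(d, 1L))),
                        t)
  ad_tape_reset()
  fl <- ad_value(out$flow)
  list(flow0 = fl[, , 1:2, drop = FALSE], flow1 = fl[, , 3:4, drop = FALSE])
}

#' Backward bilinear warping
#'
#' `output(p) = source(p + flow(p))` with bilinear interpolation;
#' out-of-bounds samples clamp to the border.  Zero flow returns the
#' source exactly.
#'
#' @param source matrix or H x W x C array
#' @param flow H x W x 2 array: channel 1 = dx (columns), channel 2 = dy
#'   (rows), in pixels
#' @return warped array with the shape of `source`
#' @export
backward_warp <- function(source, flow) {
  was_mat <- is.matrix(source)
  if (was_mat) source <- array(source, c(dim(source), 1L))
  dsrc <- dim(source)
  dfl <- dim(flow)
  if (length(dfl) != 3L || dfl[3] != 2L || any(dfl[1:2] != dsrc[1:2]))
    stop("flow must be an H x W x 2 array matching the source shape")
  out <- cpp_warp_forward(source, flow)
  if (was_mat) matrix(out, dsrc[1], dsrc[2]) else out
}
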