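# Minimal reverse-mode automatic differentiation over dense arrays.
#
# Tensors are plain R arrays (column-major), images/features use dim
# (H, W, C), flow fields (H, W, 2) with channel 1 = dx (columns) and
# channel 2 = dy (rows).  Every op appends a node to a global tape;
# ad_backward() walks the tape in reverse and accumulates gradients.
# This is deliberately single-threaded and deterministic.

.af <- new.env(parent = emptyenv())
.af$tape <- NULL
.af$n <- 0L

ad_tape_reset <- function() {
  .af$tape <- vector("list", 256L)
  .af$n <- 0L
  invisible(NULL)
}

.ad_push <- function(node) {
  n <- .af$n + 1L
  if (!is.null(.af$tape)) {
    if (n > length(.af$tape)) .af$tape <- c(.af$tape, vector("list", length(.af$tape)))
    .af$tape[[n]] <- node
    .af$n <- n
  }
  node
}

#' Create an autodiff node
#'
#' @param value numeric array
#' @param parents list of parent nodes
#' @param backfn function(grad) returning a list of gradients, one per parent
#' @param leaf logical; leaves (parameters/constants) are not taped
#' @keywords internal
ad_node <- function(value, parents = list(), backfn = NULL, leaf = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  class(n) <- "ad_node"
  if (!leaf) .ad_push(n)
  n
}

ad_param <- function(value) {
  n <- ad_node(value, leaf = TRUE)
  n$is_param <- TRUE
  n
}

ad_const <- function(value) ad_node(value, leaf = TRUE)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

.ad_acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Run backpropagation from a scalar loss node
#' @keywords internal
ad_backward <- function(loss) {
  loss$grad <- 1
  if (.af$n == 0L) return(invisible(NULL))
  for (i in seq(.af$n, 1L)) {
    nd <- .af$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      if (!is.null(gs[[k]])) .ad_acc(nd$parents[[k]], gs[[k]])
    }
    nd$grad <- NULL  # free intermediate gradients early
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- elementwise ------------------------------------------------------------

ad_add <- function(x, y) {
  ad_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

ad_sub <- function(x, y) {
  ad_node(x$value - y$value, list(x, y), function(g) list(g, -g))
}

ad_mul <- function(x, y) {
  xv <- x$value; yv <- y$value
  ad_node(xv * yv, list(x, y), function(g) list(g * yv, g * xv))
}

ad_div <- function(x, y) {
  xv <- x$value; yv <- y$value
  ad_node(xv / yv, list(x, y),
          function(g) list(g / yv, -g * xv / (yv * yv)))
}

ad_scale <- function(x, k) {
  ad_node(x$value * k, list(x), function(g) list(g * k))
}

ad_shift <- function(x, k) {
  ad_node(x$value + k, list(x), function(g) list(g))
}

ad_relu <- function(x) {
  v <- x$value
  m <- v > 0
  ad_node(v * m, list(x), function(g) list(g * m))
}

ad_leaky_relu <- function(x, slope = 0.1) {
  v <- x$value
  m <- slope + (1 - slope) * (v > 0)
  ad_node(v * m, list(x), function(g) list(g * m))
}

ad_tanh <- function(x) {
  v <- tanh(x$value)
  ad_node(v, list(x), function(g) list(g * (1 - v * v)))
}

ad_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$value))
  ad_node(v, list(x), function(g) list(g * v * (1 - v)))
}

ad_abs <- function(x) {
  v <- x$value
  s <- sign(v)
  ad_node(abs(v), list(x), function(g) list(g * s))
}

ad_square <- function(x) {
  v <- x$value
  ad_node(v * v, list(x), function(g) list(2 * g * v))
}

ad_mean <- function(x) {
  v <- x$value
  n <- length(v)
  ad_node(mean(v), list(x), function(g) list(array(g / n, dim = dim(v) %||% length(v))))
}

ad_sum <- function(x) {
  v <- x$value
  ad_node(sum(v), list(x), function(g) list(array(g, dim = dim(v) %||% length(v))))
}

# --- shape ops --------------------------------------------------------------

ad_reshape <- function(x, dims) {
  od <- dim(x$value) %||% length(x$value)
  v <- x$value
  dim(v) <- dims
  ad_node(v, list(x), function(g) { dim(g) <- od; list(g) })
}

#' Concatenate along the channel (3rd) dimension
#' @keywords internal
ad_concat <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  d <- dim(vals[[1]])
  ccount <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, dim = c(d[1], d[2], sum(ccount)))
  at <- 0L
  for (v in vals) {
    nc <- dim(v)[3]
    out[, , (at + 1L):(at + nc)] <- v
    at <- at + nc
  }
  ends <- cumsum(ccount)
  starts <- c(1, utils::head(ends, -1) + 1)
  ad_node(out, xs, function(g) {
    lapply(seq_along(xs), function(k) g[, , starts[k]:ends[k], drop = FALSE])
  })
}

ad_slice_ch <- function(x, channels) {
  v <- x$value
  d <- dim(v)
  ad_node(v[, , channels, drop = FALSE], list(x), function(g) {
    out <- array(0, dim = d)
    out[, , channels] <- g
    list(out)
  })
}

#' Nearest-neighbour 2x upsampling; exact adjoint is 2x2 block summation
#' @keywords internal
ad_upsample2 <- function(x) {
  v <- x$value
  d <- dim(v)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  out <- v[ri, ci, , drop = FALSE]
  ad_node(out, list(x), function(g) {
    gsm <- g[seq(1, 2 * d[1], by = 2), , , drop = FALSE] +
           g[seq(2, 2 * d[1], by = 2), , , drop = FALSE]
    gsm <- gsm[, seq(1, 2 * d[2], by = 2), , drop = FALSE] +
           gsm[, seq(2, 2 * d[2], by = 2), , drop = FALSE]
    list(gsm)
  })
}

# --- structured ops ---------------------------------------------------------

#' Differentiable 2-D convolution ("same" for stride 1, pad = (k-1)/2)
#' @keywords internal
ad_conv2d <- function(x, w, b, stride = 1L, pad = NULL) {
  k <- dim(w$value)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  xv <- x$value; wv <- w$value
  fw <- cpp_conv2d_forward_ws(xv, wv, b$value, as.integer(stride), as.integer(pad))
  y <- fw$y
  M <- fw$M  # im2col workspace reused in backward
  xd <- dim(xv)
  # skip gradient paths that dead-end in constants
  want_gx <- !is.null(x$backfn) || isTRUE(x$is_param)
  want_gw <- isTRUE(w$is_param)
  ad_node(y, list(x, w, b), function(g) {
    dim(g) <- dim(y)
    bw <- cpp_conv2d_backward_ws(M, xd, wv, g, as.integer(stride),
                                 as.integer(pad), want_gx, want_gw)
    list(bw$gx, bw$gw, bw$gb)
  })
}

#' Differentiable backward bilinear warp
#' @keywords internal
ad_warp <- function(x, flow) {
  xv <- x$value; fv <- flow$value
  y <- cpp_warp_forward(xv, fv)
  ad_node(y, list(x, flow), function(g) {
    dim(g) <- dim(xv)
    bw <- cpp_warp_backward(xv, fv, g)
    list(bw$gx, bw$gflow)
  })
}

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

ad_transpose <- function(x) {
  ad_node(t(x$value), list(x), function(g) list(t(g)))
}

#' Row-wise softmax of a matrix
#' @keywords internal
ad_softmax_rows <- function(x) {
  v <- x$value
  m <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  e <- exp(v - m)
  s <- e / rowSums(e)
  ad_node(s, list(x), function(g) {
    dot <- rowSums(g * s)
    list(s * (g - dot))
  })
}

#' Concatenate 4-D kernel arrays along the output-channel (4th) axis
#'
#' Lets several convolution branches over the same input collapse into a
#' single GEMM (the branches' outputs are contiguous channel blocks).
#' @keywords internal
ad_concat_w4 <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  d <- dim(vals[[1]])
  nco <- vapply(vals, function(v) dim(v)[4], numeric(1))
  ends <- cumsum(nco)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- array(0, c(d[1], d[2], d[3], sum(nco)))
  for (k in seq_along(vals)) out[, , , starts[k]:ends[k]] <- vals[[k]]
  ad_node(out, xs, function(g)
    lapply(seq_along(xs), function(k) g[, , , starts[k]:ends[k], drop = FALSE]))
}

#' Concatenate bias vectors
#' @keywords internal
ad_concat_vec <- function(xs) {
  lens <- vapply(xs, function(x) length(x$value), numeric(1))
  ends <- cumsum(lens)
  starts <- c(1, utils::head(ends, -1) + 1)
  ad_node(unlist(lapply(xs, function(x) x$value)), xs, function(g)
    lapply(seq_along(xs), function(k) g[starts[k]:ends[k]]))
}

ad_vstack <- function(a, b) {
  av <- a$value; bv <- b$value
  na <- nrow(av)
  ad_node(rbind(av, bv), list(a, b), function(g)
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE]))
}

ad_slice_rows <- function(x, rows) {
  v <- x$value
  d <- dim(v)
  ad_node(v[rows, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, d[1], d[2])
    out[rows, ] <- g
    list(out)
  })
}

ad_slice_cols <- function(x, cols) {
  v <- x$value
  d <- dim(v)
  ad_node(v[, cols, drop = FALSE], list(x), function(g) {
    out <- matrix(0, d[1], d[2])
    out[, cols] <- g
    list(out)
  })
}

ad_hstack <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  nc <- vapply(vals, ncol, numeric(1))
  ends <- cumsum(nc)
  starts <- c(1, utils::head(ends, -1) + 1)
  ad_node(do.call(cbind, vals), xs, function(g)
    lapply(seq_along(xs), function(k) g[, starts[k]:ends[k], drop = FALSE]))
}

#' Add a row vector to every row of a matrix (broadcast)
#' @keywords internal
ad_add_rowvec <- function(x, v) {
  ad_node(sweep(x$value, 2, as.numeric(v$value), "+"), list(x, v),
          function(g) list(g, colSums(g)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
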