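#' Convolutional block attention (CBAM)
#'
#' Sequential channel-then-spatial attention.  Channel attention squeezes the
#' map with global average and max pooling, pushes both descriptors through a
#' shared two-layer MLP (reduction ratio `r`, ReLU in between), sums and
#' gates through a sigmoid: \eqn{M_c(F) = \sigma(MLP(AvgPool(F)) +
#' MLP(MaxPool(F)))}, applied as \eqn{F' = M_c(F) \otimes F}.  Spatial
#' attention pools `F'` across the channel axis (mean and max), stacks the
#' two planes and convolves with a 7x7 kernel:
#' \eqn{M_s(F') = \sigma(f^{7\times7}([AvgPool(F'); MaxPool(F')]))}, applied
#' as \eqn{F'' = M_s(F') \otimes F'}.  Both gates lie strictly in (0, 1), so
#' the refined map never exceeds the input in absolute value.  On a 1x1
#' spatial map the 7x7 conv (padding 3) degenerates gracefully.
#'
#' @param channels channel count of the maps this block refines.
#' @param reduction reduction ratio `r` of the shared MLP (`channels` must be
#'   divisible by it). Default 16, the standard CBAM setting.
#' @return An object of class `wfpn_cbam`.
#' @export
cbam_block <- function(channels, reduction = 16L) {
  stopifnot(channels %% reduction == 0L)
  hidden <- channels %/% reduction
  structure(list(
    mlp1 = linear_layer(channels, hidden, bias = FALSE),
    mlp2 = linear_layer(hidden, channels, bias = FALSE),
    spatial = conv_layer(2L, 1L, k = 7L, pad = 3L),
    channels = as.integer(channels), reduction = as.integer(reduction)
  ), class = "wfpn_cbam")
}

#' @rdname cbam_block
#' @param F feature map, an `H x W x C x N` array or autograd node.
#' @param block a [cbam_block()].
#' @return `channel_attention()`: the channel-gated map \eqn{F' = M_c(F)
#'   \otimes F}, same shape as the input.
#' @export
channel_attention <- function(F, block) {
  Fn <- as_node(F)
  d <- dim4(Fn)
  C <- d[3]; N <- d[4]
  stopifnot(C == block$channels)
  mlp <- function(desc) {
    linear_fwd(block$mlp2, ag_relu(linear_fwd(block$mlp1, desc)))
  }
  davg <- ag_reshape(ag_gap(Fn), c(C, N))
  dmax <- ag_reshape(ag_gmp(Fn), c(C, N))
  gate <- ag_reshape(ag_sigmoid(ag_add(mlp(davg), mlp(dmax))),
                     c(1L, 1L, C, N))
  out <- ag_mul_bcast(Fn, gate)
  if (!is_node(F)) node_value(out) else out
}

#' @rdname cbam_block
#' @param F_prime channel-refined map `F'`.
#' @return `spatial_attention()`: the spatially gated map \eqn{F'' = M_s(F')
#'   \otimes F'}, same shape as the input.
#' @export
spatial_attention <- function(F_prime, block) {
  Fn <- as_node(F_prime)
  d <- dim4(Fn)
  stack <- ag_concat_ch(ag_chpool_mean(Fn), ag_chpool_max(Fn))
  gate <- ag_sigmoid(conv_fwd(block$spatial, stack))  # (H, W, 1, N)
  out <- ag_mul_bcast(Fn, gate)
  if (!is_node(F_prime)) node_value(out) else out
}

#' @rdname cbam_block
#' @return `apply_cbam()`: the fully refined map, channel then spatial
#'   attention in sequence.
#' @examples
#' blk <- cbam_block(16, reduction = 4)
#' x <- array(rnorm(16 * 4 * 4), c(4, 4, 16, 1))
#' all(abs(apply_cbam(x, blk)) <= abs(x))  # gates shrink magnitudes
#' @export
apply_cbam <- function(F, block) {
  out <- spatial_attention(channel_attention(as_node(F), block), block)
  if (!is_node(F)) node_value(out) else out
}

# concat two maps along the channel axis
ag_concat_ch <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  dx <- dim4(x); dy <- dim4(y)
  stopifnot(dx[1] == dy[1], dx[2] == dy[2], dx[4] == dy[4])
  z <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  z[, , seq_len(dx[3]), ] <- x$value
  z[, , dx[3] + seq_len(dy[3]), ] <- y$value
  ag_node(z, list(x, y), function(g) {
    list(g[, , seq_len(dx[3]), , drop = FALSE],
         g[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  })
}

# attention gates for inspection (arrays, eval only)
cbam_gates <- function(F, block) {
  Fn <- as_node(F)
  d <- dim4(Fn)
  C <- d[3]; N <- d[4]
  mlp <- function(desc) {
    linear_fwd(block$mlp2, ag_relu(linear_fwd(block$mlp1, desc)))
  }
  davg <- ag_reshape(ag_gap(Fn), c(C, N))
  dmax <- ag_reshape(ag_gmp(Fn), c(C, N))
  mc <- ag_sigmoid(ag_add(mlp(davg), mlp(dmax)))
  Fp <- ag_mul_bcast(Fn, ag_reshape(mc, c(1L, 1L, C, N)))
  stack <- ag_concat_ch(ag_chpool_mean(Fp), ag_chpool_max(Fp))
  ms <- ag_sigmoid(conv_fwd(block$spatial, stack))
  list(channel = node_value(mc), spatial = node_value(ms))
}
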