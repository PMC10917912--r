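#' Fusion node: learnable non-negative weights for fast-normalized fusion
#'
#' Each fusion site owns one raw learnable scalar per input plus (optionally)
#' its projection (1x1) and smoothing (3x3) convolutions.  Effective weights
#' are the rectified raw parameters, so they are non-negative on every
#' forward pass; raw weights initialize to 1 so all inputs start with equal
#' say.  The normalized coefficient of input *i* is
#' \eqn{w_i / (\sum_j w_j + \epsilon)}; the coefficients sum to
#' \eqn{\sum_j w_j / (\sum_j w_j + \epsilon) < 1}, with
#' \eqn{\epsilon = 10^{-4}} by default guarding the division.
#'
#' @param n_inputs number of fused inputs (weights created, one each).
#' @param epsilon small positive constant in the normalizing denominator.
#' @param proj optional 1x1 projection conv applied upstream by the caller.
#' @param smooth optional 3x3 smoothing conv applied downstream by the caller.
#' @param norm optional batch-normalization layer following the smoothing
#'   conv (the fusion stack is conv + BN, as is standard for normalized
#'   pyramid necks).
#' @return An object of class `wfpn_fusion_node`.
#' @export
fusion_node <- function(n_inputs = 2L, epsilon = 1e-4,
                        proj = NULL, smooth = NULL, norm = NULL) {
  stopifnot(n_inputs >= 1L, epsilon >= 0)
  structure(list(raw_weights = ag_param(rep(1, n_inputs)),
                 epsilon = epsilon, proj = proj, smooth = smooth,
                 norm = norm, n_inputs = as.integer(n_inputs)),
            class = "wfpn_fusion_node")
}

#' @rdname fusion_node
#' @param node a `wfpn_fusion_node`.
#' @return `fusion_coefficients()`: the current normalized coefficients
#'   \eqn{w_i/(\sum_j w_j + \epsilon)} as a numeric vector.
#' @export
fusion_coefficients <- function(node) {
  w <- pmax(node$raw_weights$value, 0)
  w / (sum(w) + node$epsilon)
}

# coefficients as scalar autograd nodes (training path)
fusion_coeff_nodes <- function(node) {
  w <- ag_relu(node$raw_weights)
  denom <- ag_add_const(ag_sum(w), node$epsilon)
  lapply(seq_len(node$n_inputs),
         function(i) ag_div_scalar(ag_pick(w, i), denom))
}

#' Fast-normalized weighted fusion of same-shape feature maps
#'
#' Computes \eqn{O = \sum_i \frac{w_i}{\sum_j w_j + \epsilon} I_i} with
#' non-negative learnable weights — the cheap alternative to softmax
#' weighting used at every fusion site of the pyramid.
#'
#' @param inputs list of same-shape feature maps (arrays or autograd nodes).
#' @param node a [fusion_node()] with one weight per input.
#' @return Fused map, same shape and type as the inputs.
#' @examples
#' n <- fusion_node(2, epsilon = 1e-4)
#' x <- array(1, c(2, 2, 1, 1))
#' fast_normalized_fusion(list(x, x), n)[1, 1, 1, 1]  # 2 / (2 + 1e-4)
#' @export
fast_normalized_fusion <- function(inputs, node) {
  stopifnot(inherits(node, "wfpn_fusion_node"),
            length(inputs) == node$n_inputs)
  dims <- lapply(inputs, function(x) dim(node_value(x)))
  for (d in dims[-1]) {
    if (!identical(d, dims[[1]])) stop("fused inputs must share shape")
  }
  was_array <- !any(vapply(inputs, is_node, logical(1)))
  cs <- fusion_coeff_nodes(node)
  out <- ag_scale(as_node(inputs[[1]]), cs[[1]])
  for (i in seq_along(inputs)[-1]) {
    out <- ag_add(out, ag_scale(as_node(inputs[[i]]), cs[[i]]))
  }
  if (was_array) node_value(out) else out
}

#' Single top-down fusion step
#'
#' Produces \eqn{F_n} from the raw backbone map \eqn{B_n} and the level above:
#' project \eqn{B_n} to the pyramid width with a 1x1 conv, upsample
#' \eqn{F_{n+1}} (nearest-neighbour; a spatial broadcast when it is 1x1) to
#' \eqn{B_n}'s resolution, fuse with fast-normalized weights, then smooth
#' with a 3x3 conv.
#'
#' @param B_n raw backbone map at level n.
#' @param F_above fused map of level n+1 (already at pyramid width).
#' @param node a [fusion_node()] carrying the projection and smoothing convs.
#' @param training batch-normalization mode (see [extract_hierarchy()]).
#' @return Feature map \eqn{F_n} at `B_n`'s resolution, pyramid width.
#' @export
top_down_step <- function(B_n, F_above, node, training = FALSE) {
  d <- dim(node_value(B_n))
  proj <- if (is.null(node$proj)) as_node(B_n) else conv_fwd(node$proj, B_n)
  up <- ag_upsample_nearest(as_node(F_above), d[1], d[2])
  fused <- fast_normalized_fusion(list(proj, up), node)
  out <- if (is.null(node$smooth)) as_node(fused) else conv_fwd(node$smooth, fused)
  if (!is.null(node$norm)) out <- bn_fwd(node$norm, out, training)
  if (!is_node(B_n) && !is_node(F_above)) node_value(out) else out
}

#' Initialize the top of the pyramid from `B6`
#'
#' The deepest level has no upper neighbour; its pyramid entry is
#' \eqn{F_6 = \mathrm{Conv}_{1\times1}(\mathrm{AvgPool}(B_6) +
#' \mathrm{MaxPool}(B_6))} with global pooling, so `F6` is spatially 1x1 and
#' the level-6 pathway carries global context.
#'
#' @param B6 deepest backbone map.
#' @param proj 1x1 conv adjusting channels to the pyramid width.
#' @return A 1x1 pyramid-width map.
#' @export
top_node_init <- function(B6, proj) {
  pooled <- ag_add(ag_gap(as_node(B6)), ag_gmp(as_node(B6)))
  out <- conv_fwd(proj, pooled)
  if (!is_node(B6)) node_value(out) else out
}

#' Single bottom-up fusion step
#'
#' Produces \eqn{P_n} from the attention-refined top-down map
#' \eqn{F''_n} and the level below: downsample \eqn{P_{n-1}} (average
#' pooling; global when the target is 1x1) to \eqn{F''_n}'s resolution,
#' fuse with fast-normalized weights, then smooth with a 3x3 conv.  No
#' projection conv is applied — both inputs are already at pyramid width.
#'
#' @param F_refined attention-refined top-down map at level n.
#' @param P_below bottom-up map of level n-1 (finer or equal resolution).
#' @param node a [fusion_node()] carrying the smoothing conv.
#' @param training batch-normalization mode (see [extract_hierarchy()]).
#' @return Feature map \eqn{P_n}.
#' @export
bottom_up_step <- function(F_refined, P_below, node, training = FALSE) {
  d <- dim(node_value(F_refined))
  db <- dim(node_value(P_below))
  if (db[1] < d[1] || db[2] < d[2]) {
    stop("P_below must be at finer or equal resolution")
  }
  down <- ag_avgpool_to(as_node(P_below), d[1], d[2])
  fused <- fast_normalized_fusion(list(as_node(F_refined), down), node)
  out <- if (is.null(node$smooth)) as_node(fused) else conv_fwd(node$smooth, fused)
  if (!is.null(node$norm)) out <- bn_fwd(node$norm, out, training)
  if (!is_node(F_refined) && !is_node(P_below)) node_value(out) else out
}

# Build the full neck module (fusion nodes + their convs) for a backbone.
neck_module <- function(level_channels, channels = 256L, epsilon = 1e-4) {
  fnode <- function(proj_from = NULL) {
    fusion_node(2L, epsilon,
                proj = if (!is.null(proj_from)) {
                  conv_layer(proj_from, channels, k = 1L, pad = 0L)
                },
                smooth = conv_layer(channels, channels, k = 3L, pad = 1L),
                norm = bn_layer(channels))
  }
  list(
    proj6 = conv_layer(level_channels[["6"]], channels, k = 1L, pad = 0L),
    td5 = fnode(level_channels[["5"]]),
    td4 = fnode(level_channels[["4"]]),
    bu5 = fnode(),
    bu6 = fnode(),
    channels = channels, epsilon = epsilon
  )
}

# Full dual-pathway forward: hierarchy levels (nodes) -> F, F'' and P maps.
neck_forward <- function(neck, cbam, levels, training = FALSE) {
  F6 <- top_node_init(levels[["6"]], neck$proj6)
  F5 <- top_down_step(levels[["5"]], F6, neck$td5, training)
  F4 <- top_down_step(levels[["4"]], F5, neck$td4, training)
  R4 <- apply_cbam(F4, cbam[["4"]])
  R5 <- apply_cbam(F5, cbam[["5"]])
  R6 <- apply_cbam(F6, cbam[["6"]])
  P4 <- R4  # lowest bottom-up node has no finer input: identity pass-through
  P5 <- bottom_up_step(R5, P4, neck$bu5, training)
  P6 <- bottom_up_step(R6, P5, neck$bu6, training)
  list(top_down = list(`4` = F4, `5` = F5, `6` = F6),
       refined = list(`4` = R4, `5` = R5, `6` = R6),
       bottom_up = list(`4` = P4, `5` = P5, `6` = P6))
}
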