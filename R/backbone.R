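#' Backbone adapters exposing a three-level feature hierarchy
#'
#' The fusion neck consumes the deepest three levels of a convolutional
#' feature hierarchy: `B4` at stride 16, `B5` at stride 32 and `B6` at
#' stride 64.  Any adapter that maps an `N x 3 x H x W` batch to such a
#' hierarchy (with recorded per-level channel counts) is pluggable via the
#' `backbone` config key.  The built-in adapter is a plain strided-conv
#' hierarchy: five stride-2 stages (3x3 conv + ReLU) produce the native
#' strides 2-32; `B6`, which has no native stage, is synthesized by an extra
#' stride-2 3x3 convolution on `B5`.  The `"default"` profile carries 1024
#' and 2048 channels at strides 16 and 32, matching the deepest stages of
#' the ResNeXt-50 trunk used in the reference experiments; the `"tiny"`
#' profile is a narrow configuration for fast CPU training and tests.
#'
#' @param profile `"default"`, `"tiny"`, or a numeric vector of 6 channel
#'   counts (stages at strides 2, 4, 8, 16, 32 and the synthesized stride-64
#'   level).
#' @return A backbone object usable by [wfpn_model()] and
#'   [extract_hierarchy()].
#' @export
backbone_adapter <- function(profile = "default") {
  channels <- if (is.numeric(profile)) {
    stopifnot(length(profile) == 6L)
    as.integer(profile)
  } else {
    switch(match.arg(profile, c("default", "tiny")),
      default = c(64L, 128L, 256L, 1024L, 2048L, 256L),
      tiny = c(8L, 16L, 32L, 32L, 64L, 64L)
    )
  }
  cin <- c(3L, channels[1:5])
  stages <- lapply(seq_len(6L), function(i) {
    list(conv = conv_layer(cin[i], channels[i], k = 3L, stride = 2L,
                           pad = 1L, bias = FALSE),
         norm = bn_layer(channels[i]))
  })
  structure(
    list(stages = stages, channels = channels,
         level_channels = c(`4` = channels[4], `5` = channels[5],
                            `6` = channels[6]),
         strides = c(`4` = 16L, `5` = 32L, `6` = 64L)),
    class = "wfpn_backbone"
  )
}

#' Extract the `{B4, B5, B6}` feature hierarchy from an image batch
#'
#' Runs the backbone over a batch and returns the three deepest feature
#' levels.  Spatial side lengths halve (rounding up) from one exposed level
#' to the next; all maps keep gradients to the backbone parameters.
#'
#' @param backbone a backbone built by [backbone_adapter()].
#' @param x image batch: an `H x W x 3 x N` array (values in any range) or an
#'   autograd node of that shape.  `H` and `W` must be divisible by 32.
#' @param training `TRUE` during optimization: batch normalization then uses
#'   batch statistics and updates its running estimates.  The default
#'   (evaluation mode) is deterministic.
#' @return An object of class `wfpn_hierarchy`: a list with `levels` (named
#'   list of feature maps for levels 4, 5, 6), `strides`, and `channels`.
#'   Maps are plain arrays when `x` is an array, autograd nodes otherwise.
#' @examples
#' bb <- backbone_adapter("tiny")
#' h <- extract_hierarchy(bb, array(0, c(64, 64, 3, 1)))
#' vapply(h$levels, function(m) dim(m)[1], numeric(1))  # 4, 2, 1
#' @export
extract_hierarchy <- function(backbone, x, training = FALSE) {
  stopifnot(inherits(backbone, "wfpn_backbone"))
  was_array <- !is_node(x)
  xn <- as_node(x)
  d <- dim(xn$value)
  if (length(d) != 4L || d[3] != 3L) {
    stop("input must be an H x W x 3 x N array (3 colour channels)")
  }
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("spatial size must be divisible by 32, got ", d[1], "x", d[2])
  }
  if (d[4] < 1L) stop("batch must be non-empty")
  h <- xn
  maps <- vector("list", 6L)
  for (i in seq_len(6L)) {
    st <- backbone$stages[[i]]
    h <- ag_relu(bn_fwd(st$norm, conv_fwd(st$conv, h), training))
    maps[[i]] <- h
  }
  levels <- list(`4` = maps[[4]], `5` = maps[[5]], `6` = maps[[6]])
  if (was_array) levels <- lapply(levels, node_value)
  structure(list(levels = levels,
                 strides = backbone$strides,
                 channels = backbone$level_channels),
            class = "wfpn_hierarchy")
}
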