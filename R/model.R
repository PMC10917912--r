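#' Model configuration
#'
#' Collects the architecture hyperparameters of the weighted feature pyramid
#' classifier.  Defaults follow the reference setup: a pyramid width of 256
#' channels, fusion constant \eqn{\epsilon = 10^{-4}}, CBAM reduction 16,
#' four classes, and the wide backbone profile (1024/2048 channels at
#' strides 16/32).
#'
#' @param backbone `"default"`, `"tiny"`, a 6-vector of channel counts (see
#'   [backbone_adapter()]), or a ready-made backbone object.
#' @param neck_channels pyramid width (channels of every fused map).
#' @param epsilon fusion normalization constant.
#' @param cbam_reduction CBAM channel-MLP reduction ratio.
#' @param num_classes number of output classes K.
#' @param head_hidden width of the first fully connected classifier layer.
#' @return A list of class `wfpn_cfg`.
#' @export
wfpn_config <- function(backbone = "default", neck_channels = 256L,
                        epsilon = 1e-4, cbam_reduction = 16L,
                        num_classes = 4L, head_hidden = 256L) {
  stopifnot(neck_channels >= 1L, epsilon >= 0, num_classes >= 2L)
  structure(list(backbone = backbone,
                 neck_channels = as.integer(neck_channels),
                 epsilon = epsilon,
                 cbam_reduction = as.integer(cbam_reduction),
                 num_classes = as.integer(num_classes),
                 head_hidden = as.integer(head_hidden)),
            class = "wfpn_cfg")
}

#' Build a weighted feature pyramid classification model
#'
#' Assembles backbone, dual-pathway weighted fusion neck, per-level CBAM
#' blocks (independent parameters per level) and the weighted multi-head
#' classifier.  Parameters are drawn from the current RNG stream; seed
#' before calling for reproducible initialization.
#'
#' @param config a [wfpn_config()].
#' @return An object of class `wfpn_model`.
#' @examples
#' set.seed(1)
#' m <- wfpn_model(wfpn_config(backbone = "tiny", cbam_reduction = 4,
#'                             neck_channels = 16, head_hidden = 16))
#' out <- wfpn_forward(m, array(rnorm(64 * 64 * 3), c(64, 64, 3, 1)))
#' dim(out$pred)  # 4 x 1
#' @export
wfpn_model <- function(config = wfpn_config()) {
  stopifnot(inherits(config, "wfpn_cfg"))
  bb <- if (inherits(config$backbone, "wfpn_backbone")) {
    config$backbone
  } else {
    backbone_adapter(config$backbone)
  }
  neck <- neck_module(bb$level_channels, config$neck_channels, config$epsilon)
  cbam <- list(
    `4` = cbam_block(config$neck_channels, config$cbam_reduction),
    `5` = cbam_block(config$neck_channels, config$cbam_reduction),
    `6` = cbam_block(config$neck_channels, config$cbam_reduction)
  )
  head <- ensemble_head(config$neck_channels, config$num_classes,
                        config$head_hidden, config$epsilon)
  model <- structure(list(backbone = bb, neck = neck, cbam = cbam,
                          head = head, config = config),
                     class = "wfpn_model")
  model$params <- collect_params(model[c("backbone", "neck", "cbam", "head")])
  model$bn_layers <- collect_bn(model[c("backbone", "neck", "cbam", "head")])
  model
}

#' @export
print.wfpn_model <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat("<wfpn_model> ", x$config$num_classes, " classes, pyramid width ",
      x$config$neck_channels, ", ", length(x$params), " tensors / ",
      format(npar, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Run the full model forward
#'
#' @param model a [wfpn_model()].
#' @param x image batch, `H x W x 3 x N` array (or autograd node); `H`, `W`
#'   divisible by 32. Inputs are used as given — apply channel
#'   normalization beforehand (the training/evaluation drivers do).
#' @param keep_maps if `TRUE`, also return the backbone hierarchy and all
#'   neck maps.
#' @param training batch-normalization mode (see [extract_hierarchy()]);
#'   leave `FALSE` for deterministic inference.
#' @return A list with `pred` (`K x N` ensembled scores), `outs` (the three
#'   per-level score matrices) and, if requested, `maps`.  Arrays when `x`
#'   is an array, autograd nodes otherwise.
#' @export
wfpn_forward <- function(model, x, keep_maps = FALSE, training = FALSE) {
  stopifnot(inherits(model, "wfpn_model"))
  was_array <- !is_node(x)
  xn <- as_node(x)
  hier <- extract_hierarchy(model$backbone, xn, training)
  neck_out <- neck_forward(model$neck, model$cbam, hier$levels, training)
  hd <- head_forward(model$head, neck_out$bottom_up)
  res <- list(pred = hd$pred, outs = hd$outs)
  if (keep_maps) res$maps <- c(list(backbone = hier$levels), neck_out)
  if (was_array) {
    res$pred <- node_value(res$pred)
    res$outs <- lapply(res$outs, node_value)
    if (keep_maps) res$maps <- rapply(res$maps, node_value,
                                      classes = "ag_node", how = "replace")
  }
  res
}

#' Score a batch of images with a (trained) model
#'
#' @inheritParams wfpn_forward
#' @return A tibble with one row per image: predicted class index (argmax,
#'   ties to the lowest index), and one `score_k` column per class.
#' @export
wfpn_scores <- function(model, x) {
  pred <- wfpn_forward(model, node_value(x))$pred
  K <- nrow(pred)
  tib <- tibble::tibble(pred = apply(pred, 2L, which.max))
  for (k in seq_len(K)) tib[[paste0("score_", k)]] <- pred[k, ]
  tib
}
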