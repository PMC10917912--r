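#' Per-level classifiers and their weighted ensemble
#'
#' Each pyramid level `P4, P5, P6` feeds its own classifier: global average
#' pooling, then two fully connected layers (`channels -> hidden -> K`
#' class scores, ReLU in between).  The three score vectors are combined by
#' a weighted ensemble with non-negative learnable weights:
#' \deqn{pred = \frac{\sum_k w_k \, out_k}{\epsilon + \sum_k w_k},}
#' where \eqn{\epsilon = 10^{-4}} is added once to the summed denominator
#' (note the placement differs from the per-site fusion rule).  The
#' ensembled quantities are raw class scores (logits); the training loss is
#' cross-entropy on `pred` alone, and the predicted label is the argmax of
#' `pred` with ties broken by the lowest class index.
#'
#' @param channels pyramid width feeding each branch (default 256).
#' @param num_classes number of classes K (default 4 stages).
#' @param hidden width of the first fully connected layer (default 256).
#' @param epsilon denominator constant of the ensemble rule.
#' @return An object of class `wfpn_head` with three classifier branches and
#'   the learnable ensemble weights.
#' @export
ensemble_head <- function(channels = 256L, num_classes = 4L,
                          hidden = 256L, epsilon = 1e-4) {
  branch <- function() {
    list(fc1 = linear_layer(channels, hidden),
         fc2 = linear_layer(hidden, num_classes))
  }
  structure(list(branches = list(`4` = branch(), `5` = branch(),
                                 `6` = branch()),
                 raw_weights = ag_param(rep(1, 3)),
                 epsilon = epsilon,
                 channels = as.integer(channels),
                 num_classes = as.integer(num_classes)),
            class = "wfpn_head")
}

#' @rdname ensemble_head
#' @param P_n pyramid feature map (`H x W x C x N` array or node).
#' @param branch one element of `head$branches` (or a head, in which case
#'   the level-4 branch is used).
#' @return `classify_level()`: a `K x N` score matrix (or node).
#' @export
classify_level <- function(P_n, branch) {
  if (inherits(branch, "wfpn_head")) branch <- branch$branches[["4"]]
  Fn <- as_node(P_n)
  d <- dim4(Fn)
  feat <- ag_reshape(ag_gap(Fn), c(d[3], d[4]))
  out <- linear_fwd(branch$fc2, ag_relu(linear_fwd(branch$fc1, feat)))
  if (!is_node(P_n)) node_value(out) else out
}

#' @rdname ensemble_head
#' @param outs list of three same-shape `K x N` score matrices (or nodes).
#' @param head an `ensemble_head()`.
#' @return `ensemble_logits()`: the ensembled `K x N` prediction scores.
#' @examples
#' h <- ensemble_head(channels = 8, num_classes = 3, hidden = 4)
#' outs <- list(diag(3), diag(3), diag(3))
#' ensemble_logits(outs, h)  # equal weights: mean of the three, eps-shrunk
#' @export
ensemble_logits <- function(outs, head) {
  stopifnot(inherits(head, "wfpn_head"), length(outs) == 3L)
  was_array <- !any(vapply(outs, is_node, logical(1)))
  w <- ag_relu(head$raw_weights)
  denom <- ag_add_const(ag_sum(w), head$epsilon)
  num <- ag_scale(as_node(outs[[1]]), ag_pick(w, 1L))
  for (k in 2:3) {
    num <- ag_add(num, ag_scale(as_node(outs[[k]]), ag_pick(w, k)))
  }
  pred <- ag_div_scalar(num, denom)
  if (was_array) node_value(pred) else pred
}

head_forward <- function(head, P) {
  outs <- lapply(c("4", "5", "6"), function(l) {
    classify_level(P[[l]], head$branches[[l]])
  })
  list(outs = outs, pred = ensemble_logits(outs, head))
}
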