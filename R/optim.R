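#' Cosine-annealed learning rate
#'
#' Closed form of the schedule used by the training loop: over `epochs`
#' logged steps the rate decays from `lr0` at the first step to `floor` at
#' the last, \deqn{lr(e) = floor + \tfrac{1}{2}(lr_0 - floor)\,
#' (1 + \cos(\pi (e - 1) / (E - 1))), \quad e = 1, \dots, E.}
#'
#' @param epoch 1-based epoch index (vectorized).
#' @param epochs total number of epochs E.
#' @param lr0 initial learning rate (default 2e-4).
#' @param floor terminal learning rate (default 0).
#' @return Learning rate(s) at the requested epoch(s).
#' @examples
#' cosine_lr(1, 100)    # 2e-4
#' cosine_lr(100, 100)  # 0
#' @export
cosine_lr <- function(epoch, epochs, lr0 = 2e-4, floor = 0) {
  stopifnot(all(epoch >= 1), epochs >= 1)
  if (epochs == 1L) return(rep(lr0, length(epoch)))
  floor + 0.5 * (lr0 - floor) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

# AdamW: Adam moments with decoupled weight decay (theta -= lr * wd * theta).
adamw_state <- function(params, weight_decay = 1e-4,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L, weight_decay = weight_decay,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adamw_step <- function(state, params, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + state$eps) -
      lr * state$weight_decay * p$value
  }
  state
}
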