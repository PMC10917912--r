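# Layer constructors: parameter containers around ag_param nodes.
# Initialization draws from the caller's RNG stream (seed once per model).

he_sd <- function(fan_in) sqrt(2 / fan_in)

conv_layer <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                       bias = TRUE, init_sd = NULL) {
  sd <- init_sd %||% he_sd(k * k * cin)
  w <- ag_param(array(stats::rnorm(k * k * cin * cout, sd = sd),
                      c(k, k, cin, cout)))
  b <- if (bias) ag_param(numeric(cout)) else NULL
  structure(list(w = w, b = b, k = k, stride = stride, pad = pad,
                 cin = cin, cout = cout),
            class = "wfpn_conv")
}

conv_fwd <- function(layer, x) {
  ag_conv2d(x, layer$w, layer$b, stride = layer$stride, pad = layer$pad)
}

linear_layer <- function(cin, cout, init_sd = NULL, bias = TRUE) {
  sd <- init_sd %||% he_sd(cin)
  w <- ag_param(matrix(stats::rnorm(cout * cin, sd = sd), cout, cin))
  b <- if (bias) ag_param(numeric(cout)) else NULL
  structure(list(w = w, b = b, cin = cin, cout = cout),
            class = "wfpn_linear")
}

linear_fwd <- function(layer, x) ag_linear(x, layer$w, layer$b)

# Batch normalization over (H, W, N) per channel.  Training mode normalizes
# by batch statistics and updates running estimates (kept in an environment);
# evaluation mode uses the running estimates, so it is deterministic.
bn_layer <- function(channels, momentum = 0.1, eps = 1e-5) {
  state <- new.env(parent = emptyenv())
  state$mean <- numeric(channels)
  state$var <- rep(1, channels)
  structure(list(gamma = ag_param(rep(1, channels)),
                 beta = ag_param(numeric(channels)),
                 state = state, momentum = momentum, eps = eps,
                 channels = as.integer(channels)),
            class = "wfpn_bn")
}

bn_fwd <- function(layer, x, training = FALSE) {
  x <- as_node(x)
  d <- dim4(x)
  C <- d[3]
  stopifnot(C == layer$channels)
  m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x$value, c(1L, 2L, 4L, 3L)), ncol = C)  # (m, C)
  if (training) {
    mu <- colMeans(xm)
    ctr <- xm - rep(mu, each = m)
    va <- colMeans(ctr * ctr)
    if (m > 1L) {
      st <- layer$state
      st$mean <- (1 - layer$momentum) * st$mean + layer$momentum * mu
      st$var <- (1 - layer$momentum) * st$var +
        layer$momentum * va * m / (m - 1)
    }
  } else {
    mu <- layer$state$mean
    va <- layer$state$var
    ctr <- xm - rep(mu, each = m)
  }
  s <- sqrt(va + layer$eps)
  xhat <- ctr / rep(s, each = m)
  ym <- xhat * rep(layer$gamma$value, each = m) +
    rep(layer$beta$value, each = m)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1L, 2L, 4L, 3L))
  ag_node(y, list(x, layer$gamma, layer$beta), function(g) {
    gm <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gs <- rep(layer$gamma$value / s, each = m)
    dxm <- if (training) {
      (gm - rep(dbeta / m, each = m) -
         xhat * rep(dgamma / m, each = m)) * gs
    } else {
      gm * gs
    }
    dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1L, 2L, 4L, 3L))
    list(dx, dgamma, dbeta)
  })
}

# Recursively collect every trainable ag_param in a nested module list.
collect_params <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (is_node(o)) {
      if (o$requires_grad) out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (el in o) if (!is.null(el)) walk(el)
    }
  }
  walk(obj)
  out
}

# Recursively collect batch-norm layers (their running stats live in envs).
collect_bn <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (inherits(o, "wfpn_bn")) {
      out[[length(out) + 1L]] <<- o
    } else if (is.list(o) && !is_node(o)) {
      for (el in o) if (!is.null(el)) walk(el)
    }
  }
  walk(obj)
  out
}

# Snapshot / restore parameter values (in-memory checkpointing).
param_values <- function(params) lapply(params, function(p) p$value)

set_param_values <- function(params, values) {
  stopifnot(length(params) == length(values))
  for (i in seq_along(params)) params[[i]]$value <- values[[i]]
  invisible(params)
}

# Full model state: parameters plus batch-norm running statistics.
model_state <- function(model) {
  list(params = param_values(model$params),
       bn = lapply(model$bn_layers, function(l) {
         list(mean = l$state$mean, var = l$state$var)
       }))
}

set_model_state <- function(model, state) {
  set_param_values(model$params, state$params)
  stopifnot(length(model$bn_layers) == length(state$bn))
  for (i in seq_along(state$bn)) {
    model$bn_layers[[i]]$state$mean <- state$bn[[i]]$mean
    model$bn_layers[[i]]$state$var <- state$bn[[i]]$var
  }
  invisible(model)
}
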