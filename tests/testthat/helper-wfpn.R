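# Shared fixtures: tiny model builders and a finite-difference checker.

tiny_config <- function(...) {
  wfpn_config(backbone = "tiny", neck_channels = 16L, cbam_reduction = 4L,
              head_hidden = 16L, ...)
}

tiny_model <- function(seed = 42L, ...) {
  withr::with_seed(seed, wfpn_model(tiny_config(...)))
}

# central finite differences of a scalar-node-producing closure w.r.t. a
# parameter node, at a few sampled coordinates
num_grad <- function(loss_fn, param, idx, h = 1e-6) {
  vapply(idx, function(i) {
    v0 <- param$value
    param$value[i] <- v0[i] + h
    lp <- loss_fn()$value
    param$value <- v0
    param$value[i] <- v0[i] - h
    lm <- loss_fn()$value
    param$value <- v0
    (lp - lm) / (2 * h)
  }, numeric(1))
}

expect_grad_matches <- function(loss_fn, params, n_coords = 4L, tol = 1e-6) {
  loss <- loss_fn()
  wfpn:::ag_zero_grad(params)
  wfpn:::ag_backward(loss)
  for (p in params) {
    idx <- sample(length(p$value), min(n_coords, length(p$value)))
    expect_equal(as.numeric(p$grad[idx]), num_grad(loss_fn, p, idx),
                 tolerance = tol)
  }
}

# set every parameter of a cbam block (or other module) to zero
zero_params <- function(module) {
  for (p in wfpn:::collect_params(module)) p$value <- p$value * 0
  invisible(module)
}

# small labelled score table for metric tests
random_records <- function(n, k = 4L) {
  tibble::tibble(truth = sample.int(k, n, replace = TRUE),
                 pred = sample.int(k, n, replace = TRUE)) |>
    (\(d) {
      for (j in seq_len(k)) d[[paste0("score_", j)]] <- stats::rnorm(n)
      d
    })()
}
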