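# Finite-difference validation of every backward pass in the engine.

test_that("convolution gradients match finite differences across strides and padding", {
  withr::with_seed(1, {
    for (case in list(list(k = 3L, stride = 1L, pad = 1L),
                      list(k = 3L, stride = 2L, pad = 1L),
                      list(k = 1L, stride = 1L, pad = 0L),
                      list(k = 7L, stride = 1L, pad = 3L))) {
      x <- wfpn:::ag_param(array(rnorm(6 * 7 * 2 * 2), c(6, 7, 2, 2)))
      w <- wfpn:::ag_param(array(rnorm(case$k^2 * 2 * 3, sd = 0.5),
                                 c(case$k, case$k, 2, 3)))
      b <- wfpn:::ag_param(rnorm(3))
      loss_fn <- function() {
        y <- wfpn:::ag_conv2d(x, w, b, stride = case$stride, pad = case$pad)
        wfpn:::ag_sum(wfpn:::ag_sigmoid(y))
      }
      expect_grad_matches(loss_fn, list(x, w, b))
    }
  })
})

test_that("pooling, resize and gating gradients match finite differences", {
  withr::with_seed(2, {
    x <- wfpn:::ag_param(array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2)))
    cases <- list(
      function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_gap(x))),
      function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_gmp(x))),
      function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_chpool_mean(x))),
      function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_chpool_max(x))),
      function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_upsample_nearest(x, 8L, 12L))),
      function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_upsample_nearest(x, 7L, 5L))),
      function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_avgpool_to(x, 2L, 2L))),
      function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_avgpool_to(x, 1L, 1L)))
    )
    for (loss_fn in cases) expect_grad_matches(loss_fn, list(x))

    gate_c <- wfpn:::ag_param(array(runif(3 * 2), c(1, 1, 3, 2)))
    loss_fn <- function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_mul_bcast(x, gate_c)))
    expect_grad_matches(loss_fn, list(x, gate_c))

    gate_s <- wfpn:::ag_param(array(runif(4 * 4 * 2), c(4, 4, 1, 2)))
    loss_fn <- function() wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::ag_mul_bcast(x, gate_s)))
    expect_grad_matches(loss_fn, list(x, gate_s))
  })
})

test_that("linear, batch-norm and cross-entropy gradients match finite differences", {
  withr::with_seed(3, {
    x <- wfpn:::ag_param(matrix(rnorm(5 * 4), 5, 4))
    w <- wfpn:::ag_param(matrix(rnorm(3 * 5), 3, 5))
    b <- wfpn:::ag_param(rnorm(3))
    y <- c(1L, 3L, 2L, 3L)
    loss_fn <- function() wfpn:::ag_cross_entropy(wfpn:::ag_linear(x, w, b), y)
    expect_grad_matches(loss_fn, list(x, w, b))

    # batch norm in training mode (running-stat updates don't affect the pass)
    xb <- wfpn:::ag_param(array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4)))
    bn <- wfpn:::bn_layer(2L)
    loss_fn <- function() {
      wfpn:::ag_sum(wfpn:::ag_sigmoid(wfpn:::bn_fwd(bn, xb, training = TRUE)))
    }
    expect_grad_matches(loss_fn, list(xb, bn$gamma, bn$beta), tol = 1e-5)
  })
})

test_that("gradients accumulate correctly when a node is reused", {
  x <- wfpn:::ag_param(array(2, c(1, 1, 1, 1)))
  y <- wfpn:::ag_sum(wfpn:::ag_add(x, x))  # d/dx (2x) = 2
  wfpn:::ag_backward(y)
  expect_equal(as.numeric(x$grad), 2)
})

test_that("batch norm is deterministic in evaluation mode and batch-dependent in training", {
  withr::with_seed(4, {
    bn <- wfpn:::bn_layer(3L)
    x <- array(rnorm(2 * 2 * 3 * 4), c(2, 2, 3, 4))
    e1 <- wfpn:::node_value(wfpn:::bn_fwd(bn, x, training = FALSE))
    e2 <- wfpn:::node_value(wfpn:::bn_fwd(bn, x, training = FALSE))
    expect_identical(e1, e2)
    t1 <- wfpn:::node_value(wfpn:::bn_fwd(bn, x, training = TRUE))
    # training mode standardizes by batch statistics
    expect_equal(mean(t1[, , 1, ]), 0, tolerance = 1e-8)
    expect_false(identical(e1, t1))
  })
})
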