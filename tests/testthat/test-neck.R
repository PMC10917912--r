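# Weighted-fusion core: Eq.-level examples, normalization properties,
# pathway shape contracts and gradient flow.

const_map <- function(v, h = 2L, w = 2L, c = 1L, n = 1L) array(v, c(h, w, c, n))

test_that("fast-normalized fusion reproduces hand-computed values", {
  node <- fusion_node(2L, epsilon = 1e-4)
  out <- fast_normalized_fusion(list(const_map(1), const_map(1)), node)
  expect_equal(out[1, 1, 1, 1], 2 / (2 + 1e-4))

  node0 <- fusion_node(2L, epsilon = 0)
  node0$raw_weights$value <- c(3, 1)
  out <- fast_normalized_fusion(list(const_map(1), const_map(5)), node0)
  expect_equal(unique(as.vector(out)), 2.0)
})

test_that("a zero-weight input cannot influence the fused output", {
  node <- fusion_node(2L, epsilon = 1e-4)
  node$raw_weights$value <- c(0, 2)
  withr::with_seed(1, {
    a1 <- array(rnorm(16), c(2, 2, 2, 2))
    a2 <- array(rnorm(16), c(2, 2, 2, 2))
    b <- array(rnorm(16), c(2, 2, 2, 2))
  })
  expect_identical(fast_normalized_fusion(list(a1, b), node),
                   fast_normalized_fusion(list(a2, b), node))
})

test_that("fusion coefficients are normalized, bounded and monotone in the raw weights", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      node <- fusion_node(3L, epsilon = 1e-4)
      node$raw_weights$value <- runif(3, 0, 5)
      co <- fusion_coefficients(node)
      w <- node$raw_weights$value
      expect_true(all(co >= 0 & co < 1))
      expect_equal(sum(co), sum(w) / (sum(w) + 1e-4))
      # raising one raw weight raises its coefficient, lowers the others
      i <- sample(3, 1)
      node$raw_weights$value[i] <- w[i] + 0.5
      co2 <- fusion_coefficients(node)
      expect_gt(co2[i], co[i])
      expect_true(all(co2[-i] < co[-i]))
    }
  })
})

test_that("mismatched shapes or weight counts are rejected", {
  node <- fusion_node(2L)
  expect_error(fast_normalized_fusion(list(const_map(1), const_map(1, h = 3)),
                                      node), "share shape")
  expect_error(fast_normalized_fusion(list(const_map(1)), node))
})

test_that("top-down step matches the published shape contract", {
  withr::with_seed(2, {
    node <- fusion_node(2L, epsilon = 1e-4,
                        proj = wfpn:::conv_layer(2048L, 256L, k = 1L, pad = 0L),
                        smooth = wfpn:::conv_layer(256L, 256L, k = 3L, pad = 1L))
    B5 <- array(rnorm(7 * 7 * 2048 * 2), c(7, 7, 2048, 2))
    F6 <- array(rnorm(256 * 2), c(1, 1, 256, 2))
    F5 <- top_down_step(B5, F6, node)
    expect_equal(dim(F5), c(7, 7, 256, 2))
  })
})

test_that("with the upper branch weighted zero the step reduces to the projected map", {
  withr::with_seed(3, {
    node <- fusion_node(2L, epsilon = 1e-4,
                        proj = wfpn:::conv_layer(8L, 4L, k = 1L, pad = 0L))
    node$raw_weights$value <- c(1, 0)
    B <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
    up <- array(rnorm(4 * 2 * 2), c(2, 2, 4, 1))
    out <- top_down_step(B, up, node)
    proj <- wfpn:::node_value(wfpn:::conv_fwd(node$proj, B))
    expect_equal(out, proj * (1 / (1 + 1e-4)))
  })
})

test_that("one-pixel fusion with identity projections averages the inputs", {
  node <- fusion_node(2L, epsilon = 0,
                      proj = wfpn:::conv_layer(1L, 1L, k = 1L, pad = 0L))
  node$proj$w$value <- array(1, c(1, 1, 1, 1))
  node$proj$b$value <- 0
  a <- const_map(3, h = 1L, w = 1L)
  b <- const_map(7, h = 1L, w = 1L)
  # scalar evaluation: (1*3 + 1*7) / 2 = 5
  expect_equal(as.numeric(top_down_step(a, b, node)), 5)
})

test_that("the pyramid top pools B6 globally before the channel projection", {
  proj <- wfpn:::conv_layer(1L, 1L, k = 1L, pad = 0L)
  proj$w$value <- array(1, c(1, 1, 1, 1))
  proj$b$value <- 0
  # constant map: avg = max = c, so the projected output is 2c
  expect_equal(as.numeric(top_node_init(const_map(1.5, 4, 4), proj)), 3)
  # spike: max-pool picks the spike, avg-pool the brute-force mean
  withr::with_seed(4, x <- array(rnorm(16), c(4, 4, 1, 1)))
  x[2, 3, 1, 1] <- 50
  got <- as.numeric(top_node_init(x, proj))
  oracle <- 0
  for (i in 1:4) for (j in 1:4) oracle <- oracle + x[i, j, 1, 1] / 16
  expect_equal(got, oracle + 50)
  # shape contract on a wide map
  proj256 <- withr::with_seed(5, wfpn:::conv_layer(8L, 16L, k = 1L, pad = 0L))
  F6 <- top_node_init(array(1, c(4, 4, 8, 2)), proj256)
  expect_equal(dim(F6), c(1, 1, 16, 2))
})

test_that("bottom-up step downsamples, fuses and honours the shape contract", {
  withr::with_seed(5, {
    node <- fusion_node(2L, epsilon = 1e-4,
                        smooth = wfpn:::conv_layer(256L, 256L, k = 3L, pad = 1L))
    R5 <- array(rnorm(7 * 7 * 256 * 2), c(7, 7, 256, 2))
    P4 <- array(rnorm(14 * 14 * 256 * 2), c(14, 14, 256, 2))
    expect_equal(dim(bottom_up_step(R5, P4, node)), c(7, 7, 256, 2))
  })

  # zero weight on the lower branch: identity up to the epsilon shrinkage
  node <- fusion_node(2L, epsilon = 1e-4)
  node$raw_weights$value <- c(1, 0)
  withr::with_seed(6, {
    R <- array(rnorm(2 * 2 * 3), c(2, 2, 3, 1))
    P <- array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  })
  expect_equal(bottom_up_step(R, P, node), R * (1 / (1 + 1e-4)))

  # 2x2 -> 1x1 average reduction against a hand loop
  x <- array(c(1, 2, 3, 4), c(2, 2, 1, 1))
  down <- wfpn:::node_value(wfpn:::ag_avgpool_to(wfpn:::ag_input(x), 1L, 1L))
  expect_equal(as.numeric(down), 2.5)
  expect_error(bottom_up_step(P, R, fusion_node(2L)), "finer or equal")
})

test_that("every neck output carries the pyramid width and P4 ignores upper levels", {
  m <- tiny_model(seed = 10)
  x <- withr::with_seed(11, array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2)))
  out <- wfpn_forward(m, x, keep_maps = TRUE)
  for (grp in c("top_down", "refined", "bottom_up")) {
    for (map in out$maps[[grp]]) expect_equal(dim(map)[3], 16L)
  }
  expect_equal(dim(out$maps$top_down[["6"]])[1:2], c(1L, 1L))
  expect_identical(out$maps$bottom_up[["4"]], out$maps$refined[["4"]])
  # perturbing the upper bottom-up nodes never changes P4
  m$neck$bu5$raw_weights$value <- c(9, 9)
  m$neck$bu6$raw_weights$value <- c(0.1, 5)
  out2 <- wfpn_forward(m, x, keep_maps = TRUE)
  expect_identical(out2$maps$bottom_up[["4"]], out$maps$bottom_up[["4"]])
  expect_false(identical(out2$maps$bottom_up[["5"]], out$maps$bottom_up[["5"]]))
})

test_that("one backward pass delivers gradient to every fusion weight", {
  m <- tiny_model(seed = 12)
  x <- withr::with_seed(13, array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4)))
  out <- wfpn_forward(m, wfpn:::ag_input(x), training = TRUE)
  loss <- wfpn:::ag_cross_entropy(out$pred, c(1L, 2L, 3L, 4L))
  wfpn:::ag_backward(loss)
  for (nd in list(m$neck$td5, m$neck$td4, m$neck$bu5, m$neck$bu6)) {
    expect_false(is.null(nd$raw_weights$grad))
    expect_true(all(nd$raw_weights$grad != 0))
  }
  expect_true(all(m$head$raw_weights$grad != 0))
})
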