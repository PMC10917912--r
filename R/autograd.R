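# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Feature maps are stored as 4-D arrays with dim = c(H, W, C, N) (column-major,
# spatial index fastest), vectors/matrices as (C, N).  Every op builds a graph
# node holding the forward value, its parents and a backward closure; the graph
# is rebuilt on each forward pass (define-by-run).  Only what the package needs
# is implemented; each backward is checked against finite differences in the
# test suite.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

ag_node <- function(value, parents = list(), bw = NULL, requires_grad = FALSE) {
  needs <- requires_grad
  if (!needs) {
    for (p in parents) if (p$needs) { needs <- TRUE; break }
  }
  e <- new.env(parent = emptyenv())
  .ag$id <- .ag$id + 1L
  e$nid <- .ag$id
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$requires_grad <- requires_grad
  e$needs <- needs
  class(e) <- "ag_node"
  e
}

ag_input <- function(value) ag_node(value)
ag_param <- function(value) ag_node(value, requires_grad = TRUE)

is_node <- function(x) inherits(x, "ag_node")
as_node <- function(x) if (is_node(x)) x else ag_input(x)
node_value <- function(x) if (is_node(x)) x$value else x

dim4 <- function(x) {
  d <- dim(node_value(x))
  stopifnot(length(d) == 4L)
  d
}

# Backward pass from a scalar root: topological sort, then reverse accumulation.
ag_backward <- function(root) {
  stopifnot(is_node(root), length(root$value) == 1L)
  topo <- vector("list", 256L)
  k <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  visit <- function(n) {
    id <- as.character(n$nid)
    if (!is.null(seen[[id]]) || !n$needs) return(invisible(NULL))
    seen[[id]] <- TRUE
    for (p in n$parents) visit(p)
    k <<- k + 1L
    if (k > length(topo)) length(topo) <<- 2L * k
    topo[[k]] <<- n
    invisible(NULL)
  }
  visit(root)
  root$grad <- 1
  for (i in rev(seq_len(k))) {
    n <- topo[[i]]
    if (is.null(n$bw)) next
    gs <- n$bw(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$needs || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ------------------------------------------------------------

ag_relu <- function(x) {
  x <- as_node(x)
  v <- x$value
  v[v < 0] <- 0
  ag_node(v, list(x), function(g) {
    m <- x$value > 0
    list(g * m)
  })
}

ag_sigmoid <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  stopifnot(length(x$value) == length(y$value))
  ag_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

# y = x * s with s a scalar node
ag_scale <- function(x, s) {
  x <- as_node(x); s <- as_node(s)
  stopifnot(length(s$value) == 1L)
  ag_node(x$value * as.numeric(s$value), list(x, s), function(g) {
    list(g * as.numeric(s$value), sum(g * x$value))
  })
}

# y = x / s with s a scalar node
ag_div_scalar <- function(x, s) {
  x <- as_node(x); s <- as_node(s)
  sv <- as.numeric(s$value)
  ag_node(x$value / sv, list(x, s), function(g) {
    list(g / sv, -sum(g * x$value) / sv^2)
  })
}

ag_sum <- function(x) {
  x <- as_node(x)
  ag_node(sum(x$value), list(x), function(g) {
    list(array(as.numeric(g), dim = dim(x$value) %||% length(x$value)))
  })
}

ag_add_const <- function(x, k) {
  x <- as_node(x)
  ag_node(x$value + k, list(x), function(g) list(g))
}

# element i of a vector node, as a scalar node
ag_pick <- function(x, i) {
  x <- as_node(x)
  ag_node(x$value[i], list(x), function(g) {
    z <- numeric(length(x$value))
    z[i] <- as.numeric(g)
    list(z)
  })
}

ag_reshape <- function(x, dims) {
  x <- as_node(x)
  d0 <- dim(x$value) %||% length(x$value)
  ag_node(array(x$value, dim = dims), list(x), function(g) {
    list(array(g, dim = d0))
  })
}

# ---- convolution ------------------------------------------------------------

# x: (H,W,Cin,N); w: (k,k,Cin,Cout); b: length Cout or NULL.
# im2col layout: A is (Ho*Wo*N, k*k*Cin) so columns line up with matrix(w).
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  x <- as_node(x); w <- as_node(w)
  if (!is.null(b)) b <- as_node(b)
  xv <- x$value
  wv <- w$value
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dw <- dim(wv); k <- dw[1]
  stopifnot(dw[2] == k, dw[3] == C)
  Cout <- dw[4]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  stopifnot(Hp >= k, Wp >= k)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  if (pad > 0L) {
    xp <- array(0, c(Hp, Wp, C, N))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- xv
  } else xp <- xv
  xpa <- aperm(xp, c(1L, 2L, 4L, 3L))  # (Hp,Wp,N,C)
  col <- array(0, c(Ho, Wo, N, k, k, C))
  for (ki in seq_len(k)) {
    rows <- seq.int(ki, by = stride, length.out = Ho)
    for (kj in seq_len(k)) {
      cols <- seq.int(kj, by = stride, length.out = Wo)
      col[, , , ki, kj, ] <- xpa[rows, cols, , , drop = FALSE]
    }
  }
  A <- matrix(col, nrow = Ho * Wo * N)
  Wm <- matrix(wv, ncol = Cout)
  Y <- A %*% Wm
  if (!is.null(b)) Y <- Y + rep(b$value, each = nrow(Y))
  out <- aperm(array(Y, c(Ho, Wo, N, Cout)), c(1L, 2L, 4L, 3L))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(out, parents, function(g) {
    G <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), nrow = Ho * Wo * N)
    dwv <- array(crossprod(A, G), dim = dw)
    dxv <- NULL
    if (x$needs) {
      dA <- tcrossprod(G, Wm)  # (Ho*Wo*N, k*k*C)
      dcol <- array(dA, c(Ho, Wo, N, k, k, C))
      dxpa <- array(0, c(Hp, Wp, N, C))
      for (ki in seq_len(k)) {
        rows <- seq.int(ki, by = stride, length.out = Ho)
        for (kj in seq_len(k)) {
          cols <- seq.int(kj, by = stride, length.out = Wo)
          dxpa[rows, cols, , ] <- dxpa[rows, cols, , , drop = FALSE] +
            array(dcol[, , , ki, kj, , drop = FALSE], c(Ho, Wo, N, C))
        }
      }
      dxp <- aperm(dxpa, c(1L, 2L, 4L, 3L))
      dxv <- if (pad > 0L) {
        dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
      } else dxp
    }
    if (is.null(b)) list(dxv, dwv) else list(dxv, dwv, colSums(G))
  })
}

# ---- pooling ----------------------------------------------------------------

# global average pool over H,W -> (1,1,C,N)
ag_gap <- function(x) {
  x <- as_node(x)
  d <- dim4(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  v <- colMeans(matrix(x$value, nrow = H * W))
  ag_node(array(v, c(1L, 1L, C, N)), list(x), function(g) {
    list(array(rep(as.vector(g), each = H * W) / (H * W), d))
  })
}

# global max pool over H,W -> (1,1,C,N); ties take the first position
ag_gmp <- function(x) {
  x <- as_node(x)
  d <- dim4(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- matrix(x$value, nrow = H * W)
  idx <- max.col(t(m), ties.method = "first")
  v <- m[cbind(idx, seq_len(ncol(m)))]
  ag_node(array(v, c(1L, 1L, C, N)), list(x), function(g) {
    z <- matrix(0, nrow = H * W, ncol = C * N)
    z[cbind(idx, seq_len(ncol(z)))] <- as.vector(g)
    list(array(z, d))
  })
}

# mean across the channel axis -> (H,W,1,N)
ag_chpool_mean <- function(x) {
  x <- as_node(x)
  d <- dim4(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  a <- aperm(array(x$value, c(H * W, C, N)), c(2L, 1L, 3L))  # (C, HW, N)
  v <- colMeans(matrix(a, nrow = C))
  ag_node(array(v, c(H, W, 1L, N)), list(x), function(g) {
    gm <- array(as.vector(g), c(H * W, 1L, N))
    list(array(gm[, rep(1L, C), , drop = FALSE] / C, d))
  })
}

# max across the channel axis -> (H,W,1,N); ties take the first channel
ag_chpool_max <- function(x) {
  x <- as_node(x)
  d <- dim4(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  a <- matrix(aperm(array(x$value, c(H * W, C, N)), c(2L, 1L, 3L)), nrow = C)
  idx <- max.col(t(a), ties.method = "first")
  v <- a[cbind(idx, seq_len(ncol(a)))]
  ag_node(array(v, c(H, W, 1L, N)), list(x), function(g) {
    z <- matrix(0, nrow = C, ncol = H * W * N)
    z[cbind(idx, seq_len(ncol(z)))] <- as.vector(g)
    list(array(aperm(array(z, c(C, H * W, N)), c(2L, 1L, 3L)), d))
  })
}

# nearest-neighbour resize to (oh, ow); oh >= H, ow >= W (upsample / broadcast)
ag_upsample_nearest <- function(x, oh, ow) {
  x <- as_node(x)
  d <- dim4(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  stopifnot(oh >= H, ow >= W)
  idxh <- pmin(H, ((seq_len(oh) - 1L) * H) %/% oh + 1L)
  idxw <- pmin(W, ((seq_len(ow) - 1L) * W) %/% ow + 1L)
  v <- x$value[idxh, idxw, , , drop = FALSE]
  ag_node(v, list(x), function(g) {
    # adjoint: sum output cells mapping to each source cell
    m <- matrix(g, nrow = oh)
    r <- rowsum(m, group = idxh)                       # (H, ow*C*N)
    a <- aperm(array(r, c(H, ow, C, N)), c(2L, 1L, 3L, 4L))
    r2 <- rowsum(matrix(a, nrow = ow), group = idxw)   # (W, H*C*N)
    list(aperm(array(r2, c(W, H, C, N)), c(2L, 1L, 3L, 4L)))
  })
}

# average-pool downsample to (oh, ow); requires integer factors (or global 1x1)
ag_avgpool_to <- function(x, oh, ow) {
  x <- as_node(x)
  d <- dim4(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (oh == 1L && ow == 1L) return(ag_gap(x))
  stopifnot(H %% oh == 0L, W %% ow == 0L)
  fh <- H %/% oh; fw <- W %/% ow
  s1 <- array(colSums(matrix(x$value, nrow = fh)), c(oh, W, C, N))
  a <- aperm(s1, c(2L, 1L, 3L, 4L))                    # (W, oh, C, N)
  s2 <- array(colSums(matrix(a, nrow = fw)), c(ow, oh, C, N))
  v <- aperm(s2, c(2L, 1L, 3L, 4L)) / (fh * fw)
  ag_node(v, list(x), function(g) {
    gu <- g[rep(seq_len(oh), each = fh), rep(seq_len(ow), each = fw), , ,
            drop = FALSE]
    list(gu / (fh * fw))
  })
}

# ---- broadcast multiply (attention gates) -----------------------------------

# replicate an array with singleton dims 1 and/or 3 up to dim d
bcast4 <- function(v, d) {
  dv <- dim(v)
  if (identical(as.integer(dv), as.integer(d))) return(v)
  a <- array(as.vector(v), c(dv[1] * dv[2], dv[3], dv[4]))
  if (dv[1] * dv[2] == 1L && d[1] * d[2] > 1L) {
    a <- a[rep(1L, d[1] * d[2]), , , drop = FALSE]
  }
  if (dv[3] == 1L && d[3] > 1L) {
    a <- a[, rep(1L, d[3]), , drop = FALSE]
  }
  array(a, d)
}

# x * gate where gate has singleton spatial dims (channel gate (1,1,C,N)) or a
# singleton channel dim (spatial gate (H,W,1,N)); grads sum over broadcast dims
ag_mul_bcast <- function(x, gate) {
  x <- as_node(x); gate <- as_node(gate)
  d <- dim4(x)
  dg <- dim4(gate)
  gb <- bcast4(gate$value, d)
  ag_node(x$value * gb, list(x, gate), function(g) {
    dgate <- g * x$value
    if (dg[1] == 1L && dg[2] == 1L && (d[1] > 1L || d[2] > 1L)) {
      dgate <- array(colSums(matrix(dgate, nrow = d[1] * d[2])),
                     c(1L, 1L, d[3], d[4]))
    } else if (dg[3] == 1L && d[3] > 1L) {
      a <- matrix(aperm(array(dgate, c(d[1] * d[2], d[3], d[4])),
                        c(2L, 1L, 3L)), nrow = d[3])
      dgate <- array(colSums(a), c(d[1], d[2], 1L, d[4]))
    }
    list(g * gb, dgate)
  })
}

# ---- dense / loss -----------------------------------------------------------

# x: (Cin, N); w: (Cout, Cin); b: length Cout or NULL
ag_linear <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  if (!is.null(b)) b <- as_node(b)
  y <- w$value %*% x$value
  if (!is.null(b)) y <- y + b$value
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(g) {
    dx <- if (x$needs) crossprod(w$value, g) else NULL
    dw <- tcrossprod(g, x$value)
    if (is.null(b)) list(dx, dw) else list(dx, dw, rowSums(g))
  })
}

# mean cross-entropy of logits (K, N) against labels in 1..K
ag_cross_entropy <- function(logits, labels) {
  logits <- as_node(logits)
  lv <- logits$value
  K <- nrow(lv); N <- ncol(lv)
  stopifnot(length(labels) == N, all(labels >= 1L), all(labels <= K))
  z <- sweep(lv, 2L, apply(lv, 2L, max))
  ez <- exp(z)
  p <- sweep(ez, 2L, colSums(ez), "/")
  loss <- -mean(log(pmax(p[cbind(labels, seq_len(N))], 1e-300)))
  ag_node(loss, list(logits), function(g) {
    d <- p
    d[cbind(labels, seq_len(N))] <- d[cbind(labels, seq_len(N))] - 1
    list(as.numeric(g) * d / N)
  })
}
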