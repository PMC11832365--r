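#' @useDynLib mrisynth, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Minimal eager tape-based reverse-mode autodiff over dense R arrays.
#
# Conventions:
#   * feature maps : arrays (H, W, C, N), column-major
#   * matrices     : (N, F) for dense layers
#   * scalars      : length-1 numerics
# Every op builds a node eagerly; backward() topologically sorts the graph
# reachable from a scalar loss and accumulates gradients into leaves created
# with nn_param().
# ---------------------------------------------------------------------------

.nn <- new.env(parent = emptyenv())
.nn$id <- 0L

nn_node <- function(value, parents = list(), backfn = NULL,
                    req = NULL) {
  if (is.null(req)) {
    req <- FALSE
    for (p in parents) if (p$req) { req <- TRUE; break }
  }
  e <- new.env(parent = emptyenv())
  .nn$id <- .nn$id + 1L
  e$id <- .nn$id
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$req <- req
  e$leaf <- length(parents) == 0L
  class(e) <- "nn_node"
  e
}

#' @export
print.nn_node <- function(x, ...) {
  d <- dim(x$value)
  cat("<nn_node", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$req) "grad" else "", ">\n")
  invisible(x)
}

nn_param <- function(value) {
  n <- nn_node(value, req = TRUE)
  n$is_param <- TRUE
  n$grad <- array(0, dim = if (is.null(dim(value))) length(value) else dim(value))
  n
}

nn_const <- function(value) nn_node(value, req = FALSE)

nn_is_node <- function(x) inherits(x, "nn_node")

.acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse-accumulate gradients from scalar `root` into all reachable
# require-grad leaves. Clears intermediate grads afterwards.
nn_backward <- function(root) {
  stopifnot(length(root$value) == 1L)
  # iterative DFS topological sort (post-order) over req subgraph
  topo <- vector("list", 256L); nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L)); ns <- 1L
  assign(as.character(root$id), TRUE, envir = seen)
  while (ns > 0L) {
    fr <- stack[[ns]]
    node <- fr$node
    kids <- node$parents
    advanced <- FALSE
    while (fr$i < length(kids)) {
      fr$i <- fr$i + 1L
      k <- kids[[fr$i]]
      key <- as.character(k$id)
      if (k$req && !k$leaf && is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        stack[[ns]] <- fr
        ns <- ns + 1L
        stack[[ns]] <- list(node = k, i = 0L)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      stack[[ns]] <- fr
      ns <- ns - 1L
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
    }
  }
  root$grad <- 1
  for (i in seq(nt, 1L)) {
    node <- topo[[i]]
    if (is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      if (ps[[j]]$req && !is.null(gs[[j]])) .acc(ps[[j]], gs[[j]])
    }
    if (!isTRUE(node$is_param)) node$grad <- NULL  # free
  }
  # clear non-param leaf grads picked up along the way
  invisible(NULL)
}

# ---- elementwise --------------------------------------------------------

nn_add <- function(a, b) nn_node(a$value + b$value, list(a, b),
                                 function(g) list(g, g))

nn_sub <- function(a, b) nn_node(a$value - b$value, list(a, b),
                                 function(g) list(g, -g))

nn_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  nn_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

nn_addc <- function(x, k) nn_node(x$value + k, list(x), function(g) list(g))
nn_mulc <- function(x, k) nn_node(x$value * k, list(x), function(g) list(g * k))

nn_neg <- function(x) nn_mulc(x, -1)

nn_pow <- function(x, p) {
  xv <- x$value
  nn_node(xv^p, list(x), function(g) list(g * p * xv^(p - 1)))
}

nn_log <- function(x) {
  xv <- x$value
  nn_node(log(xv), list(x), function(g) list(g / xv))
}

nn_exp <- function(x) {
  yv <- exp(x$value)
  nn_node(yv, list(x), function(g) list(g * yv))
}

nn_sqrt <- function(x) {
  yv <- sqrt(x$value)
  nn_node(yv, list(x), function(g) list(g * 0.5 / yv))
}

nn_abs <- function(x) {
  xv <- x$value
  nn_node(abs(xv), list(x), function(g) list(g * sign(xv)))
}

nn_clamp <- function(x, lo, hi) {
  xv <- x$value
  m <- (xv >= lo) & (xv <= hi)
  nn_node(pmin(pmax(xv, lo), hi), list(x), function(g) list(g * m))
}

nn_relu <- function(x) {
  xv <- x$value
  m <- xv > 0
  nn_node(xv * m, list(x), function(g) list(g * m))
}

nn_lrelu <- function(x, slope = 0.2) {
  xv <- x$value
  pos <- xv > 0
  m <- slope + (1 - slope) * pos
  nn_node(xv * m, list(x), function(g) list(g * m))
}

nn_sigmoid <- function(x) {
  yv <- 1 / (1 + exp(-x$value))
  nn_node(yv, list(x), function(g) list(g * yv * (1 - yv)))
}

nn_tanh <- function(x) {
  yv <- tanh(x$value)
  nn_node(yv, list(x), function(g) list(g * (1 - yv^2)))
}

# ---- reductions ---------------------------------------------------------

nn_sum <- function(x) {
  d <- dim(x$value); n <- length(x$value)
  nn_node(sum(x$value), list(x),
          function(g) list(if (is.null(d)) rep(g, n) else array(g, dim = d)))
}

nn_mean <- function(x) {
  d <- dim(x$value); n <- length(x$value)
  nn_node(mean(x$value), list(x),
          function(g) list(if (is.null(d)) rep(g / n, n)
                           else array(g / n, dim = d)))
}

# ---- shape ops ----------------------------------------------------------

nn_reshape <- function(x, d) {
  d0 <- dim(x$value)
  v <- x$value; dim(v) <- d
  nn_node(v, list(x), function(g) { dim(g) <- d0; list(g) })
}

# (H,W,C,N) -> (N, H*W*C) row-per-sample matrix
nn_flatten <- function(x) {
  d <- dim(x$value)
  v <- t(matrix(x$value, prod(d[1:3]), d[4]))
  nn_node(v, list(x), function(g) {
    gg <- t(g); dim(gg) <- d; list(gg)
  })
}

# inverse of nn_flatten: (N, H*W*C) -> (H,W,C,N)
nn_unflatten <- function(x, hwc) {
  d <- dim(x$value)
  v <- t(x$value); dim(v) <- c(hwc, d[1])
  nn_node(v, list(x), function(g) {
    list(t(matrix(g, prod(hwc), d[1])))
  })
}

nn_aperm <- function(x, perm) {
  inv <- order(perm)
  nn_node(aperm(x$value, perm), list(x),
          function(g) list(aperm(g, inv)))
}

nn_concat_c <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  H <- ds[[1]][1]; W <- ds[[1]][2]; N <- ds[[1]][4]
  cs <- vapply(ds, function(d) d[3], 0)
  Ct <- sum(cs)
  v <- array(0, c(H, W, Ct, N))
  at <- 0L
  for (i in seq_along(xs)) {
    v[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  nn_node(v, xs, function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- array(g[, , at + seq_len(cs[i]), , drop = FALSE],
                        dim = c(H, W, cs[i], N))
      at <- at + cs[i]
    }
    out
  })
}

nn_slice_c <- function(x, idx) {
  d <- dim(x$value)
  v <- array(x$value[, , idx, , drop = FALSE], dim = c(d[1], d[2], length(idx), d[4]))
  nn_node(v, list(x), function(g) {
    gg <- array(0, d)
    gg[, , idx, ] <- g
    list(gg)
  })
}

# ---- linear algebra -----------------------------------------------------

nn_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  nn_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

nn_transpose <- function(x) {
  nn_node(t(x$value), list(x), function(g) list(t(g)))
}

# x: (N, Fin); w: (Fin, Fout); b: (Fout)
nn_dense <- function(x, w, b) {
  xv <- x$value; wv <- w$value
  y <- xv %*% wv
  y <- sweep(y, 2, b$value, "+")
  nn_node(y, list(x, w, b), function(g)
    list(g %*% t(wv), t(xv) %*% g, colSums(g)))
}

nn_softmax_rows <- function(x) {
  xv <- x$value
  m <- apply(xv, 1, max)
  e <- exp(xv - m)
  yv <- e / rowSums(e)
  nn_node(yv, list(x), function(g) {
    list(yv * (g - rowSums(g * yv)))
  })
}

# ---- (N,C) broadcast over space ----------------------------------------

# x: (H,W,C,N); b: (N,C) -> y[h,w,c,n] = x + b[n,c]
nn_add_nc <- function(x, b) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  bb <- aperm(array(t(b$value), c(C, N, H, W)), c(3, 4, 1, 2))
  nn_node(x$value + bb, list(x, b), function(g) {
    gm <- matrix(g, H * W, C * N)
    s <- colSums(gm)                      # (C*N)
    list(g, t(matrix(s, C, N)))
  })
}

nn_mul_nc <- function(x, s) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  sv <- s$value
  ss <- aperm(array(t(sv), c(C, N, H, W)), c(3, 4, 1, 2))
  xv <- x$value
  nn_node(xv * ss, list(x, s), function(g) {
    gm <- matrix(g * xv, H * W, C * N)
    list(g * ss, t(matrix(colSums(gm), C, N)))
  })
}

# weighted global mean over space: w is a constant (H,W,1,N) weight array;
# y[n,c] = sum_hw x*w / sum_hw w
nn_global_wmean <- function(x, w) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wm <- matrix(w, H * W, N)                  # (HW, N)
  tot <- pmax(colSums(wm), 1e-8)             # per-sample mass
  xm <- matrix(x$value, H * W, C * N)
  # columns of xm are (c, n) pairs with n slowest
  widx <- rep(seq_len(N), each = C)
  v <- vapply(seq_len(C * N), function(j)
    sum(xm[, j] * wm[, widx[j]]) / tot[widx[j]], numeric(1))
  val <- t(matrix(v, C, N))                  # (N, C)
  nn_node(val, list(x), function(g) {
    gm <- matrix(0, H * W, C * N)
    for (j in seq_len(C * N))
      gm[, j] <- t(g)[j] * wm[, widx[j]] / tot[widx[j]]
    list(array(gm, d))
  })
}

nn_global_mean <- function(x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  v <- t(matrix(colMeans(matrix(x$value, H * W, C * N)), C, N))  # (N,C)
  nn_node(v, list(x), function(g) {
    gg <- aperm(array(t(g) / (H * W), c(C, N, H, W)), c(3, 4, 1, 2))
    list(gg)
  })
}

# ---- normalisation ------------------------------------------------------

# instance norm: per (channel, sample) over spatial dims
nn_instnorm <- function(x, eps = 1e-5) {
  d <- dim(x$value)
  HW <- d[1] * d[2]; CN <- d[3] * d[4]
  xm <- matrix(x$value, HW, CN)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc^2)
  sd <- sqrt(va + eps)
  xh <- sweep(xc, 2, sd, "/")
  yv <- array(xh, d)
  nn_node(yv, list(x), function(g) {
    gm <- matrix(g, HW, CN)
    t1 <- colMeans(gm)
    t2 <- colMeans(gm * xh)
    gx <- sweep(gm, 2, t1) - sweep(xh, 2, t2, "*")
    gx <- sweep(gx, 2, sd, "/")
    list(array(gx, d))
  })
}

# ---- structured ops (C++ kernels) ---------------------------------------

nn_conv <- function(x, w, b, stride = 1L, pad = 1L) {
  xv <- x$value; wv <- w$value
  y <- conv2d_fw(xv, wv, b$value, as.integer(stride), as.integer(pad))
  nn_node(y, list(x, w, b), function(g) {
    r <- conv2d_bw(xv, wv, g, as.integer(stride), as.integer(pad))
    list(r$gx, r$gw, r$gb)
  })
}

nn_upsample2 <- function(x) {
  d <- dim(x$value)
  nn_node(upsample2_fw(x$value), list(x),
          function(g) list(upsample2_bw(g, d[1], d[2])))
}

nn_avgpool2 <- function(x) {
  nn_node(avgpool2_fw(x$value), list(x),
          function(g) list(avgpool2_bw(g)))
}

nn_detach <- function(x) nn_const(x$value)

# single-sample view: (H,W,C,N) -> (H,W,C,1)
nn_slice_batch <- function(x, n) {
  d <- dim(x$value)
  v <- array(x$value[, , , n], c(d[1:3], 1))
  nn_node(v, list(x), function(g) {
    gg <- array(0, d)
    gg[, , , n] <- g
    list(gg)
  })
}

# stack (H,W,C,1) nodes into (H,W,C,N)
nn_stack_batch <- function(xs) {
  d <- dim(xs[[1]]$value)
  N <- length(xs)
  v <- array(0, c(d[1:3], N))
  for (i in seq_len(N)) v[, , , i] <- xs[[i]]$value
  nn_node(v, xs, function(g) {
    lapply(seq_len(N), function(i) array(g[, , , i], c(d[1:3], 1)))
  })
}

# ---------------------------------------------------------------------------
# Adam optimiser over a flat list of nn_param nodes.
# ---------------------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

adam_zero_grad <- function(st) {
  for (p in st$params) p$grad <- p$value * 0
  invisible(NULL)
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    st$m[[i]] <- st$b1 * st$m[[i]] + (1 - st$b1) * g
    st$v[[i]] <- st$b2 * st$v[[i]] + (1 - st$b2) * g^2
    p$value <- p$value - st$lr * (st$m[[i]] / bc1) /
      (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(NULL)
}

# Kaiming-style init helpers -------------------------------------------------

init_conv_param <- function(kh, kw, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (kh * kw * cin))
  nn_param(array(stats::rnorm(kh * kw * cin * cout, 0, sd),
                 c(kh, kw, cin, cout)))
}

init_dense_param <- function(fin, fout, gain = 1) {
  sd <- gain * sqrt(2 / fin)
  nn_param(matrix(stats::rnorm(fin * fout, 0, sd), fin, fout))
}

init_bias_param <- function(n) nn_param(numeric(n))
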