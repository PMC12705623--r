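# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Both trainable components of the package -- the relational graph attention
# network and the generative adversarial augmenter -- are expressed against
# this tape. Nodes are environments holding a value, their parents and a
# backward closure; backward() sweeps the tape in reverse creation order and
# accumulates gradients into every node created with track = TRUE (or with a
# tracked ancestor). The op set is deliberately small: exactly what graph
# attention, perceptrons and the contrastive objective need.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_push <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  nd$track <- length(parents) > 0 && any(vapply(parents, function(p) p$track, TRUE))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

# Leaf node. track = TRUE marks a trainable parameter (or anything a
# gradient is wanted for); constants enter with track = FALSE.
ad_input <- function(tape, value, track = FALSE) {
  value <- as.matrix(value)
  nd <- ad_push(tape, value)
  nd$track <- track
  nd
}

ad_value <- function(nd) nd$value

# Reverse sweep from a scalar loss node. After the call every tracked node
# on the tape carries its gradient in $grad.
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn) || !nd$track) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$track || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

# matrix + matrix, or matrix + row-vector bias (1 x d broadcast over rows)
ad_add <- function(tape, a, b) {
  bv <- b$value
  if (nrow(bv) == 1L && nrow(a$value) > 1L) {
    v <- sweep(a$value, 2, bv[1, ], "+")
    ad_push(tape, v, list(a, b), function(g) list(g, matrix(colSums(g), 1)))
  } else {
    ad_push(tape, a$value + bv, list(a, b), function(g) list(g, g))
  }
}

ad_mm <- function(tape, a, b, transpose_b = FALSE) {
  v <- if (transpose_b) a$value %*% t(b$value) else a$value %*% b$value
  av <- a$value; bv <- b$value
  ad_push(tape, v, list(a, b), function(g) {
    if (transpose_b) list(g %*% bv, t(g) %*% av) else list(g %*% t(bv), t(av) %*% g)
  })
}

ad_relu <- function(tape, a) {
  m <- a$value > 0
  ad_push(tape, a$value * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_push(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

ad_mul <- function(tape, a, b) {       # elementwise, same shape
  ad_push(tape, a$value * b$value, list(a, b),
          function(g) list(g * b$value, g * a$value))
}

ad_scale <- function(tape, a, s) {     # node * fixed scalar
  ad_push(tape, a$value * s, list(a), function(g) list(g * s))
}

# rows of a (E x d) scaled by weight column w (E x 1)
ad_scale_rows <- function(tape, a, w) {
  wv <- as.vector(w$value)
  ad_push(tape, a$value * wv, list(a, w), function(g)
    list(g * wv, matrix(rowSums(g * a$value), ncol = 1)))
}

# row-wise dot product of two E x d nodes -> E x 1
ad_rowdot <- function(tape, a, b) {
  v <- matrix(rowSums(a$value * b$value), ncol = 1)
  ad_push(tape, v, list(a, b), function(g) {
    gv <- as.vector(g)
    list(b$value * gv, a$value * gv)
  })
}

ad_gather_rows <- function(tape, a, idx) {
  nr <- nrow(a$value)
  ad_push(tape, a$value[idx, , drop = FALSE], list(a), function(g)
    list(segment_sum(g, idx, nr)))
}

ad_segment_sum <- function(tape, a, group, n) {
  ad_push(tape, segment_sum(a$value, group, n), list(a), function(g)
    list(g[group, , drop = FALSE]))
}

# softmax of a scores column (E x 1) within integer groups 1..n.
# Mean-shift per group keeps exp() in range without changing the result;
# a wide clamp guards against extreme spreads.
ad_segment_softmax <- function(tape, s, group, n) {
  sv <- as.vector(s$value)
  cnt <- tabulate(group, n)
  mu <- as.vector(segment_sum(matrix(sv), group, n)) / pmax(cnt, 1L)
  z <- pmin(pmax(sv - mu[group], -30), 30)
  e <- exp(z)
  denom <- as.vector(segment_sum(matrix(e), group, n))
  p <- e / denom[group]
  ad_push(tape, matrix(p, ncol = 1), list(s), function(g) {
    gv <- as.vector(g)
    dot <- as.vector(segment_sum(matrix(p * gv), group, n))
    list(matrix(p * (gv - dot[group]), ncol = 1))
  })
}

ad_rbind <- function(tape, nodes) {
  heights <- vapply(nodes, function(x) nrow(x$value), integer(1))
  v <- do.call(rbind, lapply(nodes, ad_value))
  ends <- cumsum(heights); starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_push(tape, v, nodes, function(g)
    lapply(seq_along(nodes), function(j) g[starts[j]:ends[j], , drop = FALSE]))
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(x) ncol(x$value), integer(1))
  v <- do.call(cbind, lapply(nodes, ad_value))
  ends <- cumsum(widths); starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_push(tape, v, nodes, function(g)
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE]))
}

# Row-wise layer normalization without affine parameters: (x - mean) / sd,
# population sd with a small epsilon.
ad_layernorm <- function(tape, a, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  y <- xc * inv
  d <- ncol(x)
  ad_push(tape, y, list(a), function(g) {
    gm <- rowMeans(g)
    gy <- rowMeans(g * y)
    list(inv * (g - gm - y * gy))
  })
}

# L2-normalize rows (zero rows pass through a floor on the norm).
ad_l2norm_rows <- function(tape, a, eps = 1e-12) {
  x <- a$value
  nrm <- sqrt(rowSums(x^2) + eps)
  y <- x / nrm
  ad_push(tape, y, list(a), function(g) {
    dot <- rowSums(g * y)
    list((g - y * dot) / nrm)
  })
}

# Mean over rows of -log softmax(logits)[target]; target is a 1-based
# column index per row. Covers both the two-class prediction head and the
# in-batch contrastive objective (target = diagonal).
ad_cross_entropy <- function(tape, logits, target) {
  z <- logits$value
  p <- softmax_rows(z)
  n <- nrow(z)
  ii <- cbind(seq_len(n), target)
  v <- matrix(-mean(log(pmax(p[ii], 1e-12))), 1, 1)
  ad_push(tape, v, list(logits), function(g) {
    gz <- p
    gz[ii] <- gz[ii] - 1
    list(gz * (as.vector(g) / n))
  })
}

# Mean binary cross-entropy on logits (numerically stable log1p form).
ad_bce_logits <- function(tape, logits, y) {
  z <- as.vector(logits$value)
  yv <- as.vector(y)
  n <- length(z)
  v <- matrix(mean(pmax(z, 0) - z * yv + log1p(exp(-abs(z)))), 1, 1)
  ad_push(tape, v, list(logits), function(g) {
    p <- 1 / (1 + exp(-z))
    list(matrix((p - yv) * (as.vector(g) / n), ncol = 1))
  })
}

ad_mean <- function(tape, a) {
  v <- matrix(mean(a$value), 1, 1)
  k <- length(a$value)
  dims <- dim(a$value)
  ad_push(tape, v, list(a), function(g)
    list(matrix(as.vector(g) / k, dims[1], dims[2])))
}

# Dropout with an externally supplied binary mask (deterministic given the
# caller's RNG state); inverted scaling so expectations match at rate 0.
ad_dropout <- function(tape, a, rate) {
  if (rate <= 0) return(a)
  m <- matrix(stats::rbinom(length(a$value), 1, 1 - rate), nrow(a$value)) / (1 - rate)
  ad_mul(tape, a, ad_input(tape, m))
}

# ---- parameter store and optimizer ----------------------------------------

# Parameters live in a flat named list of matrices; glorot init.
glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# Wrap every parameter matrix as a tracked tape input; returns a parallel
# named list of nodes.
ad_params <- function(tape, params) {
  lapply(params, function(p) ad_input(tape, p, track = TRUE))
}

ad_grads <- function(param_nodes) {
  lapply(param_nodes, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad
  })
}

# Adam with bias correction; state is carried in a closure.
make_adam <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- NULL; v <- NULL; t <- 0L
  function(params, grads) {
    if (is.null(m)) {
      m <<- lapply(params, function(p) p * 0)
      v <<- lapply(params, function(p) p * 0)
    }
    t <<- t + 1L
    for (nm in names(params)) {
      g <- grads[[nm]]
      m[[nm]] <<- beta1 * m[[nm]] + (1 - beta1) * g
      v[[nm]] <<- beta2 * v[[nm]] + (1 - beta2) * g^2
      mh <- m[[nm]] / (1 - beta1^t)
      vh <- v[[nm]] / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
    params
  }
}
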