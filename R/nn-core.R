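# Minimal neural-network core: layers with explicit forward/backward passes
# and an Adam optimizer. Batched activations are either matrices [N, D] or
# 3-d arrays [N, L, C]; parameters live in environments so the optimizer
# can update them in place.
#
# Nothing here is exported; the network module wires these pieces into the
# ResUbiNet graph.

par_new <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- array(0, dim = dim(value) %||% length(value))
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

glorot_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

# [N, L, C] <-> [N*L, C]; R's column-major order makes this a plain reshape
flat2d <- function(x) matrix(x, nrow = prod(dim(x)[1:2]), ncol = dim(x)[3])
unflat3d <- function(m, n, l) array(m, dim = c(n, l, ncol(m)))

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dense -----------------------------------------------------------------

nn_dense <- function(in_dim, out_dim, activation = c("linear", "relu", "sigmoid")) {
  activation <- match.arg(activation)
  self <- new.env(parent = emptyenv())
  self$W <- par_new(glorot_uniform(in_dim, out_dim))
  self$b <- par_new(matrix(0, 1, out_dim))
  self$params <- list(self$W, self$b)

  self$forward <- function(x, training = FALSE) {
    d3 <- length(dim(x)) == 3L
    if (d3) { self$shape3 <- dim(x); x2 <- flat2d(x) } else { self$shape3 <- NULL; x2 <- x }
    self$x2 <- x2
    z <- sweep(x2 %*% self$W$value, 2, self$b$value, "+")
    a <- switch(activation, linear = z, relu = relu(z), sigmoid = sigmoid(z))
    self$act <- a
    if (d3) unflat3d(a, self$shape3[1], self$shape3[2]) else a
  }
  self$backward <- function(dout) {
    d2 <- if (!is.null(self$shape3)) flat2d(dout) else dout
    dz <- switch(activation,
      linear = d2,
      relu = d2 * (self$act > 0),
      sigmoid = d2 * self$act * (1 - self$act))
    self$W$grad <- self$W$grad + crossprod(self$x2, dz)
    self$b$grad <- self$b$grad + matrix(colSums(dz), 1)
    dx <- tcrossprod(dz, self$W$value)
    if (!is.null(self$shape3)) unflat3d(dx, self$shape3[1], self$shape3[2]) else dx
  }
  self
}

# ---- layer normalization (over the channel axis, per position) -------------

nn_layernorm <- function(dim, eps = 1e-5) {
  self <- new.env(parent = emptyenv())
  self$g <- par_new(matrix(1, 1, dim))
  self$b <- par_new(matrix(0, 1, dim))
  self$params <- list(self$g, self$b)

  self$forward <- function(x, training = FALSE) {
    d3 <- length(dim(x)) == 3L
    if (d3) { self$shape3 <- dim(x); x2 <- flat2d(x) } else { self$shape3 <- NULL; x2 <- x }
    mu <- rowMeans(x2)
    xc <- x2 - mu
    v <- rowMeans(xc * xc)
    self$inv_sd <- 1 / sqrt(v + eps)
    self$xhat <- xc * self$inv_sd
    y <- sweep(sweep(self$xhat, 2, self$g$value, "*"), 2, self$b$value, "+")
    if (d3) unflat3d(y, self$shape3[1], self$shape3[2]) else y
  }
  self$backward <- function(dout) {
    d2 <- if (!is.null(self$shape3)) flat2d(dout) else dout
    self$g$grad <- self$g$grad + matrix(colSums(d2 * self$xhat), 1)
    self$b$grad <- self$b$grad + matrix(colSums(d2), 1)
    dxhat <- sweep(d2, 2, self$g$value, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * self$xhat)
    dx <- self$inv_sd * (dxhat - m1 - self$xhat * m2)
    if (!is.null(self$shape3)) unflat3d(dx, self$shape3[1], self$shape3[2]) else dx
  }
  self
}

# ---- multi-head self-attention ---------------------------------------------

nn_mha <- function(d_model, n_heads, key_dim) {
  self <- new.env(parent = emptyenv())
  hk <- n_heads * key_dim
  self$Wq <- par_new(glorot_uniform(d_model, hk)); self$bq <- par_new(matrix(0, 1, hk))
  self$Wk <- par_new(glorot_uniform(d_model, hk)); self$bk <- par_new(matrix(0, 1, hk))
  self$Wv <- par_new(glorot_uniform(d_model, hk)); self$bv <- par_new(matrix(0, 1, hk))
  self$Wo <- par_new(glorot_uniform(hk, d_model)); self$bo <- par_new(matrix(0, 1, d_model))
  self$params <- list(self$Wq, self$bq, self$Wk, self$bk,
                      self$Wv, self$bv, self$Wo, self$bo)
  scale <- 1 / sqrt(key_dim)
  hidx <- lapply(seq_len(n_heads), function(h) ((h - 1L) * key_dim + 1L):(h * key_dim))

  self$forward <- function(x, training = FALSE) {
    dm <- dim(x); n <- dm[1]; l <- dm[2]
    self$shape3 <- dm
    x2 <- flat2d(x)
    self$x2 <- x2
    Q <- sweep(x2 %*% self$Wq$value, 2, self$bq$value, "+")
    K <- sweep(x2 %*% self$Wk$value, 2, self$bk$value, "+")
    V <- sweep(x2 %*% self$Wv$value, 2, self$bv$value, "+")
    self$Q3 <- unflat3d(Q, n, l); self$K3 <- unflat3d(K, n, l); self$V3 <- unflat3d(V, n, l)
    self$A <- vector("list", n)           # per-sample list of per-head softmax mats
    O3 <- array(0, dim = c(n, l, length(hidx) * length(hidx[[1]])))
    for (i in seq_len(n)) {
      Ai <- vector("list", length(hidx))
      for (h in seq_along(hidx)) {
        cols <- hidx[[h]]
        Qi <- self$Q3[i, , cols, drop = TRUE]; dim(Qi) <- c(l, length(cols))
        Ki <- self$K3[i, , cols, drop = TRUE]; dim(Ki) <- c(l, length(cols))
        Vi <- self$V3[i, , cols, drop = TRUE]; dim(Vi) <- c(l, length(cols))
        S <- tcrossprod(Qi, Ki) * scale
        S <- exp(S - apply(S, 1, max))
        A <- S / rowSums(S)
        Ai[[h]] <- A
        O3[i, , cols] <- A %*% Vi
      }
      self$A[[i]] <- Ai
    }
    self$O2 <- flat2d(O3)
    out2 <- sweep(self$O2 %*% self$Wo$value, 2, self$bo$value, "+")
    unflat3d(out2, n, l)
  }

  self$backward <- function(dout) {
    dm <- self$shape3; n <- dm[1]; l <- dm[2]
    d2 <- flat2d(dout)
    self$Wo$grad <- self$Wo$grad + crossprod(self$O2, d2)
    self$bo$grad <- self$bo$grad + matrix(colSums(d2), 1)
    dO3 <- unflat3d(tcrossprod(d2, self$Wo$value), n, l)
    dQ3 <- array(0, dim = dim(self$Q3))
    dK3 <- array(0, dim = dim(self$K3))
    dV3 <- array(0, dim = dim(self$V3))
    for (i in seq_len(n)) {
      for (h in seq_along(hidx)) {
        cols <- hidx[[h]]; kd <- length(cols)
        A <- self$A[[i]][[h]]
        Qi <- self$Q3[i, , cols, drop = TRUE]; dim(Qi) <- c(l, kd)
        Ki <- self$K3[i, , cols, drop = TRUE]; dim(Ki) <- c(l, kd)
        Vi <- self$V3[i, , cols, drop = TRUE]; dim(Vi) <- c(l, kd)
        dOi <- dO3[i, , cols, drop = TRUE]; dim(dOi) <- c(l, kd)
        dA <- tcrossprod(dOi, Vi)
        dV3[i, , cols] <- crossprod(A, dOi)
        dS <- A * (dA - rowSums(dA * A))      # softmax Jacobian, row-wise
        dQ3[i, , cols] <- (dS %*% Ki) * scale
        dK3[i, , cols] <- (crossprod(dS, Qi)) * scale
      }
    }
    dQ2 <- flat2d(dQ3); dK2 <- flat2d(dK3); dV2 <- flat2d(dV3)
    self$Wq$grad <- self$Wq$grad + crossprod(self$x2, dQ2)
    self$bq$grad <- self$bq$grad + matrix(colSums(dQ2), 1)
    self$Wk$grad <- self$Wk$grad + crossprod(self$x2, dK2)
    self$bk$grad <- self$bk$grad + matrix(colSums(dK2), 1)
    self$Wv$grad <- self$Wv$grad + crossprod(self$x2, dV2)
    self$bv$grad <- self$bv$grad + matrix(colSums(dV2), 1)
    dx2 <- tcrossprod(dQ2, self$Wq$value) + tcrossprod(dK2, self$Wk$value) +
           tcrossprod(dV2, self$Wv$value)
    unflat3d(dx2, n, l)
  }
  self
}

# ---- 1-d convolution, 'same' padding ---------------------------------------

nn_conv1d <- function(in_ch, out_ch, kernel, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  self <- new.env(parent = emptyenv())
  self$W <- par_new(glorot_uniform(kernel * in_ch, out_ch,
                                   dims = c(kernel, in_ch, out_ch)))
  self$b <- par_new(matrix(0, 1, out_ch))
  self$params <- list(self$W, self$b)
  lpad <- (kernel - 1L) %/% 2L          # 'same' padding (keras convention,
  rpad <- kernel - 1L - lpad            # extra zero on the right if even)

  self$forward <- function(x, training = FALSE) {
    dm <- dim(x); n <- dm[1]; l <- dm[2]; cin <- dm[3]
    self$shape3 <- dm
    xp <- array(0, dim = c(n, l + lpad + rpad, cin))
    xp[, (lpad + 1L):(lpad + l), ] <- x
    self$xp <- xp
    z2 <- matrix(0, n * l, out_ch)
    for (j in seq_len(kernel)) {
      sl <- xp[, j:(j + l - 1L), , drop = FALSE]
      Wj <- self$W$value[j, , , drop = TRUE]; dim(Wj) <- c(cin, out_ch)
      z2 <- z2 + flat2d(sl) %*% Wj
    }
    z2 <- sweep(z2, 2, self$b$value, "+")
    a2 <- if (activation == "relu") relu(z2) else z2
    self$act <- a2
    unflat3d(a2, n, l)
  }
  self$backward <- function(dout) {
    dm <- self$shape3; n <- dm[1]; l <- dm[2]; cin <- dm[3]
    d2 <- flat2d(dout)
    if (activation == "relu") d2 <- d2 * (self$act > 0)
    self$b$grad <- self$b$grad + matrix(colSums(d2), 1)
    dxp <- array(0, dim = dim(self$xp))
    for (j in seq_len(kernel)) {
      sl <- self$xp[, j:(j + l - 1L), , drop = FALSE]
      Wj <- self$W$value[j, , , drop = TRUE]; dim(Wj) <- c(cin, out_ch)
      self$W$grad[j, , ] <- self$W$grad[j, , ] + crossprod(flat2d(sl), d2)
      dxp[, j:(j + l - 1L), ] <- dxp[, j:(j + l - 1L), ] +
        unflat3d(tcrossprod(d2, Wj), n, l)
    }
    dxp[, (lpad + 1L):(lpad + l), , drop = FALSE]
  }
  self
}

# ---- multi-kernel convolution: parallel convs, channel concatenation -------

nn_multikernel <- function(in_ch, filters_per_kernel, kernel_sizes) {
  self <- new.env(parent = emptyenv())
  self$convs <- lapply(kernel_sizes, function(k)
    nn_conv1d(in_ch, filters_per_kernel, k, activation = "relu"))
  self$params <- unlist(lapply(self$convs, function(cv) cv$params),
                        recursive = FALSE)
  f <- filters_per_kernel
  self$forward <- function(x, training = FALSE) {
    outs <- lapply(self$convs, function(cv) cv$forward(x, training))
    n <- dim(x)[1]; l <- dim(x)[2]
    y <- array(0, dim = c(n, l, f * length(outs)))
    for (j in seq_along(outs)) y[, , ((j - 1L) * f + 1L):(j * f)] <- outs[[j]]
    y
  }
  self$backward <- function(dout) {
    dx <- NULL
    for (j in seq_along(self$convs)) {
      dj <- self$convs[[j]]$backward(
        dout[, , ((j - 1L) * f + 1L):(j * f), drop = FALSE])
      dx <- if (is.null(dx)) dj else dx + dj
    }
    dx
  }
  self
}

# ---- max pooling (valid, stride = pool size) -------------------------------

nn_maxpool1d <- function(pool) {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$forward <- function(x, training = FALSE) {
    dm <- dim(x); n <- dm[1]; l <- dm[2]; ch <- dm[3]
    lo <- l %/% pool
    self$shape3 <- dm; self$lo <- lo
    y <- x[, seq(1L, by = pool, length.out = lo), , drop = FALSE]
    arg <- array(1L, dim = c(n, lo, ch))
    if (pool > 1L) for (j in 2:pool) {
      cand <- x[, seq(j, by = pool, length.out = lo), , drop = FALSE]
      hit <- cand > y
      y[hit] <- cand[hit]
      arg[hit] <- j
    }
    self$arg <- arg
    y
  }
  self$backward <- function(dout) {
    dm <- self$shape3
    dx <- array(0, dim = dm)
    for (j in seq_len(pool)) {
      pos <- seq(j, by = pool, length.out = self$lo)
      mask <- (self$arg == j)
      sl <- dx[, pos, , drop = FALSE]
      sl[mask] <- dout[mask]
      dx[, pos, ] <- sl
    }
    dx
  }
  self
}

# ---- squeeze-and-excitation ------------------------------------------------

nn_se <- function(channels, ratio) {
  stopifnot(channels %% ratio == 0L)
  self <- new.env(parent = emptyenv())
  self$fc1 <- nn_dense(channels, channels %/% ratio, "relu")
  self$fc2 <- nn_dense(channels %/% ratio, channels, "sigmoid")
  self$params <- c(self$fc1$params, self$fc2$params)

  self$forward <- function(x, training = FALSE) {
    self$x <- x
    l <- dim(x)[2]
    s <- apply(x, c(1, 3), mean)                       # squeeze: [N, C]
    dim(s) <- c(dim(x)[1], dim(x)[3])
    self$gate <- self$fc2$forward(self$fc1$forward(s, training), training)
    g3 <- aperm(array(self$gate, dim = c(dim(x)[1], dim(x)[3], l)), c(1, 3, 2))
    self$g3 <- g3
    x * g3                                             # excite: channel rescale
  }
  self$backward <- function(dout) {
    l <- dim(self$x)[2]
    dgate <- apply(dout * self$x, c(1, 3), sum)
    dim(dgate) <- c(dim(self$x)[1], dim(self$x)[3])
    ds <- self$fc1$backward(self$fc2$backward(dgate))
    dx <- dout * self$g3
    ds3 <- aperm(array(ds / l, dim = c(dim(self$x)[1], dim(self$x)[3], l)),
                 c(1, 3, 2))
    dx + ds3
  }
  self
}

# ---- dropout ---------------------------------------------------------------

nn_dropout <- function(rate) {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$forward <- function(x, training = FALSE) {
    if (!training || rate <= 0) { self$mask <- NULL; return(x) }
    keep <- 1 - rate
    self$mask <- array(stats::rbinom(length(x), 1L, keep) / keep, dim = dim(x))
    x * self$mask
  }
  self$backward <- function(dout) {
    if (is.null(self$mask)) dout else dout * self$mask
  }
  self
}

# ---- flatten ---------------------------------------------------------------

nn_flatten <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$forward <- function(x, training = FALSE) {
    self$shape3 <- dim(x)
    matrix(x, nrow = dim(x)[1])
  }
  self$backward <- function(dout) array(dout, dim = self$shape3)
  self
}

# ---- composition helpers ---------------------------------------------------

nn_seq <- function(...) {
  self <- new.env(parent = emptyenv())
  self$nodes <- list(...)
  self$params <- unlist(lapply(self$nodes, function(nd) nd$params),
                        recursive = FALSE)
  self$forward <- function(x, training = FALSE) {
    for (nd in self$nodes) x <- nd$forward(x, training)
    x
  }
  self$backward <- function(dout) {
    for (nd in rev(self$nodes)) dout <- nd$backward(dout)
    dout
  }
  self
}

# out = main(x) + shortcut(x); identity shortcut when NULL
nn_residual <- function(main, shortcut = NULL) {
  self <- new.env(parent = emptyenv())
  self$params <- c(main$params, if (!is.null(shortcut)) shortcut$params)
  self$forward <- function(x, training = FALSE) {
    m <- main$forward(x, training)
    s <- if (is.null(shortcut)) x else shortcut$forward(x, training)
    if (!identical(dim(m), dim(s)))
      stop("residual branch shapes differ: [",
           paste(dim(m), collapse = "x"), "] vs [",
           paste(dim(s), collapse = "x"), "]")
    m + s
  }
  self$backward <- function(dout) {
    dm <- main$backward(dout)
    ds <- if (is.null(shortcut)) dout else shortcut$backward(dout)
    dm + ds
  }
  self
}

# ---- optimizer -------------------------------------------------------------

adam_new <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  self <- new.env(parent = emptyenv())
  self$t <- 0L
  for (p in params) {
    p$m <- array(0, dim = dim(p$value))
    p$v <- array(0, dim = dim(p$value))
  }
  self$step <- function() {
    self$t <- self$t + 1L
    bc1 <- 1 - beta1^self$t
    bc2 <- 1 - beta2^self$t
    for (p in params) {
      p$m <- beta1 * p$m + (1 - beta1) * p$grad
      p$v <- beta2 * p$v + (1 - beta2) * p$grad * p$grad
      p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
    }
  }
  self$zero <- function() {
    for (p in params) p$grad <- array(0, dim = dim(p$value))
  }
  self
}

n_params <- function(params) sum(vapply(params, function(p) length(p$value), 0))

snapshot_params <- function(params) lapply(params, function(p) p$value)
restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}
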