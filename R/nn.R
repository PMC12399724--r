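# Minimal neural-network engine: dense, 1-D/2-D convolution, max-pooling,
# LSTM/BiLSTM, batch normalization, dropout, with reverse-mode gradients and
# an Adam optimizer. Array convention: batch first — activations are
# [n, features], [n, time, channels] or [n, height, width, channels].
# Layers are environments so parameters, optimizer state and running
# statistics update in place. Every layer's backward pass is checked against
# finite differences in the test suite.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  cfg <- list(...)
  for (nm in names(cfg)) assign(nm, cfg[[nm]], envir = e)
  class(e) <- "nn_layer"
  e
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

act_apply <- function(z, act) {
  switch(act,
    linear = z,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    tanh = tanh(z),
    stop_bad_arg("unknown activation '%s'", act)
  )
}

# derivative wrt pre-activation, expressed through the activation output `a`
act_grad <- function(a, act) {
  switch(act,
    linear = 1,
    relu = (a > 0) * 1,
    sigmoid = a * (1 - a),
    tanh = 1 - a^2
  )
}

mat_at_t <- function(x, t) {
  d <- dim(x)
  matrix(x[, t, ], d[1L], d[3L])
}

reverse_time <- function(x) {
  x[, dim(x)[2L]:1L, , drop = FALSE]
}

# layer constructors ----------------------------------------------------------

nn_dense <- function(units, activation = "linear") {
  new_layer("dense", units = as.integer(units), activation = activation)
}
nn_conv1d <- function(filters, kernel, activation = "linear", padding = "same") {
  new_layer("conv1d", filters = as.integer(filters), kernel = as.integer(kernel),
            activation = activation, padding = padding)
}
nn_conv2d <- function(filters, kernel, activation = "linear", padding = "same") {
  new_layer("conv2d", filters = as.integer(filters), kernel = as.integer(kernel),
            activation = activation, padding = padding)
}
nn_maxpool1d <- function(pool) new_layer("maxpool1d", pool = as.integer(pool))
nn_maxpool2d <- function(pool) new_layer("maxpool2d", pool = as.integer(pool))
nn_upsample1d <- function(size) new_layer("upsample1d", size = as.integer(size))
nn_lstm <- function(units, return_sequences = FALSE, recurrent_dropout = 0) {
  new_layer("lstm", units = as.integer(units), return_sequences = return_sequences,
            recurrent_dropout = recurrent_dropout)
}
nn_bilstm <- function(units, return_sequences = FALSE, recurrent_dropout = 0) {
  new_layer("bilstm", units = as.integer(units), return_sequences = return_sequences,
            recurrent_dropout = recurrent_dropout)
}
nn_flatten <- function() new_layer("flatten")
nn_reshape <- function(target) new_layer("reshape", target = as.integer(target))
nn_repeat <- function(times) new_layer("repeat", times = as.integer(times))
nn_batchnorm <- function(momentum = 0.9, eps = 1e-5) {
  new_layer("batchnorm", momentum = momentum, eps = eps)
}
nn_dropout <- function(rate) new_layer("dropout", rate = rate)
nn_multihead <- function(heads) new_layer("multihead", heads = heads)

# initialization --------------------------------------------------------------

layer_init <- function(layer, in_shape) {
  out <- switch(layer$type,
    dense = {
      f_in <- in_shape[length(in_shape)]
      layer$params <- list(
        W = glorot(f_in, layer$units, c(f_in, layer$units)),
        b = numeric(layer$units)
      )
      c(in_shape[-length(in_shape)], layer$units)
    },
    conv1d = {
      C <- in_shape[2L]; k <- layer$kernel
      layer$params <- list(
        W = glorot(k * C, k * layer$filters, c(k * C, layer$filters)),
        b = numeric(layer$filters)
      )
      T_out <- if (layer$padding == "same") in_shape[1L] else in_shape[1L] - k + 1L
      if (T_out < 1L) stop_bad_arg("conv1d kernel %d too large for %d time steps", k, in_shape[1L])
      c(T_out, layer$filters)
    },
    conv2d = {
      C <- in_shape[3L]; kh <- layer$kernel[1L]; kw <- layer$kernel[2L]
      layer$params <- list(
        W = glorot(kh * kw * C, kh * kw * layer$filters,
                   c(kh * kw * C, layer$filters)),
        b = numeric(layer$filters)
      )
      if (layer$padding == "same") c(in_shape[1L], in_shape[2L], layer$filters)
      else c(in_shape[1L] - kh + 1L, in_shape[2L] - kw + 1L, layer$filters)
    },
    maxpool1d = {
      if (in_shape[1L] %% layer$pool != 0L)
        stop_bad_arg("time dimension %d not divisible by pool %d; pad the window to %d",
                     in_shape[1L], layer$pool,
                     ceiling(in_shape[1L] / layer$pool) * layer$pool)
      c(in_shape[1L] %/% layer$pool, in_shape[2L])
    },
    maxpool2d = {
      ph <- layer$pool[1L]; pw <- layer$pool[2L]
      if (in_shape[1L] %% ph != 0L || in_shape[2L] %% pw != 0L)
        stop_bad_arg("spatial dims (%d,%d) not divisible by pool (%d,%d); pad the input",
                     in_shape[1L], in_shape[2L], ph, pw)
      c(in_shape[1L] %/% ph, in_shape[2L] %/% pw, in_shape[3L])
    },
    upsample1d = c(in_shape[1L] * layer$size, in_shape[2L]),
    lstm = {
      C <- in_shape[2L]; u <- layer$units
      b <- numeric(4L * u)
      b[(u + 1L):(2L * u)] <- 1  # forget-gate bias
      layer$params <- list(
        W = glorot(C, 4L * u, c(C, 4L * u)),
        U = glorot(u, 4L * u, c(u, 4L * u)),
        b = b
      )
      if (layer$return_sequences) c(in_shape[1L], u) else u
    },
    bilstm = {
      layer$fwd <- nn_lstm(layer$units, layer$return_sequences, layer$recurrent_dropout)
      layer$bwd <- nn_lstm(layer$units, layer$return_sequences, layer$recurrent_dropout)
      layer_init(layer$fwd, in_shape)
      layer_init(layer$bwd, in_shape)
      if (layer$return_sequences) c(in_shape[1L], 2L * layer$units) else 2L * layer$units
    },
    flatten = prod(in_shape),
    reshape = {
      if (prod(layer$target) != prod(in_shape))
        stop_bad_arg("reshape target size %d != input size %d",
                     prod(layer$target), prod(in_shape))
      layer$target
    },
    `repeat` = c(layer$times, in_shape[1L]),
    batchnorm = {
      C <- in_shape[length(in_shape)]
      layer$params <- list(gamma = rep(1, C), beta = numeric(C))
      layer$run_mean <- numeric(C)
      layer$run_var <- numeric(C)
      layer$run_n <- 0L
      in_shape
    },
    dropout = in_shape,
    multihead = {
      outs <- lapply(layer$heads, function(stack) {
        sh <- in_shape
        for (l in stack) sh <- layer_init(l, sh)
        sh
      })
      Ts <- vapply(outs, `[`, numeric(1), 1L)
      if (length(unique(Ts)) != 1L)
        stop_bad_arg("multihead branches disagree on time dimension (%s)",
                     paste(Ts, collapse = ", "))
      layer$split <- vapply(outs, `[`, numeric(1), 2L)
      c(outs[[1L]][1L], sum(layer$split))
    },
    stop_bad_arg("unknown layer type '%s'", layer$type)
  )
  layer$in_shape <- in_shape
  layer$out_shape <- out
  out
}

# forward ---------------------------------------------------------------------

conv1d_im2col <- function(xp, k, T_out) {
  d <- dim(xp)  # [n, T_pad, C]
  n <- d[1L]; C <- d[3L]
  Xc <- matrix(0, n * T_out, k * C)
  for (j in seq_len(k)) {
    Xc[, ((j - 1L) * C + 1L):(j * C)] <-
      matrix(xp[, j:(j + T_out - 1L), , drop = FALSE], n * T_out, C)
  }
  Xc
}

pad_time <- function(x, pl, pr) {
  if (pl == 0L && pr == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + pl + pr, d[3L]))
  xp[, (pl + 1L):(pl + d[2L]), ] <- x
  xp
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      d <- dim(x)
      xm <- if (length(d) == 2L) x else matrix(x, d[1L] * d[2L], d[3L])
      z <- sweep(xm %*% layer$params$W, 2L, layer$params$b, `+`)
      a <- act_apply(z, layer$activation)
      out <- if (length(d) == 2L) a else array(a, c(d[1L], d[2L], layer$units))
      list(out = out, cache = list(xm = xm, a = a, d = d))
    },
    conv1d = {
      d <- dim(x); k <- layer$kernel
      if (layer$padding == "same") {
        pl <- (k - 1L) %/% 2L; pr <- k - 1L - pl; T_out <- d[2L]
      } else {
        pl <- 0L; pr <- 0L; T_out <- d[2L] - k + 1L
      }
      xp <- pad_time(x, pl, pr)
      Xc <- conv1d_im2col(xp, k, T_out)
      z <- sweep(Xc %*% layer$params$W, 2L, layer$params$b, `+`)
      a <- act_apply(z, layer$activation)
      list(out = array(a, c(d[1L], T_out, layer$filters)),
           cache = list(Xc = Xc, a = a, d = d, pl = pl, pr = pr, T_out = T_out))
    },
    conv2d = {
      d <- dim(x)  # [n,H,W,C]
      kh <- layer$kernel[1L]; kw <- layer$kernel[2L]
      if (layer$padding == "same") {
        ph_l <- (kh - 1L) %/% 2L; ph_r <- kh - 1L - ph_l
        pw_l <- (kw - 1L) %/% 2L; pw_r <- kw - 1L - pw_l
        Ho <- d[2L]; Wo <- d[3L]
      } else {
        ph_l <- ph_r <- pw_l <- pw_r <- 0L
        Ho <- d[2L] - kh + 1L; Wo <- d[3L] - kw + 1L
      }
      xp <- array(0, c(d[1L], d[2L] + ph_l + ph_r, d[3L] + pw_l + pw_r, d[4L]))
      xp[, (ph_l + 1L):(ph_l + d[2L]), (pw_l + 1L):(pw_l + d[3L]), ] <- x
      n <- d[1L]; C <- d[4L]
      Xc <- matrix(0, n * Ho * Wo, kh * kw * C)
      col <- 0L
      for (q in seq_len(kw)) for (p in seq_len(kh)) {
        Xc[, (col * C + 1L):((col + 1L) * C)] <-
          matrix(xp[, p:(p + Ho - 1L), q:(q + Wo - 1L), , drop = FALSE], n * Ho * Wo, C)
        col <- col + 1L
      }
      z <- sweep(Xc %*% layer$params$W, 2L, layer$params$b, `+`)
      a <- act_apply(z, layer$activation)
      list(out = array(a, c(n, Ho, Wo, layer$filters)),
           cache = list(Xc = Xc, a = a, d = d, Ho = Ho, Wo = Wo,
                        ph_l = ph_l, pw_l = pw_l))
    },
    maxpool1d = {
      d <- dim(x); p <- layer$pool; To <- d[2L] %/% p
      y <- x[, seq(1L, d[2L], p), , drop = FALSE]
      idx <- array(1L, dim(y))
      if (p > 1L) for (j in 2:p) {
        cand <- x[, seq(j, d[2L], p), , drop = FALSE]
        m <- cand > y
        y[m] <- cand[m]
        idx[m] <- j
      }
      list(out = y, cache = list(idx = idx, d = d))
    },
    maxpool2d = {
      d <- dim(x); ph <- layer$pool[1L]; pw <- layer$pool[2L]
      y <- x[, seq(1L, d[2L], ph), seq(1L, d[3L], pw), , drop = FALSE]
      idx <- array(1L, dim(y))
      off <- 0L
      for (q in seq_len(pw)) for (p in seq_len(ph)) {
        off <- off + 1L
        if (off == 1L) next
        cand <- x[, seq(p, d[2L], ph), seq(q, d[3L], pw), , drop = FALSE]
        m <- cand > y
        y[m] <- cand[m]
        idx[m] <- off
      }
      list(out = y, cache = list(idx = idx, d = d))
    },
    upsample1d = {
      d <- dim(x); s <- layer$size
      y <- array(0, c(d[1L], d[2L] * s, d[3L]))
      for (j in seq_len(s)) y[, seq(j, d[2L] * s, s), ] <- x
      list(out = y, cache = list(d = d))
    },
    lstm = lstm_forward(layer, x, training),
    bilstm = {
      f <- layer_forward(layer$fwd, x, training)
      b <- layer_forward(layer$bwd, reverse_time(x), training)
      if (layer$return_sequences) {
        yb <- reverse_time(b$out)
        d <- dim(f$out)
        out <- array(0, c(d[1L], d[2L], 2L * layer$units))
        out[, , seq_len(layer$units)] <- f$out
        out[, , layer$units + seq_len(layer$units)] <- yb
      } else {
        out <- cbind(f$out, b$out)
      }
      list(out = out, cache = list(f = f$cache, b = b$cache))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1L], prod(d[-1L])), cache = list(d = d))
    },
    reshape = {
      d <- dim(x)
      list(out = array(x, c(d[1L], layer$target)), cache = list(d = d))
    },
    `repeat` = {
      d <- dim(x)
      y <- array(0, c(d[1L], layer$times, d[2L]))
      for (t in seq_len(layer$times)) y[, t, ] <- x
      list(out = y, cache = list(d = d))
    },
    batchnorm = bn_forward(layer, x, training),
    dropout = {
      if (!training || layer$rate <= 0) {
        list(out = x, cache = list(mask = NULL))
      } else {
        mask <- array(
          (stats::runif(length(x)) > layer$rate) / (1 - layer$rate), dim(x)
        )
        list(out = x * mask, cache = list(mask = mask))
      }
    },
    multihead = {
      fwd <- lapply(layer$heads, function(stack) {
        h <- x
        caches <- vector("list", length(stack))
        for (i in seq_along(stack)) {
          r <- layer_forward(stack[[i]], h, training)
          h <- r$out
          caches[[i]] <- r$cache
        }
        list(out = h, caches = caches)
      })
      d1 <- dim(fwd[[1L]]$out)
      out <- array(0, c(d1[1L], d1[2L], sum(layer$split)))
      at <- 0L
      for (i in seq_along(fwd)) {
        w <- layer$split[i]
        out[, , at + seq_len(w)] <- fwd[[i]]$out
        at <- at + w
      }
      list(out = out, cache = lapply(fwd, `[[`, "caches"))
    },
    stop_bad_arg("unknown layer type '%s'", layer$type)
  )
}

lstm_forward <- function(layer, x, training) {
  d <- dim(x)
  n <- d[1L]; T_n <- d[2L]; u <- layer$units
  W <- layer$params$W; U <- layer$params$U; b <- layer$params$b
  I <- F_ <- G <- O <- Cc <- H <- array(0, c(n, T_n, u))
  h <- matrix(0, n, u); cc <- matrix(0, n, u)
  rmask <- NULL
  if (training && layer$recurrent_dropout > 0) {
    rmask <- matrix(
      (stats::runif(n * u) > layer$recurrent_dropout) / (1 - layer$recurrent_dropout),
      n, u
    )
  }
  iu <- seq_len(u)
  for (t in seq_len(T_n)) {
    hd <- if (is.null(rmask)) h else h * rmask
    a <- sweep(mat_at_t(x, t) %*% W + hd %*% U, 2L, b, `+`)
    i_g <- 1 / (1 + exp(-a[, iu, drop = FALSE]))
    f_g <- 1 / (1 + exp(-a[, u + iu, drop = FALSE]))
    g_g <- tanh(a[, 2L * u + iu, drop = FALSE])
    o_g <- 1 / (1 + exp(-a[, 3L * u + iu, drop = FALSE]))
    cc <- f_g * cc + i_g * g_g
    h <- o_g * tanh(cc)
    I[, t, ] <- i_g; F_[, t, ] <- f_g; G[, t, ] <- g_g; O[, t, ] <- o_g
    Cc[, t, ] <- cc; H[, t, ] <- h
  }
  out <- if (layer$return_sequences) H else h
  list(out = out,
       cache = list(x = x, I = I, F_ = F_, G = G, O = O, Cc = Cc, H = H,
                    rmask = rmask, d = d))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  C <- d[length(d)]
  xm <- matrix(x, length(x) %/% C, C)
  if (training) {
    mu <- colMeans(xm)
    vr <- colMeans(xm^2) - mu^2
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * vr
    layer$run_n <- layer$run_n + 1L
  } else if (layer$run_n > 0L) {
    # bias-corrected EMA so inference statistics are usable after few steps
    corr <- 1 - layer$momentum^layer$run_n
    mu <- layer$run_mean / corr
    vr <- layer$run_var / corr
  } else {
    mu <- numeric(length(layer$params$gamma))
    vr <- rep(1, length(layer$params$gamma))
  }
  sd_inv <- 1 / sqrt(vr + layer$eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, sd_inv, `*`)
  ym <- sweep(sweep(xhat, 2L, layer$params$gamma, `*`), 2L, layer$params$beta, `+`)
  list(out = array(ym, d),
       cache = list(xhat = xhat, sd_inv = sd_inv, d = d, training = training))
}

# backward --------------------------------------------------------------------

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = {
      d <- cache$d
      dm <- if (length(d) == 2L) dout else matrix(dout, d[1L] * d[2L], layer$units)
      dz <- dm * act_grad(cache$a, layer$activation)
      layer$grads <- list(W = crossprod(cache$xm, dz), b = colSums(dz))
      dxm <- dz %*% t(layer$params$W)
      if (length(d) == 2L) dxm else array(dxm, d)
    },
    conv1d = {
      d <- cache$d; k <- layer$kernel; C <- d[3L]; n <- d[1L]
      dm <- matrix(dout, n * cache$T_out, layer$filters)
      dz <- dm * act_grad(cache$a, layer$activation)
      layer$grads <- list(W = crossprod(cache$Xc, dz), b = colSums(dz))
      dXc <- dz %*% t(layer$params$W)
      T_pad <- d[2L] + cache$pl + cache$pr
      dxp <- array(0, c(n, T_pad, C))
      for (j in seq_len(k)) {
        sl <- j:(j + cache$T_out - 1L)
        dxp[, sl, ] <- dxp[, sl, , drop = FALSE] +
          array(dXc[, ((j - 1L) * C + 1L):(j * C)], c(n, cache$T_out, C))
      }
      dxp[, (cache$pl + 1L):(cache$pl + d[2L]), , drop = FALSE]
    },
    conv2d = {
      d <- cache$d; kh <- layer$kernel[1L]; kw <- layer$kernel[2L]
      n <- d[1L]; C <- d[4L]; Ho <- cache$Ho; Wo <- cache$Wo
      dm <- matrix(dout, n * Ho * Wo, layer$filters)
      dz <- dm * act_grad(cache$a, layer$activation)
      layer$grads <- list(W = crossprod(cache$Xc, dz), b = colSums(dz))
      dXc <- dz %*% t(layer$params$W)
      dxp <- array(0, c(n, Ho + kh - 1L, Wo + kw - 1L, C))
      col <- 0L
      for (q in seq_len(kw)) for (p in seq_len(kh)) {
        blk <- array(dXc[, (col * C + 1L):((col + 1L) * C)], c(n, Ho, Wo, C))
        dxp[, p:(p + Ho - 1L), q:(q + Wo - 1L), ] <-
          dxp[, p:(p + Ho - 1L), q:(q + Wo - 1L), , drop = FALSE] + blk
        col <- col + 1L
      }
      dxp[, (cache$ph_l + 1L):(cache$ph_l + d[2L]),
          (cache$pw_l + 1L):(cache$pw_l + d[3L]), , drop = FALSE]
    },
    maxpool1d = {
      d <- cache$d; p <- layer$pool
      dx <- array(0, d)
      for (j in seq_len(p)) {
        sl <- seq(j, d[2L], p)
        blk <- dx[, sl, , drop = FALSE]
        m <- cache$idx == j
        blk[m] <- dout[m]
        dx[, sl, ] <- blk
      }
      dx
    },
    maxpool2d = {
      d <- cache$d; ph <- layer$pool[1L]; pw <- layer$pool[2L]
      dx <- array(0, d)
      off <- 0L
      for (q in seq_len(pw)) for (p in seq_len(ph)) {
        off <- off + 1L
        slh <- seq(p, d[2L], ph); slw <- seq(q, d[3L], pw)
        blk <- dx[, slh, slw, , drop = FALSE]
        m <- cache$idx == off
        blk[m] <- dout[m]
        dx[, slh, slw, ] <- blk
      }
      dx
    },
    upsample1d = {
      d <- cache$d; s <- layer$size
      dx <- array(0, d)
      for (j in seq_len(s)) {
        dx <- dx + dout[, seq(j, d[2L] * s, s), , drop = FALSE]
      }
      dx
    },
    lstm = lstm_backward(layer, cache, dout),
    bilstm = {
      u <- layer$units
      if (layer$return_sequences) {
        df_out <- dout[, , seq_len(u), drop = FALSE]
        db_out <- reverse_time(dout[, , u + seq_len(u), drop = FALSE])
      } else {
        df_out <- dout[, seq_len(u), drop = FALSE]
        db_out <- dout[, u + seq_len(u), drop = FALSE]
      }
      dxf <- layer_backward(layer$fwd, cache$f, df_out)
      dxb <- layer_backward(layer$bwd, cache$b, db_out)
      dxf + reverse_time(dxb)
    },
    flatten = array(dout, cache$d),
    reshape = array(dout, cache$d),
    `repeat` = {
      d <- cache$d
      dx <- matrix(0, d[1L], d[2L])
      for (t in seq_len(layer$times)) dx <- dx + matrix(dout[, t, ], d[1L], d[2L])
      dx
    },
    batchnorm = bn_backward(layer, cache, dout),
    dropout = {
      if (is.null(cache$mask)) dout else dout * cache$mask
    },
    multihead = {
      at <- 0L
      dx <- NULL
      for (i in seq_along(layer$heads)) {
        w <- layer$split[i]
        dh <- dout[, , at + seq_len(w), drop = FALSE]
        at <- at + w
        stack <- layer$heads[[i]]
        for (j in rev(seq_along(stack))) {
          dh <- layer_backward(stack[[j]], cache[[i]][[j]], dh)
        }
        dx <- if (is.null(dx)) dh else dx + dh
      }
      dx
    },
    stop_bad_arg("unknown layer type '%s'", layer$type)
  )
}

lstm_backward <- function(layer, cache, dout) {
  d <- cache$d
  n <- d[1L]; T_n <- d[2L]; u <- layer$units
  W <- layer$params$W; U <- layer$params$U
  dW <- array(0, dim(W)); dU <- array(0, dim(U)); db <- numeric(4L * u)
  dx <- array(0, d)
  dh_rec <- matrix(0, n, u)
  dc_next <- matrix(0, n, u)
  zero <- matrix(0, n, u)
  for (t in T_n:1L) {
    dh <- dh_rec
    if (layer$return_sequences) {
      dh <- dh + matrix(dout[, t, ], n, u)
    } else if (t == T_n) {
      dh <- dh + dout
    }
    i_g <- matrix(cache$I[, t, ], n, u)
    f_g <- matrix(cache$F_[, t, ], n, u)
    g_g <- matrix(cache$G[, t, ], n, u)
    o_g <- matrix(cache$O[, t, ], n, u)
    cc <- matrix(cache$Cc[, t, ], n, u)
    c_prev <- if (t > 1L) matrix(cache$Cc[, t - 1L, ], n, u) else zero
    h_prev <- if (t > 1L) matrix(cache$H[, t - 1L, ], n, u) else zero
    tc <- tanh(cc)
    do_g <- dh * tc
    dtc <- dh * o_g * (1 - tc^2) + dc_next
    di <- dtc * g_g
    dg <- dtc * i_g
    df <- dtc * c_prev
    dc_next <- dtc * f_g
    da <- cbind(
      di * i_g * (1 - i_g),
      df * f_g * (1 - f_g),
      dg * (1 - g_g^2),
      do_g * o_g * (1 - o_g)
    )
    x_t <- mat_at_t(cache$x, t)
    hd_prev <- if (is.null(cache$rmask)) h_prev else h_prev * cache$rmask
    dW <- dW + crossprod(x_t, da)
    dU <- dU + crossprod(hd_prev, da)
    db <- db + colSums(da)
    dx[, t, ] <- da %*% t(W)
    dh_rec <- da %*% t(U)
    if (!is.null(cache$rmask)) dh_rec <- dh_rec * cache$rmask
  }
  layer$grads <- list(W = dW, U = dU, b = db)
  dx
}

bn_backward <- function(layer, cache, dout) {
  d <- cache$d
  C <- d[length(d)]
  m <- length(dout) %/% C
  dym <- matrix(dout, m, C)
  xhat <- cache$xhat
  layer$grads <- list(
    gamma = colSums(dym * xhat),
    beta = colSums(dym)
  )
  if (!cache$training) {
    # inference-mode gradient: running stats are constants
    dxm <- sweep(dym, 2L, layer$params$gamma * cache$sd_inv, `*`)
    return(array(dxm, d))
  }
  dxhat <- sweep(dym, 2L, layer$params$gamma, `*`)
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_x <- colSums(dxhat * xhat)
  dxm <- sweep(
    dxhat - matrix(sum_dxhat / m, m, C, byrow = TRUE) -
      xhat * matrix(sum_dxhat_x / m, m, C, byrow = TRUE),
    2L, cache$sd_inv, `*`
  )
  array(dxm, d)
}

# model -----------------------------------------------------------------------

nn_build <- function(layers, in_shape, seed = NULL) {
  build <- function() {
    sh <- in_shape
    for (l in layers) sh <- layer_init(l, sh)
    structure(list(layers = layers, in_shape = in_shape, out_shape = sh),
              class = "nn_model")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

nn_forward <- function(model, x, training = FALSE, upto = NULL) {
  layers <- model$layers
  n_use <- upto %||% length(layers)
  caches <- vector("list", n_use)
  h <- x
  for (i in seq_len(n_use)) {
    r <- layer_forward(layers[[i]], h, training)
    h <- r$out
    caches[[i]] <- r$cache
  }
  list(out = h, caches = caches)
}

nn_backward <- function(model, caches, dout) {
  layers <- model$layers
  dh <- dout
  for (i in rev(seq_along(caches))) {
    dh <- layer_backward(layers[[i]], caches[[i]], dh)
  }
  dh
}

# flat list of every parameter-bearing layer environment (recursing into
# composite layers)
collect_param_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "bilstm") {
      out <- c(out, list(l$fwd, l$bwd))
    } else if (l$type == "multihead") {
      for (stack in l$heads) out <- c(out, collect_param_layers(stack))
    } else if (length(l$params) > 0L) {
      out <- c(out, list(l))
    }
  }
  out
}

# Adam ------------------------------------------------------------------------

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0L
  e
}

adam_step <- function(opt, param_layers) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (l in param_layers) {
    if (length(l$grads) == 0L) next
    if (is.null(l$opt_m)) {
      l$opt_m <- lapply(l$params, function(p) array(0, dim(p) %||% length(p)))
      l$opt_v <- l$opt_m
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      l$opt_m[[nm]] <- opt$beta1 * l$opt_m[[nm]] + (1 - opt$beta1) * g
      l$opt_v[[nm]] <- opt$beta2 * l$opt_v[[nm]] + (1 - opt$beta2) * g^2
      l$params[[nm]] <- l$params[[nm]] -
        opt$lr * (l$opt_m[[nm]] / bc1) / (sqrt(l$opt_v[[nm]] / bc2) + opt$eps)
    }
  }
  invisible(opt)
}

# losses ----------------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# categorical cross-entropy; y is a 0-based integer class vector
ce_loss_grad <- function(logits, y) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, grad = dlogits / n)
}

mse_loss_grad <- function(pred, target) {
  diff <- pred - target
  list(loss = mean(diff^2), grad = 2 * diff / length(diff))
}
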