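# Minimal reverse-mode neural-network layers on top of R matrix algebra.
#
# Conventions:
#   feature maps  [C, H, W, N]   (channel-major: channels vary fastest, so
#                                 matrix(x, C) is a free reshape to the
#                                 channels x (H*W*N) view used by GEMM,
#                                 batch norm and the activations)
#   vectors       [D, N]
#   token stacks  [D, T, N]
# Every leaf layer is an environment holding its parameters (`param_names`),
# gradient accumulators (prefix "g"), a forward(x, train) and a backward(dout).
# Composites expose the same interface and list their `children`.

nn_finalize <- function(self, cls) {
  class(self) <- c(cls, if (!is.null(self$param_names)) "nn_leaf", "nn_module")
  self
}

#' Collect all parameter-holding leaf layers of a module tree
#' @param mod an nn module
#' @return list of leaf environments
#' @keywords internal
nn_leaves <- function(mod) {
  if (!is.null(mod$param_names)) return(list(mod))
  if (is.null(mod$children)) return(list())
  unlist(lapply(mod$children, nn_leaves), recursive = FALSE)
}

#' Total number of trainable parameters in a module tree
#' @keywords internal
nn_n_params <- function(mod) {
  sum(vapply(nn_leaves(mod), function(l) {
    sum(vapply(l$param_names, function(nm) length(l[[nm]]), 0))
  }, 0))
}

nn_zero_grads <- function(mod) {
  for (l in nn_leaves(mod)) {
    for (nm in l$param_names) l[[paste0("g", nm)]] <- l[[paste0("g", nm)]] * 0
  }
  invisible(mod)
}

# replicate a [C, N] matrix over hw spatial positions -> [C*hw, N] flat view
.rep_spatial <- function(m, hw) m[rep(seq_len(nrow(m)), hw), , drop = FALSE]

# channel-wise spatial mean of a [C, H, W, N] map -> [C, N]
.spatial_mean <- function(x, d) {
  hw <- d[2] * d[3]
  dim(x) <- c(d[1] * hw, d[4])
  z <- rowsum(x, rep(seq_len(d[1]), hw), reorder = FALSE) / hw
  dimnames(z) <- NULL
  z
}

# ---- 2-D convolution (im2col + GEMM) ----------------------------------------

nn_conv2d <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = NULL,
                      bias = TRUE) {
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  pad <- as.integer(pad)
  k2 <- kernel * kernel
  fan_in <- k2 * in_ch
  # He initialisation; weight rows are output channels, columns run over
  # (kernel position fastest, then input channel)
  W <- matrix(stats::rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)), out_ch, fan_in)
  b <- if (bias) numeric(out_ch) else NULL
  gW <- W * 0
  gb <- if (bias) numeric(out_ch) else NULL
  idx_cache <- list()
  cache <- NULL
  self <- environment()

  make_idx <- function(H, Wd) {
    Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
    Ho <- (Hp - kernel) %/% stride + 1L
    Wo <- (Wp - kernel) %/% stride + 1L
    dh <- rep(seq_len(kernel), times = kernel) - 1L
    dw <- rep(seq_len(kernel), each = kernel) - 1L
    sp_off <- dh * in_ch + dw * (in_ch * Hp)           # k2 spatial offsets
    oh <- rep(seq_len(Ho), times = Wo) - 1L
    ow <- rep(seq_len(Wo), each = Ho) - 1L
    base <- oh * (stride * in_ch) + ow * (stride * in_ch * Hp)
    idx_sp <- outer(sp_off, base, "+")                 # k2 x HoWo, 0-based
    idx1 <- idx_sp[rep(seq_len(k2), in_ch), , drop = FALSE] +
      rep(seq_len(in_ch) - 1L, each = k2) + 1L
    list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx1 = idx1)
  }

  forward <- function(x, train = FALSE, need_dx = TRUE) {
    d <- dim(x)
    stopifnot(length(d) == 4L, d[1] == in_ch)
    H <- d[2]; Wd <- d[3]; N <- d[4]
    key <- paste0(H, "x", Wd)
    ii <- idx_cache[[key]]
    if (is.null(ii)) {
      ii <- make_idx(H, Wd)
      idx_cache[[key]] <<- ii
    }
    if (pad > 0L) {
      xp <- array(0, c(in_ch, ii$Hp, ii$Wp, N))
      xp[, pad + seq_len(H), pad + seq_len(Wd), ] <- x
    } else xp <- x
    dim(xp) <- NULL
    sliceN <- in_ch * ii$Hp * ii$Wp
    HoWo <- ii$Ho * ii$Wo
    cols <- matrix(0, k2 * in_ch, HoWo * N)
    for (n in seq_len(N)) {
      cols[, (n - 1L) * HoWo + seq_len(HoWo)] <- xp[ii$idx1 + (n - 1L) * sliceN]
    }
    y <- W %*% cols
    if (bias) y <- y + b
    if (train) cache <<- list(cols = cols, ii = ii, N = N, H = H, Wd = Wd,
                              need_dx = need_dx)
    dim(y) <- c(out_ch, ii$Ho, ii$Wo, N)
    y
  }

  backward <- function(dout) {
    ii <- cache$ii; N <- cache$N
    HoWo <- ii$Ho * ii$Wo
    dY <- dout
    dim(dY) <- c(out_ch, length(dY) %/% out_ch)
    gW <<- gW + tcrossprod(dY, cache$cols)
    if (bias) gb <<- gb + rowSums(dY)
    if (!cache$need_dx) return(NULL)
    dcols <- crossprod(W, dY)
    sliceN <- in_ch * ii$Hp * ii$Wp
    if (kernel == 1L && stride == 1L && pad == 0L) {
      # the gather is the identity permutation: no scatter needed
      dim(dcols) <- c(in_ch, ii$Hp, ii$Wp, N)
      return(dcols)
    }
    dxp <- numeric(sliceN * N)
    noff <- rep((seq_len(N) - 1L) * sliceN, each = in_ch * HoWo)
    # scatter one kernel offset at a time: for a fixed offset the target
    # cells are distinct across (channel, window, sample), so no collisions
    for (r in seq_len(k2)) {
      rows <- seq(r, by = k2, length.out = in_ch)
      p <- rep(ii$idx1[rows, , drop = FALSE], N) + noff
      dxp[p] <- dxp[p] + dcols[rows, , drop = FALSE]
    }
    dim(dxp) <- c(in_ch, ii$Hp, ii$Wp, N)
    if (pad > 0L) {
      dxp <- dxp[, pad + seq_len(cache$H), pad + seq_len(cache$Wd), , drop = FALSE]
    }
    dxp
  }

  param_names <- c("W", if (bias) "b")
  decay_names <- "W"
  nn_finalize(self, "nn_conv2d")
}

# ---- batch normalisation ----------------------------------------------------

nn_batchnorm2d <- function(ch, momentum = 0.1, eps = 1e-5) {
  gamma <- rep(1, ch); beta <- numeric(ch)
  ggamma <- numeric(ch); gbeta <- numeric(ch)
  run_mean <- numeric(ch); run_var <- rep(1, ch)
  cache <- NULL
  self <- environment()

  forward <- function(x, train = FALSE) {
    d <- dim(x)
    xm <- matrix(x, ch)
    if (train) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc * xc)
      m <- ncol(xm)
      run_mean <<- (1 - momentum) * run_mean + momentum * mu
      run_var <<- (1 - momentum) * run_var + momentum * v * m / max(1, m - 1)
    } else {
      mu <- run_mean; v <- run_var
      xc <- xm - mu
    }
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * istd
    y <- xhat * gamma + beta
    if (train) cache <<- list(xhat = xhat, istd = istd)
    dim(y) <- d
    y
  }

  backward <- function(dout) {
    d <- dim(dout)
    dy <- matrix(dout, ch)
    ggamma <<- ggamma + rowSums(dy * cache$xhat)
    gbeta <<- gbeta + rowSums(dy)
    dxhat <- dy * gamma
    dxm <- (dxhat - rowMeans(dxhat) -
              cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$istd
    dim(dxm) <- d
    dxm
  }

  param_names <- c("gamma", "beta")
  decay_names <- character()
  nn_finalize(self, "nn_batchnorm2d")
}

# ---- elementwise activations ------------------------------------------------

nn_relu <- function() {
  cache <- NULL
  self <- environment()
  forward <- function(x, train = FALSE) {
    y <- x * (x > 0)
    if (train) cache <<- (x > 0)
    y
  }
  backward <- function(dout) dout * cache
  nn_finalize(self, "nn_relu")
}

nn_gelu <- function() {
  cache <- NULL
  self <- environment()
  forward <- function(x, train = FALSE) {
    if (train) cache <<- x
    x * stats::pnorm(x)
  }
  backward <- function(dout) {
    x <- cache
    dout * (stats::pnorm(x) + x * stats::dnorm(x))
  }
  nn_finalize(self, "nn_gelu")
}

nn_dropout <- function(p = 0) {
  cache <- NULL
  self <- environment()
  forward <- function(x, train = FALSE) {
    if (!train || p <= 0) return(x)
    mask <- (stats::runif(length(x)) >= p) / (1 - p)
    dim(mask) <- dim(x)
    cache <<- mask
    x * mask
  }
  backward <- function(dout) if (p <= 0) dout else dout * cache
  nn_finalize(self, "nn_dropout")
}

# ---- pooling ----------------------------------------------------------------

nn_maxpool2d <- function(kernel = 3L, stride = 2L, pad = 1L) {
  kernel <- as.integer(kernel); stride <- as.integer(stride); pad <- as.integer(pad)
  k2 <- kernel * kernel
  idx_cache <- list()
  cache <- NULL
  self <- environment()

  make_idx <- function(C, H, Wd) {
    Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
    Ho <- (Hp - kernel) %/% stride + 1L
    Wo <- (Wp - kernel) %/% stride + 1L
    dh <- rep(seq_len(kernel), times = kernel) - 1L
    dw <- rep(seq_len(kernel), each = kernel) - 1L
    sp_off <- dh * C + dw * (C * Hp)
    # output columns ordered (channel fastest, then oh, then ow) so the
    # pooled matrix reshapes straight into [C, Ho, Wo]
    cv <- rep(seq_len(C) - 1L, times = Ho * Wo)
    ohv <- rep(rep(seq_len(Ho) - 1L, each = C), times = Wo)
    owv <- rep(seq_len(Wo) - 1L, each = C * Ho)
    base <- cv + ohv * (stride * C) + owv * (stride * C * Hp)
    idx1 <- outer(sp_off, base, "+") + 1L               # k2 x (C*Ho*Wo)
    list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx1 = idx1)
  }

  forward <- function(x, train = FALSE) {
    d <- dim(x)
    C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
    key <- paste0(C, "x", H, "x", Wd)
    ii <- idx_cache[[key]]
    if (is.null(ii)) { ii <- make_idx(C, H, Wd); idx_cache[[key]] <<- ii }
    xp <- array(-Inf, c(C, ii$Hp, ii$Wp, N))
    xp[, pad + seq_len(H), pad + seq_len(Wd), ] <- x
    dim(xp) <- NULL
    S <- C * ii$Hp * ii$Wp
    M <- ncol(ii$idx1)
    out <- matrix(0, M, N)
    am <- matrix(1L, M, N)
    for (n in seq_len(N)) {
      off <- (n - 1L) * S
      best <- xp[ii$idx1[1L, ] + off]
      bi <- rep(1L, M)
      for (r in 2:k2) {
        v <- xp[ii$idx1[r, ] + off]
        sel <- v > best
        if (any(sel)) { best[sel] <- v[sel]; bi[sel] <- r }
      }
      out[, n] <- best
      am[, n] <- bi
    }
    if (train) cache <<- list(am = am, ii = ii, d = d, S = S, M = M)
    dim(out) <- c(C, ii$Ho, ii$Wo, N)
    out
  }

  backward <- function(dout) {
    cc <- cache
    ii <- cc$ii; d <- cc$d
    dv <- dout
    dim(dv) <- c(cc$M, d[4])
    dxp <- numeric(cc$S * d[4])
    noff <- rep((seq_len(d[4]) - 1L) * cc$S, each = cc$M)
    # scatter one kernel offset at a time: window starts are distinct for a
    # fixed offset, so positions cannot collide within one pass
    for (r in seq_len(k2)) {
      sel <- which(cc$am == r)
      if (length(sel) == 0L) next
      j <- (sel - 1L) %% cc$M + 1L
      p <- ii$idx1[r, j] + noff[sel]
      dxp[p] <- dxp[p] + dv[sel]
    }
    dim(dxp) <- c(d[1], ii$Hp, ii$Wp, d[4])
    dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
  }

  nn_finalize(self, "nn_maxpool2d")
}

nn_gap <- function() {
  cache <- NULL
  self <- environment()
  forward <- function(x, train = FALSE) {
    d <- dim(x)
    if (train) cache <<- d
    .spatial_mean(x, d)
  }
  backward <- function(dout) {
    d <- cache
    hw <- d[2] * d[3]
    dx <- .rep_spatial(dout / hw, hw)
    dim(dx) <- d
    dx
  }
  nn_finalize(self, "nn_gap")
}

# ---- dense / layer norm -----------------------------------------------------

nn_dense <- function(in_dim, out_dim, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / in_dim)
  W <- matrix(stats::rnorm(out_dim * in_dim, sd = sd), out_dim, in_dim)
  b <- numeric(out_dim)
  gW <- W * 0; gb <- b
  cache <- NULL
  self <- environment()
  forward <- function(x, train = FALSE) {
    if (train) cache <<- x
    W %*% x + b
  }
  backward <- function(dout) {
    gW <<- gW + tcrossprod(dout, cache)
    gb <<- gb + rowSums(dout)
    crossprod(W, dout)
  }
  param_names <- c("W", "b")
  decay_names <- "W"
  nn_finalize(self, "nn_dense")
}

nn_layernorm <- function(dm, eps = 1e-6) {
  gamma <- rep(1, dm); beta <- numeric(dm)
  ggamma <- numeric(dm); gbeta <- numeric(dm)
  cache <- NULL
  self <- environment()
  forward <- function(x, train = FALSE) {
    d <- dim(x)
    xm <- matrix(x, dm)
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = dm)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * rep(istd, each = dm)
    y <- xhat * gamma + beta
    if (train) cache <<- list(xhat = xhat, istd = istd)
    if (!is.null(d)) dim(y) <- d
    y
  }
  backward <- function(dout) {
    d <- dim(dout)
    dy <- matrix(dout, dm)
    xhat <- cache$xhat
    ggamma <<- ggamma + rowSums(dy * xhat)
    gbeta <<- gbeta + rowSums(dy)
    dxhat <- dy * gamma
    dx <- (dxhat - rep(colMeans(dxhat), each = dm) -
             xhat * rep(colMeans(dxhat * xhat), each = dm)) * rep(cache$istd, each = dm)
    if (!is.null(d)) dim(dx) <- d
    dx
  }
  param_names <- c("gamma", "beta")
  decay_names <- character()
  nn_finalize(self, "nn_layernorm")
}

# ---- multi-head self-attention ----------------------------------------------

nn_mhsa <- function(dm, heads) {
  stopifnot(dm %% heads == 0)
  dh <- dm %/% heads
  sdv <- 0.02
  Wq <- matrix(stats::rnorm(dm * dm, sd = sdv), dm, dm)
  Wk <- matrix(stats::rnorm(dm * dm, sd = sdv), dm, dm)
  Wv <- matrix(stats::rnorm(dm * dm, sd = sdv), dm, dm)
  Wo <- matrix(stats::rnorm(dm * dm, sd = sdv), dm, dm)
  bq <- numeric(dm); bk <- numeric(dm); bv <- numeric(dm); bo <- numeric(dm)
  gWq <- Wq * 0; gWk <- Wk * 0; gWv <- Wv * 0; gWo <- Wo * 0
  gbq <- bq; gbk <- bk; gbv <- bv; gbo <- bo
  cache <- NULL
  self <- environment()

  forward <- function(x, train = FALSE) {
    d <- dim(x)             # D x T x N
    Tt <- d[2]; N <- d[3]
    xm <- matrix(x, dm)
    Q <- Wq %*% xm + bq
    K <- Wk %*% xm + bk
    V <- Wv %*% xm + bv
    scl <- 1 / sqrt(dh)
    att <- matrix(0, dm, Tt * N)
    Alist <- vector("list", N * heads)
    for (n in seq_len(N)) {
      cl <- (n - 1L) * Tt + seq_len(Tt)
      for (h in seq_len(heads)) {
        rw <- (h - 1L) * dh + seq_len(dh)
        Qh <- Q[rw, cl, drop = FALSE]
        Kh <- K[rw, cl, drop = FALSE]
        Vh <- V[rw, cl, drop = FALSE]
        S <- crossprod(Qh, Kh) * scl
        S <- S - apply(S, 1, max)
        A <- exp(S)
        A <- A / rowSums(A)
        att[rw, cl] <- Vh %*% t(A)
        Alist[[(n - 1L) * heads + h]] <- A
      }
    }
    y <- Wo %*% att + bo
    if (train) cache <<- list(xm = xm, Q = Q, K = K, V = V, att = att,
                              Alist = Alist, d = d)
    dim(y) <- d
    y
  }

  backward <- function(dout) {
    cc <- cache
    d <- cc$d
    Tt <- d[2]; N <- d[3]
    dy <- matrix(dout, dm)
    gWo <<- gWo + tcrossprod(dy, cc$att)
    gbo <<- gbo + rowSums(dy)
    datt <- crossprod(Wo, dy)
    dQ <- matrix(0, dm, Tt * N)
    dK <- dQ; dV <- dQ
    scl <- 1 / sqrt(dh)
    for (n in seq_len(N)) {
      cl <- (n - 1L) * Tt + seq_len(Tt)
      for (h in seq_len(heads)) {
        rw <- (h - 1L) * dh + seq_len(dh)
        A <- cc$Alist[[(n - 1L) * heads + h]]
        Vh <- cc$V[rw, cl, drop = FALSE]
        dOh <- datt[rw, cl, drop = FALSE]
        dV[rw, cl] <- dOh %*% A
        dA <- crossprod(dOh, Vh)   # T x T, dA[i,j] = sum_d dOh[d,i] Vh[d,j]
        dS <- A * (dA - rowSums(dA * A)) * scl
        dQ[rw, cl] <- cc$K[rw, cl, drop = FALSE] %*% t(dS)
        dK[rw, cl] <- cc$Q[rw, cl, drop = FALSE] %*% dS
      }
    }
    gWq <<- gWq + tcrossprod(dQ, cc$xm); gbq <<- gbq + rowSums(dQ)
    gWk <<- gWk + tcrossprod(dK, cc$xm); gbk <<- gbk + rowSums(dK)
    gWv <<- gWv + tcrossprod(dV, cc$xm); gbv <<- gbv + rowSums(dV)
    dx <- crossprod(Wq, dQ) + crossprod(Wk, dK) + crossprod(Wv, dV)
    dim(dx) <- d
    dx
  }

  param_names <- c("Wq", "Wk", "Wv", "Wo", "bq", "bk", "bv", "bo")
  decay_names <- c("Wq", "Wk", "Wv", "Wo")
  nn_finalize(self, "nn_mhsa")
}

# ---- composition ------------------------------------------------------------

nn_seq <- function(...) {
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "nn_module")) {
    children <- children[[1]]
  }
  self <- environment()
  forward <- function(x, train = FALSE) {
    for (ch in children) x <- ch$forward(x, train)
    x
  }
  backward <- function(dout) {
    for (ch in rev(children)) dout <- ch$backward(dout)
    dout
  }
  nn_finalize(self, "nn_seq")
}

# ---- optimiser --------------------------------------------------------------

#' Adam optimiser with decoupled weight decay
#' @keywords internal
nn_adam <- function(mod, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                    weight_decay = 0) {
  leaves <- nn_leaves(mod)
  state <- lapply(leaves, function(l) {
    st <- list()
    for (nm in l$param_names) {
      st[[nm]] <- list(m = l[[nm]] * 0, v = l[[nm]] * 0)
    }
    st
  })
  t <- 0L
  self <- environment()
  step <- function() {
    t <<- t + 1L
    bc1 <- 1 - beta1^t
    bc2 <- 1 - beta2^t
    for (i in seq_along(leaves)) {
      l <- leaves[[i]]
      for (nm in l$param_names) {
        g <- l[[paste0("g", nm)]]
        st <- state[[i]][[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g * g
        state[[i]][[nm]] <<- st
        upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
        if (weight_decay > 0 && nm %in% l$decay_names) {
          upd <- upd + lr * weight_decay * l[[nm]]
        }
        l[[nm]] <- l[[nm]] - upd
      }
    }
  }
  zero <- function() nn_zero_grads(mod)
  self
}
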