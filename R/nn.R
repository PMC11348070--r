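# Minimal neural-network engine: dense, 1D-convolutional, GRU and
# transformer-encoder architectures with hand-derived reverse-mode
# gradients and an Adam optimiser. Sized for 30-nt one-hot / k-mer inputs;
# every layer's gradient is validated by finite differences in the tests.

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}
he <- function(nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
}
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter initialisation -------------------------------------------

nn_init <- function(family, config, seed = 1L) {
  withr::with_seed(seed, {
    switch(family,
      mlp = {
        d <- config$input_dim
        h <- config$hidden # e.g. c(128, 64)
        p <- list()
        dims <- c(d, h, 1)
        for (i in seq_len(length(dims) - 1)) {
          p[[paste0("W", i)]] <- he(dims[i], dims[i + 1])
          p[[paste0("b", i)]] <- numeric(dims[i + 1])
        }
        p
      },
      cnn = {
        k <- config$kernel
        f <- config$filters
        nl <- config$n_conv
        L <- config$seq_len %||% 30L
        p <- list()
        cin <- 4
        for (l in seq_len(nl)) {
          p[[paste0("convW", l)]] <- he(k * cin, f)
          p[[paste0("convb", l)]] <- numeric(f)
          cin <- f
        }
        # flatten readout keeps positional information (a global pool would
        # make position-anchored motifs invisible to the head)
        p$fcW <- he(L * f, config$fc)
        p$fcb <- numeric(config$fc)
        p$outW <- glorot(config$fc, 1)
        p$outb <- 0
        p
      },
      gru = {
        H <- config$hidden
        p <- list()
        for (g in c("z", "r", "h")) {
          p[[paste0("W", g)]] <- glorot(4, H)
          p[[paste0("U", g)]] <- glorot(H, H)
          p[[paste0("b", g)]] <- numeric(H)
        }
        p$outW <- glorot(H, 1)
        p$outb <- 0
        p
      },
      transformer = {
        d <- config$dim
        ff <- config$ff
        L <- config$seq_len
        p <- list(embW = glorot(4, d), pos = glorot(L, d))
        for (bl in seq_len(config$blocks)) {
          pre <- paste0("b", bl, "_")
          p[[paste0(pre, "Wq")]] <- glorot(d, d)
          p[[paste0(pre, "Wk")]] <- glorot(d, d)
          p[[paste0(pre, "Wv")]] <- glorot(d, d)
          p[[paste0(pre, "Wo")]] <- glorot(d, d)
          p[[paste0(pre, "ln1g")]] <- rep(1, d)
          p[[paste0(pre, "ln1b")]] <- numeric(d)
          p[[paste0(pre, "ffW1")]] <- he(d, ff)
          p[[paste0(pre, "ffb1")]] <- numeric(ff)
          p[[paste0(pre, "ffW2")]] <- glorot(ff, d)
          p[[paste0(pre, "ffb2")]] <- numeric(d)
          p[[paste0(pre, "ln2g")]] <- rep(1, d)
          p[[paste0(pre, "ln2b")]] <- numeric(d)
        }
        p$outW <- glorot(d, 1)
        p$outb <- 0
        p
      },
      abort(sprintf("Unknown neural family: %s", family))
    )
  })
}

# ---- shared pieces -------------------------------------------------------

# im2col for same-padded 1D convolution; X array (n, L, C) -> (n*L) x (k*C)
im2col <- function(X, k) {
  n <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  pad <- (k - 1) %/% 2
  Xp <- array(0, c(n, L + 2 * pad, C))
  Xp[, (pad + 1):(pad + L), ] <- X
  cols <- matrix(0, n * L, k * C)
  for (o in seq_len(k)) {
    cols[, ((o - 1) * C + 1):(o * C)] <- matrix(Xp[, o:(o + L - 1), ], nrow = n * L)
  }
  cols
}

col2im <- function(dcols, n, L, C, k) {
  pad <- (k - 1) %/% 2
  dXp <- array(0, c(n, L + 2 * pad, C))
  for (o in seq_len(k)) {
    blk <- array(dcols[, ((o - 1) * C + 1):(o * C)], c(n, L, C))
    dXp[, o:(o + L - 1), ] <- dXp[, o:(o + L - 1), ] + blk
  }
  dXp[, (pad + 1):(pad + L), , drop = FALSE]
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  list(out = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  invstd <- cache$invstd
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- invstd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

# ---- forward passes ------------------------------------------------------

nn_forward <- function(family, params, X, config, cache = TRUE) {
  switch(family,
    mlp = {
      nl <- length(config$hidden) + 1
      A <- X
      acts <- list(A)
      for (i in seq_len(nl)) {
        Z <- A %*% params[[paste0("W", i)]] +
          rep(params[[paste0("b", i)]], each = nrow(A))
        A <- if (i < nl) pmax(Z, 0) else Z
        acts[[i + 1]] <- A
      }
      logit <- as.vector(A)
      list(logit = logit, prob = sigmoid(logit),
           cache = if (cache) list(acts = acts) else NULL)
    },
    cnn = {
      n <- dim(X)[1]; L <- dim(X)[2]
      k <- config$kernel; nl <- config$n_conv; f <- config$filters
      A <- X
      caches <- list()
      for (l in seq_len(nl)) {
        cols <- im2col(A, k)
        Z <- cols %*% params[[paste0("convW", l)]] +
          rep(params[[paste0("convb", l)]], each = n * L)
        H <- pmax(Z, 0)
        caches[[l]] <- list(cols = cols, Z = Z, Cin = dim(A)[3])
        A <- array(H, c(n, L, f))
      }
      flat <- matrix(A, nrow = n)
      Zfc <- flat %*% params$fcW + rep(params$fcb, each = n)
      Hfc <- pmax(Zfc, 0)
      logit <- as.vector(Hfc %*% params$outW + params$outb)
      list(logit = logit, prob = sigmoid(logit),
           cache = if (cache) {
             list(conv = caches, flat = flat, Zfc = Zfc, Hfc = Hfc,
                  n = n, L = L)
           } else NULL)
    },
    gru = {
      n <- dim(X)[1]; L <- dim(X)[2]; H <- config$hidden
      h <- matrix(0, n, H)
      steps <- vector("list", L)
      for (t in seq_len(L)) {
        xt <- matrix(X[, t, ], nrow = n)
        z <- sigmoid(xt %*% params$Wz + h %*% params$Uz +
                       rep(params$bz, each = n))
        r <- sigmoid(xt %*% params$Wr + h %*% params$Ur +
                       rep(params$br, each = n))
        hh <- tanh(xt %*% params$Wh + (r * h) %*% params$Uh +
                     rep(params$bh, each = n))
        hnew <- (1 - z) * h + z * hh
        steps[[t]] <- list(xt = xt, h_prev = h, z = z, r = r, hh = hh)
        h <- hnew
      }
      logit <- as.vector(h %*% params$outW + params$outb)
      list(logit = logit, prob = sigmoid(logit),
           cache = if (cache) list(steps = steps, hT = h, n = n, L = L) else NULL)
    },
    transformer = {
      n <- dim(X)[1]; L <- dim(X)[2]
      d <- config$dim; nh <- config$heads; dk <- d / nh
      Xm <- matrix(X, n * L, 4)
      E <- Xm %*% params$embW
      E <- E + params$pos[rep(seq_len(L), each = n), ]
      A <- E # (n*L) x d, sample-major within position
      blocks <- list()
      for (bl in seq_len(config$blocks)) {
        pre <- paste0("b", bl, "_")
        Q <- A %*% params[[paste0(pre, "Wq")]]
        K <- A %*% params[[paste0(pre, "Wk")]]
        V <- A %*% params[[paste0(pre, "Wv")]]
        O <- matrix(0, n * L, d)
        Ps <- vector("list", n)
        for (s in seq_len(n)) {
          rows <- s + n * (seq_len(L) - 1)
          Phead <- vector("list", nh)
          for (hd in seq_len(nh)) {
            cc <- ((hd - 1) * dk + 1):(hd * dk)
            S <- (Q[rows, cc, drop = FALSE] %*%
                    t(K[rows, cc, drop = FALSE])) / sqrt(dk)
            S <- S - apply(S, 1, max)
            P <- exp(S); P <- P / rowSums(P)
            O[rows, cc] <- P %*% V[rows, cc, drop = FALSE]
            Phead[[hd]] <- P
          }
          Ps[[s]] <- Phead
        }
        O2 <- O %*% params[[paste0(pre, "Wo")]]
        R1 <- A + O2
        ln1 <- layernorm_fwd(R1, params[[paste0(pre, "ln1g")]],
                             params[[paste0(pre, "ln1b")]])
        Zf <- ln1$out %*% params[[paste0(pre, "ffW1")]] +
          rep(params[[paste0(pre, "ffb1")]], each = n * L)
        Hf <- pmax(Zf, 0)
        F2 <- Hf %*% params[[paste0(pre, "ffW2")]] +
          rep(params[[paste0(pre, "ffb2")]], each = n * L)
        R2 <- ln1$out + F2
        ln2 <- layernorm_fwd(R2, params[[paste0(pre, "ln2g")]],
                             params[[paste0(pre, "ln2b")]])
        blocks[[bl]] <- list(A_in = A, Q = Q, K = K, V = V, O = O, Ps = Ps,
                             ln1 = ln1, Zf = Zf, Hf = Hf, ln2 = ln2)
        A <- ln2$out
      }
      # mean-pool positions: (n*L) x d -> n x d
      pool <- matrix(0, n, d)
      for (l in seq_len(L)) pool <- pool + A[((l - 1) * n + 1):(l * n), ]
      pool <- pool / L
      logit <- as.vector(pool %*% params$outW + params$outb)
      list(logit = logit, prob = sigmoid(logit),
           cache = if (cache) {
             list(Xm = Xm, blocks = blocks, Afinal = A, pool = pool,
                  n = n, L = L)
           } else NULL)
    }
  )
}

# ---- backward passes -----------------------------------------------------

nn_backward <- function(family, params, cache, dlogit, config) {
  grads <- lapply(params, function(p) p * 0)
  switch(family,
    mlp = {
      nl <- length(config$hidden) + 1
      dA <- matrix(dlogit, ncol = 1)
      for (i in rev(seq_len(nl))) {
        A_in <- cache$acts[[i]]
        if (i < nl) {
          dA <- dA * (cache$acts[[i + 1]] > 0)
        }
        grads[[paste0("W", i)]] <- t(A_in) %*% dA
        grads[[paste0("b", i)]] <- colSums(dA)
        if (i > 1) dA <- dA %*% t(params[[paste0("W", i)]])
      }
      grads
    },
    cnn = {
      n <- cache$n; L <- cache$L
      k <- config$kernel; nl <- config$n_conv; f <- config$filters
      dHfc <- matrix(dlogit, ncol = 1) %*% t(params$outW)
      grads$outW <- t(cache$Hfc) %*% matrix(dlogit, ncol = 1)
      grads$outb <- sum(dlogit)
      dZfc <- dHfc * (cache$Zfc > 0)
      grads$fcW <- t(cache$flat) %*% dZfc
      grads$fcb <- colSums(dZfc)
      dA <- array(dZfc %*% t(params$fcW), c(n, L, f))
      for (l in rev(seq_len(nl))) {
        cc <- cache$conv[[l]]
        dH <- matrix(dA, n * L)
        dZ <- dH * (cc$Z > 0)
        grads[[paste0("convW", l)]] <- t(cc$cols) %*% dZ
        grads[[paste0("convb", l)]] <- colSums(dZ)
        if (l > 1) {
          dcols <- dZ %*% t(params[[paste0("convW", l)]])
          dA <- col2im(dcols, n, L, cc$Cin, k)
        }
      }
      grads
    },
    gru = {
      n <- cache$n; L <- cache$L
      grads$outW <- t(cache$hT) %*% matrix(dlogit, ncol = 1)
      grads$outb <- sum(dlogit)
      dh <- matrix(dlogit, ncol = 1) %*% t(params$outW)
      for (t in rev(seq_len(L))) {
        st <- cache$steps[[t]]
        dz <- dh * (st$hh - st$h_prev)
        dhh <- dh * st$z
        dh_prev <- dh * (1 - st$z)
        da_h <- dhh * (1 - st$hh^2)
        grads$Wh <- grads$Wh + t(st$xt) %*% da_h
        grads$Uh <- grads$Uh + t(st$r * st$h_prev) %*% da_h
        grads$bh <- grads$bh + colSums(da_h)
        drh <- da_h %*% t(params$Uh)
        dr <- drh * st$h_prev
        dh_prev <- dh_prev + drh * st$r
        da_r <- dr * st$r * (1 - st$r)
        grads$Wr <- grads$Wr + t(st$xt) %*% da_r
        grads$Ur <- grads$Ur + t(st$h_prev) %*% da_r
        grads$br <- grads$br + colSums(da_r)
        dh_prev <- dh_prev + da_r %*% t(params$Ur)
        da_z <- dz * st$z * (1 - st$z)
        grads$Wz <- grads$Wz + t(st$xt) %*% da_z
        grads$Uz <- grads$Uz + t(st$h_prev) %*% da_z
        grads$bz <- grads$bz + colSums(da_z)
        dh_prev <- dh_prev + da_z %*% t(params$Uz)
        dh <- dh_prev
      }
      grads
    },
    transformer = {
      n <- cache$n; L <- cache$L
      d <- config$dim; nh <- config$heads; dk <- d / nh
      grads$outW <- t(cache$pool) %*% matrix(dlogit, ncol = 1)
      grads$outb <- sum(dlogit)
      dpool <- matrix(dlogit, ncol = 1) %*% t(params$outW) # n x d
      dA <- matrix(0, n * L, d)
      for (l in seq_len(L)) {
        dA[((l - 1) * n + 1):(l * n), ] <- dpool / L
      }
      for (bl in rev(seq_len(config$blocks))) {
        pre <- paste0("b", bl, "_")
        bc <- cache$blocks[[bl]]
        l2 <- layernorm_bwd(dA, bc$ln2, params[[paste0(pre, "ln2g")]])
        grads[[paste0(pre, "ln2g")]] <- l2$dg
        grads[[paste0(pre, "ln2b")]] <- l2$db
        dR2 <- l2$dx
        dF2 <- dR2
        grads[[paste0(pre, "ffW2")]] <- t(bc$Hf) %*% dF2
        grads[[paste0(pre, "ffb2")]] <- colSums(dF2)
        dHf <- dF2 %*% t(params[[paste0(pre, "ffW2")]])
        dZf <- dHf * (bc$Zf > 0)
        grads[[paste0(pre, "ffW1")]] <- t(bc$ln1$out) %*% dZf
        grads[[paste0(pre, "ffb1")]] <- colSums(dZf)
        dln1out <- dR2 + dZf %*% t(params[[paste0(pre, "ffW1")]])
        l1 <- layernorm_bwd(dln1out, bc$ln1, params[[paste0(pre, "ln1g")]])
        grads[[paste0(pre, "ln1g")]] <- l1$dg
        grads[[paste0(pre, "ln1b")]] <- l1$db
        dR1 <- l1$dx
        dO2 <- dR1
        dA_res <- dR1
        grads[[paste0(pre, "Wo")]] <- t(bc$O) %*% dO2
        dO <- dO2 %*% t(params[[paste0(pre, "Wo")]])
        dQ <- matrix(0, n * L, d)
        dK <- matrix(0, n * L, d)
        dV <- matrix(0, n * L, d)
        for (s in seq_len(n)) {
          rows <- s + n * (seq_len(L) - 1)
          for (hd in seq_len(nh)) {
            cc <- ((hd - 1) * dk + 1):(hd * dk)
            P <- bc$Ps[[s]][[hd]]
            dOh <- dO[rows, cc, drop = FALSE]
            Vh <- bc$V[rows, cc, drop = FALSE]
            dP <- dOh %*% t(Vh)
            dV[rows, cc] <- t(P) %*% dOh
            dS <- P * (dP - rowSums(dP * P))
            dQ[rows, cc] <- (dS %*% bc$K[rows, cc, drop = FALSE]) / sqrt(dk)
            dK[rows, cc] <- (t(dS) %*% bc$Q[rows, cc, drop = FALSE]) / sqrt(dk)
          }
        }
        grads[[paste0(pre, "Wq")]] <- t(bc$A_in) %*% dQ
        grads[[paste0(pre, "Wk")]] <- t(bc$A_in) %*% dK
        grads[[paste0(pre, "Wv")]] <- t(bc$A_in) %*% dV
        dA <- dA_res +
          dQ %*% t(params[[paste0(pre, "Wq")]]) +
          dK %*% t(params[[paste0(pre, "Wk")]]) +
          dV %*% t(params[[paste0(pre, "Wv")]])
      }
      grads$embW <- t(cache$Xm) %*% dA
      dpos <- matrix(0, L, d)
      for (l in seq_len(L)) {
        dpos[l, ] <- colSums(dA[((l - 1) * n + 1):(l * n), , drop = FALSE])
      }
      grads$pos <- dpos
      grads
    }
  )
}

# ---- loss and optimiser --------------------------------------------------

bce_loss <- function(prob, y, eps = 1e-12) {
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, frozen = character()) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    if (nm %in% frozen) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

subset_X <- function(X, idx) {
  if (length(dim(X)) == 3) X[idx, , , drop = FALSE] else X[idx, , drop = FALSE]
}

# Predict in chunks to bound memory on large candidate sets.
nn_predict <- function(family, params, X, config, chunk = 2048L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- nn_forward(family, params, subset_X(X, idx), config,
                           cache = FALSE)$prob
  }
  out
}

#' @keywords internal
fit_nn <- function(family, X, y, Xval = NULL, yval = NULL, config,
                   frozen = character(), params = NULL, seed = 1L) {
  lr <- config$lr %||% 1e-3
  batch <- config$batch %||% 64L
  max_epochs <- config$max_epochs %||% 200L
  patience <- config$patience %||% 10L
  if (is.null(params)) params <- nn_init(family, config, seed = seed)
  state <- adam_init(params)
  n <- length(y)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  history <- list()
  use_val <- !is.null(Xval) && length(unique(yval)) == 2

  withr::with_seed(derive_seed(seed, 7), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        fw <- nn_forward(family, params, subset_X(X, idx), config)
        dlogit <- (fw$prob - y[idx]) / length(idx)
        grads <- nn_backward(family, params, fw$cache, dlogit, config)
        upd <- adam_step(params, grads, state, lr = lr, frozen = frozen)
        params <- upd$params
        state <- upd$state
      }
      if (use_val) {
        pv <- nn_predict(family, params, Xval, config)
        auc <- auc_rank(yval, pv)
        history[[epoch]] <- tibble(epoch = epoch, val_auc = auc)
        if (auc > best$auc + 1e-6) {
          best <- list(auc = auc, params = params, epoch = epoch)
        } else if (epoch - best$epoch >= patience) {
          break
        }
      } else {
        best <- list(auc = NA_real_, params = params, epoch = epoch)
      }
    }
  })
  if (!use_val) best$params <- params
  list(params = best$params, val_auc = best$auc,
       history = bind_rows(history), config = config)
}
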