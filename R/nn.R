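# Minimal CPU neural-network engine used by the U-Net and the detector.
#
# A feature map batch is a (B*H*W) x C matrix; the row index is column-major
# over [H, W, B] (y fastest). Convolutions are im2col gathers followed by one
# BLAS matmul; pooling/upsampling are precomputed index gathers. Networks are
# flat tapes of nodes, each reading the output of one (or two, for skip
# concatenation) earlier nodes, which is enough to express an encoder-decoder
# with skips.

nn_geom_cache <- new.env(parent = emptyenv())

nn_geometry <- function(H, W, B) {
  key <- paste(H, W, B, sep = "_")
  g <- nn_geom_cache[[key]]
  if (!is.null(g)) return(g)
  N <- H * W * B
  zero_row <- N + 1L
  # 3x3 neighborhood gather indices (offset-major, dy then dx)
  px <- rep(rep(seq_len(W), each = H), times = B)
  py <- rep(seq_len(H), times = W * B)
  pb0 <- rep(seq_len(B) - 1L, each = H * W)
  P <- matrix(zero_row, N, 9L)
  o <- 0L
  for (dx in -1:1) {
    for (dy in -1:1) {
      o <- o + 1L
      ny <- py + dy
      nx <- px + dx
      ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
      P[ok, o] <- ny[ok] + H * (nx[ok] - 1L) + H * W * pb0[ok]
    }
  }
  g <- list(H = H, W = W, B = B, N = N, P = P)
  if (H %% 2L == 0L && W %% 2L == 0L) {
    Ho <- H %/% 2L
    Wo <- W %/% 2L
    ox <- rep(rep(seq_len(Wo), each = Ho), times = B)
    oy <- rep(seq_len(Ho), times = Wo * B)
    ob0 <- rep(seq_len(B) - 1L, each = Ho * Wo)
    child <- function(dy, dx) {
      (2L * oy - 1L + dy) + H * (2L * ox - 2L + dx) + H * W * ob0
    }
    g$pool <- list(child(0L, 0L), child(1L, 0L), child(0L, 1L), child(1L, 1L))
  }
  # nearest-neighbor 2x upsampling: child row -> parent row at half res
  Hp <- H * 2L
  Wp <- W * 2L
  ux <- rep(rep(seq_len(Wp), each = Hp), times = B)
  uy <- rep(seq_len(Hp), times = Wp * B)
  ub0 <- rep(seq_len(B) - 1L, each = Hp * Wp)
  g$up <- ((uy + 1L) %/% 2L) + H * (((ux + 1L) %/% 2L) - 1L) + H * W * ub0
  nn_geom_cache[[key]] <- g
  g
}

nn_conv_fwd <- function(X, node, geom) {
  Xz <- rbind(X, 0)
  cin <- ncol(X)
  cols <- matrix(0, geom$N, 9L * cin)
  for (o in 1:9) {
    cols[, ((o - 1L) * cin + 1L):(o * cin)] <- Xz[geom$P[, o], , drop = FALSE]
  }
  Y <- cols %*% node$W
  Y <- sweep(Y, 2, node$b, `+`)
  list(Y = Y, cols = cols)
}

nn_conv_bwd <- function(dY, X, cols, node, geom) {
  cin <- ncol(X)
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dcols <- tcrossprod(dY, node$W)
  dX <- matrix(0, nrow(X), cin)
  for (o in 1:9) {
    blk <- dcols[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
    idx <- geom$P[, o]
    ok <- idx <= nrow(X)
    if (any(ok)) {
      tgt <- idx[ok]
      dX[tgt, ] <- dX[tgt, , drop = FALSE] + blk[ok, , drop = FALSE]
    }
  }
  list(dX = dX, dW = dW, db = db)
}

nn_init_conv <- function(cin, cout, kernel = 9L) {
  fan_in <- kernel * cin
  list(
    W = matrix(stats::rnorm(kernel * cin * cout, 0, sqrt(2 / fan_in)),
               kernel * cin, cout),
    b = rep(0, cout)
  )
}

# ---- tape construction -----------------------------------------------------

nn_tape <- function() {
  list(nodes = list(), out_channels = integer(0))
}

nn_add <- function(tape, op, input, cin = NULL, cout = NULL, rate = NULL) {
  node <- list(op = op, input = input)
  if (op %in% c("conv3", "conv1")) {
    k <- if (op == "conv3") 9L else 1L
    node <- c(node, nn_init_conv(cin, cout, k))
    node$cin <- cin
    node$cout <- cout
  }
  if (op == "bnorm") {
    node$gamma <- rep(1, cin)
    node$beta <- rep(0, cin)
    node$run_mean <- rep(0, cin)
    node$run_var <- rep(1, cin)
    node$cout <- cin
  }
  if (op == "dropout") node$rate <- rate
  tape$nodes[[length(tape$nodes) + 1L]] <- node
  ch <- switch(op,
    conv3 = cout, conv1 = cout,
    concat = sum(tape$out_channels[input]),
    bnorm = cin,
    tape$out_channels[input[1]]
  )
  tape$out_channels <- c(tape$out_channels, ch)
  tape
}

# ---- forward / backward ----------------------------------------------------

nn_forward <- function(model, X, H, W, B, train = FALSE) {
  nodes <- model$tape$nodes
  outs <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  geoms <- vector("list", length(nodes))
  cur <- list(X = X, H = H, W = W)
  get_out <- function(i) if (i == 0L) X else outs[[i]]
  get_geom <- function(i) if (i == 0L) c(H, W) else geoms[[i]]
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    inp <- get_out(nd$input[1])
    hw <- get_geom(nd$input[1])
    g <- nn_geometry(hw[1], hw[2], B)
    if (nd$op == "conv3") {
      fw <- nn_conv_fwd(inp, nd, g)
      outs[[i]] <- fw$Y
      caches[[i]] <- if (train) fw$cols else NULL
      geoms[[i]] <- hw
    } else if (nd$op == "conv1") {
      outs[[i]] <- sweep(inp %*% nd$W, 2, nd$b, `+`)
      geoms[[i]] <- hw
    } else if (nd$op == "relu") {
      outs[[i]] <- pmax(inp, 0)
      geoms[[i]] <- hw
    } else if (nd$op == "pool") {
      a1 <- inp[g$pool[[1]], , drop = FALSE]
      a2 <- inp[g$pool[[2]], , drop = FALSE]
      a3 <- inp[g$pool[[3]], , drop = FALSE]
      a4 <- inp[g$pool[[4]], , drop = FALSE]
      M <- a1
      sel <- matrix(1L, nrow(M), ncol(M))
      for (k in 2:4) {
        ak <- list(a2, a3, a4)[[k - 1L]]
        upd <- ak > M
        M[upd] <- ak[upd]
        sel[upd] <- k
      }
      outs[[i]] <- M
      caches[[i]] <- sel
      geoms[[i]] <- c(hw[1] %/% 2L, hw[2] %/% 2L)
    } else if (nd$op == "up") {
      outs[[i]] <- inp[g$up, , drop = FALSE]
      geoms[[i]] <- c(hw[1] * 2L, hw[2] * 2L)
    } else if (nd$op == "concat") {
      outs[[i]] <- cbind(inp, get_out(nd$input[2]))
      geoms[[i]] <- hw
    } else if (nd$op == "dropout") {
      if (train && nd$rate > 0) {
        keep <- 1 - nd$rate
        mask <- matrix(
          stats::rbinom(length(inp), 1L, keep) / keep,
          nrow(inp), ncol(inp)
        )
        outs[[i]] <- inp * mask
        caches[[i]] <- mask
      } else {
        outs[[i]] <- inp
      }
      geoms[[i]] <- hw
    } else if (nd$op == "bnorm") {
      eps <- 1e-5
      if (train) {
        mu <- colMeans(inp)
        xc <- sweep(inp, 2, mu)
        va <- colMeans(xc^2)
        xhat <- sweep(xc, 2, sqrt(va + eps), `/`)
        caches[[i]] <- list(xhat = xhat, inv_sd = 1 / sqrt(va + eps))
        mom <- 0.9
        nodes[[i]]$run_mean <- mom * nd$run_mean + (1 - mom) * mu
        nodes[[i]]$run_var <- mom * nd$run_var + (1 - mom) * va
      } else {
        xhat <- sweep(sweep(inp, 2, nd$run_mean), 2, sqrt(nd$run_var + eps), `/`)
      }
      outs[[i]] <- sweep(sweep(xhat, 2, nd$gamma, `*`), 2, nd$beta, `+`)
      geoms[[i]] <- hw
    } else {
      stop("unknown op ", nd$op)
    }
  }
  model$tape$nodes <- nodes  # running batch-norm stats
  list(model = model, outs = outs, caches = caches, geoms = geoms)
}

nn_backward <- function(model, fw, X, H, W, B, dOut) {
  nodes <- model$tape$nodes
  n <- length(nodes)
  grads_out <- vector("list", n)
  grads_out[[n]] <- dOut
  pgrads <- vector("list", n)
  dX_input <- NULL
  get_out <- function(i) if (i == 0L) X else fw$outs[[i]]
  get_geom <- function(i) if (i == 0L) c(H, W) else fw$geoms[[i]]
  add_grad <- function(i, g) {
    if (i == 0L) {
      dX_input <<- if (is.null(dX_input)) g else dX_input + g
    } else {
      grads_out[[i]] <<- if (is.null(grads_out[[i]])) g else grads_out[[i]] + g
    }
  }
  for (i in rev(seq_len(n))) {
    dY <- grads_out[[i]]
    if (is.null(dY)) next
    nd <- nodes[[i]]
    inp <- get_out(nd$input[1])
    hw <- get_geom(nd$input[1])
    g <- nn_geometry(hw[1], hw[2], B)
    if (nd$op == "conv3") {
      bw <- nn_conv_bwd(dY, inp, fw$caches[[i]], nd, g)
      pgrads[[i]] <- list(dW = bw$dW, db = bw$db)
      add_grad(nd$input[1], bw$dX)
    } else if (nd$op == "conv1") {
      pgrads[[i]] <- list(dW = crossprod(inp, dY), db = colSums(dY))
      add_grad(nd$input[1], tcrossprod(dY, nd$W))
    } else if (nd$op == "relu") {
      add_grad(nd$input[1], dY * (fw$outs[[i]] > 0))
    } else if (nd$op == "pool") {
      sel <- fw$caches[[i]]
      dX <- matrix(0, nrow(inp), ncol(inp))
      for (k in 1:4) {
        mk <- dY * (sel == k)
        idx <- g$pool[[k]]
        dX[idx, ] <- dX[idx, , drop = FALSE] + mk
      }
      add_grad(nd$input[1], dX)
    } else if (nd$op == "up") {
      add_grad(nd$input[1], rowsum(dY, g$up, reorder = TRUE))
    } else if (nd$op == "concat") {
      c1 <- ncol(inp)
      add_grad(nd$input[1], dY[, 1:c1, drop = FALSE])
      add_grad(nd$input[2], dY[, (c1 + 1):ncol(dY), drop = FALSE])
    } else if (nd$op == "dropout") {
      mask <- fw$caches[[i]]
      add_grad(nd$input[1], if (is.null(mask)) dY else dY * mask)
    } else if (nd$op == "bnorm") {
      cache <- fw$caches[[i]]
      xhat <- cache$xhat
      m <- nrow(dY)
      dgamma <- colSums(dY * xhat)
      dbeta <- colSums(dY)
      dxhat <- sweep(dY, 2, nd$gamma, `*`)
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
      dX <- sweep(t1 - t2, 2, cache$inv_sd, `*`)
      pgrads[[i]] <- list(dgamma = dgamma, dbeta = dbeta)
      add_grad(nd$input[1], dX)
    }
  }
  list(pgrads = pgrads, dX = dX_input)
}

# ---- Adam ------------------------------------------------------------------

nn_adam_init <- function(tape) {
  lapply(tape$nodes, function(nd) {
    if (nd$op %in% c("conv3", "conv1")) {
      list(mW = nd$W * 0, vW = nd$W * 0, mb = nd$b * 0, vb = nd$b * 0)
    } else if (nd$op == "bnorm") {
      list(
        mg = nd$gamma * 0, vg = nd$gamma * 0,
        mb = nd$beta * 0, vb = nd$beta * 0
      )
    } else {
      NULL
    }
  })
}

nn_adam_step <- function(model, pgrads, lr, t, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  upd <- function(p, m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (i in seq_along(model$tape$nodes)) {
    gr <- pgrads[[i]]
    if (is.null(gr)) next
    nd <- model$tape$nodes[[i]]
    st <- model$opt[[i]]
    if (nd$op %in% c("conv3", "conv1")) {
      uW <- upd(nd$W, st$mW, st$vW, gr$dW)
      ub <- upd(nd$b, st$mb, st$vb, gr$db)
      nd$W <- uW$p; st$mW <- uW$m; st$vW <- uW$v
      nd$b <- ub$p; st$mb <- ub$m; st$vb <- ub$v
    } else if (nd$op == "bnorm") {
      ug <- upd(nd$gamma, st$mg, st$vg, gr$dgamma)
      ub <- upd(nd$beta, st$mb, st$vb, gr$dbeta)
      nd$gamma <- ug$p; st$mg <- ug$m; st$vg <- ug$v
      nd$beta <- ub$p; st$mb <- ub$m; st$vb <- ub$v
    }
    model$tape$nodes[[i]] <- nd
    model$opt[[i]] <- st
  }
  model
}

# ---- loss ------------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# binary cross-entropy with logits; returns loss and d(loss)/d(logits)
nn_bce <- function(z, y, weight = NULL) {
  p <- sigmoid(z)
  eps <- 1e-12
  ll <- -(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  if (is.null(weight)) {
    loss <- mean(ll)
    dz <- (p - y) / length(z)
  } else {
    loss <- sum(ll * weight) / sum(weight)
    dz <- (p - y) * weight / sum(weight)
  }
  list(loss = loss, dz = dz)
}

# pack a list of H x W single-channel matrices into a batch matrix
nn_pack <- function(samples) {
  matrix(unlist(samples, use.names = FALSE), ncol = 1L)
}
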