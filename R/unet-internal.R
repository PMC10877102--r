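# Internal neural-network machinery for the semantic segmenters.
#
# Feature maps are (B*H*W) x C double matrices, column-major pixel order
# within each image (pixel (r, c) of image b lives at row b*H*W + c*H + r,
# all 0-based). 3x3 convolutions run as single-precision im2col + GEMM in
# C++ (src/convnet.cpp); batch normalization (fused with ReLU), 2x2
# max-pooling and nearest upsampling complete the layer set. A forward
# pass records a tape of layer caches that the backward pass consumes in
# reverse, accumulating parameter gradients.

.geom_cache <- new.env(parent = emptyenv())

pool_geometry <- function(B, H, W) {
  key <- sprintf("p%d_%d_%d", B, H, W)
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r <- rep(seq(1L, H, 2L), times = W2)
  c <- rep(seq(1L, W, 2L), each = H2)
  base <- (c - 1L) * H + r
  off <- rep((seq_len(B) - 1L) * H * W, each = H2 * W2)
  tl <- rep(base, B) + off
  g <- list(i1 = tl, i2 = tl + 1L, i3 = tl + H, i4 = tl + H + 1L,
            n_in = B * H * W)
  .geom_cache[[key]] <- g
  g
}

upsample_geometry <- function(B, H, W) {
  # maps (B, 2H, 2W) output pixels to source pixels of a (B, H, W) map
  key <- sprintf("u%d_%d_%d", B, H, W)
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  H2 <- 2L * H; W2 <- 2L * W
  r <- rep(seq_len(H2), times = W2)
  c <- rep(seq_len(W2), each = H2)
  base <- (((c + 1L) %/% 2L) - 1L) * H + (r + 1L) %/% 2L
  rowmap <- rep(base, B) + rep((seq_len(B) - 1L) * H * W, each = H2 * W2)
  g <- list(rowmap = rowmap, n_in = B * H * W)
  .geom_cache[[key]] <- g
  g
}

tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$records <- list()
  e
}
tape_push <- function(tape, rec) {
  if (!is.null(tape)) tape$records[[length(tape$records) + 1L]] <- rec
  invisible(NULL)
}

add_rowvec <- function(X, v) X + rep(v, each = nrow(X))

nn_conv3 <- function(X, Wt, B, H, W, tape, wname) {
  Y <- .conv3_fwd(X, Wt, B, H, W)
  tape_push(tape, list(type = "conv3", w = wname, X = X, B = B, H = H, W = W))
  Y
}

# batch norm + ReLU; training mode uses batch statistics and updates the
# running ones, inference mode applies the stored statistics
nn_bnrelu <- function(X, P, S, name, training, tape, momentum = 0.9,
                      eps = 1e-5) {
  gamma <- get(paste0(name, "_g"), envir = P)
  beta <- get(paste0(name, "_b"), envir = P)
  if (training) {
    f <- .bnrelu_fwd(X, gamma, beta, eps)
    S[[paste0(name, ".rm")]] <- momentum * S[[paste0(name, ".rm")]] +
      (1 - momentum) * f$mu
    S[[paste0(name, ".rv")]] <- momentum * S[[paste0(name, ".rv")]] +
      (1 - momentum) * f$var
    tape_push(tape, list(type = "bnrelu", g = paste0(name, "_g"),
                         b = paste0(name, "_b"), Y = f$Y, xhat = f$xhat,
                         inv_sd = f$inv_sd))
    f$Y
  } else {
    n <- nrow(X)
    mu <- S[[paste0(name, ".rm")]]
    inv_sd <- 1 / sqrt(S[[paste0(name, ".rv")]] + eps)
    Y <- add_rowvec(add_rowvec(X, -mu) * rep(gamma * inv_sd, each = n), beta)
    Y * (Y > 0)
  }
}

nn_pool <- function(X, B, H, W, tape) {
  g <- pool_geometry(B, H, W)
  A1 <- X[g$i1, , drop = FALSE]; A2 <- X[g$i2, , drop = FALSE]
  A3 <- X[g$i3, , drop = FALSE]; A4 <- X[g$i4, , drop = FALSE]
  Y <- pmax(A1, A2, A3, A4)
  if (!is.null(tape)) {
    w1 <- A1 == Y
    w2 <- !w1 & (A2 == Y)
    w3 <- !(w1 | w2) & (A3 == Y)
    w4 <- !(w1 | w2 | w3)
    tape_push(tape, list(type = "pool", g = g, w = list(w1, w2, w3, w4)))
  }
  Y
}

nn_upsample <- function(X, B, H, W, tape) {
  g <- upsample_geometry(B, H, W)
  Y <- X[g$rowmap, , drop = FALSE]
  tape_push(tape, list(type = "upsample", g = g))
  Y
}

nn_concat <- function(A, Bm, tape) {
  tape_push(tape, list(type = "concat", c1 = ncol(A)))
  cbind(A, Bm)
}

# 1x1 convolution (plain GEMM); `bias` only for the output head
nn_conv1 <- function(X, Wt, b, tape, wname, bname = NULL) {
  Y <- X %*% Wt
  if (!is.null(b)) Y <- add_rowvec(Y, b)
  tape_push(tape, list(type = "conv1", w = wname, b = bname, X = X))
  Y
}

nn_sigmoid <- function(Z, tape) {
  P <- 1 / (1 + exp(-Z))
  tape_push(tape, list(type = "sigmoid", P = P))
  P
}

acc_grad <- function(grads, name, g) {
  cur <- grads[[name]]
  grads[[name]] <- if (is.null(cur)) g else cur + g
}

# Backward pass: walk the tape in reverse, accumulating parameter
# gradients into `grads` (an environment with P_env and skip_stack).
unet_backward <- function(tape, dY, grads) {
  recs <- tape$records
  for (k in rev(seq_along(recs))) {
    rec <- recs[[k]]
    dY <- switch(rec$type,
      conv3 = {
        bw <- .conv3_bwd(rec$X, get(rec$w, envir = grads$P_env), dY,
                         rec$B, rec$H, rec$W, need_dx = !rec$first)
        acc_grad(grads, rec$w, bw$dW)
        if (rec$first) NULL else bw$dX
      },
      bnrelu = {
        bw <- .bnrelu_bwd(dY, rec$Y, rec$xhat, rec$inv_sd,
                          get(rec$g, envir = grads$P_env))
        acc_grad(grads, rec$g, bw$dgamma)
        acc_grad(grads, rec$b, bw$dbeta)
        bw$dX
      },
      pool = {
        g <- rec$g
        dX <- matrix(0, g$n_in, ncol(dY))
        dX[g$i1, ] <- dY * rec$w[[1]]
        dX[g$i2, ] <- dY * rec$w[[2]]
        dX[g$i3, ] <- dY * rec$w[[3]]
        dX[g$i4, ] <- dY * rec$w[[4]]
        dX
      },
      upsample = rowsum(dY, rec$g$rowmap, reorder = TRUE),
      concat = {
        # stash the skip-path gradient; continue with the up-path part
        grads$skip_stack[[length(grads$skip_stack) + 1L]] <-
          dY[, (rec$c1 + 1L):ncol(dY), drop = FALSE]
        dY[, seq_len(rec$c1), drop = FALSE]
      },
      conv1 = {
        acc_grad(grads, rec$w, crossprod(rec$X, dY))
        if (!is.null(rec$b)) acc_grad(grads, rec$b, colSums(dY))
        tcrossprod(dY, get(rec$w, envir = grads$P_env))
      },
      sigmoid = dY * rec$P * (1 - rec$P),
      skip_merge = {
        # encoder side of a skip connection: add the stored decoder gradient
        sg <- grads$skip_stack[[length(grads$skip_stack)]]
        grads$skip_stack[[length(grads$skip_stack)]] <- NULL
        dY + sg
      },
      stop("unknown tape record ", rec$type)
    )
    recs[k] <- list(NULL)  # release the cache as we go
  }
  invisible(dY)
}

# He-initialized parameter set. Encoder/bottleneck/decoder use bias-free
# 3x3 convolutions (batch norm supplies the shift); the decoder halves
# channels with a 1x1 projection after each nearest upsample; the output
# head is a 1x1 convolution with bias.
unet_init_params <- function(depth, base_filters, in_channels = 1L) {
  P <- new.env(parent = emptyenv())
  he <- function(fan_in, nout) matrix(rnorm(fan_in * nout, 0, sqrt(2 / fan_in)),
                                      fan_in, nout)
  conv <- function(name, cin, cout, k = 3L) {
    assign(paste0(name, "_W"), he(k * k * cin, cout), envir = P)
    assign(paste0(name, "_g"), rep(1, cout), envir = P)
    assign(paste0(name, "_b"), rep(0, cout), envir = P)
  }
  ch <- function(i) base_filters * 2L^(i - 1L)
  for (i in seq_len(depth)) {
    conv(sprintf("enc%d_1", i), if (i == 1L) in_channels else ch(i - 1L), ch(i))
    conv(sprintf("enc%d_2", i), ch(i), ch(i))
  }
  conv("bott_1", ch(depth), 2L * ch(depth))
  conv("bott_2", 2L * ch(depth), 2L * ch(depth))
  for (i in seq(depth, 1L)) {
    conv(sprintf("dec%d_up", i), 2L * ch(i), ch(i), k = 1L)
    conv(sprintf("dec%d_1", i), 2L * ch(i), ch(i))
    conv(sprintf("dec%d_2", i), ch(i), ch(i))
  }
  assign("out_W", he(base_filters, 1L), envir = P)
  assign("out_b", 0, envir = P)
  P
}

unet_init_state <- function(depth, base_filters) {
  S <- new.env(parent = emptyenv())
  ch <- function(i) base_filters * 2L^(i - 1L)
  bn <- function(name, c) {
    assign(paste0(name, ".rm"), rep(0, c), envir = S)
    assign(paste0(name, ".rv"), rep(1, c), envir = S)
  }
  for (i in seq_len(depth)) {
    bn(sprintf("enc%d_1", i), ch(i)); bn(sprintf("enc%d_2", i), ch(i))
  }
  bn("bott_1", 2L * ch(depth)); bn("bott_2", 2L * ch(depth))
  for (i in seq(depth, 1L)) {
    bn(sprintf("dec%d_up", i), ch(i))
    bn(sprintf("dec%d_1", i), ch(i)); bn(sprintf("dec%d_2", i), ch(i))
  }
  S
}

conv_block <- function(X, P, S, name, B, H, W, training, tape,
                       first = FALSE) {
  Y <- nn_conv3(X, get(paste0(name, "_W"), envir = P), B, H, W, tape,
                paste0(name, "_W"))
  if (!is.null(tape))
    tape$records[[length(tape$records)]]$first <- first
  nn_bnrelu(Y, P, S, name, training, tape)
}

proj_block <- function(X, P, S, name, training, tape) {
  Y <- nn_conv1(X, get(paste0(name, "_W"), envir = P), NULL, tape,
                paste0(name, "_W"))
  nn_bnrelu(Y, P, S, name, training, tape)
}

# Full forward pass; X is the already per-image-normalized (B*H*W) x C_in
# input. Returns sigmoid probabilities and (when training) the tape.
unet_forward <- function(P, S, X, B, H, W, depth, training = FALSE,
                         with_tape = training) {
  tape <- if (with_tape) tape_new() else NULL
  skips <- list()
  hs <- H; ws <- W
  A <- X
  for (i in seq_len(depth)) {
    A <- conv_block(A, P, S, sprintf("enc%d_1", i), B, hs, ws, training,
                    tape, first = (i == 1L))
    A <- conv_block(A, P, S, sprintf("enc%d_2", i), B, hs, ws, training, tape)
    tape_push(tape, list(type = "skip_merge"))
    skips[[i]] <- A
    A <- nn_pool(A, B, hs, ws, tape)
    hs <- hs %/% 2L; ws <- ws %/% 2L
  }
  A <- conv_block(A, P, S, "bott_1", B, hs, ws, training, tape)
  A <- conv_block(A, P, S, "bott_2", B, hs, ws, training, tape)
  for (i in seq(depth, 1L)) {
    A <- nn_upsample(A, B, hs, ws, tape)
    hs <- hs * 2L; ws <- ws * 2L
    A <- proj_block(A, P, S, sprintf("dec%d_up", i), training, tape)
    A <- nn_concat(A, skips[[i]], tape)
    skips[i] <- list(NULL)
    A <- conv_block(A, P, S, sprintf("dec%d_1", i), B, hs, ws, training, tape)
    A <- conv_block(A, P, S, sprintf("dec%d_2", i), B, hs, ws, training, tape)
  }
  Z <- nn_conv1(A, get("out_W", envir = P), get("out_b", envir = P),
                tape, "out_W", "out_b")
  Pr <- nn_sigmoid(Z, tape)
  list(prob = Pr, tape = tape)
}

# soft Jaccard loss gradient wrt probabilities
soft_jaccard_grad <- function(p, t, eps = 1e-6) {
  I <- sum(p * t); U <- sum(p) + sum(t) - I
  -(t * (U + eps) - (I + eps) * (1 - t)) / (U + eps)^2
}

adam_new <- function(P) {
  st <- new.env(parent = emptyenv())
  for (nm in ls(P)) {
    st[[paste0(nm, ".m")]] <- get(nm, envir = P) * 0
    st[[paste0(nm, ".v")]] <- get(nm, envir = P) * 0
  }
  st$t <- 0L
  st
}

adam_step <- function(P, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in ls(P)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- beta1 * st[[paste0(nm, ".m")]] + (1 - beta1) * g
    v <- beta2 * st[[paste0(nm, ".v")]] + (1 - beta2) * g * g
    st[[paste0(nm, ".m")]] <- m
    st[[paste0(nm, ".v")]] <- v
    assign(nm, get(nm, envir = P) - lr * (m / bc1) / (sqrt(v / bc2) + eps),
           envir = P)
  }
  invisible(NULL)
}

env_snapshot <- function(e) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(e)) assign(nm, get(nm, envir = e), envir = out)
  out
}

# per-image min-max normalization to [0, 1]
normalize_image <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi > lo) (m - lo) / (hi - lo) else m * 0
}

# integer-factor block mean (or pixel replication when growing); falls
# back to EBImage bilinear resizing for non-integer factors
resample_image <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  if (H == h && W == w) return(m)
  if (H %% h == 0L && W %% w == 0L) {
    fh <- H %/% h; fw <- W %/% w
    rg <- rep(seq_len(h), each = fh)
    m2 <- rowsum(m, rg, reorder = TRUE) / fh
    t(rowsum(t(m2), rep(seq_len(w), each = fw), reorder = TRUE)) / fw
  } else if (h %% H == 0L && w %% W == 0L) {
    m[rep(seq_len(H), each = h %/% H), rep(seq_len(W), each = w %/% W)]
  } else {
    EBImage::imageData(EBImage::resize(m, w = h, h = w))
  }
}

# masks: block coverage >= 0.5 when shrinking, nearest when growing
resample_mask <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  if (H == h && W == w) return(m)
  if (h <= H) (resample_image(m, h, w) >= 0.5) * 1L
  else resample_image(m, h, w)
}
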