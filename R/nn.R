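# Minimal neural-network layer framework with manual backpropagation.
#
# Every layer is an environment with fields:
#   params : named list of numeric arrays (trainable weights)
#   grads  : matching list of gradient accumulators
#   fwd(x, train) / bwd(gy) closures
# Feature tensors are numeric arrays with dim = c(C, H, W, D).

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  class(e) <- c(paste0("morphssl_", type), "morphssl_layer")
  e
}

#' @keywords internal
init_weight <- function(n_out, k, fan_in, rng_sd = sqrt(2)) {
  matrix(stats::rnorm(n_out * k, sd = rng_sd / sqrt(max(fan_in, 1))), n_out, k)
}

nn_conv3d <- function(cin, cout, kern, stride = c(1L, 1L, 1L),
                      pad = NULL, groups = 1L, bias = TRUE) {
  stopifnot(cin %% groups == 0, cout %% groups == 0)
  if (is.null(pad)) pad <- (kern - 1L) %/% 2L
  l <- new_layer("conv3d")
  cing <- cin %/% groups
  K <- cing * prod(kern)
  l$params$w <- init_weight(cout, K, K)
  if (bias) l$params$b <- numeric(cout)
  l$grads <- lapply(l$params, function(p) p * 0)
  l$cin <- as.integer(cin); l$cout <- as.integer(cout)
  l$kern <- as.integer(kern); l$stride <- as.integer(stride)
  l$pad <- as.integer(pad); l$groups <- as.integer(groups)
  l$bias <- bias
  l$fwd <- function(x, train = FALSE) {
    if (train) l$x <- x
    conv3d_fw_cpp(x, dim(x), l$params$w,
                  if (l$bias) l$params$b else NULL,
                  l$kern, l$stride, l$pad, l$groups)
  }
  l$bwd <- function(gy) {
    r <- conv3d_bw_cpp(l$x, dim(l$x), l$params$w, gy,
                       l$kern, l$stride, l$pad, l$groups, l$bias)
    l$grads$w <- l$grads$w + r$gw
    if (l$bias) l$grads$b <- l$grads$b + r$gb
    l$x <- NULL
    r$gx
  }
  l
}

# Filter allocation of the separable 3D convolution: half the filters work
# within B-scans (3x3x1), the rest split equally across the two
# cross-B-scan orientations (1x3x3 and 3x1x3). For fewer than 4 output
# channels the cross-plane groups are dropped.
s3d_alloc <- function(cout) {
  n23 <- cout %/% 4L
  c(cout - 2L * n23, n23, n23)
}

# Separable 3D convolution block: three oriented 2D filter groups whose
# outputs are concatenated along the channel axis.
nn_s3dconv <- function(cin, cout, bias = TRUE) {
  l <- new_layer("s3dconv")
  a <- s3d_alloc(cout)
  kerns <- list(c(3L, 3L, 1L), c(1L, 3L, 3L), c(3L, 1L, 3L))
  l$convs <- list()
  for (i in 1:3) {
    if (a[i] > 0)
      l$convs[[length(l$convs) + 1L]] <-
        nn_conv3d(cin, a[i], kerns[[i]], bias = bias)
  }
  l$cin <- cin; l$cout <- cout
  l$fwd <- function(x, train = FALSE) {
    ys <- lapply(l$convs, function(cv) cv$fwd(x, train))
    channel_cat(ys)
  }
  l$bwd <- function(gy) {
    co <- vapply(l$convs, function(cv) cv$cout, integer(1))
    parts <- channel_split(gy, co)
    gx <- NULL
    for (i in seq_along(l$convs)) {
      g <- l$convs[[i]]$bwd(parts[[i]])
      gx <- if (is.null(gx)) g else gx + g
    }
    gx
  }
  l
}

channel_cat <- function(xs) {
  if (length(xs) == 1L) return(xs[[1L]])
  dims <- dim(xs[[1L]])
  ctot <- sum(vapply(xs, function(x) dim(x)[1L], integer(1)))
  out <- array(0, c(ctot, dims[2L], dims[3L], dims[4L]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[1L]
    out[at + seq_len(cc), , , ] <- x
    at <- at + cc
  }
  out
}

channel_split <- function(x, sizes) {
  at <- 0L
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    out[[i]] <- x[at + seq_len(sizes[i]), , , , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# Pre-activation normalization + ELU.
# norm = "layer": statistics over the whole (C,H,W,D) tensor (supports
# batch size 1); norm = "batch": per-channel statistics (the batch-size-1
# realization of batch normalization). Per-channel affine (scale, shift).
nn_norm_act <- function(C, norm = "layer", eps = 1e-5) {
  l <- new_layer("norm_act")
  l$params$g <- rep(1, C)
  l$params$b <- numeric(C)
  l$grads <- lapply(l$params, function(p) p * 0)
  l$C <- C; l$norm <- norm; l$eps <- eps
  l$fwd <- function(x, train = FALSE) {
    if (l$norm == "layer") {
      mu <- mean(x)
      sd_ <- sqrt(mean((x - mu)^2) + l$eps)
      xh <- x - mu
      xh <- xh / sd_
    } else {
      m <- apply(x, 1, mean)
      v <- apply(x, 1, function(z) mean((z - mean(z))^2))
      sd_ <- sqrt(v + l$eps)
      xh <- (x - m) / sd_   # recycles along channel (fastest) axis
    }
    z <- xh * l$params$g
    z <- z + l$params$b
    if (train) { l$xh <- xh; l$sd <- sd_; l$z <- z }
    elu(z)
  }
  l$bwd <- function(gy) {
    dz <- gy * elu_grad(l$z)
    l$grads$g <- l$grads$g + rowSums(matrix(dz * l$xh, nrow = l$C))
    l$grads$b <- l$grads$b + rowSums(matrix(dz, nrow = l$C))
    dxh <- dz * l$params$g
    if (l$norm == "layer") {
      gx <- (dxh - mean(dxh) - l$xh * mean(dxh * l$xh)) / l$sd
    } else {
      m1 <- apply(dxh, 1, mean)
      m2 <- apply(dxh * l$xh, 1, mean)
      gx <- (dxh - m1 - l$xh * m2) / l$sd
    }
    l$xh <- NULL; l$z <- NULL
    gx
  }
  l
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_grad <- function(x) {
  g <- x
  neg <- x < 0
  g[!neg] <- 1
  g[neg] <- exp(x[neg])
  g
}

# Parameter-free ELU layer (used between the 1x1x1 head convolutions).
nn_elu <- function() {
  l <- new_layer("elu")
  l$fwd <- function(x, train = FALSE) { if (train) l$x <- x; elu(x) }
  l$bwd <- function(gy) { g <- gy * elu_grad(l$x); l$x <- NULL; g }
  l
}

# Trilinear upsampling to an explicit target spatial shape (no parameters).
nn_upsample <- function(target) {
  l <- new_layer("upsample")
  l$target <- as.integer(target)
  l$fwd <- function(x, train = FALSE) {
    if (train) l$dimx <- dim(x)
    trilinear_resize_fw_cpp(x, dim(x), l$target)
  }
  l$bwd <- function(gy) trilinear_resize_bw_cpp(gy, l$dimx, l$target)
  l
}

# Sequential container.
nn_seq <- function(...) {
  l <- new_layer("seq")
  l$layers <- list(...)
  l$fwd <- function(x, train = FALSE) {
    for (m in l$layers) x <- m$fwd(x, train)
    x
  }
  l$bwd <- function(gy) {
    for (m in rev(l$layers)) gy <- m$bwd(gy)
    gy
  }
  l
}

# Positive scalar parameterized on the log scale.
nn_pos_scalar <- function(init = 1) {
  l <- new_layer("pos_scalar")
  l$params$log_v <- log(init)
  l$grads$log_v <- 0
  l$value <- function() exp(l$params$log_v)
  l$acc_grad <- function(g_value) {
    l$grads$log_v <- l$grads$log_v + g_value * exp(l$params$log_v)
  }
  l
}

# --- parameter bookkeeping ---------------------------------------------------

collect_layers <- function(m) {
  if (inherits(m, "morphssl_layer")) {
    subs <- list()
    if (!is.null(m$layers)) subs <- m$layers
    if (!is.null(m$convs)) subs <- c(subs, m$convs)
    c(list(m), unlist(lapply(subs, collect_layers), recursive = FALSE))
  } else if (is.list(m)) {
    unlist(lapply(m, collect_layers), recursive = FALSE)
  } else {
    list()
  }
}

n_params <- function(m) {
  ls <- collect_layers(m)
  sum(vapply(ls, function(l) sum(vapply(l$params, length, numeric(1))),
             numeric(1)))
}

zero_grads <- function(m) {
  for (l in collect_layers(m))
    l$grads <- lapply(l$grads, function(g) g * 0)
  invisible(NULL)
}

get_param_vector <- function(m) {
  unlist(lapply(collect_layers(m), function(l) unlist(l$params)))
}

# --- Adam optimizer ----------------------------------------------------------

adam_state <- function(model, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  ls <- collect_layers(model)
  ls <- Filter(function(l) length(l$params) > 0, ls)
  st <- list(layers = ls, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
             wd = weight_decay, t = 0,
             m = lapply(ls, function(l) lapply(l$params, function(p) p * 0)),
             v = lapply(ls, function(l) lapply(l$params, function(p) p * 0)))
  st
}

adam_step <- function(st, lr = NULL) {
  if (!is.null(lr)) st$lr <- lr
  st$t <- st$t + 1
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$layers)) {
    l <- st$layers[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (st$wd > 0) g <- g + st$wd * l$params[[nm]]
      st$m[[i]][[nm]] <- st$beta1 * st$m[[i]][[nm]] + (1 - st$beta1) * g
      st$v[[i]][[nm]] <- st$beta2 * st$v[[i]][[nm]] + (1 - st$beta2) * g^2
      mh <- st$m[[i]][[nm]] / bc1
      vh <- st$v[[i]][[nm]] / bc2
      l$params[[nm]] <- l$params[[nm]] - st$lr * mh / (sqrt(vh) + st$eps)
    }
  }
  st
}
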