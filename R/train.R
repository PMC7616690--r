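# Training loops: pre-training of the morph pretext task, TTC classifier
# training (frozen encoder or end-to-end fine-tuning), augmentation,
# the cyclic learning-rate schedule, and inference.

#' Training configuration
#'
#' Defaults mirror the reference training regime: Adam (0.9, 0.999),
#' weight decay 1e-5 for pre-training and 1e-2 for the TTC phases, cyclic
#' learning rate 1e-6..1e-4 (pre-training) or 1e-5..1e-4 (TTC), batch size
#' 1 / 16 / 6 for pretrain / frozen TTC / fine-tuning.
#'
#' @param phase `"pretrain"`, `"ttc_freeze"` or `"ttc_finetune"`.
#' @param epochs,steps_per_epoch Schedule size (tests scale these down).
#' @param seed RNG seed.
#' @param augment Apply data augmentation.
#' @export
train_config <- function(phase = c("pretrain", "ttc_freeze", "ttc_finetune"),
                         epochs = NULL, steps_per_epoch = NULL,
                         batch_size = NULL, lr_min = NULL, lr_max = 1e-4,
                         weight_decay = NULL, beta1 = 0.9, beta2 = 0.999,
                         seed = 1L, augment = TRUE) {
  phase <- match.arg(phase)
  defaults <- switch(phase,
    pretrain = list(epochs = 160L, steps_per_epoch = 2000L, batch_size = 1L,
                    lr_min = 1e-6, weight_decay = 1e-5),
    ttc_freeze = list(epochs = 400L, steps_per_epoch = 500L, batch_size = 16L,
                      lr_min = 1e-5, weight_decay = 1e-2),
    ttc_finetune = list(epochs = 400L, steps_per_epoch = 500L, batch_size = 6L,
                        lr_min = 1e-5, weight_decay = 1e-2))
  structure(list(phase = phase,
                 epochs = epochs %||% defaults$epochs,
                 steps_per_epoch = steps_per_epoch %||% defaults$steps_per_epoch,
                 batch_size = batch_size %||% defaults$batch_size,
                 lr_min = lr_min %||% defaults$lr_min, lr_max = lr_max,
                 weight_decay = weight_decay %||% defaults$weight_decay,
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

#' Triangular cyclic learning rate
#'
#' Rises linearly from `lr_min` to `lr_max` over the first half of each
#' epoch and back down over the second half.
#'
#' @param step 0-based global step.
#' @param steps_per_epoch Steps per epoch.
#' @param lr_min,lr_max Schedule bounds.
#' @export
cyclic_lr <- function(step, steps_per_epoch, lr_min, lr_max) {
  frac <- (step %% steps_per_epoch) / steps_per_epoch
  tri <- 1 - abs(2 * frac - 1)
  lr_min + tri * (lr_max - lr_min)
}

# --- augmentation ------------------------------------------------------------

shift_array <- function(v, sh, fill = -1) {
  out <- array(fill, dim(v))
  dm <- dim(v)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- sh[ax]
    src[[ax]] <- max(1, 1 - s):min(dm[ax], dm[ax] - s)
    dst[[ax]] <- src[[ax]] + s
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}

blur3d <- function(v, sigma) {
  if (sigma <= 0.05) return(v)
  r <- 2L
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  dm <- dim(v)
  pad_conv <- function(x, axis) {
    n <- dm[axis]
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- array(0, dm)
    for (j in -r:r) {
      sl <- idx(seq_len(n) + j)
      out <- out + k[j + r + 1L] * switch(axis,
        x[sl, , , drop = FALSE], x[, sl, , drop = FALSE],
        x[, , sl, drop = FALSE])
    }
    out
  }
  v <- pad_conv(v, 1L); v <- pad_conv(v, 2L); pad_conv(v, 3L)
}

#' Augment a longitudinal training pair
#'
#' Random integer 3D translation (up to `max_shift` of the image size per
#' axis) and a horizontal (lateral) flip are applied IDENTICALLY to both
#' scans and their ROI masks; Gaussian blur (sigma ~ U[0, 0.9]) and
#' Gaussian noise (sd 0.001) are applied to each scan independently.
#'
#' @param pair List with `I_t`, `I_tk` ([oct_volume()] or arrays) and
#'   optionally `R_t`, `R_tk` (`roi_mask`s or arrays).
#' @param max_shift Maximum translation as a fraction of each axis.
#' @return The augmented pair (same structure).
#' @export
augment_pair <- function(pair, max_shift = 0.15) {
  arr <- function(x) if (inherits(x, "oct_volume")) x$voxels
                     else if (inherits(x, "roi_mask")) x$mask else x
  wrap <- function(orig, v) {
    if (inherits(orig, "oct_volume")) { orig$voxels <- v; orig }
    else if (inherits(orig, "roi_mask")) { orig$mask <- v; orig }
    else v
  }
  v_t <- arr(pair$I_t); v_tk <- arr(pair$I_tk)
  dm <- dim(v_t)
  sh <- vapply(dm, function(n) {
    half <- as.integer(floor(max_shift * n))
    sample.int(2L * half + 1L, 1L) - half - 1L
  }, integer(1))
  flip <- stats::runif(1) < 0.5
  tf_shared <- function(v, fill) {
    v <- shift_array(v, sh, fill)
    if (flip) v <- v[, rev(seq_len(dm[2L])), , drop = FALSE]
    v
  }
  v_t <- tf_shared(v_t, -1); v_tk <- tf_shared(v_tk, -1)
  v_t <- blur3d(v_t, stats::runif(1, 0, 0.9)) +
    array(stats::rnorm(length(v_t), 0, 0.001), dm)
  v_tk <- blur3d(v_tk, stats::runif(1, 0, 0.9)) +
    array(stats::rnorm(length(v_tk), 0, 0.001), dm)
  out <- pair
  out$I_t <- wrap(pair$I_t, v_t)
  out$I_tk <- wrap(pair$I_tk, v_tk)
  if (!is.null(pair$R_t)) out$R_t <- wrap(pair$R_t, tf_shared(arr(pair$R_t), 0))
  if (!is.null(pair$R_tk)) out$R_tk <- wrap(pair$R_tk, tf_shared(arr(pair$R_tk), 0))
  out
}

# --- layer cache stash/restore (the encoder runs twice per step) -------------

CACHE_FIELDS <- c("x", "xh", "sd", "z", "dimx")

stash_cache <- function(m) {
  lapply(collect_layers(m), function(l)
    mget(CACHE_FIELDS, envir = l, ifnotfound = list(NULL)))
}

restore_cache <- function(m, cache) {
  ls <- collect_layers(m)
  for (i in seq_along(ls))
    for (f in CACHE_FIELDS)
      assign(f, cache[[i]][[f]], envir = ls[[i]])
  invisible(NULL)
}

# --- gradient pieces for the regularizers ------------------------------------

smoothness_grad <- function(D) {
  g <- array(0, dim(D))
  for (ax in 2:4) {
    n <- dim(D)[ax]
    if (n < 2) next
    d <- axis_slice(D, ax, 2:n) - axis_slice(D, ax, 1:(n - 1))
    add <- function(idx, val) {
      switch(ax - 1L,
             g[, idx, , ] <<- g[, idx, , ] + val,
             g[, , idx, ] <<- g[, , idx, ] + val,
             g[, , , idx] <<- g[, , , idx] + val)
    }
    add(2:n, 2 * d)
    add(1:(n - 1), -2 * d)
  }
  g
}

folding_grad <- function(D, fl) {
  g <- array(0, dim(D))
  if (is.null(fl$det)) return(g)
  act <- fl$det < 0
  if (!any(act)) return(g)
  J <- fl$J
  w <- ifelse(act, -1, 0)  # dL/ddet on active voxels
  cof <- list(
    c(1, 1,  1), c(1, 2, -1), c(1, 3,  1),
    c(2, 1, -1), c(2, 2,  1), c(2, 3, -1),
    c(3, 1,  1), c(3, 2, -1), c(3, 3,  1))
  cofactor <- function(i, j) {
    # minor of J with row i, col j removed (rows: output channel, cols: axis)
    r <- setdiff(1:3, i); cl <- setdiff(1:3, j)
    Jm <- function(a, b) J[[paste0("J", a, b)]]
    Jm(r[1], cl[1]) * Jm(r[2], cl[2]) - Jm(r[1], cl[2]) * Jm(r[2], cl[1])
  }
  ih <- fl$interior$ih; iw <- fl$interior$iw; id <- fl$interior$id
  for (i in 1:3) for (j in 1:3) {
    sgn <- (-1)^(i + j)
    gJ <- w * sgn * cofactor(i, j)   # dL/dJ_ij on the interior grid
    # J_ij = delta_ij + central difference of D_i along axis j
    half <- gJ / 2
    if (j == 1) {
      g[i, ih + 1, iw, id] <- g[i, ih + 1, iw, id] + half
      g[i, ih - 1, iw, id] <- g[i, ih - 1, iw, id] - half
    } else if (j == 2) {
      g[i, ih, iw + 1, id] <- g[i, ih, iw + 1, id] + half
      g[i, ih, iw - 1, id] <- g[i, ih, iw - 1, id] - half
    } else {
      g[i, ih, iw, id + 1] <- g[i, ih, iw, id + 1] + half
      g[i, ih, iw, id - 1] <- g[i, ih, iw, id - 1] - half
    }
  }
  g
}

# --- one pre-training step ---------------------------------------------------

# Forward + loss (+ gradient accumulation when train = TRUE) for one pair.
ssl_step <- function(model, comparator, pair, weights = ssl_loss_weights(),
                     train = TRUE) {
  enc <- model$encoder
  sc <- model$scalars
  I_t <- if (inherits(pair$I_t, "oct_volume")) pair$I_t$voxels else pair$I_t
  I_tk <- if (inherits(pair$I_tk, "oct_volume")) pair$I_tk$voxels else pair$I_tk
  R_t <- if (inherits(pair$R_t, "roi_mask")) pair$R_t$mask else pair$R_t
  R_tk <- if (inherits(pair$R_tk, "roi_mask")) pair$R_tk$mask else pair$R_tk
  dm <- dim(I_t)
  N <- length(I_t)
  x_t <- array(I_t, c(1L, dm)); x_tk <- array(I_tk, c(1L, dm))

  E_t <- enc$fwd(x_t, train = train)
  cache_t <- if (train) stash_cache(enc)
  E_tk <- enc$fwd(x_tk, train = train)

  disp <- feature_displacement(E_t, E_tk)
  a1 <- sc$alpha1$value(); a2 <- sc$alpha2$value(); gam <- sc$gamma$value()

  # displacement path
  if (disp$n_D >= MORPH_EPS) {
    xD <- gam * disp$u_D
    Dhat <- model$decoder_d$fwd(xD, train = train)
    nhD <- max(fro_norm(Dhat), MORPH_EPS)
    sD <- a1 * disp$n_D
    Df <- (sD / nhD) * Dhat
  } else {
    Df <- array(0, c(3L, dm))
  }
  # additive path
  if (disp$n_A >= MORPH_EPS) {
    xA <- gam * disp$u_A
    Ahat <- model$decoder_a$fwd(xA, train = train)
    nhA <- max(fro_norm(Ahat), MORPH_EPS)
    sA <- a2 * disp$n_A
    Af <- array((sA / nhA) * Ahat, dm)
  } else {
    Af <- array(0, dm)
  }

  W_I <- array(warp_fw_cpp(I_t, dm, Df, -1), dm)
  W_R <- array(warp_fw_cpp(R_t, dm, Df, 0), dm)
  M_tk <- I_tk * R_tk
  P1 <- W_I * W_R
  U <- M_tk - P1
  term1 <- weights$lambda1 / N * sum(U^2)
  term2 <- weights$lambda2 / N * sum((U - Af)^2)
  Ihat_m <- (W_I + Af) * W_R

  taps_ref <- comparator_fwd(comparator, M_tk, train = FALSE)
  taps_hat <- comparator_fwd(comparator, Ihat_m, train = train)
  L_prc <- mean(mapply(function(a, b) mean((a - b)^2), taps_ref, taps_hat))

  L_smth <- smoothness_loss(Df)
  fl <- folding_loss(Df)
  L_add <- sum(abs(Af))
  tot <- total_ssl_loss(list(term1 = term1, term2 = term2, L_prc = L_prc,
                             L_smth = L_smth, L_fld = fl$loss,
                             L_add = L_add), weights)

  if (!train) return(tot)

  # ---- backward ----
  gP1 <- -2 * weights$lambda1 / N * U
  gA <- -2 * weights$lambda2 / N * (U - Af) + weights$lambda6 * sign(Af)
  gtaps <- mapply(function(a, b) weights$lambda3 * 2 / (3 * length(a)) * (b - a),
                  taps_ref, taps_hat, SIMPLIFY = FALSE)
  gIhat <- comparator_bwd_input(comparator, gtaps[[1]], gtaps[[2]], gtaps[[3]])
  gW_I <- gP1 * W_R + gIhat * W_R
  gW_R <- gP1 * W_I + gIhat * (W_I + Af)
  gA <- gA + gIhat * W_R

  wb1 <- warp_bw_cpp(I_t, dm, Df, gW_I)
  wb2 <- warp_bw_cpp(R_t, dm, Df, gW_R)
  gD <- wb1$gdisp + wb2$gdisp +
    weights$lambda4 * smoothness_grad(Df) +
    weights$lambda5 * folding_grad(Df, fl)

  gFD <- array(0, dim(E_t$FD)); gFA <- array(0, dim(E_t$FA))
  if (disp$n_D >= MORPH_EPS) {
    dot <- sum(gD * Dhat)
    gDhat <- (sD / nhD) * gD - (sD * dot / nhD^3) * Dhat
    gsD <- dot / nhD
    sc$alpha1$acc_grad(gsD * disp$n_D)
    g_nD <- gsD * a1
    gxD <- model$decoder_d$bwd(gDhat)
    sc$gamma$acc_grad(sum(gxD * disp$u_D))
    guD <- gam * gxD
    mV <- max(disp$n_D, MORPH_EPS)
    gV <- (guD - disp$u_D * sum(guD * disp$u_D)) / mV + g_nD * disp$u_D
    gFD <- gV
  }
  if (disp$n_A >= MORPH_EPS) {
    gAf <- gA
    dotA <- sum(array(gAf, dm) * array(Ahat, dm))
    gAhat <- (sA / nhA) * gAf - (sA * dotA / nhA^3) * array(Ahat, dm)
    gsA <- dotA / nhA
    sc$alpha2$acc_grad(gsA * disp$n_A)
    g_nA <- gsA * a2
    gxA <- model$decoder_a$bwd(array(gAhat, c(1L, dm)))
    sc$gamma$acc_grad(sum(gxA * disp$u_A))
    guA <- gam * gxA
    mVA <- max(disp$n_A, MORPH_EPS)
    gVA <- (guA - disp$u_A * sum(guA * disp$u_A)) / mVA + g_nA * disp$u_A
    gFA <- gVA
  }

  # encoder: +g on the later visit, -g on the earlier one
  enc$bwd(gFD, gFA)              # caches currently belong to x_tk
  restore_cache(enc, cache_t)
  enc$bwd(-gFD, -gFA)
  tot
}

#' Pre-train the encoder with the morphing pretext task
#'
#' Samples eligible pairs (earlier visit first, interval bounded by
#' `max_pair_interval` months), applies shared augmentation, optimizes the
#' total self-supervision loss with Adam under a cyclic learning rate,
#' updates the EMA comparator each step and keeps the parameters with the
#' best validation loss.
#'
#' @param model A `morphssl_model` (see [make_architecture()]).
#' @param pairs List of training pairs (`I_t`, `I_tk`, `R_t`, `R_tk`).
#' @param config A [train_config()] (phase `"pretrain"`).
#' @param val_pairs Optional validation pairs (defaults to the first
#'   training pair).
#' @param weights [ssl_loss_weights()].
#' @param momentum EMA comparator momentum.
#' @return List: `model`, `comparator`, `history` (tibble of step losses),
#'   `val_loss` (best), `init_loss`.
#' @export
run_pretraining <- function(model, pairs, config = train_config("pretrain"),
                            val_pairs = NULL, weights = ssl_loss_weights(),
                            momentum = 0.99) {
  stopifnot(config$phase == "pretrain")
  if (is.null(val_pairs)) val_pairs <- pairs[1]
  comparator <- with_seed(config$seed + 1L,
                          comparator_init(model$encoder, momentum))
  opt <- adam_state(list(model$encoder, model$decoder_d, model$decoder_a,
                         model$scalars),
                    beta1 = config$beta1, beta2 = config$beta2,
                    weight_decay = config$weight_decay)
  val_loss <- function() mean(vapply(val_pairs, function(p)
    ssl_step(model, comparator, p, weights, train = FALSE)$loss, numeric(1)))
  init_loss <- val_loss()
  best <- init_loss
  best_params <- model_param_list(model)
  hist <- vector("list", config$epochs * config$steps_per_epoch)
  with_seed(config$seed, {
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      for (s in seq_len(config$steps_per_epoch)) {
        pair <- pairs[[sample.int(length(pairs), 1L)]]
        if (config$augment) pair <- augment_pair(pair)
        zero_grads(list(model$encoder, model$decoder_d, model$decoder_a,
                        model$scalars))
        out <- ssl_step(model, comparator, pair, weights, train = TRUE)
        lr <- cyclic_lr(step, config$steps_per_epoch, config$lr_min,
                        config$lr_max)
        opt <- adam_step(opt, lr = lr)
        ema_update_comparator(comparator, model$encoder)
        hist[[step + 1L]] <- tibble::tibble(step = step, epoch = ep,
                                            lr = lr, loss = out$loss)
        step <- step + 1L
      }
      v <- val_loss()
      if (v < best) {
        best <- v
        best_params <- model_param_list(model)
      }
    }
  })
  set_model_params(model, best_params)
  list(model = model, comparator = comparator,
       history = dplyr::bind_rows(hist), val_loss = best,
       init_loss = init_loss)
}

# --- TTC training ------------------------------------------------------------

roi_to_feature_grid <- function(roi, feature_shape) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  nearest_resize_3d(m, feature_shape)
}

# Binary ground truth "converted within t months" (NA = indeterminate).
label_within_horizon <- function(t_minus, t_plus, t) {
  if (is.finite(t_plus) && t_plus <= t) return(1L)
  if (!is.finite(t_plus) || t_minus >= t) return(0L)
  NA_integer_
}

# Forward + gradient for one scan through the classifier head.
ttc_step <- function(cls, feat, label, roi_small, gamma1 = 0.1,
                     gamma2 = 0.1, train = TRUE) {
  M <- cls$fwd(feat, train = train)
  roi_small <- array(roi_small, dim(M))
  S <- sum(M)
  m <- mean(M)
  a1 <- cls$alpha1$value(); a2 <- cls$alpha2$value()
  H <- spatial_entropy(M)
  b <- 1 / (a1 * m + TTC_EPS)
  a <- stats::plogis(a2 * H)
  cdf <- structure(list(a = a, b = b), class = "sigmoid_cdf")
  L_cls <- ttc_loss(cdf, label)
  tot <- ttc_total_loss(L_cls, a, M, roi_small, gamma1, gamma2)
  if (!train) return(c(tot, list(cdf = cdf)))
  g_ab <- ttc_loss_grad(cdf, label)
  ga <- g_ab[["a"]] + 2 * gamma1 * a
  gb <- g_ab[["b"]]
  den <- (a1 * m + TTC_EPS)^2
  gm <- gb * (-a1 / den)
  cls$alpha1$acc_grad(gb * (-m / den))
  gH <- ga * a * (1 - a) * a2
  cls$alpha2$acc_grad(ga * a * (1 - a) * H)
  p <- pmax(M / S, 1e-300)
  dH_dM <- -(log(p) + H) / S
  gM <- array(gm / length(M) + gH * dH_dM + gamma2 * (1 - roi_small), dim(M))
  gF <- cls$bwd(gM)
  c(tot, list(cdf = cdf, gF = gF))
}

#' Train the TTC classifier (frozen encoder or end-to-end)
#'
#' In the `ttc_freeze` phase only the classifier head receives gradient
#' updates (encoder features are precomputed once, so the encoder stays
#' bit-identical); `ttc_finetune` backpropagates into the encoder as well.
#' The checkpoint with the highest validation AUC averaged over the four
#' horizons (0, 6, 12, 18 months) is kept.
#'
#' @param model A `morphssl_model` (its encoder is used).
#' @param cohort A cohort from [make_ttc_cohort()] (visits + volumes +
#'   surfaces).
#' @param config A [train_config()] with a TTC phase.
#' @param classifier Optional warm-start [ttc_classifier()].
#' @param val_fraction Fraction of eyes held out for validation.
#' @return List: `classifier`, `model`, `history`, `val_auc` (best average),
#'   plus the per-scan feature cache.
#' @export
run_ttc_training <- function(model, cohort,
                             config = train_config("ttc_freeze"),
                             classifier = NULL, val_fraction = 0.25) {
  stopifnot(config$phase %in% c("ttc_freeze", "ttc_finetune"))
  finetune <- config$phase == "ttc_finetune"
  visits <- cohort$visits
  enc <- model$encoder
  fshape <- enc$config$input_shape %/% c(16L, 16L, 2L)
  labels <- cohort_labels(visits)
  roi_small <- lapply(visits$scan_id, function(sid) {
    s <- cohort$surfaces[[sid]]
    v <- cohort$volumes[[sid]]
    roi_to_feature_grid(build_roi_mask(s, v), fshape)
  })
  names(roi_small) <- visits$scan_id

  # precompute features (always needed for freeze; reused as cache keys)
  feats <- NULL
  if (!finetune) {
    feats <- lapply(visits$scan_id, function(sid)
      enc$fwd(array(cohort$volumes[[sid]]$voxels,
                    c(1L, dim(cohort$volumes[[sid]]$voxels))),
              train = FALSE)$F)
    names(feats) <- visits$scan_id
  }
  if (is.null(classifier))
    classifier <- with_seed(config$seed + 2L, ttc_classifier())

  eyes <- unique(visits$eye_id)
  n_val <- max(1L, round(val_fraction * length(eyes)))
  val_eyes <- with_seed(config$seed + 3L, sample(eyes, n_val))
  tr_idx <- which(!visits$eye_id %in% val_eyes)
  va_idx <- which(visits$eye_id %in% val_eyes)
  if (length(va_idx) == 0L) va_idx <- tr_idx

  scan_feat <- function(i, train = FALSE) {
    sid <- visits$scan_id[i]
    if (!finetune) return(feats[[sid]])
    enc$fwd(array(cohort$volumes[[sid]]$voxels,
                  c(1L, dim(cohort$volumes[[sid]]$voxels))),
            train = train)$F
  }

  predict_idx <- function(idx) {
    purrr::map_dfr(idx, function(i) {
      out <- ttc_step(classifier, scan_feat(i), labels[[i]],
                      roi_small[[visits$scan_id[i]]], train = FALSE)
      tibble::tibble(i = i, a = out$cdf$a, b = out$cdf$b)
    })
  }
  val_auc <- function() {
    pr <- predict_idx(va_idx)
    aucs <- vapply(c(0, 6, 12, 18), function(t_m) {
      y <- vapply(pr$i, function(i)
        label_within_horizon(visits$t_minus_months[i],
                             visits$t_plus_months[i], t_m), integer(1))
      p <- vapply(seq_len(nrow(pr)), function(j)
        cdf_eval(structure(list(a = pr$a[j], b = pr$b[j]),
                           class = "sigmoid_cdf"), t_m / 18), numeric(1))
      ok <- !is.na(y)
      if (length(unique(y[ok])) < 2L) return(NA_real_)
      auc_score(p[ok], y[ok])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }

  trainable <- if (finetune) list(classifier, enc) else list(classifier)
  opt <- adam_state(trainable, beta1 = config$beta1, beta2 = config$beta2,
                    weight_decay = config$weight_decay)
  best <- -Inf
  best_params <- model_param_list(trainable)
  hist <- list()
  with_seed(config$seed, {
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      for (s in seq_len(config$steps_per_epoch)) {
        batch <- sample(tr_idx, min(config$batch_size, length(tr_idx)))
        zero_grads(trainable)
        loss_acc <- 0
        for (i in batch) {
          out <- ttc_step(classifier, scan_feat(i, train = finetune),
                          labels[[i]], roi_small[[visits$scan_id[i]]],
                          train = TRUE)
          if (finetune) {
            gF <- out$gF
            enc$bwd(gF[1:64, , , , drop = FALSE],
                    gF[65:128, , , , drop = FALSE])
          }
          loss_acc <- loss_acc + out$loss
        }
        lr <- cyclic_lr(step, config$steps_per_epoch, config$lr_min,
                        config$lr_max)
        opt <- adam_step(opt, lr = lr)
        hist[[length(hist) + 1L]] <-
          tibble::tibble(step = step, epoch = ep, lr = lr,
                         loss = loss_acc / length(batch))
        step <- step + 1L
      }
      v <- val_auc()
      if (!is.na(v) && v > best) {
        best <- v
        best_params <- model_param_list(trainable)
      }
    }
  })
  set_model_params(trainable, best_params)
  list(classifier = classifier, model = model,
       history = dplyr::bind_rows(hist), val_auc = best)
}

#' Predict conversion risk for a set of scans
#'
#' @param model A `morphssl_model` (encoder).
#' @param classifier A trained [ttc_classifier()].
#' @param volumes Named list of [oct_volume()]s (standardized to the
#'   encoder input shape).
#' @param visits Optional tibble with `scan_id`, `eye_id`,
#'   `visit_time_months` to join onto the output.
#' @return Tibble: scan_id, eye_id, visit_time, `a`, `b`, risk `r`, and
#'   `p_0`, `p_6`, `p_12`, `p_18` (conversion probability within each
#'   horizon). Identical inputs give identical outputs.
#' @export
run_inference <- function(model, classifier, volumes, visits = NULL) {
  enc <- model$encoder
  rows <- purrr::map_dfr(names(volumes), function(sid) {
    v <- volumes[[sid]]
    f <- enc$fwd(array(v$voxels, c(1L, dim(v$voxels))), train = FALSE)$F
    M <- classifier$fwd(f, train = FALSE)
    cdf <- head_predict(M, classifier)
    ps <- vapply(c(0, 6, 12, 18) / 18, function(t) cdf_eval(cdf, t),
                 numeric(1))
    tibble::tibble(scan_id = sid, eye_id = v$eye_id,
                   visit_time_months = v$visit_time,
                   a = cdf$a, b = cdf$b, r = risk_score(cdf),
                   p_0 = ps[1], p_6 = ps[2], p_12 = ps[3], p_18 = ps[4])
  })
  if (!is.null(visits))
    rows <- dplyr::left_join(
      dplyr::select(rows, -dplyr::any_of(c("eye_id", "visit_time_months"))),
      dplyr::select(visits, dplyr::any_of(c("scan_id", "eye_id",
                                            "visit_time_months",
                                            "t_minus_months",
                                            "t_plus_months"))),
      by = "scan_id") |>
      dplyr::relocate(dplyr::any_of(c("scan_id", "eye_id",
                                      "visit_time_months")))
  rows
}
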