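# The longitudinal morphing pretext task: feature displacement, morph
# decoding with norm factorization, differentiable warping, the loss terms
# and the EMA comparator.
#
# A morph field carries a 3-channel displacement grid D (voxel units,
# channels = axial/lateral/inter-B-scan translation) and a 1-channel
# additive intensity grid A, both at image resolution. Decoding enforces
# ||D|| = alpha1 * ||V_D|| and ||A|| = alpha2 * ||V_A|| (Frobenius norms),
# so the feature-space distance controls the morph magnitude while the unit
# direction controls its nature.

MORPH_EPS <- 1e-8

#' Default pre-training loss weights
#'
#' lambda1/lambda2 weight the two reconstruction terms, lambda3 the
#' perceptual term, lambda4 the smoothness penalty, lambda5 the folding
#' penalty and lambda6 the additive-map sparsity.
#' @export
ssl_loss_weights <- function(lambda1 = 10, lambda2 = 100, lambda3 = 10,
                             lambda4 = 0.1, lambda5 = 1e6, lambda6 = 1e-5) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lambda4 = lambda4, lambda5 = lambda5, lambda6 = lambda6)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  w
}

fro_norm <- function(x) sqrt(sum(x^2))

#' Feature displacement between two visits
#'
#' @param f_t,f_tk `feature_map` objects from the encoder.
#' @return List with the displacement halves `V_D`, `V_A`, their Frobenius
#'   norms `n_D`, `n_A`, and epsilon-guarded unit directions `u_D`, `u_A`.
#' @export
feature_displacement <- function(f_t, f_tk) {
  if (!identical(dim(f_t$F), dim(f_tk$F)))
    stop("feature maps have mismatched shapes")
  V_D <- f_tk$FD - f_t$FD
  V_A <- f_tk$FA - f_t$FA
  n_D <- fro_norm(V_D)
  n_A <- fro_norm(V_A)
  list(V_D = V_D, V_A = V_A, n_D = n_D, n_A = n_A,
       u_D = V_D / max(n_D, MORPH_EPS),
       u_A = V_A / max(n_A, MORPH_EPS))
}

#' Decode the morph field from a feature pair
#'
#' Decoder-D receives only the direction information `gamma * V_D/||V_D||`;
#' its raw output is re-normalized so that `||D|| = alpha1 * ||V_D||`
#' (similarly for A). Identical features decode to the identity morph.
#'
#' @param f_t,f_tk `feature_map` objects.
#' @param model A `morphssl_model` (used for its decoders and scalars), or a
#'   list with `decoder_d`, `decoder_a`, `scalars`.
#' @return A `morph_field`: `D` (3,H,W,D) and `A` (H,W,D).
#' @export
decode_morph <- function(f_t, f_tk, model) {
  disp <- feature_displacement(f_t, f_tk)
  sc <- model$scalars
  a1 <- sc$alpha1$value(); a2 <- sc$alpha2$value(); g <- sc$gamma$value()
  sp <- model$decoder_d$config$input_shape
  if (disp$n_D < MORPH_EPS) {
    D <- array(0, c(3L, sp))
  } else {
    Dhat <- model$decoder_d$fwd(g * disp$u_D, train = FALSE)
    nh <- fro_norm(Dhat)
    if (nh < MORPH_EPS)
      stop("degenerate decoder output: ||D_hat|| below epsilon with a ",
           "non-zero target norm")
    D <- (a1 * disp$n_D / nh) * Dhat
  }
  if (disp$n_A < MORPH_EPS) {
    A <- array(0, sp)
  } else {
    Ahat <- model$decoder_a$fwd(g * disp$u_A, train = FALSE)
    nh <- fro_norm(Ahat)
    if (nh < MORPH_EPS)
      stop("degenerate decoder output: ||A_hat|| below epsilon with a ",
           "non-zero target norm")
    A <- array((a2 * disp$n_A / nh) * Ahat, sp)
  }
  morph_field(D, A)
}

#' Morph field container
#' @param D 3-channel displacement array (3,H,W,D), voxel units.
#' @param A Additive intensity array (H,W,D).
#' @export
morph_field <- function(D, A) {
  stopifnot(length(dim(D)) == 4L, dim(D)[1L] == 3L)
  A <- array(A, dim(D)[2:4])
  structure(list(D = D, A = A), class = "morph_field")
}

#' Differentiable spatial warp
#'
#' `out(p)` is the trilinear sample of the image at `p + D(p)`; samples that
#' fall outside the volume take `fill`.
#'
#' @param image An [oct_volume()] or (H,W,D) array.
#' @param D Displacement array (3,H,W,D) in voxel units.
#' @param fill Out-of-bounds fill value (default -1).
#' @return Warped array (or [oct_volume()] if one was supplied).
#' @export
warp_image <- function(image, D, fill = -1) {
  v <- if (inherits(image, "oct_volume")) image$voxels else image
  if (!all(is.finite(D))) stop("displacement field must be finite")
  if (!identical(as.integer(dim(D)[2:4]), as.integer(dim(v))))
    stop("displacement resolution does not match the image")
  out <- warp_fw_cpp(v, dim(v), D, fill)
  if (inherits(image, "oct_volume")) {
    image$voxels <- array(out, dim(v))
    image
  } else {
    array(out, dim(v))
  }
}

#' Apply a full morph (warp plus additive intensity)
#'
#' @inheritParams warp_image
#' @param field A [morph_field()].
#' @export
apply_morph <- function(image, field, fill = -1) {
  v <- if (inherits(image, "oct_volume")) image$voxels else image
  if (!identical(as.integer(dim(field$A)), as.integer(dim(v))))
    stop("morph field resolution does not match the image")
  out <- array(warp_fw_cpp(v, dim(v), field$D, fill), dim(v)) + field$A
  if (inherits(image, "oct_volume")) {
    image$voxels <- out
    image
  } else {
    out
  }
}

#' Two-step masked reconstruction loss
#'
#' Masks are applied first (`I_tk` by its ROI mask, the warped image by the
#' warped ROI mask). Term 1 penalizes the purely spatial reconstruction;
#' the residual `U` is then treated as the on-the-fly ground truth for the
#' additive map with gradient flow severed through it, so term 2 trains A
#' without letting A absorb the deformation.
#'
#' @param I_t,I_tk (H,W,D) arrays on the standardized scale.
#' @param R_t,R_tk Binary ROI arrays.
#' @param field A [morph_field()].
#' @param weights [ssl_loss_weights()].
#' @return List: `L_mse`, `term1`, `term2`, `U`, plus the masked warped
#'   image and warped mask for reuse.
#' @export
loss_reconstruction <- function(I_t, I_tk, R_t, R_tk, field,
                                weights = ssl_loss_weights()) {
  N <- length(I_t)
  W_I <- array(warp_fw_cpp(I_t, dim(I_t), field$D, -1), dim(I_t))
  W_R <- array(warp_fw_cpp(R_t, dim(R_t), field$D, 0), dim(R_t))
  M_tk <- I_tk * R_tk
  P1 <- W_I * W_R
  U <- M_tk - P1                  # gradient flow is severed through U
  term1 <- weights$lambda1 / N * sum((M_tk - P1)^2)
  term2 <- weights$lambda2 / N * sum((U - field$A)^2)
  list(L_mse = term1 + term2, term1 = term1, term2 = term2, U = U,
       warped = W_I, warped_mask = W_R, masked_target = M_tk)
}

#' Perceptual loss through the EMA comparator
#'
#' Mean over the comparator's three tap layers of the per-element MSE
#' between the feature maps of the (masked) target and reconstruction.
#'
#' @param I_tk_masked,I_hat_masked (H,W,D) arrays, already masked.
#' @param comparator A comparator state from [comparator_init()].
#' @return Scalar loss.
#' @export
loss_perceptual <- function(I_tk_masked, I_hat_masked, comparator) {
  t_ref <- comparator_fwd(comparator, I_tk_masked, train = FALSE)
  t_hat <- comparator_fwd(comparator, I_hat_masked, train = FALSE)
  terms <- mapply(function(a, b) mean((a - b)^2), t_ref, t_hat)
  mean(terms)
}

#' Deformation regularizers
#'
#' `L_smth` is the summed squared forward-difference gradient of D;
#' `L_fld` penalizes folding through the hinge on the negative Jacobian
#' determinant of `phi(p) = p + D(p)` (central differences, interior
#' voxels); `L_add` is the L1 norm of A.
#'
#' @param field A [morph_field()].
#' @return List `L_smth`, `L_fld`, `L_add`.
#' @export
loss_regularizers <- function(field) {
  list(L_smth = smoothness_loss(field$D),
       L_fld = folding_loss(field$D)$loss,
       L_add = sum(abs(field$A)))
}

smoothness_loss <- function(D) {
  l <- 0
  for (ax in 2:4) {
    n <- dim(D)[ax]
    if (n < 2) next
    d <- axis_slice(D, ax, 2:n) - axis_slice(D, ax, 1:(n - 1))
    l <- l + sum(d^2)
  }
  l
}

axis_slice <- function(x, ax, idx) {
  switch(ax - 1L,
         x[, idx, , , drop = FALSE],
         x[, , idx, , drop = FALSE],
         x[, , , idx, drop = FALSE])
}

# Jacobian determinant of p + D(p) on interior voxels (central differences).
# Returns the hinge loss and everything needed for its gradient.
folding_loss <- function(D) {
  dm <- dim(D)[2:4]
  if (any(dm < 3)) return(list(loss = 0, det = NULL))
  ih <- 2:(dm[1] - 1); iw <- 2:(dm[2] - 1); id <- 2:(dm[3] - 1)
  g <- list()
  for (ci in 1:3) {
    Dc <- array(D[ci, , , ], dm)
    g[[ci]] <- list(
      h = (Dc[ih + 1, iw, id] - Dc[ih - 1, iw, id]) / 2,
      w = (Dc[ih, iw + 1, id] - Dc[ih, iw - 1, id]) / 2,
      d = (Dc[ih, iw, id + 1] - Dc[ih, iw, id - 1]) / 2)
  }
  J11 <- 1 + g[[1]]$h; J12 <- g[[1]]$w; J13 <- g[[1]]$d
  J21 <- g[[2]]$h; J22 <- 1 + g[[2]]$w; J23 <- g[[2]]$d
  J31 <- g[[3]]$h; J32 <- g[[3]]$w; J33 <- 1 + g[[3]]$d
  det <- J11 * (J22 * J33 - J23 * J32) -
         J12 * (J21 * J33 - J23 * J31) +
         J13 * (J21 * J32 - J22 * J31)
  list(loss = sum(pmax(0, -det)), det = det,
       J = list(J11 = J11, J12 = J12, J13 = J13, J21 = J21, J22 = J22,
                J23 = J23, J31 = J31, J32 = J32, J33 = J33),
       interior = list(ih = ih, iw = iw, id = id))
}

#' Total self-supervision loss
#'
#' @param terms Named list with `L_mse` (or `term1`/`term2`), `L_prc`,
#'   `L_smth`, `L_fld`, `L_add`.
#' @param weights [ssl_loss_weights()].
#' @return List: `loss` and per-term `breakdown`.
#' @export
total_ssl_loss <- function(terms, weights = ssl_loss_weights()) {
  L_mse <- terms$L_mse %||% (terms$term1 + terms$term2)
  breakdown <- list(
    L_mse = L_mse,
    L_prc = weights$lambda3 * terms$L_prc,
    L_smth = weights$lambda4 * terms$L_smth,
    L_fld = weights$lambda5 * terms$L_fld,
    L_add = weights$lambda6 * terms$L_add)
  list(loss = sum(unlist(breakdown)), breakdown = breakdown)
}

# --- EMA comparator ----------------------------------------------------------

#' Initialize the EMA comparator
#'
#' The comparator mirrors the first three S3DConv layers of the encoder
#' (the stem and the two convolutions of the first Basic Encoder Block,
#' before any downsampling). It starts from its own random initialization
#' and is pulled toward the encoder as an exponential moving average of the
#' past encoder weights; it is never updated by gradients, so its feature
#' maps sharpen gradually as training proceeds.
#'
#' @param encoder A `morphssl_encoder`.
#' @param momentum EMA momentum `m` in (0,1); default 0.99.
#' @return A `comparator_state`.
#' @export
comparator_init <- function(encoder, momentum = 0.99) {
  cfg <- encoder$config
  st <- new_layer("comparator")
  st$stem <- clone_layer(encoder$stem)
  b <- encoder$blocks[[1L]]
  st$na1 <- clone_layer(b$na1); st$conv1 <- clone_layer(b$conv1)
  st$na2 <- clone_layer(b$na2); st$conv2 <- clone_layer(b$conv2)
  st$momentum <- momentum
  st$layers <- list(st$stem, st$na1, st$conv1, st$na2, st$conv2)
  class(st) <- c("comparator_state", class(st))
  st
}

# Structural clone: same architecture, fresh (random) weights unless
# copy_params is set.
clone_layer <- function(l, copy_params = FALSE) {
  n <- if (inherits(l, "morphssl_s3dconv")) {
    nn_s3dconv(l$cin, l$cout, bias = !is.null(l$convs[[1]]$params$b))
  } else if (inherits(l, "morphssl_conv3d")) {
    nn_conv3d(l$cin, l$cout, l$kern, l$stride, l$pad, l$groups, l$bias)
  } else if (inherits(l, "morphssl_norm_act")) {
    nn_norm_act(l$C, l$norm, l$eps)
  } else stop("cannot clone layer of type ", l$type)
  if (copy_params) {
    tl <- collect_layers(n); sl <- collect_layers(l)
    for (i in seq_along(tl)) tl[[i]]$params <- sl[[i]]$params
  }
  n
}

comparator_fwd <- function(st, image, train = FALSE) {
  x <- array(image, c(1L, dim(image)))
  t1 <- st$stem$fwd(x, train)
  t2 <- st$conv1$fwd(st$na1$fwd(t1, train), train)
  t3 <- st$conv2$fwd(st$na2$fwd(t2, train), train)
  list(t1 = t1, t2 = t2, t3 = t3)
}

# Backpropagate tap gradients to the comparator *input* (the comparator's
# own weight gradients are discarded: it is frozen).
comparator_bwd_input <- function(st, g1, g2, g3) {
  gy2 <- st$na2$bwd(st$conv2$bwd(g3))
  gy1 <- st$na1$bwd(st$conv1$bwd(g2 + gy2))
  gx <- st$stem$bwd(g1 + gy1)
  zero_grads(st)
  array(gx, dim(gx)[2:4])
}

#' EMA update of the comparator from the encoder
#'
#' `w_psi <- m * w_psi + (1 - m) * w_enc`, elementwise, for the mirrored
#' layers. `m = 1` leaves the comparator unchanged; `m = 0` copies the
#' encoder.
#'
#' @param state A `comparator_state`.
#' @param encoder The current encoder.
#' @return The updated state (invisibly; updated in place).
#' @export
ema_update_comparator <- function(state, encoder) {
  m <- state$momentum
  b <- encoder$blocks[[1L]]
  pairs <- list(list(state$stem, encoder$stem),
                list(state$na1, b$na1), list(state$conv1, b$conv1),
                list(state$na2, b$na2), list(state$conv2, b$conv2))
  for (p in pairs) {
    tl <- collect_layers(p[[1]])
    sl <- collect_layers(p[[2]])
    for (i in seq_along(tl)) {
      for (nm in names(tl[[i]]$params))
        tl[[i]]$params[[nm]] <-
          m * tl[[i]]$params[[nm]] + (1 - m) * sl[[i]]$params[[nm]]
    }
  }
  invisible(state)
}

# --- feature interpolation ---------------------------------------------------

#' Linear interpolation in feature space
#'
#' @param f_t,f_tk `feature_map` objects.
#' @param rho Interpolation weight in [0, 1].
#' @return A `feature_map` at `F_t + rho * (F_tk - F_t)`.
#' @export
interpolate_features <- function(f_t, f_tk, rho) {
  stopifnot(rho >= 0, rho <= 1)
  mix <- function(a, b) a + rho * (b - a)
  structure(list(F = mix(f_t$F, f_tk$F), FD = mix(f_t$FD, f_tk$FD),
                 FA = mix(f_t$FA, f_tk$FA)),
            class = "feature_map")
}

#' Generate an intermediate scan by feature interpolation
#'
#' Decodes the morph from `F_t` toward the interpolated feature and applies
#' it to the source scan; `rho = 0` returns the source unchanged and the
#' morph magnitude grows linearly with `rho`.
#'
#' @param I_t Source volume ([oct_volume()] or array).
#' @param f_t Features of the source scan.
#' @param f_rho Interpolated features (see [interpolate_features()]).
#' @param model A `morphssl_model`.
#' @return The generated volume (same type as `I_t`).
#' @export
generate_intermediate_scan <- function(I_t, f_t, f_rho, model) {
  field <- decode_morph(f_t, f_rho, model)
  apply_morph(I_t, field)
}
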