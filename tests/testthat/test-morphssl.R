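# Feature displacement, morph decoding, warping and the loss terms.

test_that("feature displacement: zero, unit-entry and Pythagorean cases", {
  f1 <- random_feature_map(seed = 1)
  d0 <- feature_displacement(f1, f1)
  expect_equal(d0$n_D, 0)
  expect_equal(d0$n_A, 0)
  expect_true(all(d0$u_D == 0))           # epsilon-guarded zero direction

  f2 <- f1
  f2$FD[3, 1, 2, 1] <- f2$FD[3, 1, 2, 1] + 2.5
  f2$F <- channel_cat(list(f2$FD, f2$FA))
  d1 <- feature_displacement(f1, f2)
  expect_equal(d1$n_D, 2.5)
  expect_equal(d1$n_A, 0)

  f3 <- random_feature_map(seed = 2)
  d2 <- feature_displacement(f1, f3)
  full_norm <- sqrt(sum((f3$F - f1$F)^2))
  expect_equal(d2$n_D^2 + d2$n_A^2, full_norm^2, tolerance = 1e-10)
})

test_that("decode_morph enforces the norm factorization", {
  model <- tiny_model()
  f1 <- random_feature_map(seed = 3)
  # identical features -> identity morph
  fld0 <- decode_morph(f1, f1, model)
  expect_true(all(fld0$D == 0))
  expect_true(all(fld0$A == 0))

  # ||D|| = alpha1 * ||V_D|| by construction
  f2 <- random_feature_map(seed = 4)
  a1 <- model$scalars$alpha1$value()
  disp <- feature_displacement(f1, f2)
  fld <- decode_morph(f1, f2, model)
  expect_equal(fro_norm(fld$D), a1 * disp$n_D, tolerance = 1e-5 * disp$n_D)
  expect_equal(fro_norm(fld$A), model$scalars$alpha2$value() * disp$n_A,
               tolerance = 1e-5 * disp$n_A)

  # doubling ||V_D|| with fixed direction doubles ||D||, same direction
  f3 <- f1
  f3$FD <- f1$FD + 2 * (f2$FD - f1$FD)
  f3$FA <- f2$FA
  f3$F <- channel_cat(list(f3$FD, f3$FA))
  fld2 <- decode_morph(f1, f3, model)
  expect_equal(fro_norm(fld2$D), 2 * fro_norm(fld$D), tolerance = 1e-8)
  cosang <- sum(fld$D * fld2$D) / (fro_norm(fld$D) * fro_norm(fld2$D))
  expect_equal(cosang, 1, tolerance = 1e-10)
})

test_that("warp matches identity, index-shift and linear-ramp oracles", {
  set.seed(21)
  v <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  D0 <- array(0, c(3, 8, 8, 2))
  expect_lt(max(abs(warp_image(v, D0) - v)), 1e-6)

  # constant +1 lateral shift: out(p) = v at p + 1 -> index-shift oracle
  D1 <- D0; D1[2, , , ] <- 1
  w1 <- warp_image(v, D1, fill = -1)
  oracle <- array(-1, dim(v))
  oracle[, 1:7, ] <- v[, 2:8, ]
  expect_equal(w1, oracle)

  # half-voxel shift on a ramp image is exact under trilinear sampling
  ramp <- array(rep(seq_len(8), each = 1), c(8, 8, 2))
  for (w in 1:8) ramp[, w, ] <- w
  Dh <- D0; Dh[2, , , ] <- 0.5
  wh <- warp_image(ramp, Dh)
  expect_equal(wh[, 1:7, ], ramp[, 1:7, ] + 0.5, tolerance = 1e-12)

  expect_error(warp_image(v, D0 + NaN), "finite")
})

test_that("apply_morph composes warp and intensity addition", {
  set.seed(22)
  v <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  dmn <- c(3, 6, 6, 2)
  expect_equal(apply_morph(v, morph_field(array(0, dmn), array(0, c(6, 6, 2)))), v)
  expect_equal(apply_morph(v, morph_field(array(0, dmn), array(0.3, c(6, 6, 2)))),
               v + 0.3)
  D <- array(rnorm(prod(dmn), sd = 0.2), dmn)
  A <- array(rnorm(6 * 6 * 2, sd = 0.1), c(6, 6, 2))
  expect_equal(apply_morph(v, morph_field(D, A)),
               warp_image(v, D) + A, tolerance = 1e-12)
})

test_that("reconstruction loss: zero case, constant residual, hand arithmetic", {
  w <- ssl_loss_weights()
  v <- array(runif(4 * 4 * 2), c(4, 4, 2))
  ones <- array(1, dim(v))
  id <- morph_field(array(0, c(3, 4, 4, 2)), array(0, dim(v)))
  out <- loss_reconstruction(v, v, ones, ones, id, w)
  expect_equal(out$L_mse, 0)

  # residual exactly c and A = c -> term2 = 0
  outc <- loss_reconstruction(v, v + 0.25, ones, ones,
                              morph_field(array(0, c(3, 4, 4, 2)),
                                          array(0.25, dim(v))), w)
  expect_equal(outc$term2, 0, tolerance = 1e-20)
  expect_equal(outc$term1, w$lambda1 / length(v) * sum(0.25^2 * ones))

  # printed 2x2x1 hand computation
  I_t <- array(c(0.1, 0.2, 0.3, 0.4), c(2, 2, 1))
  I_tk <- array(c(0.3, 0.1, 0.2, 0.5), c(2, 2, 1))
  A <- array(c(0.05, -0.05, 0, 0.1), c(2, 2, 1))
  m1 <- array(1, c(2, 2, 1))
  fld <- morph_field(array(0, c(3, 2, 2, 1)), A)
  res <- loss_reconstruction(I_t, I_tk, m1, m1, fld, w)
  U <- I_tk - I_t
  expect_equal(res$term1, w$lambda1 / 4 * sum(U^2), tolerance = 1e-6)
  expect_equal(res$term2, w$lambda2 / 4 * sum((U - A)^2), tolerance = 1e-6)
})

test_that("perceptual loss vanishes for identical inputs or zero comparator", {
  enc <- tiny_model()$encoder
  comp <- comparator_init(enc)
  set.seed(23)
  v1 <- array(rnorm(48 * 48 * 8, sd = 0.3), c(48, 48, 8))
  v2 <- array(rnorm(48 * 48 * 8, sd = 0.3), c(48, 48, 8))
  expect_equal(loss_perceptual(v1, v1, comp), 0)
  expect_gt(loss_perceptual(v1, v2, comp), 0)
  # zero comparator weights -> zero features -> zero loss
  for (l in collect_layers(comp))
    l$params <- lapply(l$params, function(p) p * 0)
  expect_equal(loss_perceptual(v1, v2, comp), 0)
})

test_that("perceptual loss matches an independent forward-pass oracle", {
  enc <- tiny_model()$encoder
  comp <- comparator_init(enc)
  set.seed(24)
  v1 <- array(rnorm(48 * 48 * 8, sd = 0.2), c(48, 48, 8))
  v2 <- v1 + array(rnorm(48 * 48 * 8, sd = 0.05), c(48, 48, 8))
  got <- loss_perceptual(v1, v2, comp)
  t1 <- comparator_fwd(comp, v1)
  t2 <- comparator_fwd(comp, v2)
  want <- mean(c(mean((t1$t1 - t2$t1)^2), mean((t1$t2 - t2$t2)^2),
                 mean((t1$t3 - t2$t3)^2)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("regularizers: analytic zeros, L1 arithmetic, reflection folding", {
  dmn <- c(3, 6, 6, 4)
  # constant displacement: smooth = 0, det J = 1 -> fld = 0
  Dc <- array(0.7, dmn)
  r <- loss_regularizers(morph_field(Dc, array(0, dmn[2:4])))
  expect_equal(r$L_smth, 0)
  expect_equal(r$L_fld, 0)
  # A with k entries of 0.5 -> L_add = 0.5 k
  A <- array(0, dmn[2:4]); A[c(1, 5, 9, 20)] <- 0.5
  r2 <- loss_regularizers(morph_field(array(0, dmn), A))
  expect_equal(r2$L_add, 2)
  # reflection D(p) = -2p along axial axis: det J = -1 on the interior
  Dr <- array(0, dmn)
  for (h in 1:6) Dr[1, h, , ] <- -2 * (h - 1)
  r3 <- loss_regularizers(morph_field(Dr, array(0, dmn[2:4])))
  expect_equal(r3$L_fld, 4 * 4 * 2)  # interior voxel count
})

test_that("folding penalty is zero for any positive-determinant field", {
  set.seed(25)
  for (k in 1:5) {
    # small smooth random fields keep |grad D| < 1 => positive determinant
    D <- array(0, c(3, 8, 8, 6))
    base <- 0.2 * sin(outer(1:8, 1:8) / 8)
    for (c_ in 1:3)
      D[c_, , , ] <- array(rep(base, 6), c(8, 8, 6)) * runif(1)
    fl <- folding_loss(D)
    expect_true(all(fl$det > 0))
    expect_equal(fl$loss, 0)
  }
})

test_that("total loss is the advertised weighted sum", {
  w <- ssl_loss_weights()
  unit <- list(term1 = 0.5, term2 = 0.5, L_prc = 1, L_smth = 1, L_fld = 1,
               L_add = 1)
  tot <- total_ssl_loss(unit, w)
  expect_equal(tot$loss, 1 + 10 + 0.1 + 1e6 + 1e-5)
  zero <- list(term1 = 0, term2 = 0, L_prc = 0, L_smth = 0, L_fld = 0,
               L_add = 0)
  expect_equal(total_ssl_loss(zero, w)$loss, 0)
})

test_that("EMA comparator update follows the recurrence", {
  enc <- tiny_model()$encoder
  ref <- function(comp) comp$conv1$convs[[1]]$params$w[1, 1]
  enc_w <- enc$blocks[[1]]$conv1$convs[[1]]$params$w[1, 1]
  # m = 1: unchanged
  c1 <- comparator_init(enc, momentum = 1)
  w0 <- ref(c1)
  ema_update_comparator(c1, enc)
  expect_equal(ref(c1), w0)
  # m = 0: copies the encoder
  c2 <- comparator_init(enc, momentum = 0)
  ema_update_comparator(c2, enc)
  expect_equal(ref(c2), enc_w)
  # two updates with m = 0.5 from 0 toward a constant-1 encoder: 0.75
  c3 <- comparator_init(enc, momentum = 0.5)
  for (l in collect_layers(c3)) l$params <- lapply(l$params, function(p) p * 0)
  enc1 <- tiny_model()$encoder
  for (l in collect_layers(enc1)) l$params <- lapply(l$params, function(p) p * 0 + 1)
  ema_update_comparator(c3, enc1)
  ema_update_comparator(c3, enc1)
  expect_equal(ref(c3), 0.75)
})

test_that("feature interpolation is exactly linear", {
  f1 <- random_feature_map(seed = 5)
  f2 <- random_feature_map(seed = 6)
  expect_equal(interpolate_features(f1, f2, 0)$F, f1$F)
  expect_equal(interpolate_features(f1, f2, 1)$F, f2$F)
  mid <- interpolate_features(f1, f2, 0.5)
  expect_equal(fro_norm(mid$F - f1$F), fro_norm(f2$F - f1$F) / 2)
  # norms grow linearly with rho, direction constant
  base <- f2$F - f1$F
  for (rho in c(0.2, 0.4, 0.8)) {
    d <- interpolate_features(f1, f2, rho)$F - f1$F
    expect_equal(fro_norm(d), rho * fro_norm(base), tolerance = 1e-10)
    expect_equal(sum(d * base) / (fro_norm(d) * fro_norm(base)), 1,
                 tolerance = 1e-10)
  }
})

test_that("gradient flow is severed through the additive-map target U", {
  # with only term2 active (lambda1 = 0 and all other terms off), the
  # displacement decoder must receive exactly zero gradient even though the
  # VALUE of term2 depends on D through the on-the-fly target U
  model <- tiny_model(seed = 77)
  comp <- comparator_init(model$encoder)
  pair <- make_longitudinal_pair(tiny_synth_config(seed = 9), magnitude = 1)
  w <- ssl_loss_weights(lambda1 = 0, lambda2 = 100, lambda3 = 0,
                        lambda4 = 0, lambda5 = 0, lambda6 = 0)
  zero_grads(list(model$encoder, model$decoder_d, model$decoder_a,
                  model$scalars))
  out <- ssl_step(model, comp, pair, weights = w, train = TRUE)
  grad_max <- function(m) {
    max(vapply(collect_layers(m), function(l) {
      v <- unlist(l$grads)
      if (is.null(v)) 0 else max(abs(v))
    }, numeric(1)))
  }
  gmax_d <- grad_max(model$decoder_d)
  expect_equal(gmax_d, 0)
  expect_equal(model$scalars$alpha1$grads$log_v, 0)
  # while the additive decoder does receive gradient
  gmax_a <- grad_max(model$decoder_a)
  expect_gt(gmax_a, 0)
  # and perturbing A never changes term 1
  v <- pair$I_t$voxels
  fld <- morph_field(array(0, c(3, dim(v))), array(0, dim(v)))
  fld2 <- morph_field(array(0, c(3, dim(v))), array(0.3, dim(v)))
  r1 <- loss_reconstruction(v, pair$I_tk$voxels, pair$R_t$mask,
                            pair$R_tk$mask, fld)
  r2 <- loss_reconstruction(v, pair$I_tk$voxels, pair$R_t$mask,
                            pair$R_tk$mask, fld2)
  expect_equal(r1$term1, r2$term1)
})

test_that("morph identity holds end to end on identical features", {
  model <- tiny_model()
  pair <- make_longitudinal_pair(tiny_synth_config(seed = 31), magnitude = 0)
  f <- encoder_forward(pair$I_t, model)
  fld <- decode_morph(f, f, model)
  out <- apply_morph(pair$I_t$voxels, fld)
  expect_lt(max(abs(out - pair$I_t$voxels)), 1e-5)
})

test_that("intermediate scans scale linearly in rho and are finite", {
  model <- tiny_model()
  pair <- make_longitudinal_pair(tiny_synth_config(seed = 32), magnitude = 1)
  f_t <- encoder_forward(pair$I_t, model)
  f_tk <- encoder_forward(pair$I_tk, model)
  # rho = 0 returns the source
  g0 <- generate_intermediate_scan(pair$I_t$voxels, f_t,
                                   interpolate_features(f_t, f_tk, 0), model)
  expect_lt(max(abs(g0 - pair$I_t$voxels)), 1e-5)
  # decoded morph magnitude proportional to rho
  norms <- vapply(c(0.25, 0.5, 1), function(rho) {
    fld <- decode_morph(f_t, interpolate_features(f_t, f_tk, rho), model)
    fro_norm(fld$D)
  }, numeric(1))
  expect_equal(norms[1] / norms[3], 0.25, tolerance = 1e-6)
  expect_equal(norms[2] / norms[3], 0.5, tolerance = 1e-6)
  g <- generate_intermediate_scan(pair$I_t$voxels, f_t,
                                  interpolate_features(f_t, f_tk, 0.5), model)
  expect_true(all(is.finite(g)))
  expect_equal(dim(g), dim(pair$I_t$voxels))
})
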