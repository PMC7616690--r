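# The S3DConv encoder, the twin morph decoders, and the ablation variants.
#
# Encoder: five Basic Encoder Blocks interleaved with four strided
# depthwise downsampling layers. A Basic Encoder Block applies two
# pre-activated S3DConv layers and concatenates their outputs (the skip
# connection routes the first convolution's output past the second), so a
# block running at width w emits 2*w channels. Downsampling strides are
# (2,2,1) after blocks 1-3 and (2,2,2) after block 4, reflecting the large
# inter-B-scan voxel spacing. The final block is followed by two parallel
# pairs of 1x1x1 convolutions producing the 64-channel F^D and F^A halves
# of the feature map.

#' Architecture configuration
#'
#' Builds the configuration object for the volumetric encoder/decoder
#' networks. The default channel widths were solved (see
#' `scripts/derive_channels.R`) so that the default pre-training assembly
#' reproduces the published trainable-parameter totals.
#'
#' @param variant One of `"s3dconv"` (default), `"full3d"` (every S3DConv
#'   replaced by a dense 3x3x3 convolution), `"additive_skip"`
#'   (residual additions instead of concatenations, with doubled filter
#'   counts inside the blocks), `"batchnorm"` (per-channel normalization
#'   statistics instead of whole-tensor ones).
#' @param input_shape Integer vector (H, W, D); must be divisible by the
#'   cumulative strides (16, 16, 2).
#' @param stem_channels Width of the stem S3DConv that lifts the
#'   single-channel volume into feature space.
#' @param stage_channels Widths of the five Basic Encoder Blocks (each
#'   divisible by 4: the S3DConv splits its filters as C/2 + C/4 + C/4).
#' @param head_hidden Hidden width of the two parallel 1x1x1 head pathways.
#' @param norm `"layer"` or `"batch"`.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(variant = c("s3dconv", "full3d", "additive_skip",
                                    "batchnorm"),
                        input_shape = c(192L, 192L, 32L),
                        stem_channels = NULL,
                        stage_channels = NULL,
                        head_hidden = NULL,
                        norm = NULL) {
  variant <- match.arg(variant)
  def <- morphssl_default_widths()
  if (is.null(stem_channels)) stem_channels <- def$stem
  if (is.null(stage_channels)) stage_channels <- def$stages
  if (is.null(head_hidden)) head_hidden <- def$head_hidden
  if (is.null(norm)) norm <- if (variant == "batchnorm") "batch" else "layer"
  stopifnot(length(stage_channels) == 5, all(stage_channels > 0))
  if (any(stage_channels %% 4 != 0))
    stop("stage_channels must be divisible by 4 (S3DConv filter split)")
  if (stem_channels %% 4 != 0)
    stop("stem_channels must be divisible by 4")
  input_shape <- as.integer(input_shape)
  if (any(input_shape %% c(16L, 16L, 2L) != 0))
    stop("input_shape must be divisible by the cumulative strides (16,16,2)")
  structure(list(variant = variant, input_shape = input_shape,
                 stem_channels = as.integer(stem_channels),
                 stage_channels = as.integer(stage_channels),
                 head_hidden = as.integer(head_hidden), norm = norm),
            class = "arch_config")
}

# Default widths; solved against the published parameter totals by
# scripts/derive_channels.R.
morphssl_default_widths <- function() {
  list(stem = 32L, stages = c(36L, 56L, 64L, 100L, 324L), head_hidden = 525L)
}

# A Basic Encoder Block at width w with input channels u.
make_enc_block <- function(u, w, variant, norm) {
  b <- new_layer("enc_block")
  dense <- variant == "full3d"
  additive <- variant == "additive_skip"
  wv <- if (additive) 2L * w else w
  conv_make <- function(cin, cout) {
    if (dense) nn_conv3d(cin, cout, c(3L, 3L, 3L), bias = FALSE)
    else nn_s3dconv(cin, cout, bias = TRUE)
  }
  b$na1 <- nn_norm_act(u, norm)
  b$conv1 <- conv_make(u, wv)
  b$na2 <- nn_norm_act(wv, norm)
  b$conv2 <- conv_make(wv, wv)
  b$additive <- additive
  if (additive && u != 2L * w)
    b$proj <- nn_conv3d(u, 2L * w, c(1L, 1L, 1L), bias = FALSE)
  b$out_channels <- 2L * w
  b$layers <- Filter(Negate(is.null),
                     list(b$na1, b$conv1, b$na2, b$conv2, b$proj))
  b$fwd <- function(x, train = FALSE) {
    y1 <- b$conv1$fwd(b$na1$fwd(x, train), train)
    y2 <- b$conv2$fwd(b$na2$fwd(y1, train), train)
    if (b$additive) {
      sk <- if (is.null(b$proj)) x else b$proj$fwd(x, train)
      sk + y2
    } else {
      channel_cat(list(y1, y2))
    }
  }
  b$bwd <- function(gy) {
    if (b$additive) {
      g1 <- b$na2$bwd(b$conv2$bwd(gy))
      gx <- b$na1$bwd(b$conv1$bwd(g1))
      gx + if (is.null(b$proj)) gy else b$proj$bwd(gy)
    } else {
      w1 <- b$out_channels %/% 2L
      parts <- channel_split(gy, c(w1, w1))
      g2 <- b$na2$bwd(b$conv2$bwd(parts[[2L]]))
      b$na1$bwd(b$conv1$bwd(parts[[1L]] + g2))
    }
  }
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strided depthwise downsampling (3x3x3, one filter per channel).
make_downsample <- function(C, stride, norm) {
  d <- new_layer("downsample")
  d$na <- nn_norm_act(C, norm)
  d$conv <- nn_conv3d(C, C, c(3L, 3L, 3L), stride = stride, groups = C,
                      bias = TRUE)
  d$layers <- list(d$na, d$conv)
  d$fwd <- function(x, train = FALSE) d$conv$fwd(d$na$fwd(x, train), train)
  d$bwd <- function(gy) d$na$bwd(d$conv$bwd(gy))
  d
}

# One 1x1x1 head pathway (v5 -> hidden -> 64) with ELU in between.
make_head_path <- function(cin, hidden) {
  nn_seq(nn_conv3d(cin, hidden, c(1L, 1L, 1L), bias = TRUE),
         nn_elu(),
         nn_conv3d(hidden, 64L, c(1L, 1L, 1L), bias = TRUE))
}

#' Build the volumetric encoder
#'
#' @param config An [arch_config()].
#' @return Encoder object (class `morphssl_encoder`).
#' @export
make_encoder <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  e <- new_layer("encoder")
  e$config <- config
  norm <- config$norm
  cs <- config$stem_channels
  # The stem that lifts the 1-channel volume into feature space stays a
  # separable convolution in every variant; the dense-3x3x3 substitution
  # applies to the S3DConv layers inside the basic blocks.
  e$stem <- nn_s3dconv(1L, cs, bias = TRUE)
  ws <- config$stage_channels
  us <- c(cs, 2L * ws[1:4])
  e$blocks <- lapply(1:5, function(i)
    make_enc_block(us[i], ws[i], config$variant, norm))
  strides <- list(c(2L, 2L, 1L), c(2L, 2L, 1L), c(2L, 2L, 1L), c(2L, 2L, 2L))
  e$downs <- lapply(1:4, function(i)
    make_downsample(2L * ws[i], strides[[i]], norm))
  v5 <- 2L * ws[5]
  e$head_d <- make_head_path(v5, config$head_hidden)
  e$head_a <- make_head_path(v5, config$head_hidden)
  e$layers <- c(list(e$stem), e$blocks, e$downs, list(e$head_d, e$head_a))
  e$n_tap_layers <- 3L  # stem + the two convolutions of block 1
  e$fwd <- function(x, train = FALSE, taps = FALSE) {
    big <- prod(dim(x)) > 4e6  # full-scale inputs: trim temporaries eagerly
    tap_list <- list()
    h <- e$stem$fwd(x, train)
    if (taps) tap_list$stem <- h
    for (i in 1:5) {
      b <- e$blocks[[i]]
      if (taps && i == 1L) {
        y1 <- b$conv1$fwd(b$na1$fwd(h, train), train)
        y2 <- b$conv2$fwd(b$na2$fwd(y1, train), train)
        tap_list$y1 <- y1
        tap_list$y2 <- y2
        h <- if (b$additive) {
          sk <- if (is.null(b$proj)) h else b$proj$fwd(h, train)
          sk + y2
        } else channel_cat(list(y1, y2))
      } else {
        h <- b$fwd(h, train)
      }
      if (i < 5L) h <- e$downs[[i]]$fwd(h, train)
      if (big) gc(verbose = FALSE)
    }
    fd <- e$head_d$fwd(h, train)
    fa <- e$head_a$fwd(h, train)
    out <- list(F = channel_cat(list(fd, fa)), FD = fd, FA = fa)
    if (taps) out$taps <- tap_list
    out
  }
  e$bwd <- function(g_fd, g_fa) {
    gh <- e$head_d$bwd(g_fd) + e$head_a$bwd(g_fa)
    for (i in 5:1) {
      if (i < 5L) gh <- e$downs[[i]]$bwd(gh)
      gh <- e$blocks[[i]]$bwd(gh)
    }
    e$stem$bwd(gh)
  }
  e
}

# A Basic Decoder Block: trilinear upsampling, grouped 3x3x3 compression
# (groups of 4 channels -> 1), then a pre-activated S3DConv; the upsampled
# compression and the S3DConv output are concatenated (C -> C/2 overall).
make_dec_block <- function(C, target, variant, norm) {
  b <- new_layer("dec_block")
  dense <- variant == "full3d"
  q <- C %/% 4L
  b$up <- nn_upsample(target)
  b$naU <- nn_norm_act(C, norm)
  b$gconv <- if (dense) nn_conv3d(C, q, c(3L, 3L, 3L), bias = FALSE)
             else nn_conv3d(C, q, c(3L, 3L, 3L), groups = q, bias = TRUE)
  b$naS <- nn_norm_act(q, norm)
  b$s3d <- if (dense) nn_conv3d(q, q, c(3L, 3L, 3L), bias = FALSE)
           else nn_s3dconv(q, q, bias = TRUE)
  b$q <- q
  b$layers <- list(b$up, b$naU, b$gconv, b$naS, b$s3d)
  b$fwd <- function(x, train = FALSE) {
    u0 <- b$up$fwd(x, train)
    u <- b$gconv$fwd(b$naU$fwd(u0, train), train)
    y <- b$s3d$fwd(b$naS$fwd(u, train), train)
    channel_cat(list(u, y))
  }
  b$bwd <- function(gy) {
    parts <- channel_split(gy, c(b$q, b$q))
    gu <- parts[[1L]] + b$naS$bwd(b$s3d$bwd(parts[[2L]]))
    b$up$bwd(b$naU$bwd(b$gconv$bwd(gu)))
  }
  b
}

#' Build a morph decoder
#'
#' @param config An [arch_config()].
#' @param n_out 3 for the displacement decoder, 1 for the additive-intensity
#'   decoder.
#' @return Decoder object (class `morphssl_decoder`).
#' @export
make_decoder <- function(config, n_out) {
  stopifnot(n_out %in% c(1L, 3L))
  d <- new_layer("decoder")
  d$config <- config
  norm <- config$norm
  sp <- config$input_shape %/% c(16L, 16L, 2L)
  targets <- list(sp * c(2L, 2L, 2L), sp * c(4L, 4L, 2L),
                  sp * c(8L, 8L, 2L), sp * c(16L, 16L, 2L))
  Cs <- c(64L, 32L, 16L, 8L)
  d$blocks <- lapply(1:4, function(i)
    make_dec_block(Cs[i], targets[[i]], config$variant, norm))
  d$na_out <- nn_norm_act(4L, norm)
  d$final <- nn_conv3d(4L, as.integer(n_out), c(1L, 1L, 1L), bias = TRUE)
  d$layers <- c(d$blocks, list(d$na_out, d$final))
  d$fwd <- function(x, train = FALSE) {
    for (b in d$blocks) x <- b$fwd(x, train)
    d$final$fwd(d$na_out$fwd(x, train), train)
  }
  d$bwd <- function(gy) {
    gy <- d$na_out$bwd(d$final$bwd(gy))
    for (b in rev(d$blocks)) gy <- b$bwd(gy)
    gy
  }
  d
}

#' Assemble the pre-training architecture
#'
#' Builds the encoder, both morph decoders and the learnable scalar
#' stabilizers for the requested variant.
#'
#' @param config An [arch_config()].
#' @return A `morphssl_model` list with elements `encoder`, `decoder_d`,
#'   `decoder_a`, `scalars` and `config`.
#' @export
make_architecture <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  model <- list(
    encoder = make_encoder(config),
    decoder_d = make_decoder(config, 3L),
    decoder_a = make_decoder(config, 1L),
    scalars = morph_scalars(),
    config = config
  )
  class(model) <- "morphssl_model"
  model
}

#' Learnable positive scalars of the morph head
#'
#' `alpha1`, `alpha2` rescale the decoded displacement/intensity fields to
#' the feature-displacement norms; `gamma` is the shared gain applied to the
#' unit direction vectors fed to both decoders.
#' @return A list of positive-scalar layers.
#' @export
morph_scalars <- function() {
  s <- list(alpha1 = nn_pos_scalar(1), alpha2 = nn_pos_scalar(1),
            gamma = nn_pos_scalar(1))
  class(s) <- "morph_scalars"
  s
}

#' Count trainable parameters
#'
#' Sums the lengths of every trainable weight array in a model or layer.
#' The EMA comparator (see [comparator_init()]) holds no trainable
#' parameters and is never included.
#'
#' @param model A model assembly, encoder, decoder or single layer.
#' @return Integer count.
#' @export
count_trainable_parameters <- function(model) {
  if (inherits(model, "morphssl_model"))
    return(n_params(list(model$encoder, model$decoder_d, model$decoder_a,
                         model$scalars)))
  n_params(model)
}

#' Run the encoder on a standardized volume
#'
#' @param volume An [oct_volume()] whose voxel array matches
#'   `config$input_shape`, or a bare (H,W,D) array.
#' @param model_or_config A `morphssl_model`, `morphssl_encoder`, or an
#'   [arch_config()] (a fresh encoder is built for a bare config).
#' @return A `feature_map` object: fields `F` (128 at H/16 x W/16 x D/2),
#'   `FD`, `FA`.
#' @export
encoder_forward <- function(volume, model_or_config) {
  enc <- resolve_encoder(model_or_config)
  x <- as_input_tensor(volume, enc$config$input_shape)
  out <- enc$fwd(x, train = FALSE)
  structure(list(F = out$F, FD = out$FD, FA = out$FA),
            class = "feature_map")
}

resolve_encoder <- function(m) {
  if (inherits(m, "morphssl_model")) return(m$encoder)
  if (inherits(m, "morphssl_encoder")) return(m)
  if (inherits(m, "arch_config")) return(make_encoder(m))
  stop("cannot resolve an encoder from class ", paste(class(m), collapse = "/"))
}

as_input_tensor <- function(volume, input_shape) {
  v <- if (inherits(v <- volume, "oct_volume")) v$voxels else volume
  if (length(dim(v)) != 3L)
    stop("expected a 3D volume, got ", length(dim(v)), " dimensions")
  if (!all(dim(v) == input_shape))
    stop("volume shape (", paste(dim(v), collapse = "x"),
         ") does not match the configured input shape (",
         paste(input_shape, collapse = "x"), ")")
  array(v, c(1L, dim(v)))
}

#' Tabulate the architecture layer by layer
#'
#' @param model A `morphssl_model` or encoder/decoder object.
#' @return A tibble with one row per layer: component, layer type, and
#'   trainable parameter count.
#' @export
describe_architecture <- function(model) {
  comps <- if (inherits(model, "morphssl_model")) {
    list(encoder = model$encoder, decoder_d = model$decoder_d,
         decoder_a = model$decoder_a, scalars = model$scalars)
  } else {
    list(model = model)
  }
  rows <- purrr::map_dfr(names(comps), function(nm) {
    ls <- collect_layers(comps[[nm]])
    tibble::tibble(
      component = nm,
      layer = vapply(ls, function(l) l$type, character(1)),
      n_parameters = vapply(ls, function(l)
        sum(vapply(l$params, length, numeric(1))), numeric(1))
    )
  })
  rows
}

# --- checkpointing -----------------------------------------------------------

#' Extract / restore the trainable parameters of a model
#'
#' `model_param_list()` returns every layer's parameter arrays in a stable
#' order; `set_model_params()` writes such a list back into a structurally
#' identical model (shapes are checked).
#'
#' @param model A model, layer, or list of them.
#' @export
model_param_list <- function(model) {
  ls <- collect_layers(model)
  lapply(ls, function(l) l$params)
}

#' @rdname model_param_list
#' @param plist A parameter list from [model_param_list()].
#' @export
set_model_params <- function(model, plist) {
  ls <- collect_layers(model)
  stopifnot(length(ls) == length(plist))
  for (i in seq_along(ls)) {
    stopifnot(identical(lapply(ls[[i]]$params, dim),
                        lapply(plist[[i]], dim)))
    ls[[i]]$params <- plist[[i]]
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the architecture config, every trainable weight and a
#' config hash that is verified on load.
#' @param model A `morphssl_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  cfg <- model$config
  obj <- list(config = unclass(cfg),
              config_hash = rlang::hash(unclass(cfg)),
              params = model_param_list(model),
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$config_hash, rlang::hash(obj$config)))
    stop("checkpoint config hash mismatch: ", path)
  cfg <- do.call(arch_config, obj$config[c("variant", "input_shape",
                                           "stem_channels", "stage_channels",
                                           "head_hidden", "norm")])
  model <- make_architecture(cfg)
  set_model_params(model, obj$params)
  model$extra <- obj$extra
  model
}
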