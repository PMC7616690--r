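# Shared fixtures: tiny architectures and synthetic inputs so every test
# builds its data in code.

withr_local_tempdir <- function() withr::local_tempdir(.local_envir = parent.frame())

# Desk-scale architecture (48x48x8 input) used across tests.
tiny_arch_config <- function(variant = "s3dconv") {
  arch_config(variant = variant, input_shape = c(48L, 48L, 8L),
              stem_channels = 4L, stage_channels = c(4L, 4L, 8L, 8L, 16L),
              head_hidden = 8L)
}

tiny_model <- function(variant = "s3dconv", seed = 42) {
  withr::with_seed(seed, make_architecture(tiny_arch_config(variant)))
}

tiny_synth_config <- function(seed = 1L, ...) {
  synth_config(shape = c(48L, 48L, 8L), seed = seed, ...)
}

random_feature_map <- function(shape = c(3L, 3L, 4L), seed = 7) {
  withr::with_seed(seed, {
    f <- array(rnorm(128 * prod(shape)), c(128L, shape))
    structure(list(F = f, FD = f[1:64, , , , drop = FALSE],
                   FA = f[65:128, , , , drop = FALSE]),
              class = "feature_map")
  })
}
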