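#!/usr/bin/env Rscript
# Channel-width derivation for the default architecture.
#
# The published description of the volumetric encoder/decoder fixes the
# topology (five Basic Encoder Blocks with concatenation skips, four
# strided depthwise downsamplings, twin 1x1x1 head pathways, two mirrored
# decoders) but not the stage widths, the stem width, the head hidden
# width, the bias conventions or the normalization affine style. The only
# published constraints are the three trainable-parameter totals:
#
#   S3DConv network (pre-training assembly)   2,702,329
#   dense-3x3x3 ("full 3D") variant           6,622,457
#   additive-skip variant                     7,025,881
#
# This script documents (a) the closed-form parameter-count model used for
# the search, (b) a feasibility argument showing that no symmetric-bias
# configuration can match the first two totals simultaneously, (c) the
# solved default configuration, verified against counts from the actually
# instantiated models, and (d) the residual on the additive-skip total.
#
# Run from the repository root after installing the package:
#   Rscript scripts/derive_channels.R

library(morphssl)

# ---------------------------------------------------------------------------
# (a) closed-form count model (mirrors the builders in R/backbone.R)
# ---------------------------------------------------------------------------
# conv parameter helpers: an S3DConv bank with cout filters has 9 weights
# per filter regardless of orientation; a dense 3x3x3 conv has 27.
s3d <- function(cin, cout, bias = 1) 9 * cin * cout + bias * cout
dense <- function(cin, cout, bias = 0) 27 * cin * cout + bias * cout
pw <- function(cin, cout, bias = 1) cin * cout + bias * cout
dwise <- function(c) 27 * c + c                 # depthwise 3x3x3, biased
gcomp <- function(c) 27 * c + c / 4             # groups of 4 -> 1, biased
norm_aff <- function(c) 2 * c                   # per-channel scale + shift

count_model <- function(stem, ws, h, variant = c("s3dconv", "full3d",
                                                 "additive")) {
  variant <- match.arg(variant)
  blockconv <- switch(variant, s3dconv = s3d, full3d = dense,
                      additive = s3d)
  total <- s3d(1, stem)                          # stem stays separable
  us <- c(stem, 2 * ws[1:4])
  for (i in 1:5) {
    u <- us[i]; w <- ws[i]
    wv <- if (variant == "additive") 2 * w else w
    total <- total + norm_aff(u) + blockconv(u, wv) +
      norm_aff(wv) + blockconv(wv, wv)
    if (variant == "additive" && u != 2 * w)
      total <- total + pw(u, 2 * w, bias = 0)    # 1x1x1 skip projection
  }
  for (w in ws[1:4]) total <- total + norm_aff(2 * w) + dwise(2 * w)
  v5 <- 2 * ws[5]
  total <- total + 2 * (pw(v5, h) + pw(h, 64))   # twin head pathways
  for (C in c(64, 32, 16, 8)) {                  # two decoders
    q <- C / 4
    gc <- if (variant == "full3d") dense(C, q) else gcomp(C)
    sc <- if (variant == "full3d") dense(q, q) else s3d(q, q)
    total <- total + 2 * (norm_aff(C) + gc + norm_aff(q) + sc)
  }
  total <- total + 2 * norm_aff(4) + pw(4, 3) + pw(4, 1)
  total + 3                                      # alpha1, alpha2, gamma
}

# ---------------------------------------------------------------------------
# (b) feasibility: the full3d difference forbids symmetric biases
# ---------------------------------------------------------------------------
# Replacing a 9-weight separable bank by a 27-weight dense bank with the
# SAME channels and the SAME bias convention changes the count by
# 18 * cin * cout per conv - a multiple of 18. But
#   6,622,457 - 2,702,329 = 3,920,128 = 18 * 217,784 + 16,
# so the printed difference is NOT a multiple of 18: the original
# implementation must treat the two conv types asymmetrically. The solved
# configuration keeps biases on the separable banks and builds the dense
# substitutes bias-free, which makes the difference
#   18 * sum(cin*cout) - sum(cout)  (mod-18 residue supplied by the couts).
stopifnot((6622457 - 2702329) %% 18 == 16)

# ---------------------------------------------------------------------------
# (c) the solved default and instantiated verification
# ---------------------------------------------------------------------------
stem <- 32L
ws <- c(36L, 56L, 64L, 100L, 324L)
h <- 525L

cat("closed-form model:\n")
for (v in c("s3dconv", "full3d", "additive"))
  cat(sprintf("  %-10s %d\n", v, count_model(stem, ws, h, v)))

cat("instantiated models:\n")
published <- c(s3dconv = 2702329, full3d = 6622457, additive_skip = 7025881)
set.seed(1)
for (v in names(published)) {
  m <- make_architecture(arch_config(variant = v))
  n <- count_trainable_parameters(m)
  cat(sprintf("  %-13s %d  (published %d, diff %+d)\n",
              v, n, published[[v]], n - published[[v]]))
}

# ---------------------------------------------------------------------------
# (d) residual on the additive-skip variant
# ---------------------------------------------------------------------------
# The additive-skip blocks double the filter counts of the two in-block
# convolution banks for matched input/output channels. The published
# supplementary figure defining the exact additive wiring is not part of
# the main text; over every doubling scheme we enumerated (with and
# without 1x1x1 skip projections, biased or not; four decoder-doubling
# variants; three normalization affine styles; both bias conventions; stem
# widths 1..32; stage widths up to 512 in steps of 2), no configuration
# reproduces all three totals at once. The configuration above matches the
# first two exactly and overshoots the additive total by 2,848 (0.04%).
cat("\nadditive residual:",
    count_model(stem, ws, h, "additive") - published[["additive_skip"]],
    "parameters ( +0.04% )\n")
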