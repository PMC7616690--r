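# morphssl

Forecasting conversion from intermediate to neovascular age-related
macular degeneration (iAMD → nAMD) from a single retinal OCT volume,
using self-supervised pre-training on *unlabelled* longitudinal scan
pairs. The package is a complete, native R implementation (C++ kernels
for the 3D convolutions and warps — no deep-learning framework): the
separable-3D-convolution (S3DConv) encoder and twin morph decoders, the
morphing pretext task with its five-term loss, the sigmoid-CDF
time-to-conversion (TTC) head, the conversion risk score with
Kaplan–Meier stratification, eye-level bootstrap evaluation, and a
synthetic longitudinal retina generator so everything runs without
clinical data.

## The method in brief

**Stage 1 — morphing self-supervision.** For two visits of one eye, the
encoder maps each volume to a feature grid `F` (128 @ 12×12×16), split
into halves `F^D`, `F^A`. The later scan is modelled as a morph of the
earlier one,

    Î_t = Φ(I_t; D) + A,

with a displacement field `D` and additive intensity map `A` decoded
from the *direction* of the feature displacement `V = F_{t+k} − F_t`,
re-normalized so that `‖D‖ = α₁‖V_D‖` and `‖A‖ = α₂‖V_A‖`. The loss
combines masked reconstruction (with the gradient severed through the
additive target), a perceptual term under an EMA comparator, smoothness
and anti-folding penalties on `D`, and an L1 penalty on `A`.

**Stage 2 — time-to-conversion.** With time normalized to the 18-month
horizon, the conversion CDF is `p_t = 1/(1 + exp(−(t − b)/(a + 0.05)))`.
A three-layer 1×1×1 classifier on the (frozen or fine-tuned) features
produces a saliency map `M`; `b` comes from its pooled magnitude and `a`
from its spatial entropy. Training uses the average binary cross-entropy
at two time points per scan (bracketing labels, censored scans, and
first-conversion visits each have their own case). The scalar risk score
`r = 2/(1 + exp(b/(a + 0.05)))` stratifies eyes into low/moderate/high
risk at 0.33 and 0.67.

## Worked example (desk scale)

The shipped command-line tool drives the whole pipeline on synthetic
data. At desk scale (48×48×8 volumes, a narrow encoder):

```sh
CLI=$(Rscript -e 'cat(system.file("cli","morphssl.R",package="morphssl"))')
Rscript $CLI synth      --out raw --seed 3 --n-eyes 6 --shape 48x48x8
Rscript $CLI preprocess --in raw --out std
Rscript $CLI pretrain   --in std --out pre.rds --steps 8 --seed 3
Rscript $CLI train-ttc  --in std --ckpt pre.rds --out ttc.rds --epochs 2 --seed 3
Rscript $CLI predict    --in std --ckpt ttc.rds --out pred.csv
Rscript $CLI evaluate   --pred pred.csv --out metrics.json
```

which prints, for this seed:

```
wrote 23 scans to raw
preprocessed 23 volumes
pretrain loss 59.325 -> 53.589; checkpoint at pre.rds
validation AUC (mean over horizons): 0.4583
wrote predictions for 23 scans to pred.csv
```

`pred.csv` holds one row per scan with the CDF parameters `a`, `b`, the
risk score `r` and the conversion probabilities `p_0 … p_18`; the
probabilities are monotone across horizons by construction. A tiny
6-eye, 2-epoch run like the above is only a smoke test — the test-suite
pipeline (40 eyes, 50 pre-training steps, 12 epochs) reaches a 6-month
AUC well above chance on the signal-bearing synthetic cohort.

Within R the same objects compose directly:

```r
library(morphssl)
model <- make_architecture(arch_config())        # 2,702,329 parameters
count_trainable_parameters(model)
#> [1] 2702329

cfg  <- synth_config(shape = c(48, 48, 8), seed = 1)
pair <- make_longitudinal_pair(cfg)              # known ground-truth morph
fit  <- fit_morph_field(pair$I_t, pair$I_tk, pair$R_t, pair$R_tk)
1 - fit$final_error / fit$initial_error          # masked-error reduction
```

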