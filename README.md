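# pestpipe

Automated identification of insect pests in field photographs is a
bottleneck of integrated pest management: trapping is easy, but naming the
catch needs an expert. `pestpipe` implements, end to end and at desk
scale, the classic portable-classifier design for this problem — the kind
of pipeline that runs on an embedded processor at the trap and radios the
image home:

1. **Segmentation** — convert the photo to HSV, threshold a static band on
   the hue channel, binarize, and keep the largest connected region (the
   insect); everything else is noise.
2. **Features** — reduce the masked insect to 13 numbers: nine color
   moments (mean E, standard deviation σ and skewness s of H, S, V over
   the body pixels, with s the signed cube root of the third central
   moment), the eccentricity ratio EC = p/q of the momental ellipse, the
   sphericity SP = rᵢ/r꜀ (inscribed over circumscribed circle radius),
   and the first two Hu invariant moments φ₁ = η₂₀ + η₀₂ and
   φ₂ = (η₂₀ − η₀₂)² + 4η₁₁².
3. **Classification** — a three-layer back-propagation network
   (13 inputs, 10 hidden nodes from the heuristic n₁ = √(n+m) + a with
   a = 6, one output per class) on min–max-normalized features, trained by
   the online delta rule; seeded, hence bit-reproducible.
4. **Transmission** — the image payload split into 517-byte frames
   (head `0x1B 0x7E`, 16-bit sequence number, 512 data bytes, end
   `0xFF`) and sent stop-and-wait over a lossy channel simulator with
   timeout/retransmit/reset handling.

Because the original six-species field image collection was never
published, the package ships a **synthetic generator** of insect-like
labeled images with pixel-exact ground-truth masks and six
class-conditional parameter sets, in a separable `easy` regime and an
overlapping `field_like` regime that reproduces a field-realistic
operating point (held-out accuracy in the low 80s). Every stage is tested
against analytic shapes and brute-force oracles.

## Worked example

Train on synthetic images, then classify a fresh one:

```r
library(pestpipe)

fe    <- dataset_features(make_dataset(10, "easy", seed = 1))
model <- ann_train(fe$features, fe$labels,
                   train_config(learning_rate = 0.3, max_epochs = 200, seed = 1))

li  <- make_image(class_specs("easy")[[3]], seed = 99)   # a "Sesamia inferens"
rep <- run_pipeline(li$image,
                    pipeline_config(segmentation = segmentation_config(band = generator_band())),
                    model = model)
rep
```

```
label: Sesamia inferens
scores: Anomala cupripes=0.064 Chilo suppressalis=0.035 Cnaphalocrocis medinalis=0.009 Naranga aenescens=0.000 Prodenia litura=0.000 Sesamia inferens=0.949
region: 1285 px, hue band [0.000, 0.720)
features:
    E_H sigma_H     s_H     E_S sigma_S     s_S     E_V sigma_V     s_V      EC
 0.2902  0.0101 -0.0033  0.7501  0.0391 -0.0130  0.6989  0.0396 -0.0169  3.2192
     SP    phi1    phi2
 0.3285  0.2809  0.0536
```

Reading the output: the body's mean hue (`E_H` ≈ 0.29) sits at this
class's hue center; `EC` ≈ 3.2 says the body is a slim ellipse about
three times longer than wide, and `SP` ≈ 0.33 that its inscribed circle
is a third of its circumscribed one; `phi1`/`phi2` are the
scale/rotation-invariant moment summaries. The network gives the true
class a score of 0.95 and every other class ≤ 0.06.

End-to-end benchmarks (segment → features → train → held-out predict):

```r
run_benchmark("easy",       seed = 5)$accuracy   # >= 0.95 (separable classes)
run_benchmark("field_like", seed = 42)$accuracy  # ~0.8 (overlap + pose/lighting jitter)
```

A thin command-line front end over the same functions lives at
`inst/cli/pestpipe.R` (subcommands `classify`, `train`, `features`,
`synth`, `packetize`, `depacketize`, `simulate-link`).

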