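# skinfuse

Multiclass skin-lesion classification by hybrid deep-feature selection and
fusion, as a reusable R pipeline.

Dermoscopy classifiers that feed a deep-feature matrix straight into a
classifier drag along many redundant and irrelevant columns, which costs
both accuracy and time. `skinfuse` implements a complete pipeline that
attacks this:

1. **Contrast enhancement** — a hybrid local stretch
   `I_F = ||MD + X| − SK|` built from the absolute mean deviation
   `MD = (1/n) Σ |x_i − φ̄|` of the image against the pooled dataset mean
   and its sample skewness `SK = Σ(x_i − X̄)³ / ((n−1)σ³)`, per channel,
   clipped to [0, 255].
2. **Feature extraction** — a backbone adapter (plug in any CNN's global
   average-pool features) plus a deterministic toy backbone built from
   valid convolution, ReLU and pooling, so everything runs without
   pretrained weights.
3. **Feature selection, two ways** — a wrapper (`hwoa_select()`): whale
   optimization over subset encodings in [0,1]^D scored by
   `0.99·error + 0.01·|R|/D` with the error from a small extreme learning
   machine, refined by an AMD threshold on the best position; and a filter
   (`emi_select()`): per-feature fuzzy entropy combined multiplicatively
   with mutual information against the class label, thresholded at the
   mean score.
4. **Fusion** (`mdcca()`): multiset canonical correlation analysis on the
   two selected sets via the generalized eigenproblem
   `Z_xx⁻¹ Z_xy Z_yy⁻¹ Z_yx a = λ a`, projection and concatenation,
   variance sort and correlation-based redundancy pruning.
5. **Classification** (`elm()`): single hidden layer with random `U[−1,1]`
   weights, Gaussian squashing `g(z) = exp(−z²)`, output weights solved by
   the Moore–Penrose pseudoinverse `β = H⁺B`; metrics are accuracy, macro
   precision and FDR = 100 − precision.

Synthetic generators (`make_features()`, `make_images()`) provide labeled
fixtures with known informative/redundant/noise structure and toy lesion
images with controllable lesion contrast, so every stage is testable with
no downloads.

## Worked example

```r
library(skinfuse)

# 200 samples x 60 features, 7 classes, 8 informative columns, seed 0
fm <- make_features(synthetic_spec(seed = 0))
report <- run_pipeline(features = fm, seed = 0)
print(report)
#> pipeline report
#>   original    60 features: accuracy  23.53%  precision  25.95%  FDR  74.05%
#>   hwoa        11 features: accuracy  43.14%  precision  45.40%  FDR  54.60%
#>   emi         30 features: accuracy  35.29%  precision  34.29%  FDR  65.71%
#>   fused        5 features: accuracy  47.06%  precision  52.34%  FDR  47.66%
#>   split: 98 train / 102 test, master seed 0
```

Reading the table: the raw 60-column matrix (52 of its columns pure noise)
defeats the radial-basis ELM; each selector alone recovers most of the
planted signal; fusing the two selected sets by canonical correlation and
pruning redundant variates gives the best accuracy with the fewest
columns — the qualitative fusion gain the method is built around. Every
number is reproducible from the master seed.

The image route works the same way
(`run_pipeline(images = ..., labels = ...)`): images are enhanced against
the pooled dataset mean, passed through the toy backbone, and the same
four experiments are reported. A thin command-line front end over these
functions is included at `inst/cli/skinfuse.R`
(`enhance`, `extract`, `select-hwoa`, `select-emi`, `fuse`, `train-elm`,
`evaluate`, `run`).

## Scope

Full-scale experiments on HAM10000 / ISIC2018 with a fine-tuned
NasNet-Large backbone are out of computational scope here; the backbone
adapter contract (`backbone_spec("external", ...)`) is the seam where such
features plug in. See `vignettes/lesion-pipeline.Rmd` for the full methods
account, parameter defaults and known limitations.
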