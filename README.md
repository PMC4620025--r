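# topocode

Cell-cycle phase recognition for time-lapse microscopy by **topographic
sparse coding**: dictionary learning with a smoothed, grouped L1 penalty
whose groups are neighbourhoods on a 2-D atom grid, so that nearby atoms
learn similar features. The learned codes feed a one-vs-rest RBF-kernel
SVM that labels each segmented nucleus as interphase, prophase, metaphase
or anaphase. The package is aimed at researchers analysing proliferating
cell cultures (e.g. tumour lines under treatment) who need per-nucleus
phase calls from grayscale TIFF stacks — and at anyone who wants a small,
fully testable reference implementation of topographic sparse coding.

## The method

Samples `x` (one `d`-vector per nucleus, columns of a `d × N` matrix) are
approximated as `x ≈ A s` with a `d × k` dictionary `A` (unit-norm atoms)
and sparse codes `s` (`k × N`). With atoms arranged on a grid and a binary
grouping matrix `V` mapping atoms to overlapping `group_size²`-atom grid
neighbourhoods, learning minimizes

```
J(A, s) = ||A s − x||²_F  +  λ Σ_{g,n} √( (V (s∘s))_{g,n} + ε )  +  γ ||A||²_F
          subject to ||s_col||² ≤ C,
```

by alternating mini-batch gradient descent with backtracking line
searches: codes are optimized by projected gradient descent from the
analytic start `s = Aᵀx` (convex subproblem), then the dictionary takes a
renormalized gradient step accepted on the re-encoded batch objective.
`ε` smooths the grouped L1 term (for singleton groups and `ε = 0` it *is*
the L1 norm), `γ` is weight decay, and `C` bounds each code column's
energy. A full pipeline wraps the numeric core: Otsu binarization, seeded
watershed segmentation (distance-transform maxima as seeds), fixed-size
ROI extraction, four feature families (54-element resampled RAW intensity,
HoG, Gabor-bank/GIST, dense SIFT), classification and confusion-count
metrics (sensitivity, specificity, precision, F1, accuracy, error rate).
A synthetic generator produces labeled scenes with four morphologically
distinct nucleus classes, plus numeric sparse-coding instances with a
known ground-truth dictionary, so every stage is testable offline.

## Worked example

Learn a dictionary from a synthetic instance with known ground truth, then
run the full image pipeline:

```r
library(topocode)

inst <- generate_tsc_instance(synth_tsc_config(d = 16, k = 16, N = 400, seed = 2))
fit  <- tsc_learn(inst$samples,
                  tsc_config(grid_rows = 4, grid_cols = 4, group_size = 2,
                             batch_size = 128, max_outer_iters = 40, seed = 2))
fit
#> Topographic sparse coding fit: 16 x 16 dictionary (4x4 atom grid), 400 samples
#>   40 outer iterations, final objective 176.914 (reconstruction 28.51, penalty 146.8, decay 1.6)

attr(match_atoms(fit$dictionary, inst$dictionary), "mean_abs_cosine")
#> [1] 0.982
```

The objective decomposes into reconstruction error, the λ-weighted grouped
sparsity penalty and the γ-weighted decay (the three always sum to `J`);
`match_atoms()` scores recovery of the planted dictionary up to sign and
permutation — 0.982 mean absolute cosine similarity means the atoms were
essentially recovered. The image pipeline (segment → featurize → learn →
encode → classify → evaluate, with a temporal-prefix train/test split):

```r
cfg <- pipeline_config(synth = list(n_frames = 24, n_cells_per_frame = 6, seed = 7),
                       evaluation = list(train_frames = 16), run_seed = 7)
run <- run_pipeline(cfg)
run
#> Phase-recognition run (tsc arm): 50 test nuclei, multi-class accuracy 0.960 (error rate 0.040)

run$metrics
#> # A tibble: 6 × 8
#>   class      sensitivity specificity precision    f1 accuracy error_rate undefined
#> 1 interphase       1           1         1     1         1        0      ""
#> 2 prophase         0.833       1         1     0.909     0.96     0.04   ""
#> 3 metaphase        1           1         1     1         1        0      ""
#> 4 anaphase         1           0.944     0.875 0.933     0.96     0.04   ""
#> 5 macro            0.958       0.986     0.969 0.961     0.98     0.02   ""
#> 6 overall         NA          NA        NA    NA         0.96     0.04   ""
```

Rows 1–4 are one-vs-rest metrics per phase, `macro` is their unweighted
mean, and `overall` is the multi-class accuracy from the 4-class confusion
diagonal — here 48 of 50 held-out nuclei were labeled correctly. Setting
`tsc = list(enabled = FALSE)` runs the ablation arm (features straight to
the SVM) for comparison. `autoplot(fit)` and `autoplot(run$metrics)` plot
the optimization trace and the per-phase metrics; `tidy()`/`glance()`
give tabular summaries. A thin CLI over the same functions lives at
`inst/cli/topocode.R` (subcommands `simulate`, `segment`, `featurize`,
`learn`, `encode`, `run-all`).

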