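# mlgleason

Multi-label ensemble CNN classification for patch-level Gleason grading of
prostate histopathology.

## The problem

Digitized prostate biopsies are graded by the Gleason system: annotated
tissue regions carry patterns G3, G4 or G5 (increasingly aggressive), and
whole-slide images are analysed as 512x512 patches. Patch datasets
conventionally assign each patch the single **majority-vote** label — the
grade with the most annotated pixels. Because real patches routinely mix
several patterns, majority voting silently mislabels every pixel of the
minority patterns: on average a percent or two of the patch, but up to ~30%
in individual patches. Models trained against those labels inherit the
noise, and small foci of high-grade cancer vanish from the record.

`mlgleason` implements the multi-label alternative, end to end:

* **Audit** the damage: per grade and per dataset partition, the mean and
  maximum off-majority pixel area, with histograms
  (`inconsistency_report()`).
* **Relabel** patches: grade `c` enters the label set when its pixel count
  reaches `max(min_count, floor(tau * N))` — at the default `tau = 0.01`
  and all-pixel denominator, 2621 pixels of a 512x512 patch. The NC
  (non-cancerous) label is issued only when *zero* grade pixels are present
  (`multilabel_from_mask()`, `relabel_manifest()`).
* **Detect** with an ensemble of three one-vs-all binary CNNs — a ResNet18
  truncated after the first `conv4` block (GAP directly on its ReLU) —
  trained with Adam, inverse-frequency weighted cross-entropy, a stepped
  learning-rate schedule with a 10x faster head, L2 1e-2, early stopping,
  and augmentation (`train_ensemble()`). Per-grade decision thresholds are
  selected from validation precision-recall curves (`select_thresholds()`);
  the multi-label hypothesis is every grade whose score exceeds its
  threshold, NC when none does (`predict_multilabel()`).
* **Evaluate** with per-class F1 (NC, G3, G4, G5), macro F1, macro binary
  accuracy and subset accuracy (`evaluate_ensemble()`).
* **Explain** with Grad-CAM heatmaps and stitched whole-slide activation
  maps (`grad_cam()`, `slide_activation_map()`).
* **Simulate**: a deterministic generator of H&E-like slides with planted
  grade blobs, pixel masks, patient-exclusive folds and overlap-tiled
  patches makes the whole pipeline testable with no external data
  (`generate_dataset()`).

The CNN, its backpropagation and the optimizer are implemented inside the
package (RcppArmadillo kernels + R training loop) and verified against
finite differences in the test suite.

## Worked example

```r
library(mlgleason)

# a single patch: 70% G4 and a substantial 30% G3 focus
m <- generate_patch_mask(512, c(G4 = 0.7, G3 = 0.3))
grade_name(majority_label(m))
#> [1] "G4"                      # the conventional label: G3 is discarded
misclassified_fractions(m)
#>        G3        G5
#> 0.2999992 0.0000000            # 30% of the patch is mislabelled
multilabel_from_mask(m, label_policy())
#> <multilabel> G3+G4             # the multi-label keeps both patterns

# a synthetic five-patient dataset, and the audit over its folds
cfg <- synthetic_config(n_patients = 5, slide_size = c(192L, 192L),
                        patch_size = 64L, blob_scale = 64, seed = 42)
man <- generate_dataset(cfg, tempfile("demo"))
inconsistency_report(man)
#> Majority-vote label inconsistency audit (present population)
#>  fold class mean_pct max_pct  n
#>  Test    G3     13.4    26.8  9
#>  Test    G4     25.9    39.7  4
#>  Test    G5      2.4    13.2 11
#>  Val1    G3      9.1    19.3  4
#>  ...
```

`mean_pct`/`max_pct` are the average and worst-case percentage of patch
area that majority voting would mislabel for that grade in that fold, over
the patches where the grade occurs off-majority (`n`).

Training and evaluating the full ensemble on a generated dataset (about ten
minutes on one CPU core at the packaged problem size):

```r
cfg <- synthetic_config(n_patients = 10, slides_per_patient = 2,
                        slide_size = c(320L, 320L), patch_size = 64L,
                        blob_scale = 160, seed = 11)
man <- generate_dataset(cfg, "data/synth")
tc  <- train_config(max_epochs = 10, input_size = 48, seed = 7)
ens <- train_ensemble(man, label_policy(), tc,
                      train_folds = c("Val1", "Val2", "Val3"),
                      val_folds = "Val4")
evaluate_ensemble(ens, dplyr::filter(man, fold == "Test"),
                  label_policy(), input_size = 48)
```

`tidy()`/`glance()` methods give tabular access to fits, reports and
evaluations; `autoplot()` draws training curves, PR curves, heatmaps,
audit histograms and slide maps. A thin command-line front end with
`synth`/`relabel`/`stats`/`train`/`evaluate`/`predict`/`explain`
subcommands ships in `inst/cli/mlgleason.R`.

## Documentation

The methods vignette (`vignettes/multilabel-gleason-grading.Rmd`) describes
the label policy and its edge cases, the truncated architecture and
training recipe, the evaluation definitions, what the synthetic generator
does and does not emulate, and the package's numerical choices.
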