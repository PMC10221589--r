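# sonoloc

Hierarchical classification of liver ultrasound frames into the 11
standardized scan locations used in screening protocols — SL, ST, RSPV,
RSLT, LD, RSHV, GBL, EBL, RIA, RIP, LK — from the outputs of organ and
vessel semantic-segmentation backends.

Identifying *where* the probe is (which standardized posture produced a
frame) is hard because inter-subject variability and probe motion make the
raw image an unreliable guide, while segmentation-derived structure (which
organs are visible, where, how large, with what vessel morphology) is much
more stable. `sonoloc` is aimed at researchers building scan-guidance
systems on top of segmentation models: it consumes per-image *segmentation
artifacts* (class map, pre-activation mask predictions `P`, per-segment
query embeddings `Q`, encoder feature map `F`, class scores) rather than
raw pixels, and includes a synthetic artifact generator so every stage is
trainable and testable without clinical data.

## Method

**Features.** Per artifact, the classifier input concatenates

- GAP image features `G_i = (1 / (H_F W_F)) Σ_{h,w} F_{i,h,w}`,
- the flattened query embeddings `Q ∈ R^{C_Q×N}` and raw class scores,
- per-class geometric descriptors
  `V_i = [T_i, L_{i,x}, L_{i,y}, S_i, λ1, λ2, v1, v2]`: detection tag,
  centroid, area fraction `|C_i| / (H·W)`, and the eigenstructure of the
  mask's pixel-coordinate covariance; undetected classes give zero rows, so
  `V ∈ R^{(N−1)×10}` always.

**Hierarchy.** Level 1 classifies 8 regions from organ features alone
(ST/RSPV/RSHV merged; SL/EBL merged; two fully connected layers,
cross-entropy, AdamW lr 1e-4, early stopping patience 10). Level 2 then
resolves the two merged groups:

- *ST/RSPV/RSHV* — a sub-step-1 MLP on liver+vessel features partitions
  training data into clear/ambiguous; a triplet-margin encoder
  (`max{|a−p|² − |a−n|² + α, 0}`, α = 1, batch-hard mining, 64-d
  L2-normalized output) is trained on clear data; reference points are
  sampled one per occupied cell of a 10×10 grid over the clear data's 2-d
  t-SNE; every group-1 sample is labeled by 3-nearest-reference voting in
  the 64-d space.
- *SL/EBL* — a three-channel image (vessel-masked intensities, ReLU
  background mask prediction `max(P₁,0)`, ReLU vessel mask prediction
  `max(P₂,0)`) is resized, min-max scaled and classified by a small CNN.

A single-model 11-class ablation (`trainNonHierarchical()`) and a
subject-wise evaluation harness (all C(5,3) = 10 train/test subject splits,
per-class precision/recall/F1) support the comparison between the two
architectures.

## Worked example

```r
library(sonoloc)

specs <- defaultScanSpecs()                      # 11-location study spec
ds <- generateDataset(nPerClass = 20, subjects = paste0("s", 1:5),
                      specs = specs, seed = 1)
sub <- vapply(ds$samples, `[[`, character(1), "subjectId")
fold <- subjectFolds(paste0("s", 1:5), 3)[[1]]   # 3 train / 2 test subjects

model <- trainHierarchy(ds$samples[sub %in% fold$train], hierarchyConfig())
model
#> HierarchyModel
#>   level 1: 8-region MLP (val loss 0.0075)
#>   group 1: sub-step-1 MLP + triplet encoder + 3 references
#>   group 2: cnn image classifier (side 32)
#>   group-1 routing: knn; clear fraction 1.00

test <- ds$samples[sub %in% fold$test]
pred <- predictScanLocations(model, test, trace = TRUE)
table(pred$branch)
#>
#>     group1_knn group2_cnn     level1
#>             24         16         48

truth <- vapply(test, `[[`, character(1), "label")
reportMacro(scorePredictions(truth, pred$predicted,
                             classes = scanLocations()))
#> precision    recall        f1
#>         1         1         1
```

The branch table shows the routing contract: the 6 singleton regions are
finalized at level 1, the 24 right-subcostal frames go through the
reference-point KNN, the 16 longitudinal frames through the image CNN. The
macro scores are unweighted means of per-class precision/recall/F1 over the
11 codes on the two held-out subjects — perfect here because the default
specification is fully separable; `defaultScanSpecs(overlap = 0.5)`
produces the ambiguous regime where the architectural comparisons are
made.

A command-line wrapper (`inst/cli/sonoloc-cli.R`) exposes
`simulate` / `train` / `predict` / `evaluate` over YAML run configurations.

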