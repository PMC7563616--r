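# loopForge

Prediction of cohesin (RAD21)-mediated chromatin loops from one-dimensional
chromatin features, in R.

Chromatin loops bring two distal genomic loci — the loop *anchors* — into
physical proximity, and cohesin/CTCF mark the anchors of a large fraction of
them. Experimental interaction maps (ChIA-PET, Hi-C) are expensive, but
loops can be predicted from ordinary 1D sequencing tracks. loopForge
implements that framework end to end, for computational genomicists who
want to train, interrogate and transfer such models — or to study the
methodology itself on fully synthetic data:

- **Loop sets** — intersect replicated ChIA-PET interaction calls into a
  positive set (both anchors matching within an inclusive 2 kb edge-to-edge
  gap), build candidate negatives by randomly pairing ChIP-seq peaks,
  filter out candidates overlapping real loops, and match the positives'
  genomic-distance distribution by density-ratio importance resampling on
  log10 loop length with a KS acceptance check.
- **Feature matrix** — for a loop of length L (outer span), the 3L extended
  region is split into 1500 near-equal bins (left flank 1–500, loop
  501–1000, right flank 1001–1500) and every track is scored per bin by
  read-midpoint counting, normalized as reads/kb/million mapped reads. The
  default 23-track schema gives 23 × 1500 = 34,500 columns. Category
  subsets (`Architectural`, `TF`, `Transcription`, `*-anchors` with 100-bin
  windows centred on each anchor boundary) mirror the feature-ablation
  analyses.
- **Classification** — six learners with fixed study hyperparameters
  (decision tree depth 10/entropy; random forest 250 × depth 8; XGBoost
  100 × η 0.1 × depth 3; RBF-SVM C = 100; MLP α = 0.001 adaptive; deep net
  120–30–10 with dropout 0.2), an 80/20 stratified split, and
  accuracy/precision/recall/F1 with explicit averaging.
- **Importance** — per-(track, bin) profiles from the tree-based learners,
  deterministic top-k rankings with left/in/right naming, position-resolved
  per-track curves, and an anchor-concentration summary.
- **Transfer** — schema-fingerprinted models applied across datasets/cell
  lines without refitting.
- **Synthetic data** — replicated loop calls, anchor peak sets with decoys,
  and Poisson read tracks with anchor- or within-loop enrichment, so the
  whole pipeline runs and is testable with no downloads.

## Worked example

Simulate a small dataset (CTCF, RAD21, ATF3, REST tracks; 300 loops on an
idealized 50 Mb genome), build the labeled loop universe and feature
matrix, train gradient boosting, and inspect what it learned:

```r
library(loopForge)

cfg <- SimConfig(chromSizes = c(simA = 3e7, simB = 2e7), nLoops = 300L,
                 assayProfiles = defaultAssayProfiles()[c(13, 14, 15, 19)],
                 nDecoyPeaks = 2000L, seed = 7L)
ds <- simulateLoopDataset(cfg)

positives <- intersectReplicates(ds@replicateA, ds@replicateB, maxGap = 2000)
length(positives)
#> [1] 238

cand <- generateCandidateNegatives(ds@peaks, 3000L,
                                   maxSpan = max(loopLength(positives)),
                                   seed = 8L)
cand <- removePositiveOverlaps(cand, positives, maxGap = 2000)
neg  <- matchDistanceDistribution(cand, positives, length(positives), seed = 9L)
attr(neg, "ksStatistic")
#> [1] 0.03781513

fm   <- buildFeatureMatrix(buildLabeledSet(positives, neg), ds@tracks,
                           schemaFromProfiles(cfg@assayProfiles))

sp    <- splitTrainTest(fm, SplitSpec(seed = 10L))
model <- trainModel(modelSpec("xgboost"), sp$train)
evaluateModel(model, sp$test)
#> MetricsReport (weighted averaging)
#>   algorithm=xgboost, category=All
#>   accuracy 0.9479 | precision 0.9481 | recall 0.9479 | F1 0.9479

prof <- featureImportance(model)
head(topFeatures(prof, 5))
#>   rank     feature track window position absolute_bin importance
#> 1    1   ATF3_in_2  ATF3     in        2          502 0.19884126
#> 2    2 ATF3_in_499  ATF3     in      499          999 0.06556677
#> 3    3   REST_in_8  REST     in        8          508 0.06100579
#> 4    4   REST_in_6  REST     in        6          506 0.05062904
#> 5    5   REST_in_1  REST     in        1          501 0.03806361
anchorConcentration(prof)
#> [1] 0.8386556
```

Reading this: the replicate intersection keeps 238 of 300 loops (10%
dropout per replicate), the matched negatives reach a KS statistic of 0.038
against the positives' log-length distribution, held-out accuracy is ~0.95,
and the most informative bins sit immediately inside the anchors (absolute
bins 501–508 and 999 flank the anchor boundaries at 500/501 and 1000/1001)
— 84% of the model's importance lies within the 100-bin anchor windows,
the anchor-proximity signature the framework is designed to expose.

`runPipeline(loopPipelineConfig(...))` runs the same stages end to end from
one (YAML-loadable) configuration, writing BEDPE/TSV artifacts and a JSON
manifest with per-stage cardinalities, derived seeds and a config checksum;
`writeFixtures()`/`readFixtures()` round-trip datasets through plain-text
BED/BEDPE for interoperability.

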