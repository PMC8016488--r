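# ognet — alignment-free protein orthologous group assignment

Assigning protein sequences to precomputed orthologous groups (OGs) is the
workhorse of functional annotation, and it is classically done with
alignment-based searches (profile HMMs, DIAMOND) that have become a
throughput bottleneck at metagenome scale. `ognet` implements the
alignment-free alternative: a convolutional network that reads the raw
residue string and returns, for every sequence, a probability distribution
over the OGs in its model.

The main architecture is

* a **learned embedding** of the 26 extended IUPAC amino-acid codes into
  ℝ^D (D = 10 by default), trained jointly with the classifier, so residues
  cluster by learned biochemical similarity instead of the equidistant
  one-hot geometry;
* **multi-scale 1-D convolutions** (filter sizes 8, 12, 16, 20, 24, 28, 32,
  36; 150 filters per size by default) with **SELU** activations — a
  self-normalizing network, initialized N(0, 1/fan_in), needing no explicit
  normalization layers;
* **masked adaptive max-pooling**: each filter keeps its maximum activation
  over the sequence's *valid* windows only, giving a fixed-size feature
  vector for inputs of any length, with logits provably independent of
  padding and batch composition;
* dropout (P = 0.3) and a **softmax layer directly on the pooled features**
  (no hidden layer). The rank-1 probability is the assignment confidence:
  below a threshold (default **99%**) the sequence is reported
  `"unassigned"`, which rejects most sequences whose true group is not in
  the model (open-set rejection).

A fixed-length pseudo one-hot baseline network (ReLU convolutions with batch
normalization, 1-max pooling, a hidden layer; `variant = "deepfam"`) is
included for comparison, along with a synthetic protein-family simulator
(implanted motifs, variable lengths, power-law group populations), population
filtering, stratified 81/9/10 splitting, Adam training with a 25%-per-epoch
learning-rate decay, and imbalance-aware evaluation (macro-averaged
precision/recall). Everything is testable end to end without downloading any
database.

## Worked example

Simulate five imbalanced families, train the network, and assign the
held-out test sequences:

```r
library(ognet)

specs <- family_specs(n_groups = 5, motifs_per_group = 3,
                      imbalance_exponent = 0.5, base_population = 250,
                      length_range = c(80, 200), mutation_prob = 0.05,
                      seed = 42)
specs$population
#> [1] 250 177 144 125 112

records <- simulate_sequences(specs, seed = 42)
labels  <- records[, c("id", "group")]
split   <- stratified_split(labels, seed = 42)   # 655 / 72 / 81 sequences

cfg   <- model_config("ognet", n_groups = 5, filters_per_size = 16)
count_parameters(cfg)
#> [1] 29203

model <- build_model(cfg, og_label_map(sort(unique(labels$group))), seed = 42)
model <- train_model(model, records, labels, split,
                     training_config(max_epochs = 5, seed = 42))
#> epoch 0: lr=0.01 loss=3.4173 val_acc=0.7083
#> epoch 1: lr=0.0075 loss=0.9925 val_acc=0.9722
#> ...
#> epoch 4: lr=0.00316406 loss=0.1093 val_acc=1.0000

test_recs <- records[records$id %in% split$id[split$split == "test"], ]
pred <- assign_groups(model, test_recs, threshold = 0.99)
head(pred, 4)
#> # A tibble: 4 × 4
#>   id            group      confidence model
#>   <chr>         <chr>           <dbl> <chr>
#> 1 SOG0001_00011 unassigned      0.944 ognet
#> 2 SOG0001_00019 SOG0001         0.994 ognet
#> 3 SOG0001_00021 unassigned      0.982 ognet
#> 4 SOG0001_00023 unassigned      0.929 ognet

score_assignments(pred, labels)
#> <og_score> n=81 accuracy=0.5309 macro_precision=0.8000 macro_recall=0.5508 (5 groups)

score_assignments(assign_groups(model, test_recs, threshold = 0), labels)
#> <og_score> n=81 accuracy=1.0000 macro_precision=1.0000 macro_recall=1.0000 (5 groups)
```

The two scores show exactly what the 99% threshold buys: every assignment it
does make is correct (per-group precision 1 for every group it predicts),
at the cost of leaving lower-confidence sequences unassigned — pure argmax
(`threshold = 0`) classifies this easy synthetic test set perfectly. The
strict default favours precision; `assign_groups()` reports the confidence
for unassigned sequences too, so results can be re-thresholded without
re-running inference.

Fitted models and results are tidyverse-friendly: `tidy(model)` returns the
per-epoch history, `glance(model)` a one-row summary, `autoplot(model)`
training curves, `autoplot(confidence_histogram(pred))` the confidence
distribution (bin width 0.01), and `export_embeddings(model)` the learned
26-row residue embedding for inspection.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/cli/ognet.R simulate --groups 20 --base-population 200 \
    --out-fasta db.fasta --out-labels db.tsv --seed 1
Rscript inst/cli/ognet.R train --fasta db.fasta --labels db.tsv \
    --variant ognet --epochs 5 --filters 16 --out-model model.ognet --seed 1
Rscript inst/cli/ognet.R infer --model model.ognet --fasta queries.fasta \
    --confidence-threshold 0.99 --out predictions.tsv
Rscript inst/cli/ognet.R evaluate --predictions predictions.tsv \
    --labels db.tsv --out metrics.tsv
```

Logs go to standard error, artifacts only to the named files, and every run
writes its resolved flags as JSON next to its main output. Model archives
are single plain-text files (config + label map + alphabet + weights) whose
save→load→save round trip is byte-identical.

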