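# spliceDSC

Binary classification of alternative-splicing (AS) events — exon skipping
(ES), alternative 3' (Alt3) and alternative 5' (Alt5) splice sites — into
low/high inclusion classes, from paired 140-nt sequence windows plus three
exon/intron length features. The package is aimed at anyone who wants a
self-contained, testable R implementation of the dual-branch "deep splicing
code" (DSC) CNN and its evaluation protocol: the model, the 6-hidden-layer
reference architecture it is benchmarked against, the 10-fold
cross-validation scheme with a dedicated early-stopping fold, AUC-ROC
scoring, and a synthetic splice-event generator so every stage runs with no
external download.

## The model

Each window is one-hot encoded (140 × 4, channels A,C,G,T; `N` rows are
zero). Two identical branches process the two windows, each branch being
four blocks of

    Conv1D (valid, stride 1) → Dropout(0.2) → ReLU → MaxPool(2, stride 2)

with filters 8/16/32/64 and kernels 7/4/3/2, shrinking the temporal axis
140 → 134 → 67 → 64 → 32 → 30 → 15 → 14 → 7. The branch outputs are
concatenated (7 × 128), flattened (896), joined with the three log10 length
features (899), and passed through Dense(1024, ReLU) → Dropout(0.5) →
Dense(1, sigmoid). Training minimises binary cross-entropy

    L = -(1/N) Σᵢ [ yᵢ log ŷᵢ + (1 - yᵢ) log(1 - ŷᵢ) ]

with Adam (lr 5e-4, β₁ 0.9, β₂ 0.999, ε 1e-8, no decay). Evaluation is
AUC-ROC, computed as the Mann–Whitney probability with half credit for
ties. The 10-fold protocol trains on 8 folds, monitors 1 fold for early
stopping (patience 10, min_delta 1e-4, best-epoch weights restored), and
tests on the remaining fold, rotating so each fold is tested once.

The network forward/backward passes, Adam and the training loop are
implemented in RcppArmadillo (no deep-learning framework required);
single-threaded runs are bit-reproducible from one seed.

## Worked example

```r
library(spliceDSC)

cfg    <- synthetic_config(n_per_class = 250, seed = 42)  # 500 events
events <- generate_dataset(cfg)
table(events$event_type, events$label)
#>        0   1
#> Alt3  44  44
#> Alt5  50  50
#> ES   156 156

report <- run_cv(events, max_epochs = 10, seed = 42)
report
#> <evaluation_report: dsc, 10 epochs, seed 42>
#>   fold AUCs: 0.815 0.720 0.864 0.813 0.982 0.968 0.795 0.927 0.556 0.930
#>   mean AUC : 0.8370
```

The generator plants a donor-like motif (consensus `CAGGTAAGT`) in window A
and an acceptor-like motif (`TTTTCAGGT`) in window B of high-inclusion
events with probability 0.9; the report shows the network recovering that
signal from 400 training events per rotation — per-fold AUCs vary with the
50-event test folds, and the mean rises above 0.9 at the generator's
default size (1,000 events per class). `epoch_sweep()` repeats the run for
both architectures across epoch budgets and tabulates the mean AUCs side
by side; `build_baseline()` gives the 6-hidden-layer reference network.

Inspect the architecture directly:

```r
m <- build_dsc()
m
#> <dsc_model variant=dsc, untrained>
#>   4 conv layers per branch; 935,601 total trainable parameters
model_summary(m)   # layer / output shape / parameter table
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/dsc.R simulate --out data/ --n-per-class 250 --seed 42
Rscript inst/cli/dsc.R summary  --model dsc
Rscript inst/cli/dsc.R cv --data data/ --epochs 10 --seed 42 --out run/
```

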