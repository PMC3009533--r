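# pulearn

Positive-unlabeled (PU) learning for sequence-based protein
classification, built around the problem of identifying membrane-binding
peripheral domains (C1, C2, PH, PX, FYVE, ...).

## Why PU learning

For peripheral domains a curated **positive** set exists, but there is no
gold-standard set of proteins *known not to bind* membranes — membranes
enclose most of the cell, so no localization argument can produce clean
negatives.  What is available instead is a large **unlabeled** pool mixing
hidden positives with negatives.  Standard supervised learning does not
apply; PU learning does.

The package implements the spy-based two-step protocol:

1. **Spy step.** Plant a random fraction *s* (default 15%) of the positive
   set P into the unlabeled pool U with a negative label.  Train a
   classifier on (P∖S → c1) vs (U∪S → c2) and score U.  Since spies are
   true positives, the threshold *t* = min over spy posteriors Pr[c1|d]
   is the largest cutoff at which every spy is still called positive;
   unlabeled examples strictly below *t* become **reliable negatives**
   (RN).  Iterate on the shrinking pool until RN stops changing.
2. **Expansion step.** Train P vs RN, move every undecided example
   classified negative (Pr[c1] < 0.5) into RN, repeat until none moves.

The final classifier is trained on the full P vs the converged RN.  A
**modified variant** redraws a fresh spy set every iteration with a
per-iteration threshold.  Outputs are the final RN set (most unlikely to
be positive) and the residual Q = U∖RN (the candidate list worth testing).

Sequences are encoded as 104 features: net charge (K,R = +1; D,E = −1),
Kyte–Doolittle hydrophobicity / Chou–Fasman helix / sheet propensity sums,
20 composition fractions, and an 80-slot local-environment composition
(residue identity × 4 windowed helix/sheet propensity regimes).  The
inner classifier is an information-gain decision tree with
Laplace-smoothed leaf probabilities and pessimistic pruning; any
classifier honoring the `classifier_factory()` contract can be injected.
See the methods vignette (`vignettes/pu-learning-methods.Rmd`) for the
model, its assumptions, and every tunable.

## Worked example

```r
library(pulearn)

# packaged synthetic benchmark: 200 cationic positives, 1000 unlabeled
# (20% hidden positives), K/R frequency gap 0.15 between populations
bench   <- generate_benchmark(benchmark_defaults())
split   <- holdout_split(bench$P, 40, seed = 1)
dataset <- pu_dataset(split$train, bench$U, bench$truth)
dataset
#> PU dataset: 160 positive, 1000 unlabeled (200 hidden positives)

model <- run_pu(dataset, feature_config(), spy_config(seed = 1))
pu_history(model)
#>   phase iteration n_rn n_q  threshold n_spies
#> 1     A         1  800 200 0.03703704      24
#> 2     A         2  800 200 0.03703704      24
#> 3     B         1  800 200 0.50000000       0

ev <- evaluate_holdout(model, split$holdout)
sprintf("holdout sensitivity: %.2f (%d/40)", ev$sensitivity, ev$counts$tp)
#> [1] "holdout sensitivity: 0.95 (38/40)"
ev$misclassified
#> [1] "POS0051" "POS0176"
```

Reading the history: phase A's first spy draw (24 spies) sets the
threshold at 0.037 and moves 800 of the 1,000 unlabeled sequences into RN;
the second pass changes nothing (convergence), and phase B's 0.5-cut moves
nothing more.  The 200 sequences left in Q are exactly the planted hidden
positives, and 38 of the 40 held-out positives — never seen during
training — are recovered by the final classifier.

## Command line

```sh
Rscript inst/scripts/pulearn simulate --out bench --seed 42
Rscript inst/scripts/pulearn run --positives bench/positives.fa \
    --unlabeled bench/unlabeled.fa --outdir out --holdout 40 --seed 1
Rscript inst/scripts/pulearn predict --model out/model.json \
    --fasta bench/unlabeled.fa --out predictions.tsv
```

`run` writes `rn_ids.txt`, `q_ids.txt`, the per-iteration `history.tsv`
(plot-ready RN/Q convergence curves), `model.json` (self-contained: the
tree and the feature configuration), `metrics.json` and the holdout
predictions.  All commands honor `--seed`; identical inputs and seed give
identical outputs.  A YAML config (`run --config run.yaml`) can replace
the flags.

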