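---
title: "Positive-unlabeled learning for sequence-based protein classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PU-learning methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulearn)
```

## The problem

Membrane-binding peripheral domains (C1, C2, PH, PX, FYVE, ...) are
cytosolic modules that reversibly attach to lipid membranes.  A curated
positive set of such domains exists, but there is no gold-standard set of
proteins *known not to bind* membranes: membranes enclose most organelles,
so no subcellular localization argument can manufacture negatives.  The
data therefore consist of a labeled positive set P and a much larger
unlabeled pool U that mixes hidden positives with negatives — the setting
of positive-unlabeled (PU) learning.

`pulearn` implements a two-phase PU protocol:

1. **Spy-based reliable-negative extraction.**  A random fraction
   $s$ (default 0.15) of P is planted in U as *spies* carrying a negative
   label.  A binary classifier is trained on (P∖S → c1) versus (U∪S → c2)
   and scores U.  Because spies are genuine positives, the smallest spy
   posterior $t = \min_{d \in S} \Pr[c_1 \mid d]$ is the largest threshold
   at which every spy is still classified positive; unlabeled examples with
   $\Pr[c_1 \mid d] < t$ (strictly) form the reliable-negative set RN.
   The step is repeated on the shrinking pool until RN stops changing.
2. **Iterative RN expansion.**  Train P (class c1) versus RN (class c2),
   classify the undecided set Q = U∖RN, and move every example with
   posterior below 0.5 into RN; repeat until no example moves.

The final classifier is trained on the full original P versus the
converged RN.  The protocol's two deliverables are the final RN set
(sequences most unlikely to be positive) and the residual Q set (the
candidate list for follow-up).

A **modified variant** draws a *fresh* spy set every iteration, trains
(P∖Sᵢ → c1) versus (RN∪Q∪Sᵢ → c2), applies the per-iteration threshold
$t_i$, and returns the spies to P, until RN stops changing.  Agreement of
the two variants' final RN sets is itself a useful robustness check, and
on the packaged benchmark they do agree (the acceptance suite asserts it
across ten seeds).

## Features

Each sequence is reduced to 104 numbers, in fixed order:

| block | size | definition |
|---|---|---|
| net charge | 1 | Σ charge map (K,R = +1; D,E = −1; others 0) |
| propensity sums | 3 | Σ Kyte–Doolittle hydrophobicity, Σ Chou–Fasman Pα, Σ Pβ |
| composition | 20 | fraction of each standard residue |
| local environment | 80 | residue identity × 4 window-propensity regimes |

For the local-environment block, the mean helix and sheet propensities are
taken over a centered window of 7 residues (truncated at the ends,
ambiguity codes excluded), and the environment is classified by comparing
each mean with 1.0 — the natural former/breaker boundary of the
Chou–Fasman scales.  This yields 4 regimes × 20 residues = 80 slots, and
by construction the 4 slots of each residue sum to its composition entry
(the conservation law the structural acceptance criterion checks exactly).

Choices the source material leaves open, and what this package does:

* **Scales.**  The quantities (hydrophobicity, helix/sheet propensity) are
  named but no scale is pinned; Kyte–Doolittle and Chou–Fasman are the
  canonical contemporaneous choices.  All three scales, the charge map,
  the window (odd, default 7) and both thresholds are injectable through
  `feature_config()`, so none of these defaults is hard-wired.
* **Normalization.**  Composition is normalized to fractions by default
  ("% of each kind of amino acid"); charge and propensity *sums* are kept
  as raw sums ("the sum of"), with `normalize_sums` available.
* **Ambiguity codes.**  B, Z, X, U, O are accepted on ingest and excluded
  from every count, sum and window mean — exclusion is conservative and
  testable, whereas any imputation rule would be invented.  A sequence
  with no standard residues featurizes to the all-zero vector (never NaN)
  and is flagged at prediction time.

## The inner classifier

The shipped classifier is a binary decision tree grown with the
information-gain (entropy) criterion — the loss that defines the
C4.5 family — with:

* **Laplace-smoothed leaf probabilities**, $\Pr[c_1] = (n_{c_1}+1)/(n+2)$.
  Raw leaf frequencies are almost always 0 or 1, which would make the
  min-over-spies threshold degenerate; Laplace correction is the standard
  remedy for probability-estimation trees.
* **Pessimistic pruning**: a subtree is collapsed when the
  Clopper–Pearson upper-confidence-bound (CF = 0.25) estimate of its
  collapsed error does not exceed the summed estimates of its leaves.
* Deterministic training: ties between candidate splits are broken by the
  lowest feature index, then the lowest threshold, so a fixed input gives
  a fixed tree with no RNG involvement.

The PU loop only requires the `classifier_factory()` contract — a
`train(X, y, seed)` returning an object with a `predict_proba()` method
over classes c1/c2 — so ensemble or other classifiers can be plugged in
without touching the protocol code.

## Robustness of the spy threshold

The min-over-spies rule is brittle in one specific way: if the random spy
draw happens to include a positive example that lies inside the negative
bulk (benchmarks generated at realistic settings do contain such boundary
sequences, mostly short ones), the threshold collapses to the global
minimum posterior and *nothing* falls strictly below it.  The first pass
then extracts an empty RN set even though the classes are clearly
separable — at the package defaults this happened in roughly a third of
spy draws.

Spy selection is the protocol's randomized element, so the implementation
treats an empty first pass as a failed draw of a Las-Vegas procedure: the
spy set is redrawn with the next derived seed (draw $r$ uses seed $+ r$;
everything stays deterministic given the master seed), and only after
`n_redraws` (default 10) consecutive empty draws is the "no reliable
negatives" error raised.  Genuinely inseparable input — e.g. an unlabeled
pool consisting solely of duplicates of P — fails every draw and still
produces the documented error.  In the modified variant the redraw is
implicit in its fresh-spies-per-iteration design: empty iterations before
the first RN example count against the same budget.  The RN⊎Q = U
partition, monotone RN growth and spy safety (no spy can ever enter RN)
are unaffected.

Other numerical conventions: the spy count is round-half-away-from-zero of
$s\,|P|$, with an `n_spies` override for reproducing a specific historical
configuration; ties at exactly the threshold stay in Q (strict `<`); phase
B uses the plain 0.5 posterior cut, deliberately different from phase A's
spy-derived threshold; `max_iter` (default 100) guards termination for
arbitrary injected classifiers even though the monotone, bounded RN
sequence terminates on its own for deterministic ones.

## The synthetic benchmark

`generate_benchmark()` emulates the electrostatic signal the method relies
on — cationic membrane-binding proteins versus a more anionic background —
with two i.i.d.-residue populations: the positive population reweights K/R
by `basic_enrichment`, the negative one reweights D/E by
`acidic_enrichment`, over a uniform background.  Defaults
(`benchmark_defaults()`): 200 positives, 1,000 unlabeled of which 20% are
hidden positives, lengths uniform on 60–180, seed 42, and symmetric
enrichments solved in closed form (`enrichment_for_gap()`) so the expected
per-residue K+R frequency gap is exactly 0.15 — which makes the expected
net-charge gap at the median length 120 equal to 36 elementary charges.

I.i.d. sampling is a deliberate simplification: it gives the window-based
encoder non-trivial input while keeping population expectations available
in closed form for test oracles.  The generator does **not** mimic real
domain motifs, positional structure, dipeptide statistics or database
length/composition marginals.  A green test on this benchmark therefore
establishes that the protocol recovers a planted compositional/charge
signal under its own assumptions — not that it reproduces any particular
performance level on real proteome data, which depended on a keyword-based
extraction that is not recoverable.

Separation is a parameter, not a constant, so degradation can be tested:
as the frequency gap shrinks toward 0, RN purity falls, and at
near-inseparability the protocol increasingly refuses to emit any RN set
(the documented error) — the honest terminal behavior.

The redundancy reducer `greedy_identity_reduce()` is a desk-scale stand-in
for CD-HIT-style clustering: greedy longest-first retention with pairwise
identity defined as identical aligned positions under global alignment
(match 1, mismatch 0, linear gap −1) divided by the shorter length, and a
lexicographic-id tie-break for equal lengths so the result is
deterministic.  For full-scale work on tens of thousands of sequences, use
CD-HIT itself (e.g. `cd-hit -c 0.4 -n 2` for the positive set) and feed
the representative FASTA back in.

## Evaluation protocol

With no labeled negatives, nothing can be held out from U, so final-model
evaluation uses positives only: `holdout_split()` sets aside positives
(default 40 in the workflow) that never enter any training stage, and
`evaluate_holdout()` reports sensitivity = TP/(TP+FN); on a positives-only
holdout, accuracy and sensitivity coincide.  `cross_validate()` provides
seeded, stratified k-fold (default 5) accuracy/sensitivity over a
positive/negative pair of feature matrices for parameter exploration; the
package deliberately supplies the protocol but no tuning grid.

## Known limitations

* Holdout sensitivity on the default benchmark is stochastic in the
  protocol seed; most seeds give 95–100%, but occasional seeds leak more
  hidden positives into RN during phase A and land lower.  The protocol
  offers no guarantee against this — inspecting the per-iteration history
  (`pu_history()`, `history.tsv`) is the practical diagnostic.
* The greedy reducer is quadratic in the number of sequences and intended
  for hundreds to a few thousand records.
* Posteriors from a single tree are piecewise constant; examples sharing a
  leaf are indistinguishable to the threshold rule.  This is intrinsic to
  tree-based spy thresholds and is the reason the redraw logic exists.
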