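---
title: "Weak supervision for cardiogenic-stroke evidence extraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak supervision for cardiogenic-stroke evidence extraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`echoNER` extracts diagnosis evidence of cardiogenic stroke — cardiac
sources of embolism such as mitral stenosis or a left-ventricular mural
thrombus — from free-text Chinese echocardiograph reports, without manual
span annotation.  This vignette records the model, the assumptions behind
each stage, the parameters that matter, and the design choices made where
the design was genuinely open.

## 1. The weak-supervision pipeline

The training signal is a phrase lexicon, not human labels.  A report is
normalized to a single paragraph; forward maximum matching (FMM) of the
lexicon over that paragraph yields character-level BIO tags; a BiLSTM-CRF is
trained on those tags and then applied to held-out reports.  The hoped-for
payoff of the model layer over the dictionary alone is *generalization*:
surface variants the lexicon misses (a hyphenated grade such as
二尖瓣中-重度狭窄, a synonym suffix such as 退行性病变) can still
be recognized from context, whereas exact matching structurally cannot
recognize them.

### Entity types

Eleven types are modeled: the ten most frequent evidence / potential
evidence classes plus the compound aortic+mitral calcification class (see
`entity_types()`).  Three of the eleven are "potential" evidence (cardiac
enlargement, ventricular wall hypokinesis, decreased systolic function):
findings closely associated with a cardiac embolic source without being one
themselves.  A larger registry of 24 codes (`all_entity_types()`) validates
lexicon files that also mention the rarer classes of the full clinician
catalogue; the packaged lexicon carries 27 clinician-seed phrases over 20
evidence classes plus harvested and curated forms.

### Normalization

Per line: Unicode NFC, removal of spaces (ASCII, tab, ideographic),
lowercasing of ASCII letters.  Characters are Unicode code points; all span
coordinates are 0-based, half-open.  Description lines are concatenated
without a delimiter (they carry their own terminal punctuation); conclusion
lines are joined with the full-width comma `，`, matching Chinese clinical
convention (the delimiter is configurable — the narrower design question of
half- vs full-width is unobservable from printed sources).  NFC matters
because CJK compatibility variants would otherwise break exact dictionary
matching silently.

### Forward maximum matching

At position *i* the window lengths `min(max_len, n - i) … 1` are tried and
the longest lexicon surface wins; the scan then continues after the match.
Ties cannot arise: the lexicon enforces one type per surface, so at a given
position and length at most one entry can match.  Matching is exact — no
fuzzy matching; recovering variants is deliberately left to the model.  The
implementation is indexed by first character; the test suite checks it
against a brute-force window-enumeration oracle on hundreds of random
paragraph/lexicon pairs.

### Character embeddings

The contract is "distributional character vectors of stated dimension and
window".  We compute them deterministically: symmetric co-occurrence counts
within a 5-character window, positive pointwise mutual information, and a
truncated SVD (`U √Σ`), i.e. the count-based factorization equivalent of
skip-gram with negative sampling.  The choice over a stochastic SGNS loop
buys exact reproducibility (singular-vector signs are fixed canonically) and
speed on a corpus whose character vocabulary is small (a few hundred types);
its known bias — downweighting of very rare co-occurrences — is immaterial
at this vocabulary size.  Defaults: `dim = 100`, `window = 5`.  `<unk>` is
the mean trained vector, `<pad>` is zero; unseen characters at inference map
to `<unk>`.

### BiLSTM-CRF

* Emission path: embedding (fine-tuned during training) → bidirectional
  LSTM, hidden size `hidden_units` *per direction* (the concatenated state
  is `2 × hidden_units` wide — "hidden units" is read per direction, the
  cited architecture's convention) → dropout → linear projection to the
  `k = 23` BIO labels.
* CRF: transition matrix `A` of size `(k+2) × (k+2)` with augmented START
  and STOP states kept out of the emission labels.  No hard BIO transition
  masks are imposed; `A` is learned freely, and ill-formed decoded output
  (an `I-t` without a legal predecessor) is repaired to `B-t` when reading
  spans, so every predicted character region yields a span for evaluation
  rather than silently deflating recall.
* Training: exact sequence NLL `log Z − score(gold)` via the forward
  recursion in log space, minibatch Adam, global gradient-norm clipping
  at 5, inverted dropout (0.5) on the encoder output only at training time.
  The checkpoint with the best dev strict-F1 is kept; early stopping after
  `patience` epochs without improvement.
* Decoding: Viterbi; ties resolve to the smallest label index (first
  argmax), which makes decoding deterministic.

Numerical choices: log-sum-exp with max subtraction everywhere; Glorot
uniform initialization for LSTM/projection weights; forget-gate bias 1;
transitions initialized at `N(0, 0.01)`.  The backward pass is analytic and
is verified in the tests against central finite differences at tolerance
1e-5, and the partition/Viterbi recursions against exhaustive enumeration
(`n ≤ 4`, `k ≤ 4`, tolerance 1e-8).

### Hyperparameters

| Parameter | Default | Notes |
|---|---|---|
| learning rate | 1e-4 | Adam |
| dropout | 0.5 | encoder output, training only |
| hidden units | 100/direction | |
| embedding dim | 100 | window 5 |
| epochs | 30 | with early stopping, patience 5 |
| batch size | 16 | sequences per Adam step |

Epochs, batch size and the early-stopping rule are conventions (nothing
printed fixes them); everything is surfaced in `train_config()`.

### Strict evaluation

A predicted span counts only under exact quadruple equality
⟨report, start, end, type⟩.  Empty-denominator conventions: `P := 0` when
`|S| = 0`, `R := 0` when `|G| = 0`, `F1 := 0` when `P + R = 0` — the
standard zero convention for strict NER scoring.  Overall numbers are
micro-averaged (pooled counts); macro averages are also emitted, labeled as
such.  `novel_phrases()` lists predicted surfaces that are not lexicon
entries, with frequencies — the mechanism by which the model's
generalization beyond the dictionary is made visible.

## 2. The synthetic generator

Real echocardiograph corpora cannot be redistributed, so the generator
emulates the *documented* structure of such a corpus and nothing more:

* line counts per report: shifted Poisson with means 4 (description) and 3
  (conclusion); description lines built from numeric measurement clauses
  (chamber dimensions in mm, EF percentages — with uppercase ASCII and
  spaces, so the normalization rules are actually exercised), conclusion
  lines mostly a single evidence phrase with optional short qualifiers;
* mean paragraph length ≈ 177 characters (the generator's contract tests
  check the sample mean against ±15% of that target at n = 1000);
* per-type evidence frequencies: a geometric profile (`decay = 0.78`) over
  the modeled types in their documented frequency order — only the order is
  documented, so only the order is emulated;
* novel surface variants (hyphenated grades, synonym suffixes, reordered or
  trailing qualifiers) injected with probability `injection_rate`
  (default 0.05, "rare"), flagged in the gold standard and guaranteed not
  to be lexicon entries;
* four families of challenge cases (long-dependency sentences, confusable
  grammar, out-of-distribution phrases, trailing qualifiers) available via
  `inject_error_cases()`, with per-family tags.

The central invariant is **dictionary consistency**: at
`injection_rate = 0`, FMM annotation of the generated paragraphs reproduces
the gold spans *exactly* (strict F1 = 1).  This is what makes the
end-to-end recovery experiment well-posed: a tagger trained on dictionary
labels is scored against a gold standard that the dictionary itself can
attain.  The generator achieves it constructively — filler templates are
chosen to contain no lexicon surface as a substring (a dedicated test
enforces this), and gold offsets are computed against the same normalized
layout `normalize_report()` produces.

What the generator does **not** emulate: real sonographers' orthographic
noise, true per-type frequency counts, section-order variation,
report-level duplication, or clinically coherent co-occurrence of findings.
Passing the recovery experiment therefore demonstrates that the pipeline's
machinery is correct and learnable, not that the model would attain the
same numbers on hospital text.

## 3. The scaled recovery experiment

The package's end-to-end recovery experiment trains on ~800 synthetic reports and
tests on ~200 (three replicate corpora of 1000, split 8:2), with a
desk-scale configuration: hidden size 32 per direction, learning rate 1e-3,
batch 8, at most 10 epochs with patience 3.  The architecture is unchanged;
the reduction keeps the three replicates inside a few CPU-minutes.  The
expectation is held-out strict micro-F1 ≥ 0.90 against the dictionary
annotation, and positive recall on injected novel-variant spans, against
the dictionary's structural zero.

A caveat worth stating plainly: on clean templated text the dictionary
labeling is *perfectly learnable*, so as the tagger converges its
predictions collapse onto the dictionary output and its recall on novel
variants shrinks toward zero — slightly undertrained checkpoints generalize
more.  Measured novel recall is therefore small and seed-sensitive; the
qualitative contrast (model > 0 = dictionary) is the robust finding, not
the magnitude.  On real clinical text, where dictionary labels are noisy
and contexts are diverse, the same mechanism is what surfaces genuinely new
phrases.

## 4. Known limitations

* Forward-only maximum matching (no backward or bidirectional
  disambiguation); the annotation unit is the whole merged paragraph.
* The lexicon ships only the printed subset of the full clinical
  vocabulary; the harvesting mechanism, not the vocabulary's clinical
  completeness, is the reproducible part.
* No transition masking means the CRF can emit ill-formed BIO; the repair
  rule makes this harmless for evaluation but is itself a modeling choice.
* The regex harvester's CJK-only wildcard cannot collect variants containing
  ASCII punctuation — by design, since exactly that limitation motivates
  the model layer.
* Single-threaded, CPU-scale training; paragraphs of a few hundred
  characters and corpora of a few thousand reports are the intended regime.
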